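# Multi-model PDB reading/writing and atom selection.
#
# The reader is deliberately strict: it accepts the plain ATOM/HETATM
# fixed-column dialect with MODEL/ENDMDL framing, requires identical atom
# counts and ordering across models, and rejects alternate locations other
# than '' / 'A'. Binary trajectory formats are supported through
# `register_trajectory_reader()` rather than bundled codecs.

.traj_readers <- new.env(parent = emptyenv())

#' Register a pluggable trajectory reader
#'
#' Extension point for binary trajectory formats: `reader` must be a
#' function taking a file path and returning a [trajectory()].
#'
#' @param extension file extension (without dot) the reader handles.
#' @param reader function(path) -> traj.
#' @export
register_trajectory_reader <- function(extension, reader) {
  stopifnot(is.function(reader))
  assign(tolower(extension), reader, envir = .traj_readers)
  invisible(NULL)
}

#' Read a (multi-model) PDB file as a trajectory
#'
#' Each `MODEL` becomes one trajectory frame; a file without MODEL records
#' yields a single-frame trajectory. HETATM records are accepted (ligands);
#' altLoc codes other than blank or `A` are rejected.
#'
#' @param path path to a PDB file, or a file whose extension has a reader
#'   registered via [register_trajectory_reader()].
#' @return a [trajectory()].
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (nzchar(ext) && ext != "pdb" && !is.null(.traj_readers[[ext]])) {
    return(.traj_readers[[ext]](path))
  }
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  models <- list()
  cur <- NULL
  in_model <- FALSE
  parse_atoms <- function(idx) {
    ln <- lines[idx]
    alt <- substr(ln, 17, 17)
    bad <- which(!alt %in% c(" ", "", "A"))
    if (length(bad)) {
      stop("unsupported altLoc '", alt[bad[1]], "' at line ", idx[bad[1]])
    }
    x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
    ri <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    serial <- suppressWarnings(as.integer(substr(ln, 7, 11)))
    bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z) | is.na(ri))
    if (length(bad)) {
      stop("unparsable ATOM/HETATM record at line ", idx[bad[1]], ": ",
           lines[idx[bad[1]]])
    }
    list(atoms = tibble::tibble(
      serial = serial,
      name = trimws(substr(ln, 13, 16)),
      element = trimws(substr(ln, 77, 78)),
      residue_name = trimws(substr(ln, 18, 20)),
      residue_index = ri,
      chain_id = trimws(substr(ln, 22, 22))),
      coords = cbind(x, y, z))
  }
  model_spans <- list()
  starts <- which(rec == "MODEL ")
  if (length(starts) == 0) {
    atom_idx <- which(rec %in% c("ATOM  ", "HETATM"))
    if (!length(atom_idx)) stop("no ATOM/HETATM records in ", path)
    p <- parse_atoms(atom_idx)
    return(trajectory(p$atoms, list(p$coords)))
  }
  ends <- which(rec == "ENDMDL")
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  topo <- NULL
  coords <- vector("list", length(starts))
  for (m in seq_along(starts)) {
    span <- seq(starts[m] + 1, ends[m] - 1)
    atom_idx <- span[rec[span] %in% c("ATOM  ", "HETATM")]
    p <- parse_atoms(atom_idx)
    if (is.null(topo)) {
      topo <- p$atoms
    } else if (nrow(p$atoms) != nrow(topo)) {
      stop("MODEL ", m, " has ", nrow(p$atoms), " atoms but MODEL 1 has ",
           nrow(topo))
    }
    coords[[m]] <- p$coords
  }
  trajectory(topo, coords)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  a <- traj$atoms
  fmt_atom <- function(i, xyz) {
    nm <- a$name[i]
    nm_fmt <- if (nchar(nm) <= 3) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
    sprintf("ATOM  %5d %s %-3s%2s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            a$serial[i] %% 100000, nm_fmt, a$residue_name[i], a$chain_id[i],
            a$residue_index[i], xyz[i, 1], xyz[i, 2], xyz[i, 3], a$element[i])
  }
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL %8d", f), con)
    writeLines(vapply(seq_len(nrow(a)), fmt_atom, character(1),
                      xyz = traj$coords[[f]]), con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Resolve an atom selection expression to topology indices
#'
#' Grammar: `"chain <id> [residues <i>[-<j>][,<k>...]] [names <n1>,<n2>,...]"`,
#' e.g. `"chain A residues 1-2 names C1',N9"`. Resolution is a pure function
#' of the topology (never of coordinates) and returns indices in topology
#' order; residue/name clauses restrict, never reorder.
#'
#' @param traj a [trajectory()].
#' @param selection selection string.
#' @return integer vector of 1-based atom indices into `traj$atoms`.
#' @export
resolve_selection <- function(traj, selection) {
  toks <- strsplit(trimws(selection), "\\s+")[[1]]
  if (length(toks) < 2 || toks[1] != "chain") {
    stop("selection must start with 'chain <id>': ", selection)
  }
  chain <- toks[2]
  keep <- traj$atoms$chain_id == chain
  i <- 3
  while (i <= length(toks)) {
    key <- toks[i]
    if (i + 1 > length(toks)) stop("dangling '", key, "' in selection: ", selection)
    val <- toks[i + 1]
    if (key == "residues") {
      parts <- strsplit(val, ",")[[1]]
      resids <- unlist(lapply(parts, function(p) {
        if (grepl("-", p)) {
          ab <- as.integer(strsplit(p, "-")[[1]])
          seq(ab[1], ab[2])
        } else as.integer(p)
      }))
      if (anyNA(resids)) stop("bad residue range '", val, "' in: ", selection)
      keep <- keep & traj$atoms$residue_index %in% resids
    } else if (key == "names") {
      keep <- keep & traj$atoms$name %in% strsplit(val, ",")[[1]]
    } else {
      stop("unknown selection clause '", key, "' in: ", selection)
    }
    i <- i + 2
  }
  idx <- which(keep)
  if (!length(idx)) stop("selection matched zero atoms: ", selection)
  idx
}

#' Define the ligand atom groups
#'
#' Names the functional groups of an anthraquinone-type intercalator:
#' the three fused aromatic rings A/B/C, the daunosamine sugar, the anchor
#' atoms, and the charged amine nitrogen. Ring lists must be disjoint.
#'
#' @param residue_name ligand residue name in the topology.
#' @param ring_A_atoms,ring_B_atoms,ring_C_atoms atom-name vectors (>= 3 each).
#' @param daunosamine_atoms atom-name vector for the amino-sugar moiety.
#' @param anchor_atoms atom-name vector.
#' @param amine_atom single atom name (charged N).
#' @param residue_index optional residue index, if several copies share the
#'   residue name.
#' @return object of class `ligand_definition`.
#' @export
ligand_definition <- function(residue_name, ring_A_atoms, ring_B_atoms,
                              ring_C_atoms, daunosamine_atoms,
                              anchor_atoms = character(), amine_atom = NULL,
                              residue_index = NULL) {
  rings <- list(A = ring_A_atoms, B = ring_B_atoms, C = ring_C_atoms)
  for (nm in names(rings)) {
    if (length(rings[[nm]]) < 3) stop("ring ", nm, " needs >= 3 atoms")
  }
  if (anyDuplicated(unlist(rings))) stop("ring atom lists must be disjoint")
  structure(list(residue_name = residue_name,
                 residue_index = residue_index,
                 ring_A_atoms = ring_A_atoms,
                 ring_B_atoms = ring_B_atoms,
                 ring_C_atoms = ring_C_atoms,
                 daunosamine_atoms = daunosamine_atoms,
                 anchor_atoms = anchor_atoms,
                 amine_atom = amine_atom),
            class = "ligand_definition")
}

# Topology indices of each ligand group; errors if a group resolves to
# fewer than 3 atoms (amine/anchors may be smaller).
ligand_group_idx <- function(traj, ligand) {
  sel <- traj$atoms$residue_name == ligand$residue_name
  if (!is.null(ligand$residue_index)) {
    sel <- sel & traj$atoms$residue_index == ligand$residue_index
  }
  base <- which(sel)
  if (!length(base)) stop("ligand residue ", ligand$residue_name, " not found")
  grab <- function(names, min_n) {
    idx <- base[traj$atoms$name[base] %in% names]
    if (length(idx) < min_n) {
      stop("ligand group {", paste(names, collapse = ","),
           "} resolves to ", length(idx), " atoms (need >= ", min_n, ")")
    }
    idx
  }
  list(all = base,
       ring_A = grab(ligand$ring_A_atoms, 3),
       ring_B = grab(ligand$ring_B_atoms, 3),
       ring_C = grab(ligand$ring_C_atoms, 3),
       anthraquinone = grab(c(ligand$ring_A_atoms, ligand$ring_B_atoms,
                              ligand$ring_C_atoms), 9),
       daunosamine = grab(ligand$daunosamine_atoms, 1))
}
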