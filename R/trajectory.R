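# Trajectory container: a topology table plus one coordinate matrix per frame.

#' Construct a trajectory
#'
#' @param atoms a data frame with columns `serial`, `name`, `element`,
#'   `residue_name`, `residue_index` (1-based, as in the source file),
#'   `chain_id`.
#' @param coords list of coordinate matrices, one per frame; each is
#'   `nrow(atoms)` x 3, angstrom.
#' @param times optional numeric vector of frame times in ns, strictly
#'   increasing.
#' @return an object of class `traj`.
#' @export
trajectory <- function(atoms, coords, times = NULL) {
  atoms <- tibble::as_tibble(atoms)
  needed <- c("serial", "name", "element", "residue_name", "residue_index", "chain_id")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(!nzchar(atoms$name))) stop("atom names must be non-empty")
  if (!is.list(coords)) coords <- list(coords)
  for (i in seq_along(coords)) {
    m <- coords[[i]]
    if (!is.matrix(m) || nrow(m) != nrow(atoms) || ncol(m) != 3) {
      stop("frame ", i, " does not have one 3-vector per topology atom")
    }
    if (!all(is.finite(m))) stop("frame ", i, " contains non-finite coordinates")
  }
  if (!is.null(times)) {
    if (length(times) != length(coords)) stop("times length must equal frame count")
    if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  }
  structure(list(atoms = atoms, coords = coords, times = times), class = "traj")
}

#' @export
print.traj <- function(x, ...) {
  cat(sprintf("<traj> %d atoms, %d frame(s)%s\n", nrow(x$atoms),
              length(x$coords),
              if (is.null(x$times)) "" else
                sprintf(", t = %.3g..%.3g ns", min(x$times), max(x$times))))
  invisible(x)
}

n_frames <- function(traj) length(traj$coords)

# Apply one rigid transform (rotation R then translation t) to every frame.
transform_traj <- function(traj, R, t = c(0, 0, 0)) {
  traj$coords <- lapply(traj$coords, function(m) {
    t(R %*% t(m)) + matrix(t, nrow(m), 3, byrow = TRUE)
  })
  traj
}

# Indices (topology order) of atoms in a given residue, optionally only
# the named atoms.
residue_atom_idx <- function(traj, chain_id, residue_index, names = NULL) {
  sel <- which(traj$atoms$chain_id == chain_id &
               traj$atoms$residue_index == residue_index)
  if (!is.null(names)) {
    pos <- match(names, traj$atoms$name[sel])
    if (anyNA(pos)) {
      stop("residue ", chain_id, ":", residue_index, " lacks atom(s) ",
           paste(names[is.na(pos)], collapse = ", "))
    }
    sel <- sel[pos]
  }
  sel
}

# Coordinates of a set of atom indices in one frame.
frame_coords <- function(traj, frame, idx) {
  traj$coords[[frame]][idx, , drop = FALSE]
}
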