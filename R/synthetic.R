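# Synthetic-geometry generators: idealized B-DNA duplexes with controllable
# step/pair parameters, G-tetrad stacks, planted ligand poses realizing each
# binding mode, and exact (inverse-CDF) samples from known 1-D potentials
# under harmonic umbrella biases. These are first-class, tested code: every
# downstream module is validated against geometries whose ground truth is
# known by construction.

# ---- duplex ----------------------------------------------------------------

# Global coordinates of a base template placed in a frame.
place_template <- function(tmpl, frame) {
  R <- frame_rotation(frame)
  out <- t(R %*% t(tmpl)) + matrix(frame$origin, nrow(tmpl), 3, byrow = TRUE)
  rownames(out) <- rownames(tmpl)
  out
}

# Add an O4' sugar atom giving the requested glycosidic chi (degrees).
add_o4prime <- function(coords, base, chi = 210) {
  atoms <- if (is_purine(base)) c("C4", "N9", "C1'") else c("C2", "N1", "C1'")
  o4 <- place_atom_internal(coords[atoms[1], ], coords[atoms[2], ],
                            coords[atoms[3], ], 1.42, 108, chi)
  rbind(coords, `O4'` = o4)
}

#' Build an idealized duplex trajectory
#'
#' Constructs a B-form double helix by composing the embedded standard base
#' templates along a chain of step parameters (defaults: rise 3.38 angstrom,
#' twist 36 degrees, others zero), with optional per-step and per-pair
#' parameter overrides and isotropic Gaussian coordinate noise per frame.
#' The reference strand is chain `A`, residues `1..n` (5' to 3'); the
#' complementary strand is chain `B`, residues `n+1..2n`, with residue
#' `2n+1-i` paired to reference residue `i`. Each base carries an O4'
#' pseudo-sugar atom so glycosidic states are defined (default chi 210
#' degrees, anti).
#'
#' @param sequence reference-strand sequence, 5' to 3' (e.g. `"GCGCATGCGC"`),
#'   length >= 2.
#' @param n_frames number of trajectory frames.
#' @param noise_sigma isotropic Gaussian noise sd per coordinate, angstrom.
#' @param seed integer seed for the noise stream.
#' @param step_overrides data frame with column `step_index` plus any of
#'   `shift`, `slide`, `rise`, `tilt`, `roll`, `twist`.
#' @param pair_overrides data frame with column `pair_index` plus any of
#'   `shear`, `stretch`, `stagger`, `buckle`, `propeller`, `opening`.
#' @param chi glycosidic torsion used when placing O4', degrees.
#' @return a [trajectory()]; attribute `"pairs"` holds the pair table
#'   accepted by [helical_parameters()] (also available via
#'   [duplex_pairs()]).
#' @export
build_duplex <- function(sequence, n_frames = 1, noise_sigma = 0, seed = 1,
                         step_overrides = NULL, pair_overrides = NULL,
                         chi = 210) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  n <- length(bases)
  if (n < 2) stop("sequence must have length >= 2")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  defaults <- list(shift = 0, slide = 0, rise = 3.38, tilt = 0, roll = 0, twist = 36)
  steps <- lapply(seq_len(n - 1), function(i) {
    p <- defaults
    if (!is.null(step_overrides)) {
      so <- as.data.frame(step_overrides)
      row <- so[so$step_index == i, , drop = FALSE]
      if (nrow(row) == 1) {
        for (k in intersect(names(defaults), names(row))) p[[k]] <- row[[k]]
      }
    }
    p
  })
  pair_defaults <- list(shear = 0, stretch = 0, stagger = 0,
                        buckle = 0, propeller = 0, opening = 0)
  pairp <- lapply(seq_len(n), function(i) {
    p <- pair_defaults
    if (!is.null(pair_overrides)) {
      po <- as.data.frame(pair_overrides)
      row <- po[po$pair_index == i, , drop = FALSE]
      if (nrow(row) == 1) {
        for (k in intersect(names(pair_defaults), names(row))) p[[k]] <- row[[k]]
      }
    }
    p
  })
  mids <- vector("list", n)
  mids[[1]] <- ref_frame(c(0, 0, 0), diag(3))
  for (i in seq_len(n - 1)) {
    s <- steps[[i]]
    mids[[i + 1]] <- compose_step(mids[[i]], s$shift, s$slide, s$rise,
                                  s$tilt, s$roll, s$twist)$frame
  }
  atom_rows <- list()
  coord_rows <- list()
  serial <- 0
  add_base <- function(coords, base, chain, resid) {
    nm <- rownames(coords)
    atom_rows[[length(atom_rows) + 1]] <<- tibble::tibble(
      serial = serial + seq_len(nrow(coords)),
      name = nm,
      element = substr(nm, 1, 1),
      residue_name = paste0("D", base),
      residue_index = resid,
      chain_id = chain)
    coord_rows[[length(coord_rows) + 1]] <<- coords
    serial <<- serial + nrow(coords)
  }
  placed <- vector("list", n)
  for (i in seq_len(n)) {
    pp <- pairp[[i]]
    fr <- pair_frames_from_mid(mids[[i]], pp$shear, pp$stretch, pp$stagger,
                               pp$buckle, pp$propeller, pp$opening)
    b1 <- bases[i]
    b2 <- complement_base(b1)
    c1 <- add_o4prime(place_template(base_template(b1), fr$f1), b1, chi)
    c2 <- add_o4prime(place_template(base_template(b2), flip_frame(fr$f2_flipped)),
                      b2, chi)
    placed[[i]] <- list(c1 = c1, c2 = c2, b1 = b1, b2 = b2)
  }
  for (i in seq_len(n)) add_base(placed[[i]]$c1, placed[[i]]$b1, "A", i)
  for (i in rev(seq_len(n))) {
    add_base(placed[[i]]$c2, placed[[i]]$b2, "B", 2 * n + 1 - i)
  }
  atoms <- dplyr::bind_rows(atom_rows)
  base_xyz <- do.call(rbind, coord_rows)
  colnames(base_xyz) <- c("x", "y", "z")
  rownames(base_xyz) <- NULL
  if (noise_sigma > 0) set.seed(seed)  # noiseless builds never touch the RNG
  frames <- lapply(seq_len(n_frames), function(f) {
    if (noise_sigma > 0) {
      base_xyz + matrix(stats::rnorm(length(base_xyz), 0, noise_sigma),
                        nrow(base_xyz), 3)
    } else base_xyz
  })
  tr <- trajectory(atoms, frames)
  attr(tr, "pairs") <- tibble::tibble(
    chain1 = "A", res1 = seq_len(n), base1 = bases,
    chain2 = "B", res2 = 2 * n + 1 - seq_len(n),
    base2 = vapply(bases, complement_base, character(1)))
  tr
}

#' Pair table of a synthetic duplex
#'
#' @param traj a trajectory built by [build_duplex()] or [plant_ligand()].
#' @return the pair tibble accepted by [helical_parameters()].
#' @export
duplex_pairs <- function(traj) {
  p <- attr(traj, "pairs")
  if (is.null(p)) stop("trajectory carries no pair table; supply one explicitly")
  p
}

# ---- tetrad stack ----------------------------------------------------------

#' Build a stack of G-tetrads
#'
#' Coplanar four-guanine layers in C4 arrangement, stacked along z with the
#' given rise and twist. Chain `G`, residues numbered layer-major
#' (layer 1: residues 1-4, layer 2: 5-8, ...).
#'
#' @param n_tetrads number of layers (>= 1).
#' @param rise inter-layer spacing, angstrom.
#' @param twist inter-layer rotation, degrees.
#' @param n_frames,noise_sigma,seed as in [build_duplex()].
#' @return a [trajectory()]; attribute `"tetrads"` lists the residue
#'   indices of each layer.
#' @export
build_tetrad_stack <- function(n_tetrads = 2, rise = 3.4, twist = 30,
                               n_frames = 1, noise_sigma = 0, seed = 1) {
  if (n_tetrads < 1) stop("need >= 1 tetrad")
  tmpl <- base_template("G")
  # place one guanine so its N9 sits away from the C4 axis, then replicate
  # by 90-degree rotations about z
  g0 <- sweep(tmpl, 2, c(2.2, -1.2, 0), `+`)
  atom_rows <- list()
  coord_rows <- list()
  serial <- 0
  resid <- 0
  for (layer in seq_len(n_tetrads)) {
    Rl <- rot_z((layer - 1) * twist * pi / 180)
    zoff <- c(0, 0, (layer - 1) * rise)
    for (k in 0:3) {
      resid <- resid + 1
      Rk <- Rl %*% rot_z(k * pi / 2)
      cc <- t(Rk %*% t(g0)) + matrix(zoff, nrow(g0), 3, byrow = TRUE)
      rownames(cc) <- rownames(tmpl)
      nm <- rownames(cc)
      atom_rows[[length(atom_rows) + 1]] <- tibble::tibble(
        serial = serial + seq_len(nrow(cc)),
        name = nm, element = substr(nm, 1, 1),
        residue_name = "DG", residue_index = resid, chain_id = "G")
      coord_rows[[length(coord_rows) + 1]] <- cc
      serial <- serial + nrow(cc)
    }
  }
  atoms <- dplyr::bind_rows(atom_rows)
  xyz <- do.call(rbind, coord_rows)
  colnames(xyz) <- c("x", "y", "z")
  rownames(xyz) <- NULL
  if (noise_sigma > 0) set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(f) {
    if (noise_sigma > 0) {
      xyz + matrix(stats::rnorm(length(xyz), 0, noise_sigma), nrow(xyz), 3)
    } else xyz
  })
  tr <- trajectory(atoms, frames)
  attr(tr, "tetrads") <- lapply(seq_len(n_tetrads), function(l) (l - 1) * 4 + 1:4)
  tr
}

# Tetrad frame helper for a built stack.
tetrad_frame_of <- function(traj, layer = 1, frame = 1, side_reference = NULL) {
  resids <- attr(traj, "tetrads")[[layer]]
  gc <- lapply(resids, function(ri) {
    idx <- residue_atom_idx(traj, "G", ri)
    cc <- frame_coords(traj, frame, idx)
    rownames(cc) <- traj$atoms$name[idx]
    cc
  })
  tetrad_frame(gc, side_reference = side_reference)
}

# ---- planted ligand poses --------------------------------------------------

#' A pose schedule for planting ligand binding modes
#'
#' @param mode character vector of mode labels (see [mode_levels()]).
#' @param n_frames integer vector, frames per segment.
#' @param anchor integer vector: step index for intercalated modes, pair
#'   index for stacking/groove modes (ignored for UNBOUND).
#' @param jitter_sigma per-segment pose jitter sd, angstrom (applied to the
#'   rigid ligand placement, not per atom).
#' @return tibble usable as the `schedule` of [plant_ligand()].
#' @export
pose_schedule <- function(mode, n_frames, anchor = NA_integer_,
                          jitter_sigma = 0) {
  tibble::tibble(mode = mode, n_frames = n_frames,
                 anchor = rep_len(anchor, length(mode)),
                 jitter_sigma = rep_len(jitter_sigma, length(mode)))
}

#' Plant a ligand into a synthetic duplex following a mode schedule
#'
#' Builds one duplex frame per scheduled trajectory frame and appends the
#' rigid model ligand ([ligand_template()]) posed to realize the scheduled
#' binding mode. For intercalated segments the host step's rise is opened
#' to `open_rise` for exactly those frames and restored afterwards.
#' Coordinate noise is applied after pose placement, so the schedule stays
#' the ground-truth label definition.
#'
#' @param sequence reference-strand sequence for [build_duplex()].
#' @param schedule a [pose_schedule()].
#' @param noise_sigma per-atom Gaussian noise sd, angstrom.
#' @param seed integer seed.
#' @param open_rise rise (angstrom) the host step is opened to while the
#'   ligand is intercalated (default 5.2, i.e. 0.52 nm).
#' @param stack_gap stacking height above a terminal pair, angstrom.
#' @param partial_offset in-plane offset (toward the reference strand) used
#'   for partially intercalated poses, angstrom.
#' @return a [trajectory()] including the ligand residue `LIG`; attributes:
#'   `"pairs"` (pair table), `"ligand"` (the [ligand_definition()]), and
#'   `"truth"` (tibble `frame`, `mode`, `anchor`).
#' @export
plant_ligand <- function(sequence, schedule, noise_sigma = 0, seed = 1,
                         open_rise = 5.2, stack_gap = 3.4,
                         partial_offset = 3.5) {
  lig <- ligand_template()
  total <- sum(schedule$n_frames)
  n <- nchar(sequence)
  truth <- tibble::tibble(
    frame = seq_len(total),
    mode = rep(schedule$mode, schedule$n_frames),
    anchor = rep(schedule$anchor, schedule$n_frames),
    jitter = rep(schedule$jitter_sigma, schedule$n_frames))
  base0 <- build_duplex(sequence, n_frames = 1, noise_sigma = 0)
  pairs <- duplex_pairs(base0)
  np <- nrow(pairs)
  set.seed(seed)
  coords <- vector("list", total)
  atoms <- NULL
  for (f in seq_len(total)) {
    mode <- truth$mode[f]
    anchor <- truth$anchor[f]
    jit <- truth$jitter[f]
    so <- if (mode %in% c("INTERCALATED_FULL", "INTERCALATED_PARTIAL")) {
      data.frame(step_index = anchor, rise = open_rise)
    } else NULL
    dup <- build_duplex(sequence, n_frames = 1, noise_sigma = 0,
                        step_overrides = so)
    pf <- pair_frames_for_frame(dup, pairs, 1)
    lf <- switch(
      mode,
      UNBOUND = {
        base <- pf[[max(1, min(np, ifelse(is.na(anchor), 1, anchor)))]]
        ref_frame(base$origin + 25 * base$axes[1, ], base$axes)
      },
      STACKED_TERMINAL = {
        p <- pf[[anchor]]
        side <- if (anchor == np) 1 else -1
        R <- t(frame_rotation(p) %*% rot_z(pi / 2))
        ref_frame(p$origin + side * stack_gap * p$axes[3, ], R)
      },
      INTERCALATED_FULL = {
        m <- step_mid_frame(pf[[anchor]], pf[[anchor + 1]])
        ref_frame(m$origin, t(frame_rotation(m) %*% rot_z(pi / 2)))
      },
      INTERCALATED_PARTIAL = {
        m <- step_mid_frame(pf[[anchor]], pf[[anchor + 1]])
        ref_frame(m$origin + partial_offset * m$axes[2, ],
                  t(frame_rotation(m) %*% rot_z(pi / 2)))
      },
      MINOR_GROOVE_EMBEDDED = {
        p <- pf[[anchor]]
        R <- t(frame_rotation(p) %*% rot_y(60 * pi / 180))
        ref_frame(p$origin - 5 * p$axes[1, ], R)
      },
      MAJOR_GROOVE_CONTACT = {
        p <- pf[[anchor]]
        R <- t(frame_rotation(p) %*% rot_y(60 * pi / 180))
        ref_frame(p$origin + 5 * p$axes[1, ], R)
      },
      stop("unknown scheduled mode: ", mode))
    if (jit > 0) {
      lf <- ref_frame(lf$origin + stats::rnorm(3, 0, jit), lf$axes)
    }
    lcoords <- place_template(lig$coords, lf)
    full <- rbind(dup$coords[[1]], lcoords)
    if (noise_sigma > 0) {
      full <- full + matrix(stats::rnorm(length(full), 0, noise_sigma),
                            nrow(full), 3)
    }
    rownames(full) <- NULL
    coords[[f]] <- full
    if (is.null(atoms)) {
      lat <- tibble::tibble(
        serial = nrow(dup$atoms) + seq_len(nrow(lig$coords)),
        name = rownames(lig$coords),
        element = ifelse(substr(rownames(lig$coords), 1, 1) == "N", "N", "C"),
        residue_name = "LIG",
        residue_index = max(dup$atoms$residue_index) + 1,
        chain_id = "L")
      atoms <- dplyr::bind_rows(dup$atoms, lat)
    }
  }
  tr <- trajectory(atoms, coords)
  attr(tr, "pairs") <- pairs
  attr(tr, "ligand") <- lig$definition
  attr(tr, "truth") <- truth[, c("frame", "mode", "anchor")]
  tr
}

# Mid frame of a step (between two consecutive pair frames).
step_mid_frame <- function(p1, p2) decompose_frames(p1, p2)$mid

# ---- exact biased sampling -------------------------------------------------

#' Exact samples from a potential under harmonic umbrella biases
#'
#' Draws independent samples from the biased Boltzmann density
#' `exp(-(U(x) + K/2 (x - x_j)^2) / kT)` for each window center `x_j` by
#' inverse-CDF sampling on a fine grid — no Markov chain, hence no
#' autocorrelation. Synthetic times are attached at uniform spacing so the
#' production-time filter is exercised downstream.
#'
#' @param U function of x (nm) returning energy in kcal/mol, or a two-column
#'   matrix/data frame (x, U) that will be interpolated.
#' @param centers window centers, nm.
#' @param k spring constant, kJ mol^-1 nm^-2 (the conventional per-nm^2
#'   harmonic constant).
#' @param n_per_window samples per window.
#' @param temperature kelvin.
#' @param seed integer seed.
#' @param total_time_ns synthetic duration of each window, ns.
#' @param grid_n inverse-CDF grid resolution.
#' @param xlim sampling range, nm (defaults to the span of the centers
#'   padded by 5 bias standard deviations).
#' @return list of `window_table` objects (as from [read_window_tables()]).
#' @export
sample_biased <- function(U, centers, k = 2000, n_per_window = 2000,
                          temperature = 298, seed = 1, total_time_ns = 50,
                          grid_n = 20001, xlim = NULL) {
  kT <- boltzmann_kcal(temperature)
  k_kcal <- k * KJ_TO_KCAL
  Ufun <- if (is.function(U)) U else {
    tab <- as.matrix(U)
    stats::approxfun(tab[, 1], tab[, 2], rule = 2)
  }
  sd_bias <- sqrt(kT / k_kcal)
  if (is.null(xlim)) xlim <- range(centers) + c(-5, 5) * sd_bias
  xg <- seq(xlim[1], xlim[2], length.out = grid_n)
  Ug <- Ufun(xg)
  set.seed(seed)
  lapply(centers, function(ctr) {
    e <- Ug + 0.5 * k_kcal * (xg - ctr)^2
    w <- exp(-(e - min(e)) / kT)
    # center each grid node's mass on the node (cumsum alone would spread
    # it over the cell to its left, a half-cell systematic shift that the
    # stiff umbrella biases would integrate into a visible PMF drift)
    cdf <- cumsum(w) - w / 2
    cdf <- cdf / sum(w)
    u <- stats::runif(n_per_window)
    xs <- stats::approx(cdf, xg, xout = u, rule = 2, ties = "ordered")$y
    structure(list(center = ctr, k = k,
                   samples = tibble::tibble(
                     time_ns = seq_len(n_per_window) * total_time_ns / n_per_window,
                     cv_nm = xs),
                   source = NA_character_),
              class = "window_table")
  })
}

#' Analytic double-well potential used as a validation fixture
#'
#' A smooth 1-D potential on the distance axis with a deep bound minimum, a
#' barrier, a shallow secondary minimum, and a flat bulk plateau at zero —
#' the landmark arithmetic (well depths and barrier height) is fixed by the
#' construction, so free-energy estimators can be checked against exact
#' ground truth.
#'
#' The shape is a monotone Hermite spline through landmark control points,
#' so the watershed between the two minima is exactly the stated saddle (no
#' spurious shoulders): minimum `-depth` at `x0`, saddle
#' `barrier - shallow_depth` at `xb`, minimum `-shallow_depth` at `x1`, and
#' a flat bulk plateau at 0 beyond 2.8 nm. A steep repulsive wall rises
#' below 0.18 nm.
#'
#' @param x CV values, nm.
#' @param depth deep-well depth, kcal/mol (at `x0`).
#' @param shallow_depth secondary-well depth, kcal/mol.
#' @param barrier barrier height above the shallow well, kcal/mol (the
#'   saddle sits at `barrier - shallow_depth`).
#' @param x0,x1 well positions, nm.
#' @param xb saddle position, nm.
#' @return energies, kcal/mol (0 in bulk).
#' @export
double_well_potential <- function(x, depth = 9, shallow_depth = 5.7,
                                  barrier = 3.2, x0 = 0.43, x1 = 2.0,
                                  xb = 1.1) {
  saddle <- barrier - shallow_depth  # absolute energy at the barrier top
  # piecewise monotone segments stitched at the landmarks; each segment is
  # a Fritsch-Carlson monotone interpolant of monotone data, so no segment
  # overshoots and the watershed is exactly the saddle value
  segs <- list(
    list(px = c(0.18, (0.18 + x0) / 2, x0),
         pu = c(12, (12 - depth) / 2, -depth)),
    list(px = c(x0, (x0 + xb) / 2, xb),
         pu = c(-depth, (-depth + saddle) / 2, saddle)),
    list(px = c(xb, (xb + x1) / 2, x1),
         pu = c(saddle, (saddle - shallow_depth) / 2, -shallow_depth)),
    list(px = c(x1, 2.3, 2.6, 2.8, 3.3),
         pu = c(-shallow_depth, -shallow_depth / 2, -0.5, 0, 0)))
  out <- numeric(length(x))
  lo <- segs[[1]]$px[1]
  hi <- segs[[length(segs)]]$px[length(segs[[length(segs)]]$px)]
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    fn <- stats::splinefun(s$px, s$pu, method = "monoH.FC")
    a <- s$px[1]; b <- s$px[length(s$px)]
    sel <- if (i == 1) x <= b else if (i == length(segs)) x > a else
      x > a & x <= b
    out[sel] <- fn(x[sel])
  }
  # linear walls outside the range
  out[x < lo] <- 12 + (lo - x[x < lo]) * 120
  out[x > hi] <- 0
  out
}
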