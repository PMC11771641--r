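# Mid-frame decomposition of the relative geometry of two reference
# frames into the six rigid-body helical parameters, and its exact
# inverse (used by the synthetic builders). The scheme is the CEHS
# mid-frame convention used by the 3DNA family of tools, so step values
# are comparable to those tools' rise/twist output.

# Core decomposition: rotations about the mid-frame z / y / x axes and
# translations along mid-frame x / y / z. Returns values in degrees and
# angstrom plus the mid frame itself.
decompose_frames <- function(f1, f2) {
  T1 <- frame_rotation(f1); T2 <- frame_rotation(f2)
  z1 <- T1[, 3]; z2 <- T2[, 3]
  cz <- cross3(z1, z2)
  if (vnorm(cz) < 1e-12) {
    hinge <- T1[, 2]
    gamma <- if (sum(z1 * z2) > 0) 0 else pi
    if (gamma > 0) stop("antiparallel z-axes: decomposition undefined")
  } else {
    hinge <- unit(cz)
    gamma <- acos(max(-1, min(1, sum(z1 * z2))))
  }
  A1 <- rotation_about(hinge, gamma / 2) %*% T1
  A2 <- rotation_about(hinge, -gamma / 2) %*% T2
  zm <- A1[, 3]
  twist <- signed_angle(A1[, 1], A2[, 1], zm)
  ym <- A1[, 2] + A2[, 2]
  ym <- ym - sum(ym * zm) * zm
  if (vnorm(ym) < 1e-12) stop("twist of 180 degrees: mid-frame undefined")
  ym <- unit(ym)
  xm <- cross3(ym, zm)
  Tm <- cbind(xm, ym, zm)
  phi <- signed_angle(hinge, ym, zm)
  r2d <- 180 / pi
  d <- as.numeric(t(Tm) %*% (f2$origin - f1$origin))
  list(x = d[1], y = d[2], z = d[3],
       about_x = gamma * sin(phi) * r2d,
       about_y = gamma * cos(phi) * r2d,
       about_z = twist * r2d,
       mid = frame_from_rotation(Tm, (f1$origin + f2$origin) / 2))
}

# Exact inverse of decompose_frames: given frame f1 and the six values,
# construct f2 (and the mid frame).
compose_frames <- function(f1, x, y, z, about_x, about_y, about_z) {
  d2r <- pi / 180
  tau <- about_x * d2r; rho <- about_y * d2r; om <- about_z * d2r
  gamma <- sqrt(tau^2 + rho^2)
  phi <- atan2(tau, rho)
  T1 <- frame_rotation(f1)
  T2 <- T1 %*% rot_z(om / 2 - phi) %*% rot_y(gamma) %*% rot_z(om / 2 + phi)
  Tm <- T1 %*% rot_z(om / 2 - phi) %*% rot_y(gamma / 2) %*% rot_z(phi)
  o2 <- f1$origin + as.numeric(Tm %*% c(x, y, z))
  list(f2 = frame_from_rotation(T2, o2),
       mid = frame_from_rotation(Tm, (f1$origin + o2) / 2))
}

#' Inter-base-pair step parameters
#'
#' Decomposes the relative geometry of two consecutive base-pair frames
#' (5' to 3' on the reference strand) into shift, slide, rise (angstrom)
#' and tilt, roll, twist (degrees) about the mid-frame axes.
#'
#' @param p1,p2 consecutive pair frames ([ref_frame()]).
#' @return named list: `shift`, `slide`, `rise`, `tilt`, `roll`, `twist`.
#' @export
#' @examples
#' f1 <- ref_frame(c(0, 0, 0), diag(3))
#' f2 <- compose_step(f1, rise = 3.38, twist = 36)$frame
#' step_parameters(f1, f2)
step_parameters <- function(p1, p2) {
  d <- decompose_frames(p1, p2)
  list(shift = d$x, slide = d$y, rise = d$z,
       tilt = d$about_x, roll = d$about_y, twist = d$about_z)
}

#' Compose a step: build the next pair frame from step parameters
#'
#' Exact inverse of [step_parameters()] (used to construct idealized
#' helices and in round-trip validation).
#'
#' @param p1 starting pair frame.
#' @param shift,slide,rise angstrom.
#' @param tilt,roll,twist degrees.
#' @return list with `frame` (the next pair frame) and `mid` (the step
#'   mid-frame).
#' @export
compose_step <- function(p1, shift = 0, slide = 0, rise = 3.38,
                         tilt = 0, roll = 0, twist = 36) {
  cf <- compose_frames(p1, shift, slide, rise, tilt, roll, twist)
  list(frame = cf$f2, mid = cf$mid)
}

#' Intra-base-pair parameters
#'
#' Same mid-frame decomposition as [step_parameters()] with the intra-pair
#' naming: displacement (shear, stretch, stagger) along mid-frame x, y, z
#' and rotations buckle (x), propeller (y), opening (z). `f2_flipped` is
#' the complementary base frame after [flip_frame()].
#'
#' @param f1 reference-strand base frame.
#' @param f2_flipped flipped complementary base frame.
#' @return named list: `shear`, `stretch`, `stagger`, `buckle`,
#'   `propeller`, `opening`.
#' @export
pair_parameters <- function(f1, f2_flipped) {
  d <- decompose_frames(f1, f2_flipped)
  list(shear = d$x, stretch = d$y, stagger = d$z,
       buckle = d$about_x, propeller = d$about_y, opening = d$about_z)
}

# Build the two base frames of a pair from its mid frame and pair
# parameters (half forward, half backward) — inverse of pair_parameters
# about the mid frame.
pair_frames_from_mid <- function(mid, shear = 0, stretch = 0, stagger = 0,
                                 buckle = 0, propeller = 0, opening = 0) {
  Tm <- frame_rotation(mid)
  half <- function(s) {
    compose_frames(frame_from_rotation(Tm, mid$origin),
                   s * shear / 2, s * stretch / 2, s * stagger / 2,
                   s * buckle / 2, s * propeller / 2, s * opening / 2)$f2
  }
  f2 <- half(+1)
  f1 <- half(-1)
  # mid frame of (f1, f2) is `mid` by symmetry of the decomposition
  list(f1 = f1, f2_flipped = f2)
}

#' Per-frame helical parameters of a duplex trajectory
#'
#' Fits base frames for every pair in `pairs`, forms pair frames, and
#' returns tidy per-frame tables of step and pair parameters plus
#' glycosidic states.
#'
#' @param traj a [trajectory()].
#' @param pairs a data frame with one row per base pair in 5' to 3' order
#'   of the reference strand: columns `chain1`, `res1`, `base1`, `chain2`,
#'   `res2`, `base2` (source-file numbering). Explicit pairing is
#'   preferred; [detect_pairs()] offers a geometric fallback.
#' @param frames optional integer vector of trajectory frames (default all).
#' @return list of tibbles: `steps` (frame, step_index, step_id, shift_A,
#'   slide_A, rise_A, tilt_deg, roll_deg, twist_deg), `pairs` (frame,
#'   pair_index, pair_id, shear_A, stretch_A, stagger_A, buckle_deg,
#'   propeller_deg, opening_deg, fit_rmsd_A), and `chi` (frame, chain,
#'   residue_index, base, chi_deg, state).
#' @export
helical_parameters <- function(traj, pairs, frames = NULL) {
  pairs <- as.data.frame(pairs)
  frames <- frames %||% seq_len(n_frames(traj))
  np <- nrow(pairs)
  if (np < 1) stop("need at least one base pair")
  idx1 <- lapply(seq_len(np), function(i)
    residue_atom_idx(traj, pairs$chain1[i], pairs$res1[i]))
  idx2 <- lapply(seq_len(np), function(i)
    residue_atom_idx(traj, pairs$chain2[i], pairs$res2[i]))
  pair_ids <- paste0(pairs$res1, ":", pairs$res2)
  step_ids <- if (np > 1) paste(pair_ids[-np], pair_ids[-1], sep = "->") else character()

  steps_l <- vector("list", length(frames))
  pairs_l <- vector("list", length(frames))
  chi_l <- vector("list", length(frames))
  has_chi <- function(idx) all(c("O4'", "C1'") %in% traj$atoms$name[idx])
  for (fi in seq_along(frames)) {
    fr <- frames[fi]
    pf <- vector("list", np)
    prow <- vector("list", np)
    chirow <- list()
    for (i in seq_len(np)) {
      c1 <- frame_coords(traj, fr, idx1[[i]])
      rownames(c1) <- traj$atoms$name[idx1[[i]]]
      c2 <- frame_coords(traj, fr, idx2[[i]])
      rownames(c2) <- traj$atoms$name[idx2[[i]]]
      f1 <- base_frame(c1, pairs$base1[i])
      f2 <- flip_frame(base_frame(c2, pairs$base2[i]))
      pf[[i]] <- pair_frame(f1, f2)
      pp <- pair_parameters(f1, f2)
      prow[[i]] <- tibble::tibble(
        frame = fr, pair_index = i, pair_id = pair_ids[i],
        shear_A = pp$shear, stretch_A = pp$stretch, stagger_A = pp$stagger,
        buckle_deg = pp$buckle, propeller_deg = pp$propeller,
        opening_deg = pp$opening,
        fit_rmsd_A = max(attr(f1, "fit_rmsd"), attr(flip_frame(f2), "fit_rmsd")))
      if (has_chi(idx1[[i]])) {
        cs <- chi_state(c1, pairs$base1[i])
        chirow[[length(chirow) + 1]] <- tibble::tibble(
          frame = fr, chain = pairs$chain1[i], residue_index = pairs$res1[i],
          base = pairs$base1[i], chi_deg = cs$chi, state = cs$state)
      }
      if (has_chi(idx2[[i]])) {
        cs <- chi_state(c2, pairs$base2[i])
        chirow[[length(chirow) + 1]] <- tibble::tibble(
          frame = fr, chain = pairs$chain2[i], residue_index = pairs$res2[i],
          base = pairs$base2[i], chi_deg = cs$chi, state = cs$state)
      }
    }
    if (np > 1) {
      srow <- vector("list", np - 1)
      for (i in seq_len(np - 1)) {
        sp <- step_parameters(pf[[i]], pf[[i + 1]])
        srow[[i]] <- tibble::tibble(
          frame = fr, step_index = i, step_id = step_ids[i],
          shift_A = sp$shift, slide_A = sp$slide, rise_A = sp$rise,
          tilt_deg = sp$tilt, roll_deg = sp$roll, twist_deg = sp$twist)
      }
      steps_l[[fi]] <- dplyr::bind_rows(srow)
    }
    pairs_l[[fi]] <- dplyr::bind_rows(prow)
    chi_l[[fi]] <- if (length(chirow)) dplyr::bind_rows(chirow) else NULL
  }
  list(steps = dplyr::bind_rows(steps_l),
       pairs = dplyr::bind_rows(pairs_l),
       chi = dplyr::bind_rows(chi_l))
}

# Pair frames for every pair of `pairs` in one trajectory frame; returns a
# list of ref_frame. Shared by the pose and mode modules.
pair_frames_for_frame <- function(traj, pairs, frame) {
  pairs <- as.data.frame(pairs)
  lapply(seq_len(nrow(pairs)), function(i) {
    i1 <- residue_atom_idx(traj, pairs$chain1[i], pairs$res1[i])
    i2 <- residue_atom_idx(traj, pairs$chain2[i], pairs$res2[i])
    c1 <- frame_coords(traj, frame, i1); rownames(c1) <- traj$atoms$name[i1]
    c2 <- frame_coords(traj, frame, i2); rownames(c2) <- traj$atoms$name[i2]
    pair_frame(base_frame(c1, pairs$base1[i]),
               flip_frame(base_frame(c2, pairs$base2[i])))
  })
}

#' Detect Watson-Crick pairs geometrically
#'
#' Fallback when no explicit pair list is supplied: pairs bases whose
#' C1'-C1' distance is below 12 angstrom and whose (flipped) frame z-axes
#' agree within 65 degrees, greedily by distance. Deformed nucleosomal
#' pairs defeat naive detection, so an explicit list should be preferred.
#'
#' @param traj a [trajectory()].
#' @param chain1,chain2 chain identifiers of the two strands.
#' @param frame trajectory frame used for geometry (default 1).
#' @return tibble with columns `chain1`, `res1`, `base1`, `chain2`, `res2`,
#'   `base2`.
#' @export
detect_pairs <- function(traj, chain1, chain2, frame = 1) {
  a <- traj$atoms
  res_of <- function(ch) {
    u <- unique(a$residue_index[a$chain_id == ch])
    sort(u)
  }
  base_of <- function(ch, ri) a$residue_name[a$chain_id == ch & a$residue_index == ri][1]
  r1 <- res_of(chain1); r2 <- res_of(chain2)
  get_c1p <- function(ch, ri) {
    idx <- residue_atom_idx(traj, ch, ri, "C1'")
    frame_coords(traj, frame, idx)[1, ]
  }
  frame_of <- function(ch, ri) {
    idx <- residue_atom_idx(traj, ch, ri)
    cc <- frame_coords(traj, frame, idx); rownames(cc) <- a$name[idx]
    base_frame(cc, base_of(ch, ri))
  }
  out <- list()
  used <- integer()
  for (i in r1) {
    d <- vapply(r2, function(j) vnorm(get_c1p(chain1, i) - get_c1p(chain2, j)), numeric(1))
    d[r2 %in% used] <- Inf
    ord <- order(d)
    for (j in r2[ord]) {
      if (!is.finite(d[match(j, r2)]) || d[match(j, r2)] >= 12) break
      fz1 <- frame_of(chain1, i)$axes[3, ]
      fz2 <- flip_frame(frame_of(chain2, j))$axes[3, ]
      if (sum(fz1 * fz2) >= cos(65 * pi / 180)) {
        out[[length(out) + 1]] <- tibble::tibble(
          chain1 = chain1, res1 = i, base1 = base_of(chain1, i),
          chain2 = chain2, res2 = j, base2 = base_of(chain2, j))
        used <- c(used, j)
        break
      }
    }
  }
  if (!length(out)) stop("no pairs detected between chains ", chain1, " and ", chain2)
  dplyr::bind_rows(out)
}
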