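# Per-frame binding-mode classification and episode segmentation.
#
# The label set formalizes the observed interaction taxonomy for a planar
# intercalator on duplex DNA / G-tetrad platforms: terminal stacking,
# tetrad stacking, full and partial intercalation, minor-groove embedding,
# major-groove contact, unbound. The geometric thresholds are package
# conventions (the canonical 3.4 angstrom stacking distance with slack),
# all exposed through `mode_thresholds()`.

#' Mode label levels
#'
#' @return character vector of the seven binding-mode labels in cascade
#'   order.
#' @export
mode_levels <- function() {
  c("INTERCALATED_FULL", "INTERCALATED_PARTIAL", "STACKED_TERMINAL",
    "TETRAD_STACKED", "MINOR_GROOVE_EMBEDDED", "MAJOR_GROOVE_CONTACT",
    "UNBOUND")
}

#' Geometric thresholds of the mode classifier
#'
#' @param stack_gap_max maximum plane-to-plane gap for stacking contact,
#'   angstrom.
#' @param stack_gap_min minimum gap for one-sided terminal/tetrad stacking,
#'   angstrom.
#' @param plane_angle_max maximum angle between ligand and platform plane
#'   normals, degrees.
#' @param groove_radius maximum distance from the helical-axis polyline for
#'   groove modes, angstrom.
#' @param unbound_cutoff minimum ligand-DNA heavy-atom distance that forces
#'   UNBOUND, angstrom.
#' @param footprint_inflation outward inflation of the base-footprint
#'   convex hull, angstrom.
#' @return named list of thresholds.
#' @export
mode_thresholds <- function(stack_gap_max = 4.5, stack_gap_min = 3.0,
                            plane_angle_max = 30, groove_radius = 7,
                            unbound_cutoff = 5, footprint_inflation = 1.0) {
  list(stack_gap_max = stack_gap_max, stack_gap_min = stack_gap_min,
       plane_angle_max = plane_angle_max, groove_radius = groove_radius,
       unbound_cutoff = unbound_cutoff,
       footprint_inflation = footprint_inflation)
}

# Best-fit plane normal of a point cloud (unit vector).
plane_normal <- function(pts) {
  sv <- svd(sweep(pts, 2, colMeans(pts)))
  unit(sv$v[, 3])
}

# Is 2-D point p inside the convex hull of pts (n x 2) inflated by `infl`?
in_inflated_hull <- function(p, pts, infl) {
  h <- grDevices::chull(pts)
  poly <- pts[h, , drop = FALSE]
  if (nrow(poly) >= 3 &&
      pracma::inpolygon(p[1], p[2], poly[, 1], poly[, 2], boundary = TRUE)) {
    return(TRUE)
  }
  # within `infl` of the hull boundary
  m <- nrow(poly)
  for (i in seq_len(m)) {
    a <- c(poly[i, ], 0); b <- c(poly[i %% m + 1, ], 0)
    if (point_segment_distance(c(p, 0), a, b) <= infl) return(TRUE)
  }
  FALSE
}

# In-plane (frame) coordinates of the heavy atoms of one strand's bases at
# the two pairs flanking a step.
strand_footprint <- function(traj, frame, pairs, step, strand, mid) {
  rows <- c(step, step + 1)
  pts <- do.call(rbind, lapply(rows, function(i) {
    ch <- if (strand == 1) pairs$chain1[i] else pairs$chain2[i]
    ri <- if (strand == 1) pairs$res1[i] else pairs$res2[i]
    idx <- residue_atom_idx(traj, ch, ri)
    frame_coords(traj, frame, idx)
  }))
  to_frame(mid, pts)[, 1:2, drop = FALSE]
}

classify_one <- function(traj, frame, grp, pairs, pf, terminal_pairs,
                         tetrad_frames, th, dna_idx) {
  lig_xyz <- frame_coords(traj, frame, grp$all)
  aq_xyz <- frame_coords(traj, frame, grp$anthraquinone)
  g <- colMeans(aq_xyz)
  lig_normal <- plane_normal(aq_xyz)
  # unbound override: nearest ligand-DNA heavy-atom distance
  dna_xyz <- frame_coords(traj, frame, dna_idx)
  dmin <- sqrt(min(outer(rowSums(lig_xyz^2), rowSums(dna_xyz^2), `+`) -
                   2 * lig_xyz %*% t(dna_xyz)))
  if (dmin > th$unbound_cutoff) {
    return(list(label = "UNBOUND", anchor = NA_integer_, min_dist = dmin))
  }
  np <- length(pf)
  plane_angle_ok <- function(zaxis) {
    ang <- acos(min(1, abs(sum(lig_normal * zaxis)))) * 180 / pi
    ang <= th$plane_angle_max
  }
  ring_centers <- function(mid) {
    rbind(as.numeric(to_frame(mid, colMeans(frame_coords(traj, frame, grp$ring_A)))),
          as.numeric(to_frame(mid, colMeans(frame_coords(traj, frame, grp$ring_B)))),
          as.numeric(to_frame(mid, colMeans(frame_coords(traj, frame, grp$ring_C)))))
  }
  # (1)/(2) intercalation between consecutive pair planes
  if (np >= 2) {
    for (s in seq_len(np - 1)) {
      zlo <- to_frame(pf[[s]], g)[3]
      zhi <- to_frame(pf[[s + 1]], g)[3]
      if (!(zlo > 0 && zhi < 0)) next
      if (zlo > th$stack_gap_max || -zhi > th$stack_gap_max) next
      mid <- step_mid_frame(pf[[s]], pf[[s + 1]])
      if (!plane_angle_ok(mid$axes[3, ])) next
      rc <- ring_centers(mid)[, 1:2, drop = FALSE]
      ov <- vapply(1:2, function(strand) {
        fp <- strand_footprint(traj, frame, pairs, s, strand, mid)
        any(apply(rc, 1, in_inflated_hull, pts = fp,
                  infl = th$footprint_inflation))
      }, logical(1))
      if (all(ov)) {
        return(list(label = "INTERCALATED_FULL", anchor = s, min_dist = dmin))
      }
      if (any(ov)) {
        return(list(label = "INTERCALATED_PARTIAL", anchor = s, min_dist = dmin))
      }
    }
  }
  # (3) one-sided stacking on a terminal pair or a tetrad
  stack_on <- function(platform_frame, footprint_pts) {
    z <- to_frame(platform_frame, g)[3]
    if (abs(z) < th$stack_gap_min || abs(z) > th$stack_gap_max) return(FALSE)
    if (!plane_angle_ok(platform_frame$axes[3, ])) return(FALSE)
    p2 <- as.numeric(to_frame(platform_frame, g))[1:2]
    in_inflated_hull(p2, footprint_pts, th$footprint_inflation)
  }
  for (p in terminal_pairs) {
    idx <- c(residue_atom_idx(traj, pairs$chain1[p], pairs$res1[p]),
             residue_atom_idx(traj, pairs$chain2[p], pairs$res2[p]))
    fp <- to_frame(pf[[p]], frame_coords(traj, frame, idx))[, 1:2, drop = FALSE]
    if (stack_on(pf[[p]], fp)) {
      return(list(label = "STACKED_TERMINAL", anchor = p, min_dist = dmin))
    }
  }
  if (!is.null(tetrad_frames)) {
    for (ti in seq_along(tetrad_frames)) {
      tf <- tetrad_frames[[ti]]
      fp_pts <- to_frame(tf, dna_xyz)[, 1:2, drop = FALSE]
      if (stack_on(tf, fp_pts)) {
        return(list(label = "TETRAD_STACKED", anchor = ti, min_dist = dmin))
      }
    }
  }
  # (4)/(5) groove modes: near the helical-axis polyline, side by the
  # x-axis sign of the nearest pair frame (x points to the major groove)
  if (np >= 1) {
    origins <- do.call(rbind, lapply(pf, `[[`, "origin"))
    if (np >= 2) {
      dax <- min(vapply(seq_len(np - 1), function(i) {
        point_segment_distance(g, origins[i, ], origins[i + 1, ])
      }, numeric(1)))
    } else {
      dax <- vnorm(g - origins[1, ])
    }
    if (dax <= th$groove_radius) {
      nearest <- which.min(rowSums(sweep(origins, 2, g)^2))
      xloc <- to_frame(pf[[nearest]], g)[1]
      lab <- if (xloc < 0) "MINOR_GROOVE_EMBEDDED" else "MAJOR_GROOVE_CONTACT"
      return(list(label = lab, anchor = nearest, min_dist = dmin))
    }
  }
  list(label = "UNBOUND", anchor = NA_integer_, min_dist = dmin)
}

#' Classify ligand binding modes per frame
#'
#' Decision cascade (first match wins): full intercalation between two
#' consecutive pair planes with stacking contact on both sides and ring
#' centers overlapping both strand footprints; partial intercalation (one
#' strand only); one-sided stacking on a terminal pair or tetrad; groove
#' modes by proximity to the helical-axis polyline with the side given by
#' the pair-frame x-axis sign; else unbound. A nearest ligand-DNA
#' heavy-atom distance above the unbound cutoff forces UNBOUND regardless.
#'
#' @param traj a [trajectory()].
#' @param ligand a [ligand_definition()] (default: the one attached by
#'   [plant_ligand()]).
#' @param pairs pair table (default: attached by the synthetic builder).
#' @param frames trajectory frames to classify (default all).
#' @param terminal_pairs indices (into `pairs`) of the terminal pairs
#'   (default first and last).
#' @param tetrad_frames optional list of tetrad [ref_frame()]s, one per
#'   stackable tetrad platform.
#' @param thresholds a [mode_thresholds()] list.
#' @return tibble: `frame`, `label`, `anchor` (step index for intercalated
#'   modes, pair index for stacking/groove, tetrad index for
#'   TETRAD_STACKED, NA for UNBOUND), `min_dist_A`.
#' @export
classify_modes <- function(traj, ligand = NULL, pairs = NULL, frames = NULL,
                           terminal_pairs = NULL, tetrad_frames = NULL,
                           thresholds = mode_thresholds()) {
  ligand <- ligand %||% attr(traj, "ligand")
  if (is.null(ligand)) stop("no ligand definition supplied or attached")
  pairs <- pairs %||% attr(traj, "pairs")
  if (is.null(pairs) && is.null(tetrad_frames)) {
    stop("no pair table supplied or attached, and no tetrad frames given")
  }
  frames <- frames %||% seq_len(n_frames(traj))
  grp <- ligand_group_idx(traj, ligand)
  dna_idx <- setdiff(seq_len(nrow(traj$atoms)), grp$all)
  if (!is.null(pairs)) {
    pairs <- as.data.frame(pairs)
    terminal_pairs <- terminal_pairs %||% c(1, nrow(pairs))
  }
  rows <- lapply(frames, function(fr) {
    pf <- if (is.null(pairs)) list() else pair_frames_for_frame(traj, pairs, fr)
    if (!length(pf) && is.null(tetrad_frames)) {
      stop("no pair frames available for frame ", fr)
    }
    tf <- if (is.function(tetrad_frames)) tetrad_frames(fr) else tetrad_frames
    r <- classify_one(traj, fr, grp, pairs, pf, terminal_pairs, tf,
                      thresholds, dna_idx)
    tibble::tibble(frame = fr, label = r$label, anchor = r$anchor,
                   min_dist_A = r$min_dist)
  })
  dplyr::bind_rows(rows)
}

#' Segment per-frame labels into mode episodes
#'
#' Majority-smooths the label sequence with a centered window of
#' `min_duration` frames (ties broken toward the previous smoothed label),
#' then run-length encodes; episodes shorter than `min_duration` are
#' absorbed into the flanking episode (ties toward the preceding one).
#' Episodes tile the trajectory without overlap.
#'
#' @param labels character vector of per-frame labels, or the tibble from
#'   [classify_modes()].
#' @param min_duration minimum episode length, frames.
#' @return tibble: `label`, `first_frame`, `last_frame`, `duration`.
#' @export
segment_modes <- function(labels, min_duration = 1) {
  if (is.data.frame(labels)) labels <- labels$label
  n <- length(labels)
  if (!n) stop("empty label sequence")
  if (min_duration > 1) {
    half <- floor(min_duration / 2)
    sm <- labels
    for (i in seq_len(n)) {
      w <- labels[max(1, i - half):min(n, i + half)]
      tab <- table(w)
      best <- names(tab)[tab == max(tab)]
      if (length(best) > 1) {
        prev <- if (i > 1) sm[i - 1] else labels[i]
        sm[i] <- if (prev %in% best) prev else best[1]
      } else {
        sm[i] <- best
      }
    }
    labels <- sm
  }
  rle_ <- rle(labels)
  repeat {
    short <- which(rle_$lengths < min_duration)
    short <- short[!(short == 1 & length(rle_$lengths) == 1)]
    if (!length(short)) break
    i <- short[1]
    if (i == 1) {
      rle_$values[1] <- rle_$values[2]
    } else {
      rle_$values[i] <- rle_$values[i - 1]  # tie toward the preceding episode
    }
    rle_ <- rle(inverse.rle(rle_))
  }
  ends <- cumsum(rle_$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  tibble::tibble(label = rle_$values, first_frame = starts,
                 last_frame = ends, duration = rle_$lengths)
}

#' Ensemble mode fractions
#'
#' Final-state fraction (share of trajectories whose last episode carries
#' the mode) and total-residence fraction (share of all frames) per mode,
#' with explicit denominators.
#'
#' @param episodes_list list of episode tibbles (one per trajectory, from
#'   [segment_modes()]).
#' @return tibble: `label`, `final_state_fraction`, `residence_fraction`,
#'   `n_trajectories`, `n_frames_total`.
#' @export
mode_fractions <- function(episodes_list) {
  if (!length(episodes_list)) stop("empty trajectory ensemble")
  finals <- vapply(episodes_list, function(e) e$label[nrow(e)], character(1))
  frames_by <- lapply(episodes_list, function(e) {
    stats::setNames(e$duration, e$label)
  })
  all_labels <- sort(unique(c(finals, unlist(lapply(frames_by, names)))))
  total_frames <- sum(unlist(frames_by))
  rows <- lapply(all_labels, function(l) {
    tibble::tibble(
      label = l,
      final_state_fraction = mean(finals == l),
      residence_fraction = sum(unlist(lapply(frames_by, function(fb)
        sum(fb[names(fb) == l])))) / total_frames,
      n_trajectories = length(episodes_list),
      n_frames_total = total_frames)
  })
  dplyr::bind_rows(rows)
}
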