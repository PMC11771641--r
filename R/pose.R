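# Ligand pose collective variables relative to a base-pair or tetrad
# reference frame, and their aggregation into spatial density /
# orientation-preference maps.
#
# The five CVs per frame: in-plane displacement (dx, dy) of the geometric
# center of anthraquinone ring C, in-plane orientation theta of the ring
# C -> ring A vector, signed out-of-plane height z of the ring-C center,
# and the sidedness s of the daunosamine moiety along the frame z-axis
# (s = -1: sugar points toward the plane, s = +1: away).

#' Ligand pose collective variables
#'
#' Computes one pose record per trajectory frame, expressed in a per-frame
#' reference frame (a base-pair mid-frame or a tetrad frame).
#'
#' @param traj a [trajectory()] containing the ligand.
#' @param ligand a [ligand_definition()].
#' @param frame_provider either a single [ref_frame()] (used for every
#'   trajectory frame), a list of frames (one per trajectory frame), or a
#'   function `function(frame_index) -> ref_frame`.
#' @param frames integer vector of trajectory frames (default all).
#' @return tibble with columns `frame`, `dx_A`, `dy_A`, `theta_deg`
#'   (NA when the ring C -> A vector projects to < 0.1 angstrom in-plane),
#'   `z_A`, `s` (+1/-1), and the convenience columns `centroid_dx_A`,
#'   `centroid_dy_A` (whole anthraquinone centroid).
#' @export
pose_cv <- function(traj, ligand, frame_provider, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  grp <- ligand_group_idx(traj, ligand)
  get_frame <- if (inherits(frame_provider, "ref_frame")) {
    function(i) frame_provider
  } else if (is.function(frame_provider)) {
    frame_provider
  } else {
    function(i) frame_provider[[i]]
  }
  rows <- lapply(frames, function(fr) {
    rf <- get_frame(fr)
    cC <- colMeans(frame_coords(traj, fr, grp$ring_C))
    cA <- colMeans(frame_coords(traj, fr, grp$ring_A))
    cAQ <- colMeans(frame_coords(traj, fr, grp$anthraquinone))
    cS <- colMeans(frame_coords(traj, fr, grp$daunosamine))
    pC <- as.numeric(to_frame(rf, cC))
    pA <- as.numeric(to_frame(rf, cA))
    pAQ <- as.numeric(to_frame(rf, cAQ))
    pS <- as.numeric(to_frame(rf, cS))
    v <- pA[1:2] - pC[1:2]
    theta <- if (vnorm(v) < 0.1) NA_real_ else wrap_deg(atan2(v[2], v[1]) * 180 / pi)
    tibble::tibble(
      frame = fr, dx_A = pC[1], dy_A = pC[2], theta_deg = theta,
      z_A = pC[3], s = if ((pS[3] - pAQ[3]) < 0) -1L else 1L,
      centroid_dx_A = pAQ[1], centroid_dy_A = pAQ[2])
  })
  dplyr::bind_rows(rows)
}

# Circular mean direction (deg) and resultant length of angles in degrees.
circular_stats <- function(theta_deg) {
  th <- theta_deg[!is.na(theta_deg)] * pi / 180
  if (!length(th)) return(list(mean = NA_real_, R = NA_real_, n = 0L))
  C <- mean(cos(th)); S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  list(mean = if (R < 1e-8) NA_real_ else wrap_deg(atan2(S, C) * 180 / pi),
       R = R, n = length(th))
}

#' Orientation density map over the reference plane
#'
#' Bins pose records on a square (dx, dy) grid and reports per-bin
#' occupancy probability, circular mean orientation with resultant length,
#' and the fraction of frames with the daunosamine pointing toward the
#' plane (s = -1). Bins where orientations cancel (resultant length ~ 0)
#' carry `mean_theta_deg = NA` — direction undefined, flagged rather than
#' zeroed.
#'
#' @param records tibble from [pose_cv()].
#' @param bin_width bin width, angstrom.
#' @param min_occupancy occupancy floor below which a bin's direction
#'   vector is suppressed in plots (default `1 / nrow(records)`).
#' @return object of class `orientation_map`: tibble with columns
#'   `bin_x_A`, `bin_y_A`, `n`, `occupancy`, `mean_theta_deg`,
#'   `resultant_length`, `s_fraction`; attributes `bin_width`,
#'   `min_occupancy`, `n_records`.
#' @export
orientation_map <- function(records, bin_width = 0.5, min_occupancy = NULL) {
  if (!nrow(records) || all(is.na(records$theta_deg))) {
    stop("need at least one record with a defined orientation")
  }
  min_occupancy <- min_occupancy %||% (1 / nrow(records))
  d <- records
  d$bin_ix <- floor(records$dx_A / bin_width)
  d$bin_iy <- floor(records$dy_A / bin_width)
  m <- dplyr::group_by(d, .data$bin_ix, .data$bin_iy)
  m <- dplyr::summarise(
    m,
    n = dplyr::n(),
    mean_theta_deg = circular_stats(.data$theta_deg)$mean,
    resultant_length = circular_stats(.data$theta_deg)$R,
    s_fraction = mean(.data$s == -1L),
    .groups = "drop")
  m <- dplyr::mutate(
    m,
    bin_x_A = (.data$bin_ix + 0.5) * bin_width,
    bin_y_A = (.data$bin_iy + 0.5) * bin_width,
    occupancy = .data$n / sum(.data$n))
  m <- dplyr::select(m, "bin_x_A", "bin_y_A", "n", "occupancy",
                     "mean_theta_deg", "resultant_length", "s_fraction")
  structure(m, class = c("orientation_map", class(m)),
            bin_width = bin_width, min_occupancy = min_occupancy,
            n_records = nrow(records))
}

#' Merge two orientation maps
#'
#' Occupancy-weighted combination: merging equals the map of the pooled
#' record lists.
#'
#' @param a,b `orientation_map` objects with identical bin widths.
#' @return an `orientation_map`.
#' @export
merge_orientation_maps <- function(a, b) {
  if (!isTRUE(all.equal(attr(a, "bin_width"), attr(b, "bin_width")))) {
    stop("bin widths differ")
  }
  bw <- attr(a, "bin_width")
  key <- function(m) paste(round(m$bin_x_A / bw - 0.5), round(m$bin_y_A / bw - 0.5))
  all_keys <- union(key(a), key(b))
  pick <- function(m, kk) {
    i <- match(kk, key(m))
    list(n = ifelse(is.na(i), 0L, m$n[i]),
         C = ifelse(is.na(i), 0, m$n[i] * m$resultant_length[i] *
               cos(m$mean_theta_deg[i] * pi / 180)),
         S = ifelse(is.na(i), 0, m$n[i] * m$resultant_length[i] *
               sin(m$mean_theta_deg[i] * pi / 180)),
         sneg = ifelse(is.na(i), 0, m$n[i] * m$s_fraction[i]),
         x = ifelse(is.na(i), NA, m$bin_x_A[i]),
         y = ifelse(is.na(i), NA, m$bin_y_A[i]))
  }
  pa <- pick(a, all_keys); pb <- pick(b, all_keys)
  n <- pa$n + pb$n
  C <- (pa$C + pb$C) / n
  S <- (pa$S + pb$S) / n
  R <- sqrt(C^2 + S^2)
  out <- tibble::tibble(
    bin_x_A = ifelse(is.na(pa$x), pb$x, pa$x),
    bin_y_A = ifelse(is.na(pa$y), pb$y, pa$y),
    n = n,
    occupancy = n / sum(n),
    mean_theta_deg = ifelse(R < 1e-8, NA_real_, wrap_deg(atan2(S, C) * 180 / pi)),
    resultant_length = R,
    s_fraction = (pa$sneg + pb$sneg) / n)
  structure(out, class = c("orientation_map", class(out)),
            bin_width = bw,
            min_occupancy = 1 / sum(n), n_records = sum(n))
}

#' Pose stability summary
#'
#' Quantifies how localized a ligand stays on its platform: RMS in-plane
#' displacement about the center of the occupancy-weighted mode bin,
#' circular standard deviation of the orientation, and the fraction of
#' frames within `radius` of the mode center.
#'
#' @param records tibble from [pose_cv()].
#' @param radius inclusion radius about the mode bin center, angstrom.
#' @param bin_width bin width used to locate the mode, angstrom.
#' @return one-row tibble: `n_frames`, `mode_x_A`, `mode_y_A`,
#'   `rms_displacement_A`, `circ_sd_theta_deg`, `frac_within_radius`.
#' @export
stability_summary <- function(records, radius = 2, bin_width = 0.5) {
  if (!nrow(records)) stop("no pose records")
  m <- orientation_map(records, bin_width = bin_width)
  mode_bin <- m[which.max(m$occupancy), ]
  dx <- records$dx_A - mode_bin$bin_x_A
  dy <- records$dy_A - mode_bin$bin_y_A
  r2 <- dx^2 + dy^2
  cs <- circular_stats(records$theta_deg)
  circ_sd <- if (is.na(cs$R) || cs$R <= 0) NA_real_ else
    sqrt(-2 * log(cs$R)) * 180 / pi
  tibble::tibble(
    n_frames = nrow(records),
    mode_x_A = mode_bin$bin_x_A, mode_y_A = mode_bin$bin_y_A,
    rms_displacement_A = sqrt(mean(r2)),
    circ_sd_theta_deg = circ_sd,
    frac_within_radius = mean(sqrt(r2) <= radius))
}

#' Write an orientation map as JSON
#'
#' @param map an `orientation_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orientation_map <- function(map, path) {
  jsonlite::write_json(
    list(bin_width_A = attr(map, "bin_width"),
         n_records = attr(map, "n_records"),
         bins = as.data.frame(map)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot orientation_map
#' @export
autoplot.orientation_map <- function(object, arrow_scale = 1, ...) {
  d <- as.data.frame(object)
  floor_ <- attr(object, "min_occupancy")
  arrows <- d[!is.na(d$mean_theta_deg) & d$occupancy > floor_, ]
  len <- arrow_scale * attr(object, "bin_width") * arrows$resultant_length
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_x_A, y = .data$bin_y_A)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$occupancy)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "dx (Å)", y = "dy (Å)", fill = "occupancy")
  if (nrow(arrows)) {
    arrows$xend <- arrows$bin_x_A + len * cos(arrows$mean_theta_deg * pi / 180)
    arrows$yend <- arrows$bin_y_A + len * sin(arrows$mean_theta_deg * pi / 180)
    p <- p + ggplot2::geom_segment(
      data = arrows,
      ggplot2::aes(xend = .data$xend, yend = .data$yend,
                   colour = .data$s_fraction),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "cm"))) +
      ggplot2::scale_colour_gradient(low = "blue", high = "red",
                                     limits = c(0, 1), name = "s = -1 frac")
  }
  p
}
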