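# Torsional-stress hotspot profiles: time-averaged rise per base-pair
# step, smoothed by a centered sliding window along the duplex, with
# HIGH/LOW flags and a permutation test for intercalation enrichment.

#' Sliding-window rise stress profile
#'
#' Time-averages the per-step rise (and twist) over `time_slice` first,
#' then applies a centered sliding mean of `window` steps along the duplex
#' (edge steps use the truncated window, no padding). Steps are flagged
#' HIGH when the running rise exceeds `high` and LOW below `low`. Twist
#' stress is reported as deviation from the profile median twist.
#'
#' @param steps tidy step table (from `helical_parameters()$steps`):
#'   columns `frame`, `step_index`, `rise_A` and optionally `twist_deg`,
#'   `step_id`.
#' @param window sliding-window width in steps; odd, >= 1.
#' @param high,low flag thresholds on the running rise, angstrom
#'   (`high > low`).
#' @param time_slice optional length-2 frame range (inclusive) to average
#'   over; with `times` given, the default is the final 200 ns, else all
#'   frames.
#' @param times optional per-frame times, ns (parallel to the frame index).
#' @return object of class `stress_profile`: tibble with `step_index`,
#'   `step_id`, `mean_rise_A`, `running_rise_A`, `twist_dev_deg`, `flag`;
#'   attributes `window`, `high`, `low`, `n_frames_used`.
#' @export
stress_profile <- function(steps, window = 5, high = 3.5, low = 3.2,
                           time_slice = NULL, times = NULL) {
  if (window < 1 || window %% 2 != 1) stop("window must be odd and >= 1")
  if (high <= low) stop("high threshold must exceed low")
  frames <- sort(unique(steps$frame))
  if (is.null(time_slice) && !is.null(times)) {
    tmax <- max(times)
    keep_frames <- frames[times[frames] > tmax - 200]
  } else if (!is.null(time_slice)) {
    keep_frames <- frames[frames >= time_slice[1] & frames <= time_slice[2]]
  } else {
    keep_frames <- frames
  }
  d <- steps[steps$frame %in% keep_frames, , drop = FALSE]
  if (!nrow(d)) stop("time slice selects no frames")
  g <- dplyr::group_by(d, .data$step_index)
  prof <- dplyr::summarise(
    g,
    step_id = if ("step_id" %in% names(d)) .data$step_id[1] else
      as.character(.data$step_index[1]),
    mean_rise_A = mean(.data$rise_A),
    mean_twist_deg = if ("twist_deg" %in% names(d)) mean(.data$twist_deg) else NA_real_,
    .groups = "drop")
  prof <- dplyr::arrange(prof, .data$step_index)
  ns <- nrow(prof)
  if (window > ns) stop("window (", window, ") exceeds step count (", ns, ")")
  half <- (window - 1) / 2
  run <- vapply(seq_len(ns), function(i) {
    mean(prof$mean_rise_A[max(1, i - half):min(ns, i + half)])
  }, numeric(1))
  med_tw <- stats::median(prof$mean_twist_deg)
  out <- tibble::tibble(
    step_index = prof$step_index,
    step_id = prof$step_id,
    mean_rise_A = prof$mean_rise_A,
    running_rise_A = run,
    twist_dev_deg = prof$mean_twist_deg - med_tw,
    flag = ifelse(run > high, "HIGH", ifelse(run < low, "LOW", "NONE")))
  structure(out, class = c("stress_profile", class(out)),
            window = window, high = high, low = low,
            n_frames_used = length(keep_frames))
}

#' @method tidy stress_profile
#' @export
tidy.stress_profile <- function(x, ...) tibble::as_tibble(unclass(x))

#' @method glance stress_profile
#' @export
glance.stress_profile <- function(x, ...) {
  tibble::tibble(n_steps = nrow(x), window = attr(x, "window"),
                 high_A = attr(x, "high"), low_A = attr(x, "low"),
                 n_high = sum(x$flag == "HIGH"), n_low = sum(x$flag == "LOW"),
                 n_frames_used = attr(x, "n_frames_used"))
}

#' @method autoplot stress_profile
#' @export
autoplot.stress_profile <- function(object, ...) {
  d <- tidy.stress_profile(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step_index)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_rise_A), colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$running_rise_A), colour = "red") +
    ggplot2::geom_hline(yintercept = attr(object, "high"), linetype = 2) +
    ggplot2::geom_hline(yintercept = attr(object, "low"), linetype = 2) +
    ggplot2::geom_point(
      data = d[d$flag != "NONE", ],
      ggplot2::aes(y = .data$running_rise_A, colour = .data$flag)) +
    ggplot2::scale_colour_manual(values = c(HIGH = "red", LOW = "blue")) +
    ggplot2::labs(x = "base-pair step", y = "rise (Å)")
}

#' Export HIGH/LOW flag intervals as BED-like text
#'
#' Zero-based half-open intervals over step indices, for genome-browser
#' style viewing of e.g. a 147-bp nucleosomal coordinate.
#'
#' @param profile a `stress_profile`.
#' @param path output path.
#' @param chrom name placed in the first column.
#' @return `path`, invisibly.
#' @export
write_flag_bed <- function(profile, path, chrom = "duplex") {
  r <- rle(profile$flag)
  ends <- cumsum(r$lengths)
  starts <- c(0, utils::head(ends, -1))
  keep <- r$values != "NONE"
  lines <- sprintf("%s\t%d\t%d\t%s", chrom, starts[keep], ends[keep],
                   r$values[keep])
  writeLines(lines, path)
  invisible(path)
}

#' Intercalation-hotspot overlap with a permutation null
#'
#' Fraction of intercalation events whose anchor step (within +/- 1 step)
#' is flagged HIGH in a ligand-free stress profile, compared against a
#' null in which the same number of events is placed independently and
#' uniformly over the eligible steps (terminal steps excluded). The
#' one-sided empirical p-value is the fraction of permutations with
#' overlap at least as large as observed.
#'
#' @param profile a `stress_profile` (computed without the ligand).
#' @param events integer vector of intercalation anchor step indices.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param exclude_terminal number of steps dropped from each end of the
#'   eligible set (terminal stacking dominates there, not intercalation).
#' @param match_window half-width of the step-matching window.
#' @return one-row tibble: `n_events`, `overlap_fraction`, `p_value`,
#'   `high_coverage`, `n_perm`, `n_eligible`.
#' @export
hotspot_overlap <- function(profile, events, n_perm = 10000, seed = 1,
                            exclude_terminal = 2, match_window = 1) {
  if (!length(events)) stop("need >= 1 intercalation event")
  steps <- profile$step_index
  ns <- length(steps)
  eligible <- steps[(exclude_terminal + 1):(ns - exclude_terminal)]
  if (!length(eligible)) stop("no eligible steps after terminal exclusion")
  high_steps <- profile$step_index[profile$flag == "HIGH"]
  hit <- function(ev) {
    vapply(ev, function(e) any(abs(high_steps - e) <= match_window), logical(1))
  }
  obs <- mean(hit(events))
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    mean(hit(sample(eligible, length(events), replace = TRUE)))
  }, numeric(1))
  tibble::tibble(
    n_events = length(events),
    overlap_fraction = obs,
    p_value = mean(perm >= obs),
    high_coverage = mean(hit(eligible)),
    n_perm = n_perm,
    n_eligible = length(eligible))
}
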