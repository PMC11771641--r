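# 1-D potential of mean force from umbrella-sampling windows via the
# self-consistent weighted histogram analysis method (WHAM), with the
# production-time filter, bulk-reference pinning, bootstrap uncertainties
# and a landmark (minima/barrier) report.

KJ_TO_KCAL <- 1 / 4.184
R_KCAL <- 0.0019872041  # kcal mol^-1 K^-1

boltzmann_kcal <- function(temperature) R_KCAL * temperature

#' Keep the production tail of an umbrella window
#'
#' Retains samples from the final `last` ns of the window time series (the
#' production segment used for the PMF). Without a time column the last
#' `last / total_duration` fraction of samples is kept, which requires
#' `total_duration`.
#'
#' @param window a `window_table` (see [read_window_tables()]).
#' @param last production length to keep, ns.
#' @param total_duration total duration, ns (only needed when the table has
#'   no usable times).
#' @return an `umbrella_window`: list with `center` (nm), `k`
#'   (kJ mol^-1 nm^-2), `cv` (numeric, nm), `n`.
#' @export
filter_production <- function(window, last = 20, total_duration = NULL) {
  s <- window$samples
  has_times <- "time_ns" %in% names(s) && !anyNA(s$time_ns)
  if (has_times) {
    tmax <- max(s$time_ns)
    if (last >= tmax) {
      message("production window covers the whole series; keeping all samples")
      keep <- rep(TRUE, nrow(s))
    } else {
      # small tolerance so a sample at exactly t_max - last is excluded even
      # under floating-point accumulation of the time grid
      keep <- s$time_ns > (tmax - last) + 1e-9
    }
  } else {
    if (is.null(total_duration)) {
      stop("window has no times; supply total_duration to filter by fraction")
    }
    frac <- min(1, last / total_duration)
    n <- nrow(s)
    keep <- seq_len(n) > n - round(frac * n)
  }
  cv <- s$cv_nm[keep]
  if (!length(cv)) stop("production filter removed all samples")
  structure(list(center = window$center, k = window$k, cv = cv, n = length(cv)),
            class = "umbrella_window")
}

as_umbrella_window <- function(w) {
  if (inherits(w, "umbrella_window")) return(w)
  structure(list(center = w$center, k = w$k, cv = w$samples$cv_nm,
                 n = nrow(w$samples)), class = "umbrella_window")
}

#' Solve WHAM for a 1-D PMF
#'
#' Iterates the coupled WHAM equations
#' \deqn{p(x_k) \propto \sum_i h_i(x_k) \Big/ \sum_j n_j
#'   e^{(f_j - w_j(x_k))/k_BT}, \qquad
#'   f_j = -k_BT \ln \sum_k p(x_k) e^{-w_j(x_k)/k_BT}}
#' with harmonic biases \eqn{w_j(x) = K/2 (x - x_j)^2}, starting from
#' `f_j = 0`, until the largest change in any `f_j` falls below `tol`.
#' The resulting free energy `G = -kT ln p` is shifted so its mean over
#' `reference_region` (default: the top 0.2 nm of the sampled range, the
#' bulk-water side) is zero.
#'
#' @param windows list of `umbrella_window` (or `window_table`, converted
#'   without time filtering).
#' @param bin_width histogram bin width, nm.
#' @param temperature kelvin.
#' @param tol convergence tolerance on the window free-energy constants,
#'   kcal/mol.
#' @param max_iter iteration cap (exceeding it is an error).
#' @param reference_region length-2 numeric, nm: interval over which the
#'   mean of G is pinned to zero.
#' @param min_overlap minimum shared-bin sample count required between
#'   adjacent windows (gap -> error).
#' @param subgrid internal quadrature refinement: the equations are
#'   iterated on a grid of `bin_width / subgrid` and the profile is
#'   aggregated back onto the requested grid (stiff biases vary by ~kT
#'   across a bin; see the methods vignette).
#' @return object of class `pmf_profile`: list with `x` (bin centers, nm),
#'   `G` (kcal/mol), `counts` (pooled samples per bin), `err` (NA until
#'   [bootstrap_error()]), `f_shifts` (kcal/mol), `reference_region`,
#'   `iterations`, `temperature`, `bin_width`, `converged`,
#'   `residual_trace`.
#' @export
solve_wham <- function(windows, bin_width = 0.01, temperature = 298,
                       tol = 1e-7, max_iter = 100000,
                       reference_region = NULL, min_overlap = 10,
                       subgrid = 4) {
  windows <- lapply(windows, as_umbrella_window)
  if (length(windows) < 2) stop("need >= 2 umbrella windows")
  kT <- boltzmann_kcal(temperature)
  cvs <- lapply(windows, `[[`, "cv")
  rng <- range(unlist(cvs))
  # the coupled equations are iterated on an internal grid of
  # bin_width/subgrid (quadrature for the steep biases and density); the
  # profile is reported on the requested grid by mass aggregation
  bw_int <- bin_width / subgrid
  edges <- seq(rng[1] - 1e-9, rng[2] + bin_width, by = bw_int)
  x <- edges[-length(edges)] + bw_int / 2
  nb <- length(x)
  nw <- length(windows)
  H <- matrix(0, nw, nb)
  for (j in seq_len(nw)) {
    H[j, ] <- tabulate(findInterval(cvs[[j]], edges, rightmost.closed = TRUE),
                       nbins = nb)
  }
  # adjacency check in center order: adjacent windows must share bins with
  # enough combined sampling to tie their free energies together
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  for (a in seq_len(nw - 1)) {
    j1 <- ord[a]; j2 <- ord[a + 1]
    shared <- (H[j1, ] > 0) & (H[j2, ] > 0)
    if (sum(H[j1, shared]) + sum(H[j2, shared]) < min_overlap) {
      stop(sprintf(
        "insufficient histogram overlap between windows at %.3f and %.3f nm",
        windows[[j1]]$center, windows[[j2]]$center))
    }
  }
  n_j <- vapply(windows, `[[`, numeric(1), "n")
  k_kcal <- vapply(windows, function(w) w$k * KJ_TO_KCAL, numeric(1))
  centers <- vapply(windows, `[[`, numeric(1), "center")
  # Boltzmann factor of the bias, averaged over each internal bin by
  # 5-point midpoint quadrature: with stiff springs the bias varies by ~kT
  # across a bin, and evaluating it only at the center biases the window
  # constants
  sub <- bw_int * (-2:2) / 5
  expW <- matrix(0, nw, nb)
  for (s in sub) {
    Ws <- 0.5 * outer(k_kcal, rep(1, nb)) *
      (outer(centers, x + s, function(c0, xx) (xx - c0)))^2
    expW <- expW + exp(-Ws / kT) / length(sub)
  }
  htot <- colSums(H)
  f <- rep(0, nw)
  residuals <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    denom <- colSums(n_j * exp(f / kT) * expW)  # length nb
    p <- htot / denom
    p[!is.finite(p)] <- 0
    Z <- as.numeric(expW %*% p)
    fnew <- -kT * log(Z)
    fnew <- fnew - fnew[1]
    res <- max(abs(fnew - f))
    residuals <- c(residuals, res)
    f <- fnew
    if (res < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("WHAM did not converge within ", max_iter,
         " iterations (last residual ", signif(res, 3), " kcal/mol)")
  }
  denom <- colSums(n_j * exp(f / kT) * expW)
  p <- htot / denom
  # aggregate internal sub-bins onto the requested output grid
  grp <- (seq_len(nb) - 1) %/% subgrid
  n_out <- max(grp) + 1
  x_out <- vapply(seq_len(n_out) - 1, function(g) mean(x[grp == g]), numeric(1))
  p_out <- vapply(seq_len(n_out) - 1, function(g) mean(p[grp == g]), numeric(1))
  c_out <- vapply(seq_len(n_out) - 1, function(g) sum(htot[grp == g]), numeric(1))
  occupied <- c_out > 0 & p_out > 0
  G <- rep(NA_real_, n_out)
  G[occupied] <- -kT * log(p_out[occupied])
  if (is.null(reference_region)) {
    reference_region <- c(rng[2] - 0.2, rng[2])
  }
  in_ref <- occupied & x_out >= reference_region[1] & x_out <= reference_region[2]
  if (!any(in_ref)) stop("no occupied bins inside the reference region")
  G <- G - mean(G[in_ref])
  structure(list(x = x_out, G = G, counts = c_out,
                 err = rep(NA_real_, n_out),
                 f_shifts = f, reference_region = reference_region,
                 iterations = length(residuals), temperature = temperature,
                 bin_width = bin_width, converged = converged,
                 residual_trace = residuals),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("<pmf_profile> %d bins over [%.3f, %.3f] nm, %d iterations\n",
              length(x$x), min(x$x), max(x$x), x$iterations))
  cat(sprintf("  min G: %.2f kcal/mol at %.3f nm (reference: [%.3f, %.3f] nm)\n",
              min(x$G, na.rm = TRUE), x$x[which.min(x$G)],
              x$reference_region[1], x$reference_region[2]))
  invisible(x)
}

#' Bootstrap uncertainty of a PMF
#'
#' Resamples each window's production samples with replacement, re-solves
#' WHAM, and reports the per-bin standard deviation across replicates
#' (defined as 0 for a single replicate).
#'
#' @param windows list of `umbrella_window`.
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed (the whole procedure is deterministic given it).
#' @param ... passed to [solve_wham()].
#' @return the `pmf_profile` of the full data with `err` filled in.
#' @export
bootstrap_error <- function(windows, n_boot = 50, seed = 1, ...) {
  windows <- lapply(windows, as_umbrella_window)
  full <- solve_wham(windows, ...)
  if (n_boot < 2) {
    message("n_boot < 2: bootstrap SD defined as 0")
    full$err <- rep(0, length(full$x))
    return(full)
  }
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, length(full$x))
  for (b in seq_len(n_boot)) {
    wb <- lapply(windows, function(w) {
      w$cv <- sample(w$cv, w$n, replace = TRUE)
      w
    })
    gb <- solve_wham(wb, ...)
    reps[b, ] <- stats::approx(gb$x, gb$G, xout = full$x, rule = 2)$y
  }
  full$err <- apply(reps, 2, stats::sd)
  full
}

#' Landmark report: minima and barriers of a PMF
#'
#' For each named CV interval, reports the minimum free energy and its
#' location; barriers between consecutive interval minima are the watershed
#' (profile maximum between the two minima) measured from the shallower
#' minimum.
#'
#' @param profile a `pmf_profile`, or a list/data frame with `x` and `G`.
#' @param intervals named list of length-2 numeric CV intervals, nm.
#' @return list with tibbles `minima` (interval, x_nm, G_kcal_mol,
#'   depth_kcal_mol — depth is relative to the reference zero) and
#'   `barriers` (from, to, x_nm, barrier_kcal_mol; zero rows for a profile
#'   with no interior barrier).
#' @export
landmark_report <- function(profile, intervals) {
  x <- profile$x
  G <- profile$G
  if (is.null(names(intervals)) || any(!nzchar(names(intervals)))) {
    stop("intervals must be named")
  }
  minima <- purrr::imap(intervals, function(iv, nm) {
    sel <- which(x >= iv[1] & x <= iv[2] & is.finite(G))
    if (!length(sel)) stop("interval '", nm, "' lies outside the profile grid")
    i <- sel[which.min(G[sel])]
    tibble::tibble(interval = nm, x_nm = x[i], G_kcal_mol = G[i],
                   depth_kcal_mol = -G[i])
  })
  minima <- dplyr::arrange(dplyr::bind_rows(minima), .data$x_nm)
  barriers <- list()
  if (nrow(minima) > 1) {
    for (i in seq_len(nrow(minima) - 1)) {
      i1 <- which.min(abs(x - minima$x_nm[i]))
      i2 <- which.min(abs(x - minima$x_nm[i + 1]))
      span <- seq(min(i1, i2), max(i1, i2))
      fin <- span[is.finite(G[span])]
      top <- fin[which.max(G[fin])]
      shallow <- max(minima$G_kcal_mol[i], minima$G_kcal_mol[i + 1])
      b <- G[top] - shallow
      if (b > 1e-9) {
        barriers[[length(barriers) + 1]] <- tibble::tibble(
          from = minima$interval[i], to = minima$interval[i + 1],
          x_nm = x[top], barrier_kcal_mol = b)
      }
    }
  }
  list(minima = minima,
       barriers = if (length(barriers)) dplyr::bind_rows(barriers) else
         tibble::tibble(from = character(), to = character(),
                        x_nm = numeric(), barrier_kcal_mol = numeric()))
}

#' Center-of-mass distance collective variable
#'
#' The biased CV of the umbrella protocol: distance between the
#' mass-weighted centers of two atom selections, reported in nm.
#'
#' @param traj a [trajectory()].
#' @param sel1,sel2 atom-index vectors (e.g. from [resolve_selection()]).
#' @return numeric vector, one distance (nm) per trajectory frame.
#' @export
com_distance_cv <- function(traj, sel1, sel2) {
  mass_of <- function(el) {
    m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06)
    out <- m[toupper(el)]
    out[is.na(out)] <- 12.011
    unname(out)
  }
  m1 <- mass_of(traj$atoms$element[sel1])
  m2 <- mass_of(traj$atoms$element[sel2])
  vapply(seq_len(n_frames(traj)), function(f) {
    c1 <- colSums(traj$coords[[f]][sel1, , drop = FALSE] * m1) / sum(m1)
    c2 <- colSums(traj$coords[[f]][sel2, , drop = FALSE] * m2) / sum(m2)
    vnorm(c1 - c2) / 10
  }, numeric(1))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy pmf_profile
#' @export
tidy.pmf_profile <- function(x, ...) {
  tibble::tibble(x_nm = x$x, G_kcal_mol = x$G, err_kcal_mol = x$err,
                 n_samples = x$counts)
}

#' @method glance pmf_profile
#' @export
glance.pmf_profile <- function(x, ...) {
  tibble::tibble(n_bins = length(x$x), bin_width_nm = x$bin_width,
                 n_windows = length(x$f_shifts),
                 iterations = x$iterations, converged = x$converged,
                 temperature_K = x$temperature,
                 min_G_kcal_mol = min(x$G, na.rm = TRUE),
                 min_x_nm = x$x[which.min(x$G)])
}

#' @method autoplot pmf_profile
#' @export
autoplot.pmf_profile <- function(object, ...) {
  d <- tidy.pmf_profile(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x_nm, y = .data$G_kcal_mol)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "CV (nm)", y = "G (kcal/mol)")
  if (any(is.finite(d$err_kcal_mol))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$G_kcal_mol - .data$err_kcal_mol,
                   ymax = .data$G_kcal_mol + .data$err_kcal_mol),
      alpha = 0.3)
  }
  p
}
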