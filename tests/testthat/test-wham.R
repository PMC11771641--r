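# WHAM validation against exactly sampled fixtures: the ground truth is the
# generating potential itself, and the zero-bias limit is checked against
# direct Boltzmann inversion of the pooled histogram.

kT298 <- helipose:::boltzmann_kcal(298)

test_that("production filter keeps the final-20-ns tail", {
  w <- structure(list(center = 0.5, k = 2000,
                      samples = tibble::tibble(
                        time_ns = seq(0.05, 50, by = 0.05),
                        cv_nm = seq_len(1000) / 1000)),
                 class = "window_table")
  uw <- filter_production(w, last = 20)
  expect_equal(uw$n, 400)
  expect_true(all(w$samples$time_ns[w$samples$cv_nm %in% uw$cv] > 30))
  expect_message(filter_production(w, last = 60), "all samples")
  w2 <- w; w2$samples$time_ns <- NULL
  expect_error(filter_production(w2, last = 20), "total_duration")
  uw2 <- filter_production(w2, last = 20, total_duration = 50)
  expect_equal(uw2$n, 400)
})

test_that("near-zero bias recovers Boltzmann inversion of the pooled histogram", {
  set.seed(42)
  xs <- c(rnorm(20000, 1.0, 0.15), rnorm(20000, 1.6, 0.2))
  mk <- function(v) structure(list(center = 1.3, k = 1e-8,
                                   samples = tibble::tibble(time_ns = seq_along(v),
                                                            cv_nm = v)),
                              class = "window_table")
  halves <- list(mk(xs[1:20000]), mk(xs[20001:40000]))
  prof <- solve_wham(halves, bin_width = 0.02, reference_region = c(0.9, 1.1))
  h <- table(cut(xs, seq(min(xs) - 1e-9, max(xs) + 0.02, by = 0.02)))
  Gref <- -kT298 * log(as.numeric(h))
  Gref[!is.finite(Gref)] <- NA
  keep <- is.finite(prof$G) & is.finite(Gref[seq_along(prof$G)])
  diff <- prof$G[keep] - Gref[seq_along(prof$G)][keep]
  expect_lt(max(diff) - min(diff), 1e-6)  # equal up to an additive constant
})

test_that("flat landscape under a single-window pair is recovered flat", {
  flat <- function(x) rep(0, length(x))
  tabs <- sample_biased(flat, centers = c(1.0, 1.05), k = 2000,
                        n_per_window = 1e5, seed = 3)
  prof <- solve_wham(tabs, bin_width = 0.01)
  sampled <- prof$counts >= 2000
  expect_lt(max(abs(prof$G[sampled] - mean(prof$G[sampled]))), 0.05)
})

test_that("double-well PMF reconstruction is consistent and landmark-faithful", {
  # dense sampling: the estimator tracks the generating potential closely
  centers <- seq(0.25, 3.0, by = 0.05)
  tabs <- sample_biased(double_well_potential, centers, k = 2000,
                        n_per_window = 50000, seed = 17)
  prof <- solve_wham(tabs, bin_width = 0.01)
  expect_true(prof$converged)
  well <- prof$counts >= 2500
  Ut <- double_well_potential(prof$x)
  ref <- well & prof$x >= prof$reference_region[1] &
    prof$x <= prof$reference_region[2]
  Ut <- Ut - mean(Ut[ref])
  err_dense <- max(abs(prof$G[well] - Ut[well]))
  expect_lt(err_dense, 0.15)

  # the reconstructed landmarks echo the generating potential
  masked <- prof
  masked$G[prof$counts < 500] <- NA
  lm <- landmark_report(masked, list(deep = c(0.25, 0.8), shallow = c(1.5, 2.5)))
  expect_equal(lm$minima$x_nm[1], 0.43, tolerance = 0.05)
  expect_equal(lm$minima$depth_kcal_mol[1], 9.0, tolerance = 0.3)
  expect_equal(lm$minima$depth_kcal_mol[2], 5.7, tolerance = 0.3)
  expect_equal(lm$barriers$barrier_kcal_mol[1], 3.2, tolerance = 0.4)

  # at the protocol sampling depth (2000/window) the error is larger but the
  # estimator remains unbiased: error shrinks with sampling
  tabs2 <- sample_biased(double_well_potential, centers, k = 2000,
                         n_per_window = 2000, seed = 17)
  prof2 <- solve_wham(tabs2, bin_width = 0.01)
  well2 <- prof2$counts >= 100
  Ut2 <- double_well_potential(prof2$x)
  ref2 <- well2 & prof2$x >= prof2$reference_region[1] &
    prof2$x <= prof2$reference_region[2]
  Ut2 <- Ut2 - mean(Ut2[ref2])
  err_sparse <- max(abs(prof2$G[well2] - Ut2[well2]))
  expect_gt(err_sparse, err_dense)
  expect_lt(err_sparse, 0.6)

  # self-consistency residual decreases monotonically past the early
  # normalization transient (a small bump around iteration 12-16 as the
  # f-shift normalization settles)
  rt <- prof2$residual_trace
  expect_true(all(diff(rt[20:length(rt)]) <= 1e-12))
})

test_that("bin-width halving leaves the aggregated profile unchanged", {
  centers <- seq(0.25, 3.0, by = 0.05)
  tabs <- sample_biased(double_well_potential, centers, k = 2000,
                        n_per_window = 2000, seed = 17)
  kT <- helipose:::boltzmann_kcal(298)
  coarse <- solve_wham(tabs, bin_width = 0.01)
  fine <- solve_wham(tabs, bin_width = 0.005)
  # aggregate fine half-bins pairwise (density average) onto the coarse grid
  agg_G <- vapply(coarse$x, function(xc) {
    i <- which(abs(fine$x - xc) < 0.005)
    g <- fine$G[i]
    g <- g[is.finite(g)]
    if (!length(g)) return(NA_real_)
    -kT * log(mean(exp(-g / kT)))
  }, numeric(1))
  well <- coarse$counts >= 100 & is.finite(agg_G)
  shift <- mean(agg_G[well] - coarse$G[well])
  expect_lt(max(abs(agg_G[well] - coarse$G[well] - shift)), 0.02)
})

test_that("WHAM agrees with an independent log-space reimplementation", {
  centers <- seq(0.4, 1.2, by = 0.05)
  U <- function(x) 4 * (x - 0.8)^2
  tabs <- sample_biased(U, centers, k = 1500, n_per_window = 2000, seed = 31)
  prof <- solve_wham(tabs, bin_width = 0.01)
  # independent route: normalized probabilities, log-sum-exp updates
  kT <- helipose:::boltzmann_kcal(298)
  cvs <- lapply(tabs, function(w) w$samples$cv_nm)
  rng <- range(unlist(cvs))
  edges <- seq(rng[1] - 1e-9, rng[2] + 0.01, by = 0.01)
  x <- edges[-length(edges)] + 0.005
  H <- t(vapply(cvs, function(v)
    tabulate(findInterval(v, edges, rightmost.closed = TRUE),
             nbins = length(x)), numeric(length(x))))
  nj <- lengths(cvs)
  kk <- vapply(tabs, function(w) w$k / 4.184, numeric(1))
  ww <- 0.5 * kk * (outer(vapply(tabs, function(w) w$center, numeric(1)),
                          x, `-`))^2
  lf <- rep(0, length(nj))
  for (it in 1:50000) {
    lden <- vapply(seq_along(x), function(b) {
      v <- log(nj) + lf - ww[, b] / kT
      m <- max(v); m + log(sum(exp(v - m)))
    }, numeric(1))
    lp <- log(colSums(H)) - lden
    lp <- lp - max(lp, na.rm = TRUE)
    lfn <- vapply(seq_along(nj), function(j) {
      v <- lp - ww[j, ] / kT
      v <- v[is.finite(v)]
      m <- max(v); -(m + log(sum(exp(v - m))))
    }, numeric(1))
    lfn <- lfn - lfn[1]
    if (max(abs(lfn - lf)) < 1e-10 / kT) { lf <- lfn; break }
    lf <- lfn
  }
  expect_lt(max(abs(lf * kT - prof$f_shifts)), 0.05)
})

test_that("mean PMF is pinned to zero over the reference region", {
  centers <- seq(0.3, 1.2, by = 0.1)
  tabs <- sample_biased(function(x) 2 * (x - 0.7)^2, centers, k = 1000,
                        n_per_window = 1000, seed = 5)
  prof <- solve_wham(tabs, bin_width = 0.02, reference_region = c(1.0, 1.2))
  in_ref <- is.finite(prof$G) & prof$x >= 1.0 & prof$x <= 1.2
  expect_lt(abs(mean(prof$G[in_ref])), 1e-9)
})

test_that("non-overlapping windows are rejected naming the gap", {
  mk <- function(ctr, v) structure(
    list(center = ctr, k = 2000,
         samples = tibble::tibble(time_ns = seq_along(v), cv_nm = v)),
    class = "window_table")
  set.seed(8)
  w1 <- mk(0.3, rnorm(500, 0.3, 0.01))
  w2 <- mk(1.5, rnorm(500, 1.5, 0.01))
  expect_error(solve_wham(list(w1, w2), bin_width = 0.01), "overlap")
  expect_error(solve_wham(list(w1), bin_width = 0.01), ">= 2")
})

test_that("bootstrap errors are deterministic, scale with n, and stabilize", {
  centers <- seq(0.4, 1.4, by = 0.1)
  U <- function(x) 3 * (x - 0.9)^2
  mk_tabs <- function(n) sample_biased(U, centers, k = 800, n_per_window = n,
                                       seed = 21)
  b1 <- bootstrap_error(mk_tabs(300), n_boot = 50, seed = 7, bin_width = 0.02)
  b1b <- bootstrap_error(mk_tabs(300), n_boot = 50, seed = 7, bin_width = 0.02)
  expect_identical(b1$err, b1b$err)
  expect_true(all(b1$err >= 0))

  # doubling samples shrinks the mean error roughly like 1/sqrt(2)
  b2 <- bootstrap_error(mk_tabs(600), n_boot = 50, seed = 7, bin_width = 0.02)
  m1 <- mean(b1$err[b1$counts >= 50])
  m2 <- mean(b2$err[b2$counts >= 100])
  ratio <- m2 / m1
  expect_lt(abs(ratio - 1 / sqrt(2)), 0.3 / sqrt(2))

  # different seeds agree on the error scale
  b3 <- bootstrap_error(mk_tabs(300), n_boot = 50, seed = 99, bin_width = 0.02)
  m3 <- mean(b3$err[b3$counts >= 50])
  expect_lt(abs(m3 - m1) / m1, 0.2)

  # single replicate: SD defined as zero
  expect_message(
    b0 <- bootstrap_error(mk_tabs(300), n_boot = 1, seed = 1, bin_width = 0.02),
    "0")
  expect_true(all(b0$err == 0))
})

test_that("landmark report handles analytic profiles and degenerate cases", {
  x <- seq(0.25, 3, by = 0.002)
  prof <- list(x = x, G = double_well_potential(x))
  lm <- landmark_report(prof, list(deep = c(0.25, 0.8), shallow = c(1.5, 2.5)))
  # oracle: direct grid minimization of the analytic potential
  i1 <- which.min(prof$G[x < 0.8])
  expect_equal(lm$minima$G_kcal_mol[1], prof$G[i1], tolerance = 1e-12)
  sh <- which(x >= 1.5 & x <= 2.5)
  expect_equal(lm$minima$G_kcal_mol[2], min(prof$G[sh]), tolerance = 1e-12)
  span <- x >= lm$minima$x_nm[1] & x <= lm$minima$x_nm[2]
  expect_equal(lm$barriers$barrier_kcal_mol[1],
               max(prof$G[span]) - lm$minima$G_kcal_mol[2], tolerance = 1e-12)

  mono <- list(x = x, G = 2 * x)
  lm2 <- landmark_report(mono, list(lo = c(0.3, 1), hi = c(2, 3)))
  expect_equal(nrow(lm2$barriers), 0)
  expect_error(landmark_report(prof, list(out = c(5, 6))), "outside")
  expect_error(landmark_report(prof, list(c(0.3, 1))), "named")
})

test_that("COM-distance CV matches hand-computed centers of mass", {
  tr <- build_duplex("GC", n_frames = 1)
  s1 <- which(tr$atoms$chain_id == "A")
  s2 <- which(tr$atoms$chain_id == "B")
  cv <- com_distance_cv(tr, s1, s2)
  mass <- c(C = 12.011, N = 14.007, O = 15.999)
  com <- function(idx) {
    m <- mass[tr$atoms$element[idx]]
    colSums(tr$coords[[1]][idx, ] * m) / sum(m)
  }
  expect_equal(cv, helipose:::vnorm(com(s1) - com(s2)) / 10, tolerance = 1e-12)
})

test_that("tidy and glance summarize a PMF profile", {
  tabs <- sample_biased(function(x) rep(0, length(x)), c(0.5, 0.55), k = 2000,
                        n_per_window = 2000, seed = 2)
  prof <- solve_wham(tabs, bin_width = 0.01)
  td <- tidy(prof)
  expect_named(td, c("x_nm", "G_kcal_mol", "err_kcal_mol", "n_samples"))
  gl <- glance(prof)
  expect_true(gl$converged)
  expect_equal(gl$n_windows, 2)
  expect_s3_class(ggplot2::autoplot(prof), "ggplot")
})
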