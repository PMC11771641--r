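test_that("a template base at the origin self-fits to the identity frame", {
  for (b in c("A", "C", "G", "T")) {
    f <- base_frame(base_template(b), b)
    expect_lt(max(abs(f$axes - diag(3))), 1e-8)
    expect_lt(max(abs(f$origin)), 1e-8)
    expect_lt(attr(f, "fit_rmsd"), 1e-8)
  }
})

test_that("base frames co-transform with rigid motions of the base", {
  set.seed(101)
  R <- helipose:::random_rotation()
  t0 <- rnorm(3, sd = 10)
  tmpl <- base_template("G")
  moved <- t(R %*% t(tmpl)) + matrix(t0, nrow(tmpl), 3, byrow = TRUE)
  rownames(moved) <- rownames(tmpl)
  f <- base_frame(moved, "G")
  expect_lt(max(abs(f$origin - t0)), 1e-8)
  expect_lt(max(abs(f$axes - t(R))), 1e-8)
})

test_that("noisy base fit stays within 5 degrees of the oracle Kabsch fit", {
  set.seed(1)
  tmpl <- base_template("A")
  ring <- helipose:::ring_atom_names("A")
  noisy <- tmpl + matrix(rnorm(length(tmpl), 0, 0.3), nrow(tmpl), 3)
  rownames(noisy) <- rownames(tmpl)
  f <- base_frame(noisy, "A")
  # independent oracle: direct SVD superposition of ring atoms
  oracle <- helipose:::kabsch(tmpl[ring, ], noisy[ring, ])
  expect_lt(max(abs(f$axes - t(oracle$R))), 1e-10)
  ang <- acos((sum(diag(oracle$R)) - 1) / 2) * 180 / pi
  expect_lt(ang, 5)
})

test_that("missing ring atoms are reported by name", {
  tmpl <- base_template("G")
  expect_error(base_frame(tmpl[rownames(tmpl) != "N7", ], "G"), "N7")
})

test_that("pair frame is the halfway rotation at the midpoint", {
  f1 <- identity_frame()
  expect_frames_equal(pair_frame(f1, f1), f1, tol = 1e-9)
  f2 <- ref_frame(c(0, 0, 0), t(helipose:::rot_z(10 * pi / 180)))
  pm <- pair_frame(f1, f2)
  expect_lt(max(abs(pm$axes - t(helipose:::rot_z(5 * pi / 180)))), 1e-9)
  f3 <- ref_frame(c(2, 0, 0), diag(3))
  expect_equal(pair_frame(f1, f3)$origin, c(1, 0, 0))
})

test_that("antiparallel ideal pair from the builder has z along the helix axis", {
  d <- build_duplex("GCGC", n_frames = 1)
  pf <- helipose:::pair_frames_for_frame(d, duplex_pairs(d), 1)
  expect_lt(max(abs(pf[[1]]$axes[3, ] - c(0, 0, 1))), 1e-6)
})

test_that("pairing precondition is enforced when requested", {
  f1 <- identity_frame()
  f_far <- ref_frame(c(0, 0, 0), t(helipose:::rot_x(80 * pi / 180)))
  expect_error(pair_frame(f1, f_far, check = TRUE), "pairing")
})

test_that("step parameters recover construction values", {
  f1 <- identity_frame()
  ideal <- compose_step(f1, rise = 3.4, twist = 36)$frame
  sp <- step_parameters(f1, ideal)
  expect_equal(sp$rise, 3.4, tolerance = 1e-6)
  expect_equal(sp$twist, 36, tolerance = 1e-6)
  expect_lt(max(abs(c(sp$roll, sp$tilt, sp$shift, sp$slide))), 1e-6)

  # pure translation of 5.2 A along z: the fully intercalated rise
  f2 <- ref_frame(c(0, 0, 5.2), diag(3))
  sp2 <- step_parameters(f1, f2)
  expect_equal(sp2$rise, 5.2, tolerance = 1e-9)
  expect_equal(sp2$twist, 0, tolerance = 1e-9)

  sp3 <- step_parameters(f1, f1)
  expect_lt(max(abs(unlist(sp3))), 1e-9)
})

test_that("compose-then-decompose round-trips 200 random 6-tuples to 1e-6", {
  set.seed(2024)
  for (i in 1:200) {
    p <- random_step_params()
    f1 <- random_frame()
    f2 <- compose_step(f1, p$shift, p$slide, p$rise, p$tilt, p$roll, p$twist)$frame
    got <- step_parameters(f1, f2)
    expect_lt(max(abs(unlist(got) - unlist(p))), 1e-6)
  }
})

test_that("pair parameters decompose planted intra-pair rotations", {
  f1 <- identity_frame()
  expect_lt(max(abs(unlist(pair_parameters(f1, f1)))), 1e-9)

  f2 <- compose_step(f1, 0, 0, 0, 20, 0, 0)$frame  # +20 deg about mid-frame x
  pp <- pair_parameters(f1, f2)
  expect_equal(pp$buckle, 20, tolerance = 1e-6)
  expect_lt(max(abs(c(pp$propeller, pp$opening, pp$shear, pp$stretch,
                      pp$stagger))), 1e-6)

  # planted buckle 15 + propeller -10, composed forward then decomposed
  mid <- identity_frame()
  fr <- helipose:::pair_frames_from_mid(mid, buckle = 15, propeller = -10)
  got <- pair_parameters(fr$f1, fr$f2_flipped)
  expect_equal(got$buckle, 15, tolerance = 1e-6)
  expect_equal(got$propeller, -10, tolerance = 1e-6)
  expect_lt(abs(got$opening), 1e-6)
})

test_that("chi state follows the anti/syn boundary convention", {
  make_purine <- function(chi) {
    tmpl <- base_template("G")
    helipose:::add_o4prime(tmpl, "G", chi = chi)
  }
  expect_equal(chi_state(make_purine(180), "G")$state, "anti")
  expect_equal(chi_state(make_purine(60), "G")$state, "syn")
  b <- chi_state(make_purine(90), "G")
  expect_equal(b$chi, 90, tolerance = 1e-6)
  expect_equal(b$state, "anti")  # boundary closed on the anti side
  expect_equal(chi_state(make_purine(270), "G")$state, "syn")
  expect_error(chi_state(base_template("G"), "G"), "O4'")
})

test_that("tetrad frame sits at the centroid with z normal to the plane", {
  ts <- build_tetrad_stack(3, rise = 3.4, twist = 30)
  f1 <- helipose:::tetrad_frame_of(ts, 1)
  f2 <- helipose:::tetrad_frame_of(ts, 2)
  expect_lt(max(abs(f1$axes[3, ] - c(0, 0, 1))), 1e-8)
  expect_lt(abs(helipose:::vnorm(f2$origin - f1$origin) - 3.4), 1e-8)
  ang <- acos(sum(f1$axes[1, ] * f2$axes[1, ])) * 180 / pi
  expect_equal(ang, 30, tolerance = 1e-6)

  # covariance under a rigid motion
  set.seed(5)
  R <- helipose:::random_rotation(); t0 <- rnorm(3)
  ts2 <- helipose:::transform_traj(ts, R, t0)
  g1 <- helipose:::tetrad_frame_of(ts2, 1)
  expect_lt(max(abs(g1$origin - (as.numeric(R %*% f1$origin) + t0))), 1e-8)
  expect_lt(max(abs(g1$axes - f1$axes %*% t(R))), 1e-6)
})

test_that("tilted-tetrad plane normal matches a direct TLS plane fit", {
  ts <- build_tetrad_stack(1)
  # tilt one guanine by 10 degrees about x through its own centroid
  idx <- helipose:::residue_atom_idx(ts, "G", 4)
  cc <- ts$coords[[1]][idx, ]
  ctr <- colMeans(cc)
  Rx <- helipose:::rot_x(10 * pi / 180)
  ts$coords[[1]][idx, ] <- t(Rx %*% t(sweep(cc, 2, ctr))) +
    matrix(ctr, length(idx), 3, byrow = TRUE)
  f <- helipose:::tetrad_frame_of(ts, 1)
  # oracle: TLS plane through the four base-frame origins
  origins <- t(vapply(1:4, function(ri) {
    ii <- helipose:::residue_atom_idx(ts, "G", ri)
    ccc <- ts$coords[[1]][ii, ]; rownames(ccc) <- ts$atoms$name[ii]
    base_frame(ccc, "G")$origin
  }, numeric(3)))
  sv <- svd(sweep(origins, 2, colMeans(origins)))
  normal <- sv$v[, 3]
  if (normal[3] < 0) normal <- -normal
  expect_lt(acos(abs(sum(f$axes[3, ] * normal))) * 180 / pi, 1e-5)
  # and within 3 degrees of the untilted-3-base plane normal (z)
  expect_lt(acos(abs(f$axes[3, 3])) * 180 / pi, 3)
})

test_that("helical parameters of an ideal duplex match the build spec", {
  so <- data.frame(step_index = 3, rise = 5.2, roll = 8)
  po <- data.frame(pair_index = 2, buckle = 12)
  d <- build_duplex("GCATGC", n_frames = 2, noise_sigma = 0, seed = 3,
                    step_overrides = so, pair_overrides = po)
  hp <- helical_parameters(d, duplex_pairs(d))
  s <- hp$steps[hp$steps$frame == 1, ]
  expect_equal(s$rise_A[s$step_index == 3], 5.2, tolerance = 1e-6)
  expect_equal(s$roll_deg[s$step_index == 3], 8, tolerance = 1e-6)
  expect_equal(s$rise_A[s$step_index == 1], 3.38, tolerance = 1e-6)
  expect_equal(s$twist_deg[s$step_index == 2], 36, tolerance = 1e-6)
  p <- hp$pairs[hp$pairs$frame == 1, ]
  expect_equal(p$buckle_deg[p$pair_index == 2], 12, tolerance = 1e-6)
  expect_lt(max(abs(p$buckle_deg[p$pair_index != 2])), 1e-6)
  expect_true(all(hp$chi$state == "anti"))
  # step ids carry source numbering
  expect_equal(s$step_id[1], "1:12->2:11")
})

test_that("helical parameters are invariant under global rigid motion", {
  set.seed(17)
  d <- build_duplex("GCAT", n_frames = 1, noise_sigma = 0.1, seed = 8)
  hp1 <- helical_parameters(d, duplex_pairs(d))
  d2 <- helipose:::transform_traj(d, helipose:::random_rotation(), rnorm(3, sd = 20))
  hp2 <- helical_parameters(d2, duplex_pairs(d2))
  expect_equal(as.data.frame(hp1$steps), as.data.frame(hp2$steps), tolerance = 1e-6)
  expect_equal(as.data.frame(hp1$pairs), as.data.frame(hp2$pairs), tolerance = 1e-6)
  expect_equal(hp1$chi$chi_deg, hp2$chi$chi_deg, tolerance = 1e-6)
})

test_that("swapping strand roles negates tilt and shift, preserves rise and twist", {
  set.seed(23)
  p <- random_step_params()
  f1 <- random_frame()
  f2 <- compose_step(f1, p$shift, p$slide, p$rise, p$tilt, p$roll, p$twist)$frame
  # strand swap: both pair frames flip (x kept, y and z reversed) and the
  # 5'->3' step order reverses
  swap <- function(f) ref_frame(f$origin, diag(c(1, -1, -1)) %*% f$axes)
  got <- step_parameters(swap(f2), swap(f1))
  expect_equal(got$rise, p$rise, tolerance = 1e-6)
  expect_equal(got$twist, p$twist, tolerance = 1e-6)
  expect_equal(got$roll, p$roll, tolerance = 1e-6)
  expect_equal(got$slide, p$slide, tolerance = 1e-6)
  expect_equal(got$tilt, -p$tilt, tolerance = 1e-6)
  expect_equal(got$shift, -p$shift, tolerance = 1e-6)
})

test_that("geometric pair detection recovers the built pairing", {
  d <- build_duplex("GCGATC", n_frames = 1)
  det <- detect_pairs(d, "A", "B")
  expect_equal(det$res2, 12:7)
  expect_equal(sub("^D", "", det$base2),
               unname(vapply(det$base1, helipose:::complement_base, "")))
})
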