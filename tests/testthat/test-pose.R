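# Pose CV fixtures are built by planting the rigid ligand template at known
# displacements/orientations relative to an identity reference frame.

make_pose_traj <- function(n, dx = 0, dy = 0, theta = 0, z = 0, noise = 0,
                           seed = 1, tilt = 0) {
  lig <- ligand_template()
  R <- helipose:::rot_z(theta * pi / 180)
  if (tilt != 0) R <- R %*% helipose:::rot_y(tilt * pi / 180)
  base <- t(R %*% t(lig$coords))
  # shift so the ring-C center lands at (dx, dy, z)
  cC <- colMeans(base[paste0("C", 1:6), ])
  base <- sweep(base, 2, c(dx, dy, z) - cC, `+`)
  atoms <- tibble::tibble(
    serial = seq_len(nrow(base)), name = rownames(lig$coords),
    element = "C", residue_name = "LIG", residue_index = 1, chain_id = "L")
  set.seed(seed)
  frames <- lapply(seq_len(n), function(i) {
    m <- base + if (noise > 0) matrix(rnorm(length(base), 0, noise),
                                      nrow(base), 3) else 0
    rownames(m) <- NULL
    m
  })
  tr <- trajectory(atoms, frames)
  list(traj = tr, ligand = lig$definition)
}

test_that("a ligand at the frame origin yields the zero pose record", {
  p <- make_pose_traj(1, theta = 0)
  rec <- pose_cv(p$traj, p$ligand, identity_frame())
  expect_equal(rec$dx_A, 0, tolerance = 1e-9)
  expect_equal(rec$dy_A, 0, tolerance = 1e-9)
  expect_equal(rec$theta_deg, 0, tolerance = 1e-9)
  expect_equal(rec$z_A, 0, tolerance = 1e-9)
  expect_equal(rec$s, -1L)  # template sugar centroid sits below the plane
})

test_that("pose records are invariant under global rigid motion", {
  set.seed(31)
  p <- make_pose_traj(3, dx = 2, dy = -1.5, theta = 135, z = 3.2, noise = 0.2)
  f0 <- identity_frame()
  rec1 <- pose_cv(p$traj, p$ligand, f0)
  R <- helipose:::random_rotation(); t0 <- rnorm(3, sd = 10)
  tr2 <- helipose:::transform_traj(p$traj, R, t0)
  f2 <- helipose:::apply_rigid_frame(f0, R, t0)
  rec2 <- pose_cv(tr2, p$ligand, f2)
  expect_equal(as.data.frame(rec1), as.data.frame(rec2), tolerance = 1e-8)
})

test_that("perpendicular ligand yields a missing orientation, not zero", {
  p <- make_pose_traj(1, tilt = 90)
  rec <- pose_cv(p$traj, p$ligand, identity_frame())
  expect_true(is.na(rec$theta_deg))
})

test_that("circular mean of a noisy planted orientation is recovered within 2 degrees", {
  p <- make_pose_traj(500, dx = 2, dy = -1.5, theta = 135, noise = 0.2, seed = 77)
  rec <- pose_cv(p$traj, p$ligand, identity_frame())
  cs <- helipose:::circular_stats(rec$theta_deg)
  expect_lt(abs(cs$mean - 135), 2)
  # oracle: direct circular statistics on the observed angles
  th <- rec$theta_deg * pi / 180
  oracle <- atan2(mean(sin(th)), mean(cos(th))) * 180 / pi
  expect_equal(cs$mean, oracle, tolerance = 1e-9)
})

test_that("orientation map concentrates identical records in one full bin", {
  p <- make_pose_traj(10, dx = 1.2, dy = 0.7, theta = 40)
  rec <- pose_cv(p$traj, p$ligand, identity_frame())
  m <- orientation_map(rec, bin_width = 0.5)
  expect_equal(nrow(m), 1)
  expect_equal(m$occupancy, 1)
  expect_equal(m$resultant_length, 1, tolerance = 1e-9)
  expect_equal(m$mean_theta_deg, 40, tolerance = 1e-9)
})

test_that("antipodal orientations cancel and are flagged undefined", {
  rec <- tibble::tibble(frame = 1:2, dx_A = 0.1, dy_A = 0.1,
                        theta_deg = c(0, 180), z_A = 0, s = 1L)
  m <- orientation_map(rec, bin_width = 0.5)
  expect_lt(m$resultant_length, 1e-8)
  expect_true(is.na(m$mean_theta_deg))
})

test_that("two planted clusters with opposite sugar sidedness separate cleanly", {
  rec <- tibble::tibble(
    frame = 1:40,
    dx_A = rep(c(0.2, 5.2), each = 20), dy_A = 0.2,
    theta_deg = rep(c(10, 100), each = 20), z_A = 3,
    s = rep(c(-1L, 1L), each = 20))
  m <- orientation_map(rec, bin_width = 1)
  m <- m[order(m$bin_x_A), ]
  expect_equal(nrow(m), 2)
  expect_equal(m$s_fraction, c(1, 0))
  expect_equal(m$occupancy, c(0.5, 0.5))
})

test_that("occupancy is a probability distribution and maps merge by pooling", {
  set.seed(4)
  rec <- tibble::tibble(
    frame = 1:200, dx_A = rnorm(200), dy_A = rnorm(200),
    theta_deg = runif(200, -180, 180), z_A = 0,
    s = sample(c(-1L, 1L), 200, TRUE))
  m <- orientation_map(rec, bin_width = 0.8)
  expect_equal(sum(m$occupancy), 1, tolerance = 1e-12)
  expect_true(all(m$occupancy >= 0))
  expect_true(all(m$resultant_length <= 1 + 1e-12))
  ma <- orientation_map(rec[1:120, ], bin_width = 0.8)
  mb <- orientation_map(rec[121:200, ], bin_width = 0.8)
  merged <- merge_orientation_maps(ma, mb)
  key <- function(m) paste(round(m$bin_x_A, 3), round(m$bin_y_A, 3))
  i <- match(key(m), key(merged))
  expect_false(anyNA(i))
  expect_equal(merged$occupancy[i], m$occupancy, tolerance = 1e-12)
  expect_equal(merged$s_fraction[i], m$s_fraction, tolerance = 1e-12)
  expect_equal(merged$resultant_length[i], m$resultant_length, tolerance = 1e-9)
})

test_that("mirror through the plane flips sidedness and negates orientation", {
  set.seed(9)
  rec <- tibble::tibble(
    frame = 1:100, dx_A = rnorm(100, 1), dy_A = rnorm(100, -1),
    theta_deg = runif(100, -179, 180), z_A = rnorm(100),
    s = sample(c(-1L, 1L), 100, TRUE))
  mirrored <- dplyr::mutate(rec, theta_deg = -theta_deg, s = -s,
                            z_A = -z_A)
  m1 <- orientation_map(rec, bin_width = 1)
  m2 <- orientation_map(mirrored, bin_width = 1)
  key <- function(m) paste(round(m$bin_x_A, 3), round(m$bin_y_A, 3))
  i <- match(key(m1), key(m2))
  expect_equal(m2$s_fraction[i], 1 - m1$s_fraction, tolerance = 1e-12)
  expect_equal(helipose:::wrap_deg(m2$mean_theta_deg[i] + m1$mean_theta_deg),
               rep(0, nrow(m1)), tolerance = 1e-9)
})

test_that("stability summary matches closed forms on planted data", {
  p <- make_pose_traj(5, dx = 1.2, dy = 0.7)
  rec0 <- pose_cv(p$traj, p$ligand, identity_frame())
  s0 <- stability_summary(rec0)
  # zero-noise records sit at the mode bin center offset only
  expect_lt(s0$rms_displacement_A, sqrt(2) * 0.25 + 1e-9)
  expect_equal(s0$frac_within_radius, 1)

  # isotropic 2-D Gaussian, sigma = 1: RMS displacement = sqrt(2)
  set.seed(123)
  n <- 1e4
  rec <- tibble::tibble(frame = 1:n, dx_A = rnorm(n), dy_A = rnorm(n),
                        theta_deg = 0, z_A = 0, s = 1L)
  s1 <- stability_summary(rec, radius = 2)
  expect_lt(abs(s1$rms_displacement_A - sqrt(2)) / sqrt(2), 0.05)

  # two equal clusters 6 A apart: about half the frames near the mode
  rec2 <- tibble::tibble(frame = 1:400,
                         dx_A = rep(c(0.1, 6.1), each = 200),
                         dy_A = 0.1, theta_deg = 0, z_A = 0, s = 1L)
  s2 <- stability_summary(rec2, radius = 2)
  expect_equal(s2$frac_within_radius, 0.5, tolerance = 0.01)
})

test_that("orientation map writes JSON and autoplots", {
  p <- make_pose_traj(20, dx = 1, dy = 1, theta = 30, noise = 0.3, seed = 2)
  rec <- pose_cv(p$traj, p$ligand, identity_frame())
  m <- orientation_map(rec)
  path <- tempfile(fileext = ".json")
  write_orientation_map(m, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$bin_width_A, 0.5)
  expect_equal(sum(back$bins$occupancy), 1, tolerance = 1e-9)
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
})
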