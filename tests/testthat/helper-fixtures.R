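# Shared fixtures, all generated in code at test time.

identity_frame <- function() ref_frame(c(0, 0, 0), diag(3))

random_frame <- function() {
  ref_frame(stats::rnorm(3, sd = 5), t(helipose:::random_rotation()))
}

# Random step 6-tuple inside the bounded box used by the round-trip suite.
random_step_params <- function() {
  list(shift = stats::runif(1, -2, 2), slide = stats::runif(1, -2, 2),
       rise = stats::runif(1, 2, 6), tilt = stats::runif(1, -20, 20),
       roll = stats::runif(1, -20, 20), twist = stats::runif(1, 10, 50))
}

# Small planted-schedule trajectory covering every mode.
all_modes_schedule <- function(frames_each = 5, jitter = 0) {
  pose_schedule(
    c("UNBOUND", "STACKED_TERMINAL", "INTERCALATED_FULL",
      "INTERCALATED_PARTIAL", "MINOR_GROOVE_EMBEDDED", "MAJOR_GROOVE_CONTACT"),
    n_frames = rep(frames_each, 6),
    anchor = c(1, 8, 4, 4, 4, 4),
    jitter_sigma = jitter)
}

# Write a tiny multi-model PDB and return its path.
write_fixture_pdb <- function(traj, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "fixture.pdb")
  write_multimodel_pdb(traj, path)
  path
}

expect_frames_equal <- function(f1, f2, tol = 1e-6) {
  expect_lt(max(abs(f1$origin - f2$origin)), tol)
  expect_lt(max(abs(f1$axes - f2$axes)), tol)
}
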