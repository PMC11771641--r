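# Pipeline entry points: each stage reads a config (YAML path or list),
# validates it strictly (unknown keys are rejected), runs the underlying
# module functions, and writes CSV/JSON outputs plus the fully resolved
# config next to them. A thin command-line wrapper around these functions
# ships in inst/cli/helipose.R.

load_config <- function(config, allowed, required = character()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  miss <- setdiff(required, names(config))
  if (length(miss)) {
    stop("missing required config key(s): ", paste(miss, collapse = ", "))
  }
  config
}

write_resolved_config <- function(config, out_dir, stage) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(out_dir, paste0(stage, "_config_resolved.yaml")))
}

write_csv_ <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = FALSE)
  path
}

#' Generate the canonical synthetic fixture set
#'
#' Builds a planted-schedule ligand trajectory (multi-model PDB plus
#' ground-truth schedule JSON) and, optionally, umbrella window tables
#' drawn from the analytic double-well potential.
#'
#' Config keys: `out_dir`, `seed`, `sequence`, `noise_sigma`, `schedule`
#' (list of `{mode, n_frames, anchor, jitter_sigma}`), `windows`
#' (`{from, to, spacing, k, n_per_window, temperature}` or `NULL` to skip).
#'
#' @param config list or YAML path.
#' @return invisibly, a list of written paths.
#' @export
run_simulate <- function(config) {
  cfg <- load_config(config,
                     allowed = c("out_dir", "seed", "sequence", "noise_sigma",
                                 "schedule", "windows"),
                     required = c("out_dir"))
  cfg$seed <- cfg$seed %||% 1
  cfg$sequence <- cfg$sequence %||% "GCGCATATGCGC"
  cfg$noise_sigma <- cfg$noise_sigma %||% 0.3
  if (is.null(cfg$schedule)) {
    np <- nchar(cfg$sequence)
    cfg$schedule <- list(
      list(mode = "UNBOUND", n_frames = 40, anchor = 1, jitter_sigma = 0.1),
      list(mode = "STACKED_TERMINAL", n_frames = 80, anchor = np,
           jitter_sigma = 0.1),
      list(mode = "INTERCALATED_FULL", n_frames = 120,
           anchor = floor(np / 2), jitter_sigma = 0.1))
  }
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  sched <- dplyr::bind_rows(lapply(cfg$schedule, tibble::as_tibble))
  tr <- plant_ligand(cfg$sequence, sched, noise_sigma = cfg$noise_sigma,
                     seed = cfg$seed)
  paths <- list()
  paths$trajectory <- write_multimodel_pdb(tr, file.path(out, "fixture.pdb"))
  paths$pairs <- write_csv_(duplex_pairs(tr), file.path(out, "pairs.csv"))
  jsonlite::write_json(attr(tr, "truth"), file.path(out, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$truth <- file.path(out, "truth.json")
  if (!is.null(cfg$windows)) {
    w <- cfg$windows
    centers <- seq(w$from %||% 0.25, w$to %||% 3.0, by = w$spacing %||% 0.05)
    tabs <- sample_biased(double_well_potential, centers,
                          k = w$k %||% 2000,
                          n_per_window = w$n_per_window %||% 2000,
                          temperature = w$temperature %||% 298,
                          seed = cfg$seed)
    meta <- write_window_tables(tabs, file.path(out, "windows"))
    meta$file <- basename(meta$file)
    yaml::write_yaml(
      list(windows = lapply(seq_len(nrow(meta)), function(i) {
        list(file = meta$file[i], center_nm = meta$center_nm[i],
             k_kj_mol_nm2 = meta$k_kj_mol_nm2[i])
      })),
      file.path(out, "windows", "windows.yaml"))
    paths$windows <- file.path(out, "windows", "windows.yaml")
  }
  write_resolved_config(cfg, out, "simulate")
  invisible(paths)
}

#' Run the per-frame structural and pose analyses
#'
#' Config keys: `trajectory` (multi-model PDB), `pairs` (CSV with the pair
#' table), `ligand` (list with the [ligand_definition()] fields, or
#' `"none"` for a helical-only run), `out_dir`, `seed`, `frames`,
#' `bin_width`, `thresholds` (any of the [mode_thresholds()] names),
#' `min_duration`.
#'
#' @param config list or YAML path.
#' @return invisibly, a list of written paths.
#' @export
run_analyze <- function(config) {
  cfg <- load_config(config,
                     allowed = c("trajectory", "pairs", "ligand", "out_dir",
                                 "seed", "frames", "bin_width", "thresholds",
                                 "min_duration"),
                     required = c("trajectory", "pairs", "out_dir"))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tr <- read_multimodel_pdb(cfg$trajectory)
  pairs <- utils::read.csv(cfg$pairs)
  frames <- cfg$frames %||% seq_len(n_frames(tr))
  hp <- helical_parameters(tr, pairs, frames = frames)
  paths <- list(
    steps = write_csv_(hp$steps, file.path(out, "steps.csv")),
    pairs = write_csv_(hp$pairs, file.path(out, "pair_parameters.csv")),
    chi = write_csv_(hp$chi, file.path(out, "chi.csv")))
  summary <- list(
    n_frames = length(frames),
    n_pairs = nrow(pairs),
    mean_rise_A = mean(hp$steps$rise_A),
    mean_rise_nm = mean(hp$steps$rise_A) / 10,
    mean_twist_deg = mean(hp$steps$twist_deg))
  lig_cfg <- cfg$ligand
  if (is.null(lig_cfg) && any(tr$atoms$residue_name == "LIG")) {
    lig_cfg <- "default"
  }
  if (!is.null(lig_cfg) && !identical(lig_cfg, "none")) {
    ligand <- if (identical(lig_cfg, "default")) {
      ligand_template()$definition
    } else {
      do.call(ligand_definition, lig_cfg)
    }
    th <- do.call(mode_thresholds, cfg$thresholds %||% list())
    modes <- classify_modes(tr, ligand, pairs, frames = frames,
                            thresholds = th)
    episodes <- segment_modes(modes, min_duration = cfg$min_duration %||% 5)
    paths$modes <- write_csv_(modes, file.path(out, "modes.csv"))
    paths$episodes <- write_csv_(episodes, file.path(out, "episodes.csv"))
    provider <- function(i) pair_frames_for_frame(tr, pairs, i)[[1]]
    records <- pose_cv(tr, ligand, provider, frames = frames)
    paths$pose <- write_csv_(records, file.path(out, "pose.csv"))
    if (any(!is.na(records$theta_deg))) {
      om <- orientation_map(records, bin_width = cfg$bin_width %||% 0.5)
      paths$orientation_map <- write_orientation_map(
        om, file.path(out, "orientation_map.json"))
    }
    summary$final_mode <- episodes$label[nrow(episodes)]
    summary$n_episodes <- nrow(episodes)
  }
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$summary <- file.path(out, "summary.json")
  write_resolved_config(cfg, out, "analyze")
  invisible(paths)
}

#' Run the hotspot (stress-profile) analysis
#'
#' Config keys: `steps` (CSV from [run_analyze()]), `out_dir`, `window`,
#' `high`, `low`, `time_slice`, `events` (optional intercalation anchor
#' steps for the enrichment test), `n_perm`, `seed`.
#'
#' @param config list or YAML path.
#' @return invisibly, a list of written paths.
#' @export
run_hotspot <- function(config) {
  cfg <- load_config(config,
                     allowed = c("steps", "out_dir", "window", "high", "low",
                                 "time_slice", "events", "n_perm", "seed"),
                     required = c("steps", "out_dir"))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  steps <- utils::read.csv(cfg$steps)
  prof <- stress_profile(steps,
                         window = cfg$window %||% 5,
                         high = cfg$high %||% 3.5, low = cfg$low %||% 3.2,
                         time_slice = unlist(cfg$time_slice))
  paths <- list(
    profile = write_csv_(tidy(prof), file.path(out, "stress_profile.csv")),
    bed = write_flag_bed(prof, file.path(out, "stress_flags.bed")))
  report <- list(profile_summary = as.list(glance(prof)))
  if (!is.null(cfg$events)) {
    ov <- hotspot_overlap(prof, unlist(cfg$events),
                          n_perm = cfg$n_perm %||% 10000,
                          seed = cfg$seed %||% 1)
    report$overlap <- as.list(ov)
  }
  jsonlite::write_json(report, file.path(out, "hotspot_report.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$report <- file.path(out, "hotspot_report.json")
  write_resolved_config(cfg, out, "hotspot")
  invisible(paths)
}

#' Run the umbrella-sampling PMF reconstruction
#'
#' Config keys: `windows` (YAML window-metadata config, see
#' [read_window_config()]), `out_dir`, `last_ns`, `bin_width`,
#' `temperature`, `tol`, `max_iter`, `n_boot`, `seed`, `reference_region`,
#' `landmarks` (named list of CV intervals, nm).
#'
#' @param config list or YAML path.
#' @return invisibly, a list of written paths.
#' @export
run_pmf <- function(config) {
  cfg <- load_config(config,
                     allowed = c("windows", "out_dir", "last_ns", "bin_width",
                                 "temperature", "tol", "max_iter", "n_boot",
                                 "seed", "reference_region", "landmarks"),
                     required = c("windows", "out_dir"))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tabs <- read_window_config(cfg$windows)
  uw <- lapply(tabs, filter_production, last = cfg$last_ns %||% 20)
  args <- list(windows = uw,
               bin_width = cfg$bin_width %||% 0.01,
               temperature = cfg$temperature %||% 298,
               tol = cfg$tol %||% 1e-7,
               max_iter = cfg$max_iter %||% 100000,
               reference_region = unlist(cfg$reference_region))
  prof <- if ((cfg$n_boot %||% 0) >= 2) {
    do.call(bootstrap_error,
            c(list(windows = uw, n_boot = cfg$n_boot, seed = cfg$seed %||% 1),
              args[-1]))
  } else {
    do.call(solve_wham, args)
  }
  paths <- list(pmf = write_csv_(tidy(prof), file.path(out, "pmf.csv")))
  writeLines(sprintf("iter %d residual %.3e", seq_along(prof$residual_trace),
                     prof$residual_trace),
             file.path(out, "wham_convergence.log"))
  paths$log <- file.path(out, "wham_convergence.log")
  report <- list(glance = as.list(glance(prof)))
  if (!is.null(cfg$landmarks)) {
    lm <- landmark_report(prof, lapply(cfg$landmarks, unlist))
    report$minima <- lm$minima
    report$barriers <- lm$barriers
  }
  jsonlite::write_json(report, file.path(out, "landmarks.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$landmarks <- file.path(out, "landmarks.json")
  write_resolved_config(cfg, out, "pmf")
  invisible(paths)
}
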