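# Umbrella-window time-series tables: plain-text two-column files
# (time ns, CV nm), '#' comments, whitespace- or comma-delimited.

#' Read umbrella-sampling window tables
#'
#' Reads one file per biased window together with its bias metadata. No
#' time filtering happens here; see [filter_production()].
#'
#' @param paths character vector of file paths.
#' @param centers numeric vector of window centers, nm (one per file).
#' @param spring_constants numeric vector (or scalar, recycled) of harmonic
#'   spring constants, kJ mol^-1 nm^-2.
#' @return a list of `window_table` objects sorted by center (duplicate
#'   centers are kept, never merged), each with fields `center`, `k`,
#'   `samples` (tibble: `time_ns`, `cv_nm`) and `source`.
#' @export
read_window_tables <- function(paths, centers, spring_constants) {
  if (length(centers) != length(paths)) {
    stop("need one center per file")
  }
  spring_constants <- rep_len(spring_constants, length(paths))
  if (any(spring_constants <= 0)) stop("spring constants must be > 0")
  tabs <- purrr::pmap(list(paths, centers, spring_constants),
                      function(p, ctr, k) {
    if (!file.exists(p)) stop("no such file: ", p)
    lines <- readLines(p, warn = FALSE)
    keep <- which(!grepl("^\\s*(#|$)", lines))
    if (!length(keep)) stop("no data rows in ", p)
    vals <- lapply(keep, function(i) {
      fields <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
      v <- suppressWarnings(as.numeric(fields))
      if (length(v) < 2 || anyNA(v[1:2]) || !all(is.finite(v[1:2]))) {
        stop("non-numeric cell in ", p, " at line ", i)
      }
      v[1:2]
    })
    m <- do.call(rbind, vals)
    structure(list(center = ctr, k = k,
                   samples = tibble::tibble(time_ns = m[, 1], cv_nm = m[, 2]),
                   source = p),
              class = "window_table")
  })
  tabs[order(vapply(tabs, `[[`, numeric(1), "center"))]
}

#' Read window metadata config and its tables
#'
#' The config (YAML or JSON) holds a list `windows:` of entries
#' `{file, center_nm, k_kj_mol_nm2}`; file paths are resolved relative to
#' the config file.
#'
#' @param config_path path to a YAML/JSON config.
#' @return list of `window_table` as in [read_window_tables()].
#' @export
read_window_config <- function(config_path) {
  cfg <- if (grepl("\\.json$", config_path)) {
    jsonlite::fromJSON(config_path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(config_path)
  }
  if (is.null(cfg$windows) || !length(cfg$windows)) {
    stop("config has no 'windows' list: ", config_path)
  }
  dir <- dirname(config_path)
  files <- vapply(cfg$windows, function(w) {
    p <- w$file
    if (!grepl("^/", p)) p <- file.path(dir, p)
    p
  }, character(1))
  read_window_tables(
    files,
    centers = vapply(cfg$windows, function(w) as.numeric(w$center_nm), numeric(1)),
    spring_constants = vapply(cfg$windows, function(w) as.numeric(w$k_kj_mol_nm2), numeric(1)))
}

#' Write window tables to plain-text files
#'
#' @param windows list of `window_table`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return tibble with columns `file`, `center_nm`, `k_kj_mol_nm2`.
#' @export
write_window_tables <- function(windows, dir, prefix = "window") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- purrr::imap(windows, function(w, i) {
    f <- file.path(dir, sprintf("%s_%03d.dat", prefix, i))
    con <- file(f, "w")
    writeLines(sprintf("# center_nm %.6g k_kj_mol_nm2 %.6g", w$center, w$k), con)
    writeLines(sprintf("%.6f %.8f", w$samples$time_ns, w$samples$cv_nm), con)
    close(con)
    tibble::tibble(file = f, center_nm = w$center, k_kj_mol_nm2 = w$k)
  })
  dplyr::bind_rows(meta)
}
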