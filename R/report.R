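#' Run configuration for an end-to-end analysis
#'
#' Bundles input paths and analysis options for [run_report()]. All defaults
#' are recorded in the provenance block of the report so that reruns are
#' auditable.
#'
#' @param contour_csv optional path to a PF contour table.
#' @param kymo_csv optional path to a kymograph trace table.
#' @param out_dir output directory (created if absent).
#' @param pixel_size,frame_interval kymograph calibration.
#' @param step,window,degree,n_terminal_joints PF pipeline options.
#' @param min_pause_s,max_pause_rate pause rule options.
#' @param seed integer seed recorded in the provenance (the analyses
#'   themselves are deterministic).
#' @return An object of class `run_config`.
#' @export
run_config <- function(contour_csv = NULL, kymo_csv = NULL,
                       out_dir = tempfile("tipshape-report-"),
                       pixel_size = 0.064, frame_interval = 3,
                       step = 2, window = 10L, degree = 2L,
                       n_terminal_joints = 3L,
                       min_pause_s = 15, max_pause_rate = 0.05,
                       seed = 1L) {
  for (p in c(contour_csv, kymo_csv))
    if (!is.null(p) && !file.exists(p))
      stop("input file not found: ", p, call. = FALSE)
  num <- c(pixel_size = pixel_size, frame_interval = frame_interval,
           step = step, window = window, degree = degree,
           n_terminal_joints = n_terminal_joints, min_pause_s = min_pause_s)
  if (any(num <= 0))
    stop("non-positive option(s): ",
         paste(names(num)[num <= 0], collapse = ", "), call. = FALSE)
  structure(list(contour_csv = contour_csv, kymo_csv = kymo_csv,
                 out_dir = out_dir, pixel_size = pixel_size,
                 frame_interval = frame_interval, step = step,
                 window = as.integer(window), degree = as.integer(degree),
                 n_terminal_joints = as.integer(n_terminal_joints),
                 min_pause_s = min_pause_s, max_pause_rate = max_pause_rate,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  opts <- config[setdiff(names(config), "out_dir")]
  jsonlite::write_json(opts, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the configured analyses end to end
#'
#' Executes the PF-geometry pipeline on the contour table (per-end
#' statistics, capping fractions, curvature--length correlation, tip-aligned
#' profile) and the kymograph pipeline on the trace table (classified
#' events, end categories, catastrophe frequency, time-weighted rate table),
#' writes CSV and JSON outputs into `config$out_dir`, and embeds a
#' provenance block (package version, config hash, seed). Given the same
#' config and inputs the outputs are byte-identical.
#'
#' @param config a [run_config()].
#' @return An object of class `report_bundle`: list with `per_end`
#'   (data.frame), `cap_stats`, `correlation`, `tip_profile`, `events`,
#'   `categories`, `catastrophe`, `rate_table` and `provenance`, plus
#'   `paths` of the written files. Components of unconfigured stages are
#'   `NULL`.
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  per_end <- cap_stats <- correlation <- tip_profile <- NULL
  events <- categories <- catastrophe <- rate_table <- NULL

  if (!is.null(config$contour_csv)) {
    ends <- tryCatch(read_contour_table(config$contour_csv),
                     error = function(e) stop("stage pf_geometry/read: ",
                                              conditionMessage(e),
                                              call. = FALSE))
    stats <- lapply(ends, per_end_stats, step = config$step,
                    window = config$window, degree = config$degree,
                    n_terminal_joints = config$n_terminal_joints)
    per_end <- per_end_table(stats)
    cap_stats <- cap_statistics(ends, mode = "per_grid")
    pooled <- cap_statistics(ends, mode = "pooled")
    ok <- sum(!is.na(per_end$mean_curvature_deg_per_nm) &
                !is.na(per_end$mean_length_nm))
    correlation <- if (ok >= 3L &&
                       sd(per_end$mean_curvature_deg_per_nm, na.rm = TRUE) > 0 &&
                       sd(per_end$mean_length_nm, na.rm = TRUE) > 0)
      curvature_length_correlation(stats) else NULL
    profiles <- list()
    for (e in ends) for (tr in e$traces) {
      sm <- loess_smooth(resample_uniform(tr, step = config$step),
                         window_points = config$window,
                         degree = config$degree)
      pr <- curvature_profile(sm)
      if (!pr$empty) profiles[[length(profiles) + 1L]] <- pr
    }
    tip_profile <- if (length(profiles)) tip_aligned_profile(profiles) else NULL
    p <- file.path(config$out_dir, "per_end_stats.csv")
    write.csv(per_end, p, row.names = FALSE); paths <- c(paths, p)
    if (!is.null(tip_profile)) {
      p <- file.path(config$out_dir, "tip_aligned_profile.csv")
      write.csv(data.frame(offset_nm = tip_profile$offsets,
                           mean_curvature = tip_profile$mean_curvature,
                           sem_curvature = tip_profile$sem_curvature,
                           n = tip_profile$n_per_offset),
                p, row.names = FALSE)
      paths <- c(paths, p)
    }
    cap_stats$pooled <- pooled
  }

  if (!is.null(config$kymo_csv)) {
    calib <- kymo_calibration(config$pixel_size, config$frame_interval)
    events <- tryCatch(
      read_kymo_table(config$kymo_csv, calib,
                      min_pause_s = config$min_pause_s,
                      max_pause_rate = config$max_pause_rate),
      error = function(e) stop("stage kymo_dynamics/read: ",
                               conditionMessage(e), call. = FALSE))
    if (nrow(events)) {
      categories <- vapply(split(events, events$mt_id), end_category, "")
      catastrophe <- catastrophe_frequency(events)
      rate_table <- time_weighted_rate_distribution(events)$table
      p <- file.path(config$out_dir, "events.csv")
      write_events_table(events, p); paths <- c(paths, p)
      p <- file.path(config$out_dir, "rate_distribution.csv")
      write.csv(rate_table, p, row.names = FALSE); paths <- c(paths, p)
    }
  }

  provenance <- list(package = "tipshape",
                     version = as.character(packageVersion("tipshape")),
                     config_hash = config_hash(config),
                     seed = config$seed,
                     options = config[setdiff(names(config),
                                              c("out_dir"))])
  summary <- list(
    provenance = provenance,
    cap_fractions = if (!is.null(cap_stats)) list(
      per_grid = cap_stats$summary, pooled = cap_stats$pooled) else NULL,
    correlation = correlation,
    tip_profile_fit = if (!is.null(tip_profile)) list(
      slope = tip_profile$fit_slope,
      intercept = tip_profile$fit_intercept) else NULL,
    end_categories = if (!is.null(categories))
      as.list(table(categories)) else NULL,
    catastrophe = catastrophe)
  p <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  paths <- c(paths, p)

  structure(list(per_end = per_end, cap_stats = cap_stats,
                 correlation = correlation, tip_profile = tip_profile,
                 events = events, categories = categories,
                 catastrophe = catastrophe, rate_table = rate_table,
                 provenance = provenance, paths = paths),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  if (!is.null(x$per_end))
    cat(sprintf("  per-end stats: %d MT ends\n", nrow(x$per_end)))
  if (!is.null(x$events))
    cat(sprintf("  events: %d (%d MTs)\n", nrow(x$events),
                length(unique(x$events$mt_id))))
  cat(sprintf("  outputs: %s\n", paste(basename(x$paths), collapse = ", ")))
  invisible(x)
}
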