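#' Run configuration for pipeline entry points
#'
#' Collects the paths and analysis options used by [run_subject()] and
#' [run_cohort()]. Can be read from a YAML file whose keys mirror the
#' argument names.
#'
#' @param series_path 4D BOLD NIfTI path.
#' @param mask_path VOI label NIfTI path.
#' @param legend Named legend vector or path to a JSON/YAML legend file.
#' @param records_path CSV of subject records (for cohort runs).
#' @param out_dir Output directory, created if absent.
#' @param timing A [protocol_timing()].
#' @param window_s Peak averaging window (s).
#' @param alpha Significance level for group statistics.
#' @param posthoc `"tukey"` or `"bonferroni"`.
#' @param exclusions Character vector of subject IDs excluded as outliers,
#'   applied with reason `"user exclusion list"`. Exclusion is never
#'   automatic.
#' @param seed Integer seed recorded in the run log.
#' @return An object of class `run_config`.
#' @export
run_config <- function(series_path = NULL, mask_path = NULL, legend = NULL,
                       records_path = NULL, out_dir = ".",
                       timing = protocol_timing(), window_s = 3,
                       alpha = 0.05, posthoc = "tukey",
                       exclusions = character(0), seed = 1L) {
  if (!(alpha > 0 && alpha < 1))
    stop_with("muscleBOLD_bad_config", "alpha must be in (0, 1)")
  structure(list(series_path = series_path, mask_path = mask_path,
                 legend = legend, records_path = records_path,
                 out_dir = out_dir, timing = timing, window_s = window_s,
                 alpha = alpha, posthoc = posthoc, exclusions = exclusions,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys as in [run_config()], with `timing` given as a
#'   mapping of [protocol_timing()] arguments.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_with("muscleBOLD_bad_config", "config file not found: %s", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$timing)) y$timing <- do.call(protocol_timing, y$timing)
  do.call(run_config, y)
}

check_paths <- function(config, what) {
  for (p in what) {
    val <- config[[p]]
    if (is.null(val))
      stop_with("muscleBOLD_bad_config", "config lacks '%s'", p)
    if (is.character(val) && length(val) == 1L && !file.exists(val) &&
        p != "legend")
      stop_with("muscleBOLD_bad_config", "%s does not exist: %s", p, val)
  }
  invisible(config)
}

round_df <- function(df, digits_map) {
  for (col in names(digits_map))
    if (col %in% names(df) && is.numeric(df[[col]]))
      df[[col]] <- round(df[[col]], digits_map[[col]])
  df
}

write_run_log <- function(config, out_dir, extra = list()) {
  cfg <- unclass(config)
  cfg$timing <- unclass(cfg$timing)
  key <- utf8ToInt(paste(unlist(lapply(cfg, format)), collapse = "|"))
  log <- c(list(package_version = as.character(utils::packageVersion("muscleBOLD")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                config_hash = sprintf("%08x", sum(key * (seq_along(key) %% 97L)) %%
                                        .Machine$integer.max),
                seed = config$seed, config = cfg), extra)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(log)
}

#' Analyse one subject: VOI time courses and the four indices per muscle
#'
#' Reads the series + mask, extracts and normalises each muscle's time
#' course, computes PHV/TTP/MIV/TTR, and writes `indices.csv` (display
#' rounding: one decimal), `indices.json` (full precision),
#' `timecourses.csv` (long-format percent-change curves), and
#' `run_log.json`. All results are computed before anything is written, so a
#' failure leaves no partial output. Deterministic given the inputs.
#'
#' @param config A [run_config()] with `series_path`, `mask_path`, `legend`,
#'   and `out_dir` set.
#' @return Invisibly, the per-muscle indices data.frame.
#' @export
run_subject <- function(config) {
  stopifnot(inherits(config, "run_config"))
  check_paths(config, c("series_path", "mask_path", "legend"))
  series <- read_bold_series(config$series_path)
  legend <- if (is.character(config$legend) && length(config$legend) == 1L &&
                file.exists(config$legend)) read_voi_legend(config$legend)
            else config$legend
  mask <- read_voi_labels(config$mask_path, legend)
  validate_alignment(series, mask)
  muscles <- intersect(calf_muscles(), mask$legend)
  if (length(muscles) == 0L)
    stop_with("muscleBOLD_bad_config", "mask legend names no calf muscle")
  rows <- list(); curves <- list()
  for (m in muscles) {
    raw <- extract_voi_timecourse(series, mask, m,
                                  start = config$timing$baseline_start)
    ntc <- percent_change_normalize(raw, config$timing)
    idx <- compute_indices(ntc, config$timing, window_s = config$window_s)
    tab <- as.data.frame(idx)
    tab$n_voxels <- ntc$n_voxels
    tab$baseline_si <- ntc$baseline_si
    tab$baseline_sd <- ntc$baseline_sd
    rows[[m]] <- tab
    curves[[m]] <- data.frame(muscle = m, time_s = ntc$times, pct = ntc$pct,
                              stringsAsFactors = FALSE)
  }
  indices <- do.call(rbind, rows); rownames(indices) <- NULL
  curves <- do.call(rbind, curves); rownames(curves) <- NULL
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  disp <- round_df(indices, list(phv = 1, ttp = 1, miv = 1, ttr = 1,
                                 baseline_si = 1, baseline_sd = 2))
  utils::write.csv(disp, file.path(config$out_dir, "indices.csv"),
                   row.names = FALSE)
  jsonlite::write_json(indices, file.path(config$out_dir, "indices.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(round_df(curves, list(pct = 4, time_s = 2)),
                   file.path(config$out_dir, "timecourses.csv"),
                   row.names = FALSE)
  write_run_log(config, config$out_dir)
  invisible(indices)
}

#' Cohort analysis: repeatability, group/muscle comparisons, correlations
#'
#' Takes a subject-record table (data.frame or CSV path in the config),
#' applies the configured exclusion list, and writes `repeatability.csv`
#' (mean, SD, CV per visit and the paired p-value, per muscle x parameter),
#' `group_stats.csv` (omnibus ANOVA plus post-hoc rows), `correlations.csv`
#' (PHV vs vertical/broad jump per muscle), and a full-precision
#' `cohort.json`. Display rounding: indices/CV one decimal, r two, p three.
#' When only controls are present the group comparison is skipped with a
#' message; when no second visit exists the repeatability table degrades to
#' single-visit moments.
#'
#' @param config A [run_config()]; `records_path` used when `records` is
#'   missing.
#' @param records Optional [subject_records()] data.frame, overriding
#'   `records_path`.
#' @return Invisibly, a list with elements `repeatability`, `group_stats`,
#'   `correlations`.
#' @export
run_cohort <- function(config, records = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(records)) {
    check_paths(config, "records_path")
    records <- utils::read.csv(config$records_path, stringsAsFactors = FALSE)
  }
  records <- subject_records(records)
  if (length(config$exclusions)) {
    sel <- records$subject_id %in% config$exclusions
    records$excluded[sel] <- TRUE
    records$exclude_reason[sel] <- "user exclusion list"
  }
  rep_tab <- repeatability_table(records)
  groups_present <- unique(records$group)
  gstats <- NULL
  if (length(groups_present) >= 2L) {
    gstats <- lapply(index_parameters(), function(p)
      group_muscle_anova(records, p, alpha = config$alpha,
                         posthoc = config$posthoc))
    names(gstats) <- index_parameters()
  } else {
    message("single subject group present; group comparison skipped")
  }
  cors <- do.call(rbind, lapply(unique(records$muscle), function(m) {
    rbind(try_cor(records, m, "vertical"), try_cor(records, m, "broad"))
  }))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    round_df(rep_tab, list(visit1_mean = 1, visit1_sd = 1, visit1_cv = 1,
                           visit2_mean = 1, visit2_sd = 1, visit2_cv = 1,
                           paired_p = 3)),
    file.path(config$out_dir, "repeatability.csv"), row.names = FALSE)
  if (!is.null(gstats)) {
    omni <- do.call(rbind, lapply(gstats, function(g) g$omnibus))
    utils::write.csv(round_df(omni, list(F = 2, anova_p = 3)),
                     file.path(config$out_dir, "group_stats.csv"),
                     row.names = FALSE)
    ph <- do.call(rbind, lapply(gstats, function(g)
      if (!is.null(g$posthoc)) cbind(parameter = g$parameter, g$posthoc)))
    if (!is.null(ph))
      utils::write.csv(round_df(ph, list(diff = 1, p = 3)),
                       file.path(config$out_dir, "group_posthoc.csv"),
                       row.names = FALSE)
  }
  if (!is.null(cors))
    utils::write.csv(round_df(cors, list(r = 2, p = 3)),
                     file.path(config$out_dir, "correlations.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(repeatability = rep_tab,
         group_stats = if (!is.null(gstats))
           lapply(gstats, function(g) unclass(g)[c("omnibus", "normality",
                                                   "posthoc")]),
         correlations = cors),
    file.path(config$out_dir, "cohort.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_run_log(config, config$out_dir)
  invisible(list(repeatability = rep_tab, group_stats = gstats,
                 correlations = cors))
}

try_cor <- function(records, muscle, measure) {
  tryCatch(jump_correlation(records, muscle, measure),
           muscleBOLD_error = function(e) NULL)
}

#' Average normalised time courses across subjects
#'
#' Produces the group-averaged dynamic curve (mean percent change per frame
#' across subjects) used for cohort-level time-course figures.
#'
#' @param curves List of `normalized_timecourse` objects on a common frame
#'   grid.
#' @return A `normalized_timecourse` with the frame-wise mean and the pooled
#'   voxel count.
#' @export
average_timecourses <- function(curves) {
  stopifnot(length(curves) >= 1L)
  nt <- length(curves[[1L]]$pct)
  for (cv in curves)
    if (length(cv$pct) != nt || max(abs(cv$times - curves[[1L]]$times)) > 1e-6)
      stop_with("muscleBOLD_bad_times",
                "all time courses must share one frame grid")
  m <- rowMeans(vapply(curves, function(cv) cv$pct, numeric(nt)))
  out <- curves[[1L]]
  out$pct <- m
  out$n_voxels <- sum(vapply(curves, function(cv) cv$n_voxels, integer(1)))
  out$muscle <- paste0(curves[[1L]]$muscle, " (group mean of ",
                       length(curves), ")")
  out
}
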