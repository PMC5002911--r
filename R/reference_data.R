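#' Published test-retest reference values for the four BOLD indices
#'
#' Per-muscle, per-visit mean, sample SD, coefficient of variation, and the
#' paired visit-comparison p-value of the four oximetry indices, reported for
#' a cohort of 10 sedentary control subjects scanned twice (at least one week
#' apart) under the standard 15-minute cuff paradigm. Used as the default
#' parameterization of the cohort generator and as worked examples for
#' [coefficient_of_variation()]. Note that several printed CVs were derived
#' from unrounded source moments, so recomputing `100 * sd / |mean|` from the
#' rounded columns reproduces the printed CV to one decimal only for a subset
#' of rows.
#'
#' @return data.frame with columns `muscle`, `parameter` (`phv`, `miv`,
#'   `ttp`, `ttr`), `visit`, `mean`, `sd`, `cv` (%), `paired_p`. Units: %
#'   for `phv`/`miv`, seconds for `ttp`/`ttr`.
#' @export
retest_reference <- function() {
  utils::read.csv(system.file("extdata", "retest_reference.csv",
                              package = "muscleBOLD", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
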