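#' Protocol timing for the cuff occlusion / reactive hyperemia paradigm
#'
#' Describes the three-phase acquisition on a common time axis: resting
#' baseline from `baseline_start` to `occlusion_start`, proximal cuff
#' occlusion (ischemia) until `deflation_time`, then reactive hyperemia until
#' `end_time`. Defaults encode the standard 15-minute protocol: 5 min
#' baseline, 5 min occlusion, 5 min hyperemia at TR = 3 s.
#'
#' `baseline_discard` frames are dropped from the start of the baseline phase
#' before the baseline statistic is computed, to skip T1 saturation
#' transients at the beginning of the acquisition.
#'
#' @param baseline_start Start of baseline phase (s).
#' @param occlusion_start Cuff inflation time (s).
#' @param deflation_time Cuff deflation time (s).
#' @param end_time End of acquisition (s).
#' @param tr Repetition time (s per volume).
#' @param baseline_discard Number of initial baseline frames excluded from
#'   the baseline statistic; at least 3 usable baseline frames must remain.
#' @return An object of class `protocol_timing`.
#' @export
protocol_timing <- function(baseline_start = 0, occlusion_start = 300,
                            deflation_time = 600, end_time = 900,
                            tr = 3, baseline_discard = 5) {
  if (!(baseline_start < occlusion_start && occlusion_start < deflation_time &&
        deflation_time < end_time))
    stop_with("muscleBOLD_bad_timing",
              "phase boundaries must satisfy baseline < occlusion < deflation < end")
  if (tr <= 0) stop_with("muscleBOLD_bad_tr", "'tr' must be positive")
  baseline_discard <- as.integer(baseline_discard)
  if (baseline_discard < 0L)
    stop_with("muscleBOLD_bad_timing", "'baseline_discard' must be >= 0")
  n_baseline <- floor((occlusion_start - baseline_start) / tr + 1e-9)
  if (n_baseline - baseline_discard < 3L)
    stop_with("muscleBOLD_bad_timing",
              "baseline phase leaves %d usable frames after discarding %d; need >= 3",
              n_baseline - baseline_discard, baseline_discard)
  structure(list(baseline_start = baseline_start,
                 occlusion_start = occlusion_start,
                 deflation_time = deflation_time,
                 end_time = end_time, tr = tr,
                 baseline_discard = baseline_discard),
            class = "protocol_timing")
}

#' @export
print.protocol_timing <- function(x, ...) {
  cat(sprintf(paste0("<protocol_timing> baseline [%g, %g) s | occlusion [%g, %g) s | ",
                     "hyperemia [%g, %g] s; TR = %g s, discard %d baseline frames\n"),
              x$baseline_start, x$occlusion_start, x$occlusion_start,
              x$deflation_time, x$deflation_time, x$end_time, x$tr,
              x$baseline_discard))
  invisible(x)
}

#' Frame-centre timestamps
#'
#' Frame `i` of an acquisition starting at `start` covers
#' `[start + (i-1)*tr, start + i*tr)` and is timestamped at its centre.
#'
#' @param n Number of frames.
#' @param tr Repetition time (s).
#' @param start Acquisition start time (s).
#' @return Numeric vector of `n` frame-centre times.
#' @export
frame_times <- function(n, tr, start = 0) start + (seq_len(n) - 0.5) * tr

#' Extract the mean signal time course of one muscle VOI
#'
#' For every time frame, averages the raw signal intensity over all voxels
#' carrying the muscle's label (unweighted voxel mean).
#'
#' @param series A [bold_series()].
#' @param mask A [voi_label_map()] aligned with `series`.
#' @param muscle Muscle name present in the mask legend.
#' @param start Time of acquisition start (s); defaults to 0.
#' @return An object of class `raw_timecourse` with fields `muscle`, `times`
#'   (frame centres, s), `si` (mean signal per frame, scanner units),
#'   `n_voxels`, and `tr`.
#' @export
extract_voi_timecourse <- function(series, mask, muscle, start = 0) {
  validate_alignment(series, mask)
  hit <- names(mask$legend)[mask$legend == muscle]
  if (length(hit) != 1L)
    stop_with("muscleBOLD_unknown_muscle",
              "muscle '%s' is not in the mask legend (%s)", muscle,
              paste(mask$legend, collapse = ", "))
  idx <- which(mask$labels == as.integer(hit))
  if (length(idx) == 0L)
    stop_with("muscleBOLD_empty_voi", "VOI '%s' contains no voxels", muscle)
  d <- dim(series$voxels)
  m <- matrix(series$voxels, nrow = prod(d[1:3]), ncol = d[4])
  si <- colMeans(m[idx, , drop = FALSE])
  structure(list(muscle = muscle,
                 times = frame_times(d[4], series$tr, start),
                 si = si, n_voxels = length(idx), tr = series$tr),
            class = "raw_timecourse")
}

#' Normalise a raw VOI time course to percent change from baseline
#'
#' The baseline signal intensity (baseline SI) is the mean raw signal over
#' the baseline-phase frames, after dropping the first
#' `timing$baseline_discard` of them. Every frame is then expressed as
#' `100 * (SI - baseline SI) / baseline SI`, i.e. percent change from the
#' resting baseline. By construction, the mean of the normalised signal over
#' the usable baseline frames is zero.
#'
#' @param raw A [raw_timecourse][extract_voi_timecourse()].
#' @param timing A [protocol_timing()].
#' @param detrend_baseline If `TRUE`, a linear trend fitted to the usable
#'   baseline frames is removed from the whole series before normalisation.
#'   Off by default: the standard analysis applies no drift correction.
#' @return An object of class `normalized_timecourse` with fields `muscle`,
#'   `times`, `pct` (percent change per frame), `baseline_si`, `baseline_sd`
#'   (both in scanner units), `n_voxels`, and `tr`.
#' @export
percent_change_normalize <- function(raw, timing, detrend_baseline = FALSE) {
  stopifnot(inherits(raw, "raw_timecourse"), inherits(timing, "protocol_timing"))
  bl <- which(raw$times >= timing$baseline_start &
              raw$times < timing$occlusion_start)
  if (length(bl) == 0L)
    stop_with("muscleBOLD_no_baseline", "time course does not cover the baseline window")
  use <- bl[seq_along(bl) > timing$baseline_discard]
  if (length(use) < 3L)
    stop_with("muscleBOLD_no_baseline",
              "only %d usable baseline frames after discarding %d; need >= 3",
              length(use), timing$baseline_discard)
  si <- raw$si
  if (detrend_baseline) {
    fit <- stats::lm(si[use] ~ raw$times[use])
    si <- si - stats::coef(fit)[2] * (raw$times - mean(raw$times[use]))
  }
  b <- mean(si[use])
  if (!is.finite(b) || b <= 0)
    stop_with("muscleBOLD_bad_baseline", "baseline SI must be positive, got %g", b)
  structure(list(muscle = raw$muscle, times = raw$times,
                 pct = 100 * (si - b) / b,
                 baseline_si = b, baseline_sd = stats::sd(si[use]),
                 n_voxels = raw$n_voxels, tr = raw$tr),
            class = "normalized_timecourse")
}

#' Construct a normalized time course directly
#'
#' Mostly used by the simulation layer; [percent_change_normalize()] is the
#' route for measured data.
#'
#' @param muscle Muscle name.
#' @param times Frame-centre times (s), strictly increasing, constant step.
#' @param pct Percent-change values, one per frame.
#' @param tr Repetition time (s).
#' @param baseline_si,baseline_sd Baseline signal mean/SD in scanner units.
#' @param n_voxels VOI voxel count.
#' @return A `normalized_timecourse`.
#' @export
normalized_timecourse <- function(muscle, times, pct, tr,
                                  baseline_si = 100, baseline_sd = 0,
                                  n_voxels = 1L) {
  stopifnot(length(times) == length(pct), length(times) >= 2L)
  dt <- diff(times)
  if (any(dt <= 0) || max(abs(dt - tr)) > 1e-6)
    stop_with("muscleBOLD_bad_times",
              "'times' must increase in constant steps of tr = %g s", tr)
  structure(list(muscle = muscle, times = as.numeric(times),
                 pct = as.numeric(pct), baseline_si = baseline_si,
                 baseline_sd = baseline_sd, n_voxels = as.integer(n_voxels),
                 tr = tr),
            class = "normalized_timecourse")
}

#' @export
print.normalized_timecourse <- function(x, ...) {
  cat(sprintf("<normalized_timecourse> %s: %d frames @ TR %g s, %d voxels, baseline SI %.1f\n",
              x$muscle, length(x$pct), x$tr, x$n_voxels, x$baseline_si))
  invisible(x)
}

#' Trailing rolling average of a normalised time course
#'
#' Generalises the short-window averaging used for peak detection. The window
#' length is `w = max(1, round(window_s / tr))` frames; output value `i` is
#' the mean of frames `i .. i+w-1`, timestamped at the centre of the window,
#' so the result has `nt - w + 1` frames. At the standard TR of 3 s a
#' "3-second average" is a single frame and the operation is the identity.
#'
#' @param ntc A `normalized_timecourse`.
#' @param window_s Averaging window in seconds (> 0).
#' @return A `normalized_timecourse` with `nt - w + 1` frames.
#' @export
rolling_average <- function(ntc, window_s) {
  stopifnot(inherits(ntc, "normalized_timecourse"))
  if (window_s <= 0) stop_with("muscleBOLD_bad_window", "'window_s' must be > 0")
  w <- max(1L, as.integer(round(window_s / ntc$tr)))
  nt <- length(ntc$pct)
  if (w > nt)
    stop_with("muscleBOLD_bad_window",
              "window of %d frames exceeds series length %d", w, nt)
  if (w == 1L) return(ntc)
  out <- structure(ntc, class = "normalized_timecourse")
  out$pct <- as.numeric(zoo::rollmean(ntc$pct, w, align = "left"))
  out$times <- as.numeric(zoo::rollmean(ntc$times, w, align = "left"))
  out
}
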