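#' Peak hyperemic value and time to peak
#'
#' PHV is the highest short-window average of the percent-change signal
#' recorded after cuff deflation (default window 3 s); TTP is the time from
#' cuff deflation to that peak, measured at the centre of the first maximal
#' window. Ties resolve to the earliest window so TTP is deterministic.
#'
#' @param ntc A `normalized_timecourse` covering the post-deflation window.
#' @param timing A [protocol_timing()].
#' @param window_s Averaging window in seconds.
#' @return `list(phv = %, ttp = s)`.
#' @export
compute_phv_ttp <- function(ntc, timing, window_s = 3) {
  stopifnot(inherits(ntc, "normalized_timecourse"),
            inherits(timing, "protocol_timing"))
  seg <- window_segment(ntc, timing$deflation_time, timing$end_time,
                        closed_right = TRUE)
  if (is.null(seg))
    stop_with("muscleBOLD_empty_segment", "no frames after cuff deflation")
  sm <- rolling_average(seg, window_s)
  i <- which.max(sm$pct)  # first maximal window
  list(phv = sm$pct[i], ttp = sm$times[i] - timing$deflation_time)
}

#' Minimum ischemic value
#'
#' The lowest (rolling-averaged) percent-change value attained during the
#' cuff occlusion phase. The same short averaging window as for the peak is
#' applied by default, for symmetry and noise robustness; set
#' `window_s = timing$tr` (or smaller) for single-frame minima.
#'
#' @inheritParams compute_phv_ttp
#' @return Minimum ischemic value (%).
#' @export
compute_miv <- function(ntc, timing, window_s = 3) {
  stopifnot(inherits(ntc, "normalized_timecourse"),
            inherits(timing, "protocol_timing"))
  seg <- window_segment(ntc, timing$occlusion_start, timing$deflation_time)
  if (is.null(seg))
    stop_with("muscleBOLD_empty_segment", "no frames in the occlusion window")
  sm <- rolling_average(seg, window_s)
  min(sm$pct)
}

#' Time to recovery of the baseline signal
#'
#' Scans the unsmoothed percent-change signal forward from the hyperemic
#' peak; TTR is the time from cuff deflation to the first return to the
#' baseline level (0 % by construction), linearly interpolated between the
#' bracketing frame centres. If the signal never returns to baseline before
#' the end of the acquisition, `recovered` is `FALSE` and `ttr` is `NA` —
#' cohort summaries should average over recovered cases only and report the
#' count.
#'
#' @inheritParams compute_phv_ttp
#' @param ttp Time to peak (s), as returned by [compute_phv_ttp()].
#' @param threshold Recovery threshold in percent-change units. The default
#'   0 is the baseline itself; a small positive band (e.g. half the baseline
#'   noise SD) can be supplied for noisy data.
#' @return `list(ttr = s or NA, recovered = logical)`.
#' @export
compute_ttr <- function(ntc, timing, ttp, threshold = 0) {
  stopifnot(inherits(ntc, "normalized_timecourse"),
            inherits(timing, "protocol_timing"))
  seg <- window_segment(ntc, timing$deflation_time, timing$end_time,
                        closed_right = TRUE)
  if (is.null(seg))
    stop_with("muscleBOLD_empty_segment", "no frames after cuff deflation")
  peak_time <- timing$deflation_time + ttp
  k0 <- which.min(abs(seg$times - peak_time))
  below <- which(seg$pct[k0:length(seg$pct)] <= threshold)
  if (length(below) == 0L) return(list(ttr = NA_real_, recovered = FALSE))
  j <- k0 + below[1L] - 1L
  if (j == k0 || seg$pct[j - 1L] <= threshold) {
    t_cross <- seg$times[j]
  } else {
    p1 <- seg$pct[j - 1L] - threshold
    p2 <- seg$pct[j] - threshold
    t_cross <- seg$times[j - 1L] + (seg$times[j] - seg$times[j - 1L]) * p1 / (p1 - p2)
  }
  list(ttr = max(t_cross - timing$deflation_time, ttp), recovered = TRUE)
}

#' Compute all four dynamic BOLD oximetry indices
#'
#' Composes [compute_miv()], [compute_phv_ttp()], and [compute_ttr()] over a
#' full baseline / occlusion / hyperemia time course:
#' * **PHV** — peak hyperemic value (%), highest `window_s` average after deflation;
#' * **TTP** — time to peak (s) from cuff deflation;
#' * **MIV** — minimum ischemic value (%) during occlusion;
#' * **TTR** — time to recovery (s) of the baseline level after the peak.
#'
#' @inheritParams compute_phv_ttp
#' @param miv_window_s Averaging window for the ischemic minimum; defaults to
#'   the peak window.
#' @param recovery_threshold Passed to [compute_ttr()].
#' @return An object of class `bold_indices`: fields `muscle`, `phv`, `ttp`,
#'   `miv`, `ttr` (`NA` when not recovered), `recovered`.
#' @export
compute_indices <- function(ntc, timing, window_s = 3,
                            miv_window_s = window_s, recovery_threshold = 0) {
  pk <- compute_phv_ttp(ntc, timing, window_s)
  miv <- compute_miv(ntc, timing, miv_window_s)
  rec <- compute_ttr(ntc, timing, pk$ttp, recovery_threshold)
  out <- structure(list(muscle = ntc$muscle, phv = pk$phv, ttp = pk$ttp,
                        miv = miv, ttr = rec$ttr, recovered = rec$recovered),
                   class = "bold_indices")
  check_bold_indices(out, timing)
  out
}

check_bold_indices <- function(x, timing = NULL) {
  if (x$phv < x$miv)
    stop_with("muscleBOLD_bad_indices", "PHV (%g) below MIV (%g)", x$phv, x$miv)
  if (x$ttp < 0)
    stop_with("muscleBOLD_bad_indices", "negative TTP (%g)", x$ttp)
  if (!is.null(timing) && x$ttp > timing$end_time - timing$deflation_time + 1e-9)
    stop_with("muscleBOLD_bad_indices", "TTP (%g) beyond hyperemia phase", x$ttp)
  if (x$recovered && is.finite(x$ttr) && x$ttr < x$ttp - 1e-9)
    stop_with("muscleBOLD_bad_indices", "TTR (%g) precedes TTP (%g)", x$ttr, x$ttp)
  invisible(x)
}

#' @export
print.bold_indices <- function(x, ...) {
  cat(sprintf("<bold_indices> %s: PHV %.1f%%, TTP %.1f s, MIV %.1f%%, TTR %s\n",
              x$muscle, x$phv, x$ttp, x$miv,
              if (x$recovered) sprintf("%.1f s", x$ttr) else "not recovered"))
  invisible(x)
}

#' @export
as.data.frame.bold_indices <- function(x, ...) {
  data.frame(muscle = x$muscle, phv = x$phv, ttp = x$ttp, miv = x$miv,
             ttr = if (x$recovered) x$ttr else NA_real_,
             recovered = x$recovered, stringsAsFactors = FALSE)
}

# Sub-timecourse of frames whose centres fall in [from, to) (or [from, to]).
# Returns NULL when empty.
window_segment <- function(ntc, from, to, closed_right = FALSE) {
  keep <- if (closed_right) {
    ntc$times >= from - 1e-9 & ntc$times <= to + 1e-9
  } else {
    ntc$times >= from - 1e-9 & ntc$times < to - 1e-9
  }
  if (!any(keep)) return(NULL)
  out <- ntc
  out$times <- ntc$times[keep]
  out$pct <- ntc$pct[keep]
  out
}
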