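#' Ground-truth parameters for one simulated muscle response
#'
#' The generative counterpart of the four measured indices, plus the nuisance
#' terms of the noise model. The noise-free response is zero at baseline,
#' declines exponentially toward `miv` during occlusion with time constant
#' `tau_isch`, rises along a half-cosine from the deflation value to `phv`
#' at `ttp` after deflation, decays along a half-cosine back to baseline at
#' `ttr`, and stays at baseline afterwards. The half-cosine shape places the
#' peak and the zero-crossing exactly at `ttp` and `ttr`, so the truth is
#' recoverable by definition.
#'
#' @param phv Peak hyperemic value (%, > 0).
#' @param ttp Time to peak after deflation (s, > 0).
#' @param miv Minimum ischemic value (%, < 0).
#' @param ttr Time to baseline recovery after deflation (s, > ttp).
#' @param tau_isch Ischemic exponential time constant (s). The default, a
#'   fifth of the occlusion duration under the standard 15-min protocol,
#'   lets the ischemic plateau reach > 99 % of `miv` by deflation.
#' @param noise_sd Per-frame white Gaussian noise SD in percent-change units.
#' @param drift Linear drift in %/min added over the acquisition.
#' @return An object of class `curve_truth`.
#' @export
curve_truth <- function(phv, ttp, miv, ttr, tau_isch = 60,
                        noise_sd = 0, drift = 0) {
  if (!(phv > 0 && miv < 0))
    stop_with("muscleBOLD_bad_truth", "need phv > 0 > miv (got %g, %g)", phv, miv)
  if (!(ttp > 0 && ttr > ttp))
    stop_with("muscleBOLD_bad_truth", "need 0 < ttp < ttr (got %g, %g)", ttp, ttr)
  if (tau_isch <= 0) stop_with("muscleBOLD_bad_truth", "tau_isch must be > 0")
  if (noise_sd < 0) stop_with("muscleBOLD_bad_truth", "noise_sd must be >= 0")
  structure(list(phv = phv, ttp = ttp, miv = miv, ttr = ttr,
                 tau_isch = tau_isch, noise_sd = noise_sd, drift = drift),
            class = "curve_truth")
}

#' Noise-free ischemia/hyperemia response curve
#'
#' Evaluates the piecewise generative curve of a [curve_truth()] at times `t`
#' (seconds on the protocol axis). Continuous at all phase boundaries.
#'
#' @param truth A [curve_truth()].
#' @param timing A [protocol_timing()]; `ttr` must not exceed the hyperemia
#'   phase duration.
#' @param t Numeric vector of times in `[0, end_time]`.
#' @return Percent-change values at `t`.
#' @export
ideal_curve <- function(truth, timing, t) {
  stopifnot(inherits(truth, "curve_truth"), inherits(timing, "protocol_timing"))
  if (truth$ttr > timing$end_time - timing$deflation_time)
    stop_with("muscleBOLD_bad_truth",
              "ttr (%g s) exceeds the hyperemia phase (%g s)",
              truth$ttr, timing$end_time - timing$deflation_time)
  if (any(t < timing$baseline_start - 1e-9 | t > timing$end_time + 1e-9))
    stop_with("muscleBOLD_bad_times", "t outside [%g, %g] s",
              timing$baseline_start, timing$end_time)
  occ <- timing$occlusion_start; defl <- timing$deflation_time
  v_defl <- truth$miv * (1 - exp(-(defl - occ) / truth$tau_isch))
  out <- numeric(length(t))
  isch <- t >= occ & t < defl
  out[isch] <- truth$miv * (1 - exp(-(t[isch] - occ) / truth$tau_isch))
  rise <- t >= defl & t < defl + truth$ttp
  out[rise] <- v_defl + (truth$phv - v_defl) *
    (1 - cos(pi * (t[rise] - defl) / truth$ttp)) / 2
  fall <- t >= defl + truth$ttp & t < defl + truth$ttr
  out[fall] <- truth$phv *
    (1 + cos(pi * (t[fall] - defl - truth$ttp) / (truth$ttr - truth$ttp))) / 2
  out  # baseline and post-recovery stay 0
}

#' Simulate a noisy normalised time course with known truth
#'
#' Samples the ideal curve at frame centres, adds white Gaussian noise and a
#' linear drift, and returns the truth alongside the time course.
#' Deterministic for a fixed `seed`.
#'
#' @param truth A [curve_truth()].
#' @param timing A [protocol_timing()].
#' @param muscle Muscle name attached to the time course.
#' @param seed Optional integer seed.
#' @return `list(timecourse = normalized_timecourse, truth = curve_truth)`,
#'   class `simulated_timecourse`.
#' @export
simulate_timecourse <- function(truth, timing, muscle = "synthetic", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nt <- as.integer(round((timing$end_time - timing$baseline_start) / timing$tr))
  tt <- frame_times(nt, timing$tr, timing$baseline_start)
  pct <- ideal_curve(truth, timing, tt)
  if (truth$noise_sd > 0) pct <- pct + stats::rnorm(nt, 0, truth$noise_sd)
  if (truth$drift != 0) pct <- pct + truth$drift * (tt - timing$baseline_start) / 60
  structure(list(timecourse = normalized_timecourse(muscle, tt, pct, timing$tr,
                                                    baseline_sd = truth$noise_sd),
                 truth = truth),
            class = "simulated_timecourse")
}

default_phantom_regions <- function() {
  # in-plane ellipses (voxel units on the 128 x 64 grid), inside a calf disc
  list(gastrocnemius     = c(cx = 45, cy = 42, rx = 14, ry = 9),
       soleus            = c(cx = 45, cy = 22, rx = 14, ry = 8),
       anterior_tibialis = c(cx = 86, cy = 42, rx = 12, ry = 9),
       peroneus_longus   = c(cx = 86, cy = 22, rx = 12, ry = 8))
}

#' Specification of a 4D digital phantom
#'
#' Defines the geometry and generative dynamics of a synthetic BOLD
#' acquisition: a calf-like elliptical cross-section containing four
#' non-overlapping elliptical muscle regions, replicated over `dims[3]`
#' contiguous slices, imaged for the full protocol. Defaults mirror the
#' standard acquisition: 128 x 64 in-plane matrix over a 360 x 180 mm field
#' of view (2.8125 mm in-plane voxels), 6 slices of 5 mm, TR 3 s.
#'
#' @param timing A [protocol_timing()].
#' @param truths Named list of [curve_truth()] per muscle (all four calf
#'   muscles by default, with magnitudes typical of sedentary controls).
#' @param dims Integer length-3 spatial dimensions.
#' @param voxel_size mm triple.
#' @param s0 Baseline signal intensity (scanner units) for muscle tissue.
#' @param s0_other Baseline intensity of non-muscle leg tissue.
#' @param s0_background Baseline intensity outside the leg.
#' @param noise_sd Additive Gaussian noise SD in scanner units, applied to
#'   every voxel and frame.
#' @param regions Named list of in-plane ellipses `c(cx, cy, rx, ry)` (voxel
#'   units) for the four muscles; must not overlap.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(timing = protocol_timing(),
                         truths = list(
                           gastrocnemius     = curve_truth(7.4, 28.5, -13.3, 129.4),
                           soleus            = curve_truth(12.9, 21.0, -12.4, 134.1),
                           anterior_tibialis = curve_truth(7.7, 26.3, -7.5, 136.5),
                           peroneus_longus   = curve_truth(9.2, 25.1, -9.4, 140.6)),
                         dims = c(128L, 64L, 6L),
                         voxel_size = c(2.8125, 2.8125, 5),
                         s0 = 400, s0_other = 300, s0_background = 20,
                         noise_sd = 0,
                         regions = default_phantom_regions()) {
  stopifnot(inherits(timing, "protocol_timing"))
  if (any(dims < 1L)) stop_with("muscleBOLD_bad_dims", "dims must be positive")
  if (s0 <= 0 || s0_other <= 0 || s0_background <= 0)
    stop_with("muscleBOLD_bad_spec", "baseline intensities must be positive")
  if (noise_sd < 0) stop_with("muscleBOLD_bad_spec", "noise_sd must be >= 0")
  if (!all(names(truths) %in% calf_muscles()) || length(truths) == 0L)
    stop_with("muscleBOLD_bad_spec", "truths must be named by calf muscle")
  if (!all(names(truths) %in% names(regions)))
    stop_with("muscleBOLD_bad_spec", "every muscle in 'truths' needs a region")
  structure(list(timing = timing, truths = truths, dims = as.integer(dims),
                 voxel_size = voxel_size, s0 = s0, s0_other = s0_other,
                 s0_background = s0_background, noise_sd = noise_sd,
                 regions = regions),
            class = "phantom_spec")
}

#' Generate a ground-truthed 4D BOLD phantom
#'
#' Builds the label map from the requested geometry, synthesises each muscle's
#' voxel signal as `S0 * (1 + s(t) / 100)` from its noise-free response
#' curve, adds Gaussian scanner noise, and returns a coregistered series +
#' mask + per-muscle truth table. Deterministic for a fixed `seed`.
#'
#' @param spec A [phantom_spec()].
#' @param seed Optional integer seed for the voxel noise.
#' @return `list(series = bold_series, mask = voi_label_map,
#'   truth = data.frame)` of class `bold_phantom`.
#' @export
simulate_phantom <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(seed)) set.seed(seed)
  d <- spec$dims
  xg <- matrix(rep(seq_len(d[1]), d[2]), d[1], d[2])
  yg <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
  leg <- ((xg - (d[1] + 1) / 2) / (0.42 * d[1]))^2 +
         ((yg - (d[2] + 1) / 2) / (0.42 * d[2]))^2 < 1
  slice <- matrix(0L, d[1], d[2])
  muscles <- names(spec$truths)
  for (i in seq_along(muscles)) {
    e <- spec$regions[[muscles[i]]]
    inside <- ((xg - e["cx"]) / e["rx"])^2 + ((yg - e["cy"]) / e["ry"])^2 < 1
    if (any(slice[inside] != 0L))
      stop_with("muscleBOLD_region_overlap",
                "muscle region '%s' overlaps another region", muscles[i])
    slice[inside] <- i
  }
  other_label <- length(muscles) + 1L
  slice[leg & slice == 0L] <- other_label
  labels <- array(rep(slice, d[3]), dim = d)
  legend <- stats::setNames(c(muscles, "other"),
                            as.character(seq_len(other_label)))
  mask <- voi_label_map(labels, legend, spec$voxel_size)

  nt <- as.integer(round((spec$timing$end_time - spec$timing$baseline_start) /
                           spec$timing$tr))
  tt <- frame_times(nt, spec$timing$tr, spec$timing$baseline_start)
  nvox <- prod(d)
  v <- matrix(spec$s0_background, nrow = nvox, ncol = nt)
  lab_vec <- as.vector(labels)
  v[lab_vec == other_label, ] <- spec$s0_other
  for (i in seq_along(muscles)) {
    s <- ideal_curve(spec$truths[[muscles[i]]], spec$timing, tt)
    idx <- which(lab_vec == i)
    v[idx, ] <- rep(spec$s0 * (1 + s / 100), each = length(idx))
  }
  if (spec$noise_sd > 0)
    v <- v + stats::rnorm(length(v), 0, spec$noise_sd)
  series <- bold_series(array(v, dim = c(d, nt)), spec$voxel_size,
                        spec$timing$tr)
  truth <- do.call(rbind, lapply(muscles, function(m) {
    tr <- spec$truths[[m]]
    data.frame(muscle = m, phv = tr$phv, ttp = tr$ttp, miv = tr$miv,
               ttr = tr$ttr, tau_isch = tr$tau_isch, stringsAsFactors = FALSE)
  }))
  structure(list(series = series, mask = mask, truth = truth),
            class = "bold_phantom")
}

#' Specification of a simulated study cohort
#'
#' Population moments for per-subject ground truths, by group and muscle.
#' Defaults reproduce the structure of the study population this generator
#' emulates: 12 linemen, 11 defensive backs/wide receivers, and 10 sedentary
#' controls; PHV means/SDs differ by group and muscle, while MIV/TTP/TTR
#' moments are shared across groups (no group differences were reported for
#' those indices). Controls are scanned twice, the second visit re-drawing
#' each index around the subject's truth with SD `within_sd`. Jump distances
#' are generated correlated (at `rho`) with the subject's gastrocnemius PHV
#' truth.
#'
#' @param group_sizes Named integer vector of subjects per group.
#' @param phv_mean,phv_sd Muscle x group matrices of PHV moments (%).
#' @param miv,ttp,ttr Named lists per muscle: `c(mean, sd)` of the other
#'   three indices, shared across groups.
#' @param within_sd Named vector: within-subject (between-visit) SD per index.
#' @param rho Correlation between gastrocnemius PHV truth and jump distance.
#' @param jump_mean,jump_sd Named vectors (`vertical`, `broad`) of jump
#'   distance moments in cm.
#' @param bounds Admissible truth ranges used to truncate the population
#'   draws (named list of `c(lo, hi)`).
#' @param noise_sd_pct Per-frame measurement noise SD (percent-change units)
#'   used when time courses are simulated.
#' @param timing A [protocol_timing()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(linemen = 12L, backs_receivers = 11L,
                                        controls = 10L),
                        phv_mean = default_phv_moments()$mean,
                        phv_sd = default_phv_moments()$sd,
                        miv = list(gastrocnemius = c(-13.3, 4.3),
                                   soleus = c(-12.4, 6.4),
                                   anterior_tibialis = c(-7.5, 3.4),
                                   peroneus_longus = c(-9.4, 5.5)),
                        ttp = list(gastrocnemius = c(28.5, 5.6),
                                   soleus = c(21.0, 2.8),
                                   anterior_tibialis = c(26.3, 5.0),
                                   peroneus_longus = c(25.1, 6.6)),
                        ttr = list(gastrocnemius = c(129.4, 28.5),
                                   soleus = c(134.1, 21.5),
                                   anterior_tibialis = c(136.5, 40.2),
                                   peroneus_longus = c(140.6, 48.4)),
                        within_sd = c(phv = 2, miv = 2, ttp = 5, ttr = 25),
                        rho = 0.56,
                        jump_mean = c(vertical = 60, broad = 238),
                        jump_sd = c(vertical = 10, broad = 32),
                        bounds = list(phv = c(2, 30), ttp = c(10, 60),
                                      miv = c(-20, -2), ttr = c(60, 250)),
                        noise_sd_pct = 1,
                        timing = protocol_timing()) {
  if (any(group_sizes < 2L))
    stop_with("muscleBOLD_bad_spec", "every group needs >= 2 subjects")
  if (abs(rho) > 1) stop_with("muscleBOLD_bad_spec", "|rho| must be <= 1")
  if (any(within_sd < 0) || noise_sd_pct < 0)
    stop_with("muscleBOLD_bad_spec", "SDs must be >= 0")
  structure(list(group_sizes = group_sizes, phv_mean = phv_mean,
                 phv_sd = phv_sd, miv = miv, ttp = ttp, ttr = ttr,
                 within_sd = within_sd, rho = rho, jump_mean = jump_mean,
                 jump_sd = jump_sd, bounds = bounds,
                 noise_sd_pct = noise_sd_pct, timing = timing),
            class = "cohort_spec")
}

#' Default PHV population moments per muscle and group
#'
#' Muscle x group matrices (percent change) used as the generator's default
#' peak-hyperemic-value parameterization: athletes show higher PHV than
#' sedentary controls in the gastrocnemius, soleus, and anterior tibialis,
#' but not the peroneus longus.
#'
#' @return `list(mean = matrix, sd = matrix)` with muscles as rows and
#'   groups as columns.
#' @export
default_phv_moments <- function() {
  mus <- calf_muscles(); grp <- valid_groups()
  mean <- matrix(c(15.8, 17.9, 7.4,
                   25.9, 22.0, 12.9,
                   12.8, 12.6, 7.7,
                   14.1, 11.7, 9.0),
                 nrow = 4, byrow = TRUE, dimnames = list(mus, grp))
  sd <- matrix(c(9.1, 5.1, 3.5,
                 11.5, 9.4, 5.8,
                 5.3, 3.9, 4.0,
                 6.9, 4.6, 4.9),
               nrow = 4, byrow = TRUE, dimnames = list(mus, grp))
  list(mean = mean, sd = sd)
}

# inverse-CDF truncated normal draw
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) {
    if (mean < lo || mean > hi)
      stop_with("muscleBOLD_bad_truncation",
                "degenerate draw at %g outside [%g, %g]", mean, lo, hi)
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo < 1e-12)
    stop_with("muscleBOLD_bad_truncation",
              "truncation to [%g, %g] leaves no mass around N(%g, %g)",
              lo, hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulate a full study cohort with known per-subject truths
#'
#' Draws per-subject index truths from the group/muscle population
#' distributions (truncated to the admissible ranges), generates a second
#' visit for controls by re-drawing around the subject truth with the
#' within-subject SD, and attaches jump distances correlated with the
#' gastrocnemius PHV truth. With `measure = "timecourse"` (default) each
#' subject x visit x muscle response is synthesised as a noisy time course
#' and the indices are re-estimated through [compute_indices()], so the
#' records carry measurement error; with `measure = "truth"` the per-visit
#' truths are recorded directly.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @param measure `"timecourse"` or `"truth"`.
#' @return A [subject_records()] data.frame; the per-subject truth table is
#'   attached as `attr(, "truth")`.
#' @export
simulate_cohort <- function(spec, seed = NULL,
                            measure = c("timecourse", "truth")) {
  stopifnot(inherits(spec, "cohort_spec"))
  measure <- match.arg(measure)
  if (!is.null(seed)) set.seed(seed)
  mus <- rownames(spec$phv_mean)
  groups <- names(spec$group_sizes)
  subj <- data.frame(
    subject_id = sprintf("S%03d", seq_len(sum(spec$group_sizes))),
    group = rep(groups, spec$group_sizes), stringsAsFactors = FALSE)

  draw_visit <- function(base, b, wsd) {
    # one between-visit redraw around the subject truth, clamped to bounds
    pmin(pmax(base + stats::rnorm(length(base), 0, wsd), b[1]), b[2])
  }
  truth_rows <- list(); rec_rows <- list()
  for (m in mus) {
    b <- spec$bounds
    phv1 <- numeric(nrow(subj)); for (g in groups) {
      sel <- subj$group == g
      phv1[sel] <- rtruncnorm(sum(sel), spec$phv_mean[m, g], spec$phv_sd[m, g],
                              b$phv[1], b$phv[2])
    }
    miv1 <- rtruncnorm(nrow(subj), spec$miv[[m]][1], spec$miv[[m]][2],
                       b$miv[1], b$miv[2])
    ttp1 <- rtruncnorm(nrow(subj), spec$ttp[[m]][1], spec$ttp[[m]][2],
                       b$ttp[1], b$ttp[2])
    ttr1 <- vapply(ttp1, function(tp)
      rtruncnorm(1L, spec$ttr[[m]][1], spec$ttr[[m]][2],
                 max(b$ttr[1], tp + 2 * spec$timing$tr), b$ttr[2]), numeric(1))
    truth_rows[[m]] <- data.frame(subject_id = subj$subject_id,
                                  group = subj$group, muscle = m,
                                  phv = phv1, ttp = ttp1, miv = miv1,
                                  ttr = ttr1, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows); rownames(truth) <- NULL

  # jump distances share a latent factor with the gastrocnemius PHV truth
  g_phv <- truth[truth$muscle == "gastrocnemius", ]
  z <- as.numeric(scale(g_phv$phv))
  mix <- function(target_mean, target_sd) {
    e <- stats::rnorm(length(z))
    target_mean + target_sd * (spec$rho * z + sqrt(1 - spec$rho^2) * e)
  }
  subj$vertical_jump <- mix(spec$jump_mean["vertical"], spec$jump_sd["vertical"])
  subj$broad_jump <- mix(spec$jump_mean["broad"], spec$jump_sd["broad"])

  measure_one <- function(tr_row, visit_truth) {
    if (measure == "truth") return(visit_truth)
    ct <- curve_truth(visit_truth[["phv"]], visit_truth[["ttp"]],
                      visit_truth[["miv"]], visit_truth[["ttr"]],
                      noise_sd = spec$noise_sd_pct)
    sim <- simulate_timecourse(ct, spec$timing, muscle = tr_row$muscle)
    idx <- compute_indices(sim$timecourse, spec$timing)
    c(phv = idx$phv, ttp = idx$ttp, miv = idx$miv,
      ttr = if (idx$recovered) idx$ttr else NA_real_)
  }
  for (i in seq_len(nrow(truth))) {
    tr_row <- truth[i, ]
    visits <- if (tr_row$group == "controls") 1:2 else 1L
    base <- c(phv = tr_row$phv, ttp = tr_row$ttp, miv = tr_row$miv,
              ttr = tr_row$ttr)
    for (v in visits) {
      vt <- base
      if (v == 2L) {
        for (p in names(vt))
          vt[p] <- draw_visit(base[p], spec$bounds[[p]], spec$within_sd[p])
        vt["ttr"] <- max(vt["ttr"], vt["ttp"] + 2 * spec$timing$tr)
      }
      got <- measure_one(tr_row, vt)
      rec_rows[[length(rec_rows) + 1L]] <- data.frame(
        subject_id = tr_row$subject_id, group = tr_row$group, visit = v,
        muscle = tr_row$muscle, phv = got[["phv"]], ttp = got[["ttp"]],
        miv = got[["miv"]], ttr = got[["ttr"]],
        recovered = is.finite(got[["ttr"]]), stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rec_rows); rownames(records) <- NULL
  records <- merge(records, subj, by = c("subject_id", "group"), sort = FALSE)
  records <- records[order(records$subject_id, records$muscle, records$visit), ]
  rownames(records) <- NULL
  records <- subject_records(records)
  attr(records, "truth") <- truth
  records
}
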