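#' Coefficient of variation
#'
#' `100 * sd / |mean|`, the test-retest repeatability measure tabulated per
#' muscle and parameter. The absolute value keeps the CV positive for
#' negative-valued means (the ischemic minimum).
#'
#' @param mean Mean value(s); must be nonzero.
#' @param sd Standard deviation(s), same length.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(mean, sd) {
  if (any(mean == 0))
    stop_with("muscleBOLD_zero_mean", "CV is undefined for a zero mean")
  100 * sd / abs(mean)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardised sample skewness (D'Agostino's transformed Z) and
#' kurtosis (Anscombe-Glynn transformed Z) into the omnibus statistic
#' `K2 = Z1^2 + Z2^2`, referred to a chi-squared distribution with 2 df.
#' Requires n >= 8 (the skewness transform is unreliable below that).
#'
#' @param x Numeric vector of observations.
#' @return An object of class `htest` with the K2 statistic, the two
#'   component Z values, and the p-value.
#' @export
dagostino_pearson_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L)
    stop_with("muscleBOLD_small_sample",
              "normality test needs n >= 8 observations, got %d", n)
  if (stats::sd(x) == 0)
    stop_with("muscleBOLD_zero_variance", "normality test needs nonzero variance")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)

  # skewness component (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis component (Anscombe & Glynn 1983)
  b <- m4 / m2^2
  eb <- 3 * (n - 1) / (n + 1)
  vb <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b - eb) / sqrt(vb)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) *
    sqrt(9 * a / 2)

  k2 <- z1^2 + z2^2
  structure(list(statistic = c(K2 = k2), parameter = c(df = 2),
                 p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
                 estimate = c(skew.Z = z1, kurt.Z = z2),
                 method = "D'Agostino-Pearson omnibus normality test",
                 data.name = deparse(substitute(x))),
            class = "htest")
}

valid_groups <- function() c("linemen", "backs_receivers", "controls")
index_parameters <- function() c("phv", "ttp", "miv", "ttr")

#' Validate a long-format subject record table
#'
#' One row per subject x visit x muscle, with the four index columns. Used by
#' all cohort-level statistics.
#'
#' @param records data.frame with columns `subject_id`, `group` (one of
#'   `linemen`, `backs_receivers`, `controls`), `visit` (1 or 2), `muscle`,
#'   `phv`, `ttp`, `miv`, `ttr`; optional `recovered`, `vertical_jump`,
#'   `broad_jump` (cm), `excluded` (logical), `exclude_reason`.
#' @return The records, with optional columns filled in.
#' @export
subject_records <- function(records) {
  req <- c("subject_id", "group", "visit", "muscle", index_parameters())
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop_with("muscleBOLD_bad_records", "records lack column(s): %s",
              paste(miss, collapse = ", "))
  if (!all(records$group %in% valid_groups()))
    stop_with("muscleBOLD_bad_records", "unknown group(s): %s",
              paste(setdiff(records$group, valid_groups()), collapse = ", "))
  if (!all(records$visit %in% c(1L, 2L)))
    stop_with("muscleBOLD_bad_records", "'visit' must be 1 or 2")
  if (any(records$visit == 2L & records$group != "controls"))
    stop_with("muscleBOLD_bad_records",
              "visit 2 exists only for the control (repeatability) group")
  if (is.null(records$excluded)) records$excluded <- FALSE
  if (is.null(records$exclude_reason)) records$exclude_reason <- NA_character_
  if (any(records$excluded & is.na(records$exclude_reason)))
    stop_with("muscleBOLD_bad_records", "excluded subjects need an exclusion reason")
  if (is.null(records$vertical_jump)) records$vertical_jump <- NA_real_
  if (is.null(records$broad_jump)) records$broad_jump <- NA_real_
  if (is.null(records$recovered)) records$recovered <- !is.na(records$ttr)
  records
}

#' Test-retest repeatability table
#'
#' For control subjects scanned at two visits, computes per muscle x
#' parameter the per-visit mean, sample SD (n-1), coefficient of variation,
#' and a two-sided paired comparison across visits. Only subjects present at
#' both visits enter the table. With identical values at both visits the
#' paired test is undefined (zero variance of the differences) and the
#' p-value is reported as `NA`.
#'
#' @param records A [subject_records()] table.
#' @param parameters Which indices to tabulate.
#' @param method `"t"` for a paired t-test (default) or `"wilcoxon"` for the
#'   signed-rank test when normality is doubtful.
#' @return data.frame with one row per muscle x parameter: visit means, SDs,
#'   CVs (%), the paired p-value, and the number of paired subjects.
#' @export
repeatability_table <- function(records, parameters = index_parameters(),
                                method = c("t", "wilcoxon")) {
  records <- subject_records(records)
  method <- match.arg(method)
  ctl <- records[records$group == "controls", ]
  rows <- list()
  for (mus in unique(ctl$muscle)) {
    v1 <- ctl[ctl$muscle == mus & ctl$visit == 1L, ]
    v2 <- ctl[ctl$muscle == mus & ctl$visit == 2L, ]
    paired_ids <- intersect(v1$subject_id, v2$subject_id)
    for (p in parameters) {
      if (length(paired_ids) >= 2L) {
        a <- v1[[p]][match(paired_ids, v1$subject_id)]
        b <- v2[[p]][match(paired_ids, v2$subject_id)]
        ok <- is.finite(a) & is.finite(b)
        a <- a[ok]; b <- b[ok]
      } else if (nrow(v2) == 0L && nrow(v1) > 0L) {
        # single-visit degradation: report visit-1 moments, no comparison
        a <- v1[[p]][is.finite(v1[[p]])]; b <- numeric(0)
      } else {
        stop_with("muscleBOLD_no_pairs",
                  "muscle '%s': need >= 2 control subjects with both visits", mus)
      }
      pval <- NA_real_
      if (length(b) >= 2L) {
        d <- a - b
        if (stats::sd(d) > 0) {
          pval <- if (method == "t") stats::t.test(a, b, paired = TRUE)$p.value
                  else stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        muscle = mus, parameter = p, n_pairs = length(b),
        visit1_mean = mean(a), visit1_sd = stats::sd(a),
        visit1_cv = coefficient_of_variation(mean(a), stats::sd(a)),
        visit2_mean = if (length(b)) mean(b) else NA_real_,
        visit2_sd = if (length(b)) stats::sd(b) else NA_real_,
        visit2_cv = if (length(b)) coefficient_of_variation(mean(b), stats::sd(b))
                    else NA_real_,
        paired_p = pval, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Group-wise and muscle-wise ANOVA of a BOLD index
#'
#' For one index (e.g. PHV), runs a one-way ANOVA across subject groups
#' within each muscle, and across muscles within each subject group, on
#' visit-1, non-excluded records. Each cell is screened with the
#' D'Agostino-Pearson omnibus normality test (reported `NA` when the cell is
#' too small or degenerate). When an omnibus test is significant at `alpha`,
#' Tukey HSD pairwise comparisons (or Bonferroni-adjusted pairwise t-tests)
#' are reported.
#'
#' @param records A [subject_records()] table.
#' @param parameter One of `"phv"`, `"ttp"`, `"miv"`, `"ttr"`.
#' @param alpha Significance level gating the post-hoc comparisons.
#' @param posthoc `"tukey"` (default) or `"bonferroni"`.
#' @return An object of class `group_stats`: data.frames `omnibus`
#'   (factor/stratum/F/p), `normality` (per cell), `posthoc` (pairwise p).
#' @export
group_muscle_anova <- function(records, parameter = "phv", alpha = 0.05,
                               posthoc = c("tukey", "bonferroni")) {
  records <- subject_records(records)
  posthoc <- match.arg(posthoc)
  parameter <- match.arg(parameter, index_parameters())
  d <- records[records$visit == 1L & !records$excluded, ]
  d <- d[is.finite(d[[parameter]]), ]
  omni <- list(); norm <- list(); ph <- list()
  run_oneway <- function(values, fac, factor_name, stratum) {
    fac <- factor(fac)
    counts <- table(fac)
    if (length(counts) < 2L) return(NULL)
    if (any(counts < 2L))
      stop_with("muscleBOLD_degenerate_cell",
                "%s '%s': every cell needs >= 2 subjects", factor_name, stratum)
    for (lv in levels(fac)) {
      xs <- values[fac == lv]
      np <- tryCatch(dagostino_pearson_test(xs)$p.value,
                     muscleBOLD_error = function(e) NA_real_)
      norm[[length(norm) + 1L]] <<- data.frame(
        factor = factor_name, stratum = stratum, cell = lv,
        n = length(xs), normality_p = np, stringsAsFactors = FALSE)
    }
    fit <- stats::aov(values ~ fac)
    tab <- summary(fit)[[1L]]
    pval <- tab[["Pr(>F)"]][1L]
    omni[[length(omni) + 1L]] <<- data.frame(
      factor = factor_name, stratum = stratum, parameter = parameter,
      df1 = tab[["Df"]][1L], df2 = tab[["Df"]][2L],
      F = tab[["F value"]][1L], anova_p = pval, stringsAsFactors = FALSE)
    if (is.finite(pval) && pval < alpha) {
      if (posthoc == "tukey") {
        tk <- stats::TukeyHSD(fit)$fac
        ph[[length(ph) + 1L]] <<- data.frame(
          factor = factor_name, stratum = stratum,
          contrast = rownames(tk), diff = tk[, "diff"],
          p = tk[, "p adj"], stringsAsFactors = FALSE, row.names = NULL)
      } else {
        pt <- stats::pairwise.t.test(values, fac, p.adjust.method = "bonferroni")$p.value
        cmb <- which(!is.na(pt), arr.ind = TRUE)
        ph[[length(ph) + 1L]] <<- data.frame(
          factor = factor_name, stratum = stratum,
          contrast = paste(rownames(pt)[cmb[, 1]], colnames(pt)[cmb[, 2]], sep = "-"),
          diff = NA_real_, p = pt[cmb], stringsAsFactors = FALSE)
      }
    }
    invisible(NULL)
  }
  for (mus in unique(d$muscle)) {
    dd <- d[d$muscle == mus, ]
    run_oneway(dd[[parameter]], dd$group, "group", mus)
  }
  for (grp in unique(d$group)) {
    dd <- d[d$group == grp, ]
    run_oneway(dd[[parameter]], dd$muscle, "muscle", grp)
  }
  structure(list(parameter = parameter, alpha = alpha,
                 omnibus = do.call(rbind, omni),
                 normality = do.call(rbind, norm),
                 posthoc = if (length(ph)) do.call(rbind, ph) else NULL),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("<group_stats> parameter: %s (alpha = %g)\n", x$parameter, x$alpha))
  print(x$omnibus, row.names = FALSE)
  if (!is.null(x$posthoc)) {
    cat("post-hoc (omnibus significant):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Correlation between a muscle's peak hyperemic value and jump performance
#'
#' Pearson correlation between one muscle's index (PHV by default) and a
#' functional measure (maximal vertical or broad jump), pooled across groups
#' over visit-1, non-excluded subjects with both values present.
#'
#' @param records A [subject_records()] table.
#' @param muscle Muscle name.
#' @param functional_measure `"vertical"` or `"broad"`.
#' @param parameter Index to correlate; default `"phv"`.
#' @return data.frame with `muscle`, `functional_measure`, `r`, `p`, `n`, and
#'   `n_excluded` (subjects dropped as excluded or with missing values).
#' @export
jump_correlation <- function(records, muscle,
                             functional_measure = c("vertical", "broad"),
                             parameter = "phv") {
  records <- subject_records(records)
  functional_measure <- match.arg(functional_measure)
  col <- paste0(functional_measure, "_jump")
  d <- records[records$visit == 1L & records$muscle == muscle, ]
  if (nrow(d) == 0L)
    stop_with("muscleBOLD_unknown_muscle", "no records for muscle '%s'", muscle)
  usable <- !d$excluded & is.finite(d[[parameter]]) & is.finite(d[[col]])
  n_excluded <- sum(!usable)
  d <- d[usable, ]
  if (nrow(d) < 3L)
    stop_with("muscleBOLD_small_sample",
              "correlation needs >= 3 usable subjects, got %d", nrow(d))
  if (stats::sd(d[[parameter]]) == 0 || stats::sd(d[[col]]) == 0)
    stop_with("muscleBOLD_zero_variance",
              "correlation undefined: zero variance in one variable")
  ct <- stats::cor.test(d[[parameter]], d[[col]], method = "pearson")
  data.frame(muscle = muscle, functional_measure = functional_measure,
             parameter = parameter, r = unname(ct$estimate), p = ct$p.value,
             n = nrow(d), n_excluded = n_excluded, stringsAsFactors = FALSE)
}
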