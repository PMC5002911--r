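test_that("coefficient of variation reproduces tabulated reference cells", {
  # worked examples from the bundled test-retest reference table
  expect_equal(round(coefficient_of_variation(12.9, 5.8), 1), 45.0)
  expect_equal(round(coefficient_of_variation(134.1, 21.5), 1), 16.0)
  expect_equal(coefficient_of_variation(10, 0), 0)
  # negative means (ischemic minima) still give positive CVs
  expect_gt(coefficient_of_variation(-13.3, 4.3), 0)
  expect_error(coefficient_of_variation(0, 1), class = "muscleBOLD_zero_mean")
  # scale invariance
  for (cc in c(0.1, 3, 250))
    expect_equal(coefficient_of_variation(cc * 12.9, cc * 5.8),
                 coefficient_of_variation(12.9, 5.8))
})

test_that("bundled reference table is complete and self-describing", {
  ref <- retest_reference()
  expect_equal(nrow(ref), 32)  # 4 muscles x 4 parameters x 2 visits
  expect_setequal(unique(ref$muscle), calf_muscles())
  expect_setequal(unique(ref$parameter), c("phv", "miv", "ttp", "ttr"))
})

test_that("normality test matches the reference implementation", {
  # expected values computed independently with scipy.stats.normaltest
  x <- c(2.3, 1.9, 3.1, 2.8, 4.0, 1.5, 2.2, 3.6, 2.9, 2.4, 5.1, 1.8)
  ht <- dagostino_pearson_test(x)
  expect_equal(unname(ht$statistic), 3.2239644566, tolerance = 1e-9)
  expect_equal(ht$p.value, 0.1994917836, tolerance = 1e-9)
  y <- c(10.2, 9.8, 30.0, 10.5, 9.9, 10.1, 10.0, 9.7, 10.3, 9.6)
  expect_equal(unname(dagostino_pearson_test(y)$statistic), 28.4126601868,
               tolerance = 1e-9)
  expect_error(dagostino_pearson_test(1:5), class = "muscleBOLD_small_sample")
  expect_error(dagostino_pearson_test(rep(1, 12)),
               class = "muscleBOLD_zero_variance")
})

make_paired_controls <- function(v2_shift = 0, seed = 3, n = 10) {
  set.seed(seed)
  base <- rnorm(n, 12, 4)
  rbind(
    data.frame(subject_id = sprintf("C%02d", 1:n), group = "controls",
               visit = 1L, muscle = "soleus", phv = base, ttp = rnorm(n, 21, 3),
               miv = rnorm(n, -12, 3), ttr = rnorm(n, 134, 20)),
    data.frame(subject_id = sprintf("C%02d", 1:n), group = "controls",
               visit = 2L, muscle = "soleus", phv = base + v2_shift,
               ttp = rnorm(n, 21, 3), miv = rnorm(n, -12, 3),
               ttr = rnorm(n, 134, 20)))
}

test_that("repeatability table: identical visits give equal CVs, NA paired p", {
  rec <- make_paired_controls(v2_shift = 0)
  tab <- repeatability_table(rec, parameters = "phv")
  expect_equal(tab$visit1_cv, tab$visit2_cv)
  expect_equal(tab$visit1_mean, tab$visit2_mean)
  expect_true(is.na(tab$paired_p))  # zero-variance differences: undefined
  expect_equal(tab$n_pairs, 10)
})

test_that("repeatability table matches hand-computed moments and t-test", {
  rec <- make_paired_controls(seed = 8)
  rec$phv[rec$visit == 2] <- rec$phv[rec$visit == 2] + rnorm(10, 0, 2)
  tab <- repeatability_table(rec, parameters = "phv")
  a <- rec$phv[rec$visit == 1]; b <- rec$phv[rec$visit == 2]
  expect_equal(tab$visit1_mean, mean(a))
  expect_equal(tab$visit1_sd, sd(a))
  expect_equal(tab$visit1_cv, 100 * sd(a) / abs(mean(a)))
  expect_equal(tab$paired_p, t.test(a, b, paired = TRUE)$p.value)
})

test_that("repeatability degrades to single-visit moments without visit 2", {
  rec <- make_paired_controls()
  rec <- rec[rec$visit == 1L, ]
  tab <- repeatability_table(rec, parameters = "phv")
  expect_equal(tab$visit1_mean, mean(rec$phv))
  expect_equal(tab$visit1_sd, sd(rec$phv))
  expect_true(is.na(tab$visit2_mean))
})

test_that("paired comparison has no systematic visit effect under the null", {
  # visit 2 redraws around the same subject truth: p should be ~U(0,1)
  set.seed(15)
  spec <- cohort_spec(group_sizes = c(controls = 10L))
  ps <- replicate(120, {
    rec <- simulate_cohort(spec, measure = "truth")
    rec <- rec[rec$muscle == "soleus", ]
    repeatability_table(rec, parameters = "phv")$paired_p
  })
  expect_gt(mean(ps < 0.05), 0)   # sanity: p actually varies
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps), 0.35); expect_lt(mean(ps), 0.65)
})

test_that("subject record validation catches malformed tables", {
  rec <- random_records()
  expect_silent(subject_records(rec))
  bad <- rec; bad$group[1] <- "coaches"
  expect_error(subject_records(bad), class = "muscleBOLD_bad_records")
  bad2 <- rec; bad2$visit[bad2$group == "linemen"][1] <- 2L
  expect_error(subject_records(bad2), class = "muscleBOLD_bad_records")
  bad3 <- rec[, setdiff(names(rec), "miv")]
  expect_error(subject_records(bad3), class = "muscleBOLD_bad_records")
})

test_that("two-group ANOVA reduces to the squared t statistic", {
  set.seed(21)
  rec <- random_records(n_per_group = c(linemen = 8, controls = 9))
  gs <- group_muscle_anova(rec, "phv")
  omni <- gs$omnibus[gs$omnibus$factor == "group", ]
  a <- rec$phv[rec$group == "linemen"]; b <- rec$phv[rec$group == "controls"]
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(omni$F, unname(tt$statistic)^2)
  expect_equal(omni$anova_p, tt$p.value)
})

test_that("ANOVA layer reports normality per cell and gates post hoc", {
  set.seed(2)
  rec <- random_records(n_per_group = c(linemen = 10, backs_receivers = 10,
                                        controls = 10),
                        muscles = c("gastrocnemius", "soleus"))
  rec$phv[rec$group == "controls"] <- rec$phv[rec$group == "controls"] - 8
  gs <- group_muscle_anova(rec, "phv")
  expect_true(all(gs$normality$n == 10))
  expect_true(all(is.na(gs$normality$normality_p) |
                    (gs$normality$normality_p >= 0 &
                       gs$normality$normality_p <= 1)))
  sig <- gs$omnibus$anova_p < 0.05
  expect_true(any(sig))
  # every significant omnibus has its pairwise rows; none without
  for (i in which(sig & gs$omnibus$factor == "group"))
    expect_true(any(gs$posthoc$stratum == gs$omnibus$stratum[i]))
  # small cells are rejected
  tiny <- rec[!(rec$subject_id %in% unique(rec$subject_id[rec$group == "linemen"])[-1]), ]
  expect_error(group_muscle_anova(tiny, "phv"),
               class = "muscleBOLD_degenerate_cell")
})

test_that("identical group means with large n give non-significant post hoc", {
  set.seed(31)
  rec <- random_records(n_per_group = c(linemen = 300, backs_receivers = 300,
                                        controls = 300))
  gs <- group_muscle_anova(rec, "phv", alpha = 0.999)  # force post hoc rows
  expect_true(all(gs$posthoc$p > 0.05))
})

test_that("jump correlation: exact on linear data, honours exclusions", {
  n <- 12
  rec <- random_records(n_per_group = c(controls = n))
  rec$vertical_jump <- 40 + 2 * rec$phv         # perfectly linear
  rec$broad_jump <- NA_real_
  out <- jump_correlation(rec, "gastrocnemius", "vertical")
  expect_equal(out$r, 1)
  expect_equal(out$n, n)

  rec$excluded <- c(TRUE, rep(FALSE, n - 1))
  rec$exclude_reason <- c("outlier", rep(NA, n - 1))
  out2 <- jump_correlation(rec, "gastrocnemius", "vertical")
  expect_equal(out2$n, n - 1)
  expect_equal(out2$n_excluded, 1)

  expect_error(jump_correlation(rec, "gastrocnemius", "broad"),
               class = "muscleBOLD_small_sample")
  rec$excluded <- FALSE; rec$vertical_jump <- 50
  expect_error(jump_correlation(rec, "gastrocnemius", "vertical"),
               class = "muscleBOLD_zero_variance")
})

test_that("simulated cohorts carry the requested PHV-jump correlation", {
  set.seed(77)
  spec <- cohort_spec(rho = 0.56)
  rs <- replicate(60, {
    rec <- simulate_cohort(spec, measure = "truth")
    jump_correlation(rec, "gastrocnemius", "vertical")$r
  })
  expect_lt(abs(mean(rs) - 0.56), 0.06)
  # null cohorts centre on zero
  spec0 <- cohort_spec(rho = 0)
  rs0 <- replicate(60, {
    rec <- simulate_cohort(spec0, measure = "truth")
    jump_correlation(rec, "gastrocnemius", "vertical")$r
  })
  expect_lt(abs(mean(rs0)), 0.08)
})
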