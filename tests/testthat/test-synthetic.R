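test_that("ideal curve hits its defining landmarks exactly", {
  tm <- std_timing()
  tr_true <- curve_truth(12.9, 21, -12.4, 134.1, tau_isch = 60)
  # baseline is identically zero
  expect_equal(ideal_curve(tr_true, tm, c(0, 100, 299.9)), c(0, 0, 0))
  # peak placed exactly at deflation + ttp
  expect_equal(ideal_curve(tr_true, tm, 600 + 21), 12.9)
  # exponential half-life point of the ischemic decline
  expect_equal(ideal_curve(tr_true, tm, 300 + 60 * log(2)), -12.4 / 2)
  # back at baseline from ttr onward
  expect_equal(ideal_curve(tr_true, tm, c(600 + 134.1, 880)), c(0, 0))
  expect_error(ideal_curve(tr_true, tm, 901), class = "muscleBOLD_bad_times")
  expect_error(ideal_curve(curve_truth(10, 30, -10, 400), tm, 100),
               class = "muscleBOLD_bad_truth")
})

test_that("ideal curve is continuous at every phase boundary", {
  tm <- std_timing()
  set.seed(6)
  for (k in 1:25) {
    tr_true <- curve_truth(runif(1, 2, 30), runif(1, 10, 60),
                           runif(1, -20, -2), runif(1, 65, 250),
                           tau_isch = runif(1, 20, 120))
    if (tr_true$ttr <= tr_true$ttp + 1) next
    eps <- 1e-7
    for (b in c(300, 600, 600 + tr_true$ttp, 600 + tr_true$ttr)) {
      lo <- ideal_curve(tr_true, tm, b - eps)
      hi <- ideal_curve(tr_true, tm, b + eps)
      expect_lt(abs(hi - lo), 1e-4)
    }
  }
})

test_that("curve truth rejects inadmissible parameters", {
  expect_error(curve_truth(-5, 20, -10, 100), class = "muscleBOLD_bad_truth")
  expect_error(curve_truth(5, 20, 10, 100), class = "muscleBOLD_bad_truth")
  expect_error(curve_truth(5, 120, -10, 100), class = "muscleBOLD_bad_truth")
  expect_error(curve_truth(5, 20, -10, 100, tau_isch = 0),
               class = "muscleBOLD_bad_truth")
})

test_that("simulated time course is the ideal curve plus calibrated noise", {
  tm <- std_timing()
  tr0 <- curve_truth(15, 27, -12, 130, noise_sd = 0)
  sim <- simulate_timecourse(tr0, tm)
  expect_equal(sim$timecourse$pct,
               ideal_curve(tr0, tm, sim$timecourse$times))

  # determinism for a fixed seed
  tr1 <- curve_truth(15, 27, -12, 130, noise_sd = 1)
  a <- simulate_timecourse(tr1, tm, seed = 123)
  b <- simulate_timecourse(tr1, tm, seed = 123)
  expect_identical(a$timecourse$pct, b$timecourse$pct)

  # residual SD within the chi-square 99% band for n = 300
  resid <- a$timecourse$pct - ideal_curve(tr1, tm, a$timecourse$times)
  expect_gt(sd(resid), 0.84)
  expect_lt(sd(resid), 1.16)

  # drift enters linearly
  trd <- curve_truth(15, 27, -12, 130, drift = 0.6)
  simd <- simulate_timecourse(trd, tm)
  expect_equal(simd$timecourse$pct - sim$timecourse$pct,
               0.6 * simd$timecourse$times / 60, tolerance = 1e-9)
})

test_that("phantom label geometry matches the analytic ellipse areas", {
  ph <- simulate_phantom(small_phantom_spec(), seed = 1)
  regions <- small_regions()
  for (i in seq_along(regions)) {
    e <- regions[[i]]
    n_vox <- sum(ph$mask$labels == i)
    per_slice <- n_vox / dim(ph$mask$labels)[3]
    area <- pi * e[["rx"]] * e[["ry"]]
    expect_lt(abs(per_slice - area) / area, 0.25)  # pixelation tolerance
  }
  # overlap detection
  bad <- small_regions()
  bad$soleus <- bad$gastrocnemius
  expect_error(simulate_phantom(phantom_spec(dims = c(32L, 16L, 2L),
                                             regions = bad)),
               class = "muscleBOLD_region_overlap")
})

test_that("noise-free phantom analysis recovers every muscle's truth", {
  tm <- std_timing()
  ph <- simulate_phantom(small_phantom_spec())
  for (m in ph$truth$muscle) {
    raw <- extract_voi_timecourse(ph$series, ph$mask, m)
    idx <- compute_indices(percent_change_normalize(raw, tm), tm)
    tr_true <- ph$truth[ph$truth$muscle == m, ]
    expect_lt(abs(idx$phv - tr_true$phv), 0.2)
    expect_lt(abs(idx$miv - tr_true$miv), 0.2)
    expect_lt(abs(idx$ttp - tr_true$ttp), 3 + 1e-9)
    expect_lt(abs(idx$ttr - tr_true$ttr), 3 + 1e-9)
  }
})

test_that("phantom background carries no paradigm-locked structure", {
  tm <- std_timing()
  ph <- simulate_phantom(small_phantom_spec(noise_sd = 2), seed = 9)
  paradigm <- ideal_curve(curve_truth(10, 25, -10, 130), tm,
                          frame_times(300, 3))
  lab_vec <- as.vector(ph$mask$labels)
  v <- matrix(ph$series$voxels, nrow = length(lab_vec))
  bg <- v[lab_vec == 0L, ][1:50, ]
  cors <- apply(bg, 1, function(row) cor(row, paradigm))
  expect_lt(abs(mean(cors)), 0.05)
})

test_that("phantom series is bit-reproducible and marked with protocol TR", {
  spec <- small_phantom_spec(noise_sd = 1.5)
  a <- simulate_phantom(spec, seed = 42)
  b <- simulate_phantom(spec, seed = 42)
  expect_identical(a$series$voxels, b$series$voxels)
  expect_equal(a$series$tr, 3)
  expect_equal(dim(a$series$voxels)[4], 300)
})

test_that("cohort generator honours its contract", {
  spec <- cohort_spec()
  rec <- simulate_cohort(spec, seed = 10, measure = "truth")
  expect_equal(length(unique(rec$subject_id)), 33)
  expect_equal(sum(rec$visit == 2L), 10 * 4)  # controls only, all muscles
  expect_true(all(rec$group[rec$visit == 2L] == "controls"))
  tr_tab <- attr(rec, "truth")
  b <- spec$bounds
  expect_true(all(tr_tab$phv >= b$phv[1] & tr_tab$phv <= b$phv[2]))
  expect_true(all(tr_tab$miv >= b$miv[1] & tr_tab$miv <= b$miv[2]))
  expect_true(all(tr_tab$ttr > tr_tab$ttp))

  # zero within-subject SD: both visits identical per subject
  spec0 <- cohort_spec(within_sd = c(phv = 0, miv = 0, ttp = 0, ttr = 0))
  rec0 <- simulate_cohort(spec0, seed = 11, measure = "truth")
  ctl <- rec0[rec0$group == "controls", ]
  v1 <- ctl[ctl$visit == 1L, ]; v2 <- ctl[ctl$visit == 2L, ]
  key <- paste(v1$subject_id, v1$muscle)
  expect_equal(v1$phv, v2$phv[match(key, paste(v2$subject_id, v2$muscle))])

  # determinism
  r1 <- simulate_cohort(spec, seed = 5)
  r2 <- simulate_cohort(spec, seed = 5)
  expect_identical(r1$phv, r2$phv)
})

test_that("estimator error shrinks to the discretization floor as noise -> 0", {
  tm <- std_timing()
  sds <- c(2, 0.5, 0.05)
  mae <- vapply(sds, function(s) {
    set.seed(1000 + s * 100)
    mean(replicate(15, {
      sim <- simulate_timecourse(curve_truth(15, 27, -12, 130, noise_sd = s), tm)
      abs(compute_indices(sim$timecourse, tm)$phv - 15)
    }))
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
  expect_lt(mae[3], 0.1)
})
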