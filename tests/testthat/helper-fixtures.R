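# shared fixtures: short protocols and small phantoms keep the suite fast

std_timing <- function(...) protocol_timing(...)

# compressed protocol for unit tests: 60 s baseline / 60 s occlusion /
# 120 s hyperemia at TR 3 s, no discard
short_timing <- function(tr = 3) {
  protocol_timing(baseline_start = 0, occlusion_start = 60,
                  deflation_time = 120, end_time = 240, tr = tr,
                  baseline_discard = 0)
}

small_regions <- function() {
  list(gastrocnemius     = c(cx = 11, cy = 11, rx = 4.0, ry = 2.5),
       soleus            = c(cx = 11, cy = 5,  rx = 4.0, ry = 2.2),
       anterior_tibialis = c(cx = 22, cy = 11, rx = 3.5, ry = 2.5),
       peroneus_longus   = c(cx = 22, cy = 5,  rx = 3.5, ry = 2.2))
}

small_phantom_spec <- function(...) {
  phantom_spec(dims = c(32L, 16L, 2L), regions = small_regions(), ...)
}

# normalized timecourse on the full standard grid from explicit post-phase
# values; baseline/occlusion default to zero
ntc_from_phases <- function(timing, baseline = NULL, occlusion = NULL,
                            hyperemia = NULL, muscle = "synthetic") {
  nt <- round((timing$end_time - timing$baseline_start) / timing$tr)
  tt <- frame_times(nt, timing$tr, timing$baseline_start)
  pct <- numeric(nt)
  put <- function(vals, from, to) {
    idx <- which(tt >= from & tt <= to)
    if (!is.null(vals)) pct[idx[seq_along(vals)]] <<- vals
  }
  put(baseline, timing$baseline_start, timing$occlusion_start)
  put(occlusion, timing$occlusion_start, timing$deflation_time)
  put(hyperemia, timing$deflation_time, timing$end_time)
  normalized_timecourse(muscle, tt, pct, timing$tr)
}

# brute-force oracle: trailing window means by explicit nested loop
naive_rolling <- function(x, w) {
  vapply(seq_len(length(x) - w + 1L),
         function(i) mean(x[i:(i + w - 1L)]), numeric(1))
}

# random records table for statistics tests
random_records <- function(n_per_group = c(linemen = 6, backs_receivers = 6,
                                           controls = 6),
                           muscles = "gastrocnemius", seed = 1) {
  set.seed(seed)
  rows <- list()
  id <- 0L
  for (g in names(n_per_group)) for (s in seq_len(n_per_group[[g]])) {
    id <- id + 1L
    for (m in muscles) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("R%03d", id), group = g, visit = 1L, muscle = m,
        phv = rnorm(1, 12, 4), ttp = rnorm(1, 25, 5), miv = rnorm(1, -10, 3),
        ttr = rnorm(1, 130, 25), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
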