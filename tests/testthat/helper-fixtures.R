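# Shared fixtures and independent oracles for the test suite.

# Noiseless phenotype: deterministic trace content apart from protocol /
# latency randomness; blinks off.
noiseless <- function(...) {
  phenotype(noise_sd = 0, blink_rate = 0, ...)
}

# Independent quartile oracle: linear interpolation between order
# statistics written out by hand (not via quantile()).
oracle_quartile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_fences <- function(x) {
  q1 <- oracle_quartile(x, 0.25)
  q3 <- oracle_quartile(x, 0.75)
  c(lower = q1 - 1.5 * (q3 - q1), upper = q3 + 1.5 * (q3 - q1))
}

# Expensive shared fixture: the staging-recovery cohort (31 controls,
# 20 stage-1, 10 stage-2). Built once per test run and reused.
.fixture_env <- new.env(parent = emptyenv())

staging_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- build_synthetic_cohort(
      n_control = 31, n_stage1 = 20, n_stage2 = 10, seed = 20260101
    )
  }
  .fixture_env$cohort
}

# A trace holding hand-placed saccades on an otherwise stationary eye,
# built from the closed-form waveform (independent of the subject
# simulator's scheduling).
fixation_trace_with_saccades <- function(duration, saccades,
                                         ms_vmax = 470, ms_c = 8,
                                         protocol = NULL) {
  fs <- VOG_SAMPLE_RATE
  time <- seq(0, duration - 1 / fs, by = 1 / fs)
  # superpose step profiles: each waveform holds its plateau afterwards
  pos <- numeric(length(time))
  for (i in seq_len(nrow(saccades))) {
    w <- simulate_saccade_waveform(saccades$amplitude[i], ms_vmax, ms_c,
                                   onset = saccades$onset[i], pad = 0)
    pos <- pos + stats::approx(w$time, w$position, xout = time,
                               yleft = 0, yright = dplyr::last(w$position))$y
  }
  tr <- tibble::tibble(time_s = time, gaze_h = pos,
                       gaze_v = numeric(length(time)),
                       target_h = numeric(length(time)),
                       target_v = numeric(length(time)),
                       valid = TRUE)
  attr(tr, "sample_rate") <- fs
  attr(tr, "paradigm") <- "fixation"
  attr(tr, "protocol") <- protocol
  class(tr) <- c("vog_trace", class(tr))
  tr
}
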