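pro_battery <- make_protocols(100)

spem_trace <- function(ph, seed = 5) {
  preprocess_recording(
    simulate_subject(ph, pro_battery, seed = seed, paradigms = "spem")$spem)
}

test_that("perfect pursuit yields 100% gain and a zero saccade sum", {
  out <- analyze_spem(spem_trace(noiseless(spem_gain_true = 1,
                                           pursuit_error_mode = "none")))
  expect_equal(out$spem_gain, 100, tolerance = 0.005)
  expect_equal(out$spem_saccade_sum, 0)
})

test_that("catch-up pursuit recovers the true gain with a negative saccade sum", {
  out <- analyze_spem(spem_trace(noiseless(spem_gain_true = 0.5,
                                           pursuit_error_mode = "catchup")))
  expect_equal(out$spem_gain, 50, tolerance = 0.1)  # +/- 5 points
  expect_lt(out$spem_saccade_sum, 0)
})

test_that("five 4-degree anticipatory jumps accumulate to about +20 degrees", {
  out <- analyze_spem(spem_trace(noiseless(
    spem_gain_true = 0.95, pursuit_error_mode = "anticipatory",
    n_anticipatory = 5, anticipatory_amplitude = 4)))
  expect_equal(out$spem_saccade_sum, 20, tolerance = 0.2)  # +/- 4 deg
  expect_gt(out$spem_saccade_sum, 0)
  expect_equal(out$spem_gain, 95, tolerance = 0.053)
})

test_that("pursuit endpoints go missing when too few cycles are usable", {
  tr <- spem_trace(noiseless(spem_gain_true = 1))
  tr$valid[tr$time_s > 8] <- FALSE  # 3 usable cycles only
  out <- analyze_spem(tr)
  expect_true(is.na(out$spem_gain))
  expect_true(is.na(out$spem_saccade_sum))
})

test_that("reactive-saccade endpoints match the generative phenotype", {
  ph <- noiseless()
  tr_h <- preprocess_recording(
    simulate_subject(ph, pro_battery, seed = 23, paradigms = "vgrs_h")$vgrs_h)
  out <- analyze_vgrs(tr_h)
  expect_equal(out$gain, 92, tolerance = 0.055)         # +/- 5 points
  v20 <- ph$ms_vmax * (1 - exp(-20 / ph$ms_c))
  expect_equal(out$pv, v20, tolerance = 0.05)
  expect_equal(out$latency_ms, 235, tolerance = 0.08)
  expect_equal(out$intrusion_rate, 1.2, tolerance = 0.15)

  tr_v <- preprocess_recording(
    simulate_subject(ph, pro_battery, seed = 23, paradigms = "vgrs_v")$vgrs_v)
  outv <- analyze_vgrs(tr_v)
  expect_equal(outv$up_gain, 92, tolerance = 0.055)
  expect_equal(outv$down_gain, 92, tolerance = 0.055)
  expect_equal(outv$up_pv, v20, tolerance = 0.05)
  expect_equal(outv$down_pv, v20, tolerance = 0.05)
})

test_that("saccades under 2 degrees are excluded from the intrusion rate", {
  ph <- noiseless(intrusion_rate_true = 0)
  tr <- preprocess_recording(
    simulate_subject(ph, pro_battery, seed = 31, paradigms = "vgrs_h")$vgrs_h)
  base <- analyze_vgrs(tr)
  expect_equal(base$intrusion_rate, 0)

  inject <- function(tr, amps) {
    ev <- attr(tr, "protocol")$events
    quiet <- ev$onset[seq_along(amps)] + 1.7
    for (i in seq_along(amps)) {
      w <- simulate_saccade_waveform(amps[i], 470, 8, onset = quiet[i],
                                     pad = 0)
      add <- stats::approx(w$time, w$position, xout = tr$time_s,
                           yleft = 0, yright = dplyr::last(w$position))$y
      tr$gaze_h <- tr$gaze_h + add
    }
    tr
  }
  # 1.9 deg intrusions: below the printed 2 deg bound, rate stays 0
  small <- analyze_vgrs(inject(tr, c(1.9, -1.9, 1.9)))
  expect_equal(small$intrusion_rate, 0)
  # three 3 deg intrusions over the 92.8 s acquisition: 9 / 92.8 deg/s
  big <- analyze_vgrs(inject(tr, c(3, -3, 3)))
  expect_equal(big$intrusion_rate, 9 / 92.8, tolerance = 0.05)
})

test_that("delayed-saccade errors are scored exactly against the injected truth", {
  run <- function(p) {
    rec <- simulate_subject(noiseless(delayed_error_prob = p), pro_battery,
                            seed = 41, paradigms = "delayed")$delayed
    list(out = analyze_delayed(preprocess_recording(rec)),
         truth = attr(rec, "truth")$trials)
  }
  none <- run(0)
  expect_equal(none$out$delayed_error_rate, 0)
  all_err <- run(1)
  expect_equal(all_err$out$delayed_error_rate, 100)
  some <- run(0.4)
  expect_equal(some$out$delayed_error_rate,
               100 * mean(some$truth$is_error))
  expect_equal(some$out$n_scored, 16)
})

test_that("anti-saccade errors count the first saccade only, corrections do not rescind", {
  run <- function(p, seed = 43) {
    rec <- simulate_subject(noiseless(anti_error_prob = p), pro_battery,
                            seed = seed, paradigms = "anti")$anti
    list(out = analyze_anti(preprocess_recording(rec)),
         truth = attr(rec, "truth")$trials)
  }
  none <- run(0)
  expect_equal(none$out$anti_error_rate, 0)
  some <- run(0.5)
  # every scripted error trial contains a fast mirror-ward correction;
  # the trial still scores as one error
  expect_equal(some$out$anti_error_rate, 100 * mean(some$truth$is_error))
  all_err <- run(1)
  expect_equal(all_err$out$anti_error_rate, 100)
})

test_that("voluntary gaze shifts are counted above 10 degrees and averaged over axes", {
  ph <- noiseless(shift_rate = 1)
  recs <- simulate_subject(ph, pro_battery, seed = 51,
                           paradigms = c("alternating_h", "alternating_v"))
  tr_h <- preprocess_recording(recs$alternating_h)
  tr_v <- preprocess_recording(recs$alternating_v)
  n_h <- nrow(attr(recs$alternating_h, "truth")$saccades)
  n_v <- nrow(attr(recs$alternating_v, "truth")$saccades)
  out <- analyze_voluntary_shifts(tr_h, tr_v)
  expect_equal(out$n_voluntary_shifts, mean(c(n_h, n_v)))
  expect_false(out$partial)
  expect_true(abs(out$n_voluntary_shifts - 30) <= 2)

  partial <- analyze_voluntary_shifts(tr_h, NULL)
  expect_equal(partial$n_voluntary_shifts, n_h)
  expect_true(partial$partial)
})

test_that("9-degree shifts fall below the counting threshold", {
  pro_small <- pro_battery
  pro_small$alternating_h$positions <- c(-4.5, 4.5)
  rec <- simulate_subject(noiseless(shift_rate = 1), pro_small, seed = 52,
                          paradigms = "alternating_h")$alternating_h
  out <- analyze_voluntary_shifts(preprocess_recording(rec), NULL)
  expect_equal(out$n_voluntary_shifts, 0)
})

test_that("extract_profile assembles all fourteen parameters and tolerates missing paradigms", {
  recs <- simulate_subject(noiseless(), pro_battery, seed = 61)
  traces <- lapply(recs, preprocess_recording)
  prof <- extract_profile(traces)
  expect_named(prof, profile_parameters())
  expect_true(all(is.finite(unlist(prof))))

  partial <- suppressWarnings(extract_profile(traces["anti"]))
  expect_false(is.na(partial$anti_error_rate))
  expect_true(is.na(partial$spem_gain))
  expect_true(is.na(partial$vgrs_h_pv))
})
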