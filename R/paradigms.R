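#' Smooth-pursuit gain and accumulated saccade sum
#'
#' Two endpoints are extracted from the sinusoidal pursuit record:
#'
#' * `spem_gain` (%): 100 times the median, over desaccaded valid
#'   samples where the absolute target velocity exceeds 10 deg/s, of the
#'   smooth eye velocity / target velocity ratio.
#' * `spem_saccade_sum` (deg): the accumulated signed amplitudes of all
#'   saccades interrupting pursuit. A saccade that *reduces* the
#'   absolute eye-target position error (a back-correction / catch-up
#'   saccade) contributes negatively; one that *increases* it (jumping
#'   ahead of the target, anticipatory) contributes positively. A
#'   negative total therefore flags the predominance of catch-up
#'   saccades; a positive total flags predominant anticipatory
#'   saccades.
#'
#' @param trace A pursuit `vog_trace`.
#' @param protocol The matching `vog_protocol` (sinusoid parameters).
#' @param min_cycles Minimum usable cycles after masking; fewer yields
#'   missing endpoints.
#' @return Tibble with `spem_gain` (%) and `spem_saccade_sum` (deg).
#' @export
analyze_spem <- function(trace, protocol = attr(trace, "protocol"),
                         min_cycles = 8) {
  fs <- attr(trace, "sample_rate") %||% VOG_SAMPLE_RATE
  f <- protocol$frequency
  usable_cycles <- sum(trace$valid) / fs * f
  if (usable_cycles < min_cycles) {
    return(tibble(spem_gain = NA_real_, spem_saccade_sum = NA_real_))
  }
  ev <- detect_saccades(trace, baseline = "pursuit")
  g <- trace$gaze_h
  tgt <- protocol$amplitude * sin(2 * pi * f * trace$time_s)
  v_tgt <- 2 * pi * f * protocol$amplitude * cos(2 * pi * f * trace$time_s)
  v_eye <- central_velocity(g, fs)

  # desaccade: saccade spans +/- 20 ms removed before the velocity ratio
  keep <- trace$valid & is.finite(v_eye)
  if (nrow(ev) > 0) {
    pad <- ceiling(0.02 * fs)
    for (i in seq_len(nrow(ev))) {
      keep[max(1, ev$onset_idx[i] - pad):
             min(length(keep), ev$offset_idx[i] + pad)] <- FALSE
    }
  }
  sel <- keep & abs(v_tgt) > 10
  gain <- if (any(sel)) 100 * median(v_eye[sel] / v_tgt[sel]) else NA_real_

  sac_sum <- 0
  if (nrow(ev) > 0) {
    # saccadic displacement net of the smooth-pursuit drift accumulated
    # during the saccade (running-median velocity as smooth estimate)
    k <- floor(0.25 * fs / 2) * 2 + 1
    v0 <- v_eye
    v0[!is.finite(v0)] <- 0
    v_smooth <- runmed(v0, k, endrule = "median")
    drift <- purrr::map2_dbl(ev$amp_onset_idx, ev$amp_offset_idx,
                             function(a, b) {
      mean(v_smooth[a:b]) * (trace$time_s[b] - trace$time_s[a])
    })
    amp_net <- abs(ev$amplitude - drift)
    e_pre <- abs(g[ev$amp_onset_idx] - tgt[ev$amp_onset_idx])
    e_post <- abs(g[ev$amp_offset_idx] - tgt[ev$amp_offset_idx])
    sac_sum <- sum(ifelse(e_post > e_pre, 1, -1) * amp_net)
  }
  tibble(spem_gain = gain, spem_saccade_sum = sac_sum)
}

#' Visually guided reactive saccade endpoints
#'
#' Per direction class (pooled for the horizontal task; up and down
#' separately for the vertical task):
#'
#' * gain (%) via [fit_gain()] over the primary saccades,
#' * peak velocity (deg/s) at 20 deg amplitude via the main-sequence
#'   fit of the primary saccades ([fit_main_sequence()] and
#'   [evaluate_at()]),
#' * median latency (ms) over found primaries (pooled across directions).
#'
#' For the horizontal task the saccadic intrusion rate is also computed:
#' the accumulated absolute amplitude of non-primary saccades of at
#' least 2 deg, divided by the valid acquisition time (deg/s); smaller
#' saccades are excluded.
#'
#' @param trace A VGRS `vog_trace`.
#' @param protocol Matching `vog_protocol`.
#' @return One-row tibble; horizontal: `gain`, `latency_ms`, `pv`,
#'   `intrusion_rate`; vertical: `up_gain`, `down_gain`, `latency_ms`,
#'   `up_pv`, `down_pv`.
#' @export
analyze_vgrs <- function(trace, protocol = attr(trace, "protocol")) {
  fs <- attr(trace, "sample_rate") %||% VOG_SAMPLE_RATE
  ev <- detect_saccades(trace)
  steps <- protocol$events
  prim <- purrr::map_dfr(seq_len(nrow(steps)), function(i) {
    find_primary_saccade(ev, steps$onset[i], steps$step[i])
  })
  prim$step_index <- seq_len(nrow(prim))

  pv_of <- function(p) {
    found <- dplyr::filter(p, .data$found)
    tryCatch(
      evaluate_at(fit_main_sequence(
        tibble(amplitude = found$gain_amplitude,
               peak_velocity = found$peak_velocity)), 20),
      vog_insufficient_data = function(e) NA_real_)
  }
  lat_ms <- function(p) {
    found <- dplyr::filter(p, .data$found)
    if (nrow(found) == 0) NA_real_ else 1000 * median(found$latency)
  }

  if (protocol$axis == "horizontal") {
    # intrusion rate: non-primary saccades >= 2 deg per valid second
    found_prim <- dplyr::filter(prim, .data$found)
    prim_onsets <- found_prim$latency + steps$onset[found_prim$step_index]
    is_primary <- purrr::map_lgl(ev$onset,
                                 function(o) any(abs(o - prim_onsets) < 1e-6))
    intr <- dplyr::filter(ev, !is_primary, abs(.data$amplitude) >= 2)
    t_valid <- sum(trace$valid) / fs
    tibble(
      gain = fit_gain(prim),
      latency_ms = lat_ms(prim),
      pv = pv_of(prim),
      intrusion_rate = if (t_valid > 0) sum(abs(intr$amplitude)) / t_valid
      else NA_real_
    )
  } else {
    up <- prim[steps$step > 0, ]
    dn <- prim[steps$step < 0, ]
    tibble(
      up_gain = fit_gain(up), down_gain = fit_gain(dn),
      latency_ms = lat_ms(prim),
      up_pv = pv_of(up), down_pv = pv_of(dn)
    )
  }
}

#' Delayed-saccade error rate
#'
#' A trial counts as an error when a saccade of at least 2 deg toward
#' the new target occurs between 80 ms after target onset and the
#' acoustic go cue. The rate is 100 * errors / scored trials.
#'
#' @param trace A delayed-saccade `vog_trace`.
#' @param protocol Matching protocol (trials carry `cue_delay`).
#' @return Tibble with `delayed_error_rate` (%) and `n_scored`.
#' @export
analyze_delayed <- function(trace, protocol = attr(trace, "protocol")) {
  ev <- detect_saccades(trace)
  trials <- protocol$events
  if (nrow(trials) == 0) {
    return(tibble(delayed_error_rate = NA_real_, n_scored = 0L))
  }
  big <- abs(ev$amplitude) >= 2
  err <- purrr::map_lgl(seq_len(nrow(trials)), function(i) {
    any(big &
          ev$onset > trials$onset[i] + 0.08 &
          ev$onset < trials$onset[i] + trials$cue_delay[i] &
          sign(ev$amplitude) == sign(trials$step[i]))
  })
  tibble(delayed_error_rate = 100 * mean(err), n_scored = length(err))
}

#' Anti-saccade error rate
#'
#' A trial counts as an error when the *first* saccade of at least 2 deg
#' starting more than 80 ms after target onset (and within the display
#' window) is directed toward the target rather than its mirror
#' position. A later correction does not rescind the error.
#'
#' @param trace An anti-saccade `vog_trace`.
#' @param protocol Matching protocol.
#' @return Tibble with `anti_error_rate` (%) and `n_scored`.
#' @export
analyze_anti <- function(trace, protocol = attr(trace, "protocol")) {
  ev <- detect_saccades(trace)
  trials <- protocol$events
  if (nrow(trials) == 0) {
    return(tibble(anti_error_rate = NA_real_, n_scored = 0L))
  }
  disp <- protocol$display_time %||% 1.5
  scored <- logical(nrow(trials))
  err <- logical(nrow(trials))
  big <- abs(ev$amplitude) >= 2
  for (i in seq_len(nrow(trials))) {
    sel <- which(big & ev$onset > trials$onset[i] + 0.08 &
                   ev$onset < trials$onset[i] + disp)
    if (length(sel) == 0) next
    scored[i] <- TRUE
    first <- sel[which.min(ev$onset[sel])]
    err[i] <- sign(ev$amplitude[first]) == sign(trials$step[i])
  }
  if (!any(scored)) {
    return(tibble(anti_error_rate = NA_real_, n_scored = 0L))
  }
  tibble(anti_error_rate = 100 * mean(err[scored]),
         n_scored = sum(scored))
}

#' Rapid alternating voluntary gaze-shift count
#'
#' Counts saccades exceeding 10 deg amplitude within each 30 s
#' alternating-gaze record and returns the arithmetic mean of the
#' horizontal and vertical counts. With one record missing the other
#' count is returned with a partial-data flag.
#'
#' @param trace_h,trace_v The two 30 s `vog_trace` records (either may
#'   be `NULL`).
#' @param min_amplitude Counting threshold (deg), exclusive.
#' @return Tibble with `n_voluntary_shifts` and `partial` (logical).
#' @export
analyze_voluntary_shifts <- function(trace_h, trace_v, min_amplitude = 10) {
  count1 <- function(tr) {
    if (is.null(tr)) return(NA_real_)
    ev <- detect_saccades(tr)
    sum(abs(ev$amplitude) > min_amplitude)
  }
  nh <- count1(trace_h)
  nv <- count1(trace_v)
  if (is.na(nh) && is.na(nv)) {
    warn("Both alternating-gaze records missing.")
    return(tibble(n_voluntary_shifts = NA_real_, partial = TRUE))
  }
  tibble(n_voluntary_shifts = mean(c(nh, nv), na.rm = TRUE),
         partial = is.na(nh) || is.na(nv))
}

#' Extract the full oculomotor profile of one subject
#'
#' Runs every paradigm analysis on a named list of clean traces and
#' returns the subject's fourteen-parameter oculomotor profile (one row;
#' missing endpoints are `NA`).
#'
#' @param traces Named list of `vog_trace` objects; recognized names are
#'   `spem`, `vgrs_h`, `vgrs_v`, `delayed`, `anti`, `alternating_h`,
#'   `alternating_v`. Absent paradigms yield missing endpoints.
#' @return One-row tibble with columns `spem_gain`, `spem_saccade_sum`,
#'   `vgrs_h_gain`, `vgrs_down_gain`, `vgrs_up_gain`, `vgrs_h_latency`,
#'   `vgrs_v_latency`, `vgrs_h_pv`, `vgrs_down_pv`, `vgrs_up_pv`,
#'   `intrusion_rate`, `delayed_error_rate`, `anti_error_rate`,
#'   `n_voluntary_shifts`.
#' @export
extract_profile <- function(traces) {
  sp <- if (!is.null(traces$spem)) analyze_spem(traces$spem) else
    tibble(spem_gain = NA_real_, spem_saccade_sum = NA_real_)
  vh <- if (!is.null(traces$vgrs_h)) analyze_vgrs(traces$vgrs_h) else
    tibble(gain = NA_real_, latency_ms = NA_real_, pv = NA_real_,
           intrusion_rate = NA_real_)
  vv <- if (!is.null(traces$vgrs_v)) analyze_vgrs(traces$vgrs_v) else
    tibble(up_gain = NA_real_, down_gain = NA_real_, latency_ms = NA_real_,
           up_pv = NA_real_, down_pv = NA_real_)
  de <- if (!is.null(traces$delayed)) analyze_delayed(traces$delayed) else
    tibble(delayed_error_rate = NA_real_)
  an <- if (!is.null(traces$anti)) analyze_anti(traces$anti) else
    tibble(anti_error_rate = NA_real_)
  sh <- analyze_voluntary_shifts(traces$alternating_h, traces$alternating_v)
  tibble(
    spem_gain = sp$spem_gain,
    spem_saccade_sum = sp$spem_saccade_sum,
    vgrs_h_gain = vh$gain,
    vgrs_down_gain = vv$down_gain,
    vgrs_up_gain = vv$up_gain,
    vgrs_h_latency = vh$latency_ms,
    vgrs_v_latency = vv$latency_ms,
    vgrs_h_pv = vh$pv,
    vgrs_down_pv = vv$down_pv,
    vgrs_up_pv = vv$up_pv,
    intrusion_rate = vh$intrusion_rate,
    delayed_error_rate = de$delayed_error_rate,
    anti_error_rate = an$anti_error_rate,
    n_voluntary_shifts = sh$n_voluntary_shifts
  )
}

#' The fourteen profile parameter names
#' @return Character vector of profile column names.
#' @export
profile_parameters <- function() {
  c("spem_gain", "spem_saccade_sum", "vgrs_h_gain", "vgrs_down_gain",
    "vgrs_up_gain", "vgrs_h_latency", "vgrs_v_latency", "vgrs_h_pv",
    "vgrs_down_pv", "vgrs_up_pv", "intrusion_rate", "delayed_error_rate",
    "anti_error_rate", "n_voluntary_shifts")
}

#' Simulate, preprocess and extract in one call
#'
#' Full per-subject pipeline: simulate the battery under a phenotype,
#' preprocess every recording, and extract the oculomotor profile.
#'
#' @inheritParams simulate_subject
#' @return One-row profile tibble (see [extract_profile()]).
#' @export
simulate_and_extract <- function(phen, protocols = make_protocols(seed),
                                 seed = 1L) {
  recs <- simulate_subject(phen, protocols, seed = seed)
  traces <- lapply(recs, preprocess_recording)
  extract_profile(traces)
}

#' @export
print.vog_trace <- function(x, ...) {
  cat("<vog_trace> ", attr(x, "paradigm") %||% "?", ", ",
      nrow(x), " samples at ", attr(x, "sample_rate") %||% VOG_SAMPLE_RATE,
      " Hz, ", round(100 * mean(x$valid)), "% valid\n", sep = "")
  NextMethod()
}
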