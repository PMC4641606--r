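#' Detect saccades in a clean trace
#'
#' Velocity is computed by central differences on valid samples. An
#' event spans samples where the speed exceeds 30 deg/s, extended
#' outward to the 10 deg/s boundaries; events separated by less than
#' 20 ms are merged; events overlapping invalid samples are discarded.
#' Amplitude is the position difference offset minus onset along the
#' task axis, peak velocity the maximum speed within the span.
#'
#' For smooth-pursuit records (`baseline = "pursuit"`) the thresholds
#' are applied to the velocity *residual* after subtracting a running
#' median of the velocity (window `pursuit_window_s`), so that smooth
#' tracking at up to ~47 deg/s is not itself detected; amplitudes and
#' peak velocities are still reported from the raw signal.
#'
#' @param trace A `vog_trace` from [preprocess_recording()], or any
#'   tibble with `time_s`, gaze columns and a `valid` mask.
#' @param axis `"horizontal"` or `"vertical"`; defaults to the trace's
#'   paradigm axis.
#' @param baseline `"static"` (fixation/saccade tasks) or `"pursuit"`.
#' @param peak_threshold,edge_threshold Speed thresholds (deg/s).
#' @param merge_gap_s Events closer than this (s) are merged.
#' @param pursuit_window_s Running-median window (s) for the pursuit
#'   baseline.
#' @return Tibble of events: `onset`, `offset` (s), `amplitude` (deg,
#'   signed), `peak_velocity` (deg/s), `axis`, `onset_idx`,
#'   `offset_idx`. Zero rows when nothing is detected.
#' @export
detect_saccades <- function(trace, axis = NULL, baseline = c("static", "pursuit"),
                            peak_threshold = 30, edge_threshold = 10,
                            merge_gap_s = 0.02, pursuit_window_s = 0.25) {
  baseline <- match.arg(baseline)
  fs <- attr(trace, "sample_rate") %||% VOG_SAMPLE_RATE
  axis <- axis %||% trace_axis(trace)
  g <- if (axis == "horizontal") trace$gaze_h else trace$gaze_v
  valid <- trace$valid & is.finite(g)
  n <- length(g)
  empty <- tibble(onset = numeric(0), offset = numeric(0),
                  amplitude = numeric(0), peak_velocity = numeric(0),
                  axis = character(0), onset_idx = integer(0),
                  offset_idx = integer(0), amp_onset_idx = integer(0),
                  amp_offset_idx = integer(0))
  if (n < 3 || !any(valid)) return(empty)

  v <- central_velocity(g, fs)
  v[!valid] <- NA_real_
  resid <- v
  if (baseline == "pursuit") {
    k <- floor(pursuit_window_s * fs / 2) * 2 + 1
    vs <- v
    vs[is.na(vs)] <- 0
    resid <- v - runmed(vs, k, endrule = "median")
  }
  speed <- abs(resid)
  speed[is.na(speed)] <- 0

  core <- speed > peak_threshold
  if (!any(core)) return(empty)
  above_edge <- speed > edge_threshold
  # extend every core run outward to the surrounding edge-threshold run
  runs <- rle(above_edge)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  core_cum <- cumsum(core)
  n_core <- core_cum[ends] - core_cum[starts] + core[starts]
  keep <- runs$values & n_core > 0
  spans <- tibble(start = starts[keep], end = ends[keep])
  if (nrow(spans) == 0) return(empty)

  # merge events separated by < merge_gap_s
  gap <- merge_gap_s * fs
  merged <- list(c(spans$start[1], spans$end[1]))
  for (i in seq_len(nrow(spans))[-1]) {
    last <- merged[[length(merged)]]
    if (spans$start[i] - last[2] < gap) {
      merged[[length(merged)]][2] <- spans$end[i]
    } else {
      merged[[length(merged) + 1]] <- c(spans$start[i], spans$end[i])
    }
  }
  i1 <- pmax(1L, purrr::map_int(merged, function(sp) as.integer(sp[1])))
  i2 <- pmin(n, purrr::map_int(merged, function(sp) as.integer(sp[2])))
  ok <- purrr::map2_lgl(i1, i2, function(a, b) all(valid[a:b]))
  i1 <- i1[ok]; i2 <- i2[ok]
  if (length(i1) == 0) return(empty)
  # amplitude is measured over a slightly extended window (25 ms each
  # side, clamped to valid samples and to the midpoint towards adjacent
  # events): the position tails beyond the 10 deg/s boundaries would
  # otherwise be truncated from the amplitude
  ext <- round(0.025 * fs)
  prev_end <- c(0L, i2[-length(i2)])
  next_start <- c(i1[-1], n + 1L)
  m1 <- pmax(i1 - ext, prev_end + 1L, 1L)
  m2 <- pmin(i2 + ext, next_start - 1L, n)
  m1 <- purrr::map2_int(m1, i1, function(a, b) {
    if (all(valid[a:b])) as.integer(a) else as.integer(b)
  })
  m2 <- purrr::map2_int(i2, m2, function(a, b) {
    if (all(valid[a:b])) as.integer(b) else as.integer(a)
  })
  tibble(onset = trace$time_s[i1], offset = trace$time_s[i2],
         amplitude = g[m2] - g[m1],
         peak_velocity = purrr::map2_dbl(i1, i2,
                                         function(a, b) max(speed[a:b])),
         axis = axis, onset_idx = i1, offset_idx = i2,
         amp_onset_idx = m1, amp_offset_idx = m2)
}

central_velocity <- function(g, fs) {
  n <- length(g)
  v <- rep(NA_real_, n)
  if (n >= 3) v[2:(n - 1)] <- (g[3:n] - g[1:(n - 2)]) * fs / 2
  v
}

trace_axis <- function(trace) {
  proto <- attr(trace, "protocol")
  if (!is.null(proto)) proto$axis else "horizontal"
}

#' Identify the primary saccade of a target step
#'
#' The primary saccade is the first detected event whose onset lies in
#' (step onset + 80 ms, step onset + 800 ms), whose direction matches
#' the target step, and whose amplitude is at least
#' `max(2, 0.3 * |target_step|)` deg (so small twitches and anticipatory
#' responses are not mistaken for the primary response).
#'
#' @param events Event tibble from [detect_saccades()].
#' @param step_onset Target step onset (s).
#' @param target_step Signed target step (deg).
#' @param window Latency acceptance window (s) after step onset.
#' @return One-row tibble: `latency` (s), `gain_amplitude` (deg),
#'   `peak_velocity`, `target_step`, `found`.
#' @export
find_primary_saccade <- function(events, step_onset, target_step,
                                 window = c(0.08, 0.8)) {
  min_amp <- max(2, 0.3 * abs(target_step))
  sel <- which(events$onset > step_onset + window[1] &
                 events$onset < step_onset + window[2] &
                 sign(events$amplitude) == sign(target_step) &
                 abs(events$amplitude) >= min_amp)
  if (length(sel) == 0) {
    return(tibble(latency = NA_real_, gain_amplitude = NA_real_,
                  peak_velocity = NA_real_, target_step = target_step,
                  found = FALSE))
  }
  first <- sel[which.min(events$onset[sel])]
  tibble(latency = events$onset[first] - step_onset,
         gain_amplitude = events$amplitude[first],
         peak_velocity = events$peak_velocity[first],
         target_step = target_step, found = TRUE)
}

#' Fit the saccadic main sequence
#'
#' Least-squares fit of the saturating exponential peak-velocity law
#' `v(A) = vmax * (1 - exp(-A / c))` over absolute amplitudes. The fit
#' is the basis of the peak-velocity endpoint, reported by convention at
#' 20 deg amplitude via [evaluate_at()].
#'
#' @param events Event tibble with `amplitude` and `peak_velocity`
#'   columns (at least 3 events over at least 2 distinct amplitudes).
#' @return A `vog_main_sequence` object with elements `vmax`, `c`,
#'   `n_events`, `rms_residual` and the fitting data.
#' @examples
#' ev <- tibble::tibble(amplitude = c(5, 10, 20, 40),
#'                      peak_velocity = 500 * (1 - exp(-c(5, 10, 20, 40) / 8)))
#' fit <- fit_main_sequence(ev)
#' evaluate_at(fit, 20)
#' @export
fit_main_sequence <- function(events) {
  a <- abs(events$amplitude)
  v <- events$peak_velocity
  ok <- is.finite(a) & is.finite(v) & a > 0
  a <- a[ok]; v <- v[ok]
  if (length(a) < 3 || length(unique(round(a, 3))) < 2) {
    abort("Insufficient data for a main-sequence fit (need >= 3 events over >= 2 amplitudes).",
          class = "vog_insufficient_data")
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * (1 - exp(-a / cc)),
                      data = data.frame(a = a, v = v),
                      start = list(vmax = max(v) * 1.2,
                                   cc = max(1, stats::median(a) / 2)),
                      lower = c(vmax = 1, cc = 0.1),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort("Main-sequence fit failed to converge.",
                              class = "vog_insufficient_data")
  )
  co <- coef(fit)
  res <- v - co[["vmax"]] * (1 - exp(-a / co[["cc"]]))
  structure(list(vmax = co[["vmax"]], c = co[["cc"]],
                 n_events = length(a),
                 rms_residual = sqrt(mean(res^2)),
                 data = tibble(amplitude = a, peak_velocity = v)),
            class = "vog_main_sequence")
}

#' @rdname fit_main_sequence
#' @param fit A `vog_main_sequence`.
#' @param amplitude Amplitude(s) (deg) at which to evaluate the law.
#' @export
evaluate_at <- function(fit, amplitude) {
  stopifnot(inherits(fit, "vog_main_sequence"))
  fit$vmax * (1 - exp(-abs(amplitude) / fit$c))
}

#' @export
print.vog_main_sequence <- function(x, ...) {
  cat(sprintf(
    "<vog_main_sequence> vmax = %.1f deg/s, c = %.2f deg (n = %d, rms = %.1f)\n",
    x$vmax, x$c, x$n_events, x$rms_residual))
  invisible(x)
}

#' @rdname fit_main_sequence
#' @param x A `vog_main_sequence`.
#' @param ... Unused.
#' @export
tidy.vog_main_sequence <- function(x, ...) {
  tibble(term = c("vmax", "c"), estimate = c(x$vmax, x$c))
}

#' @rdname fit_main_sequence
#' @export
glance.vog_main_sequence <- function(x, ...) {
  tibble(n_events = x$n_events, rms_residual = x$rms_residual,
         v20 = evaluate_at(x, 20))
}

#' Saccadic gain by regression through the origin
#'
#' Gain (%) of the primary saccades, obtained by linear fitting of
#' primary amplitudes as a function of target steps with a no-intercept
#' least-squares line (a zero step must predict zero amplitude),
#' pooling both directions.
#'
#' @param primaries Tibble from [find_primary_saccade()] rows (needs
#'   `gain_amplitude`, `target_step`, `found`).
#' @return Gain in percent, or `NA` when fewer than 3 primaries were
#'   found.
#' @export
fit_gain <- function(primaries) {
  ok <- dplyr::filter(primaries, .data$found)
  if (nrow(ok) < 3) return(NA_real_)
  fit <- lm(gain_amplitude ~ 0 + target_step, data = ok)
  100 * unname(coef(fit)[1])
}
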