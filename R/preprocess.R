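#' Zero-phase low-pass filter
#'
#' Noise reduction by low-pass filtering below 30 Hz, applied with a
#' 4th-order Butterworth run forward and backward (zero phase, so
#' latency endpoints are not biased). The sequence ends are extended by
#' reflection before filtering to suppress edge transients.
#'
#' @param x Numeric signal (may contain `NA`; contiguous finite runs are
#'   filtered independently).
#' @param sample_rate Sampling rate (Hz).
#' @param cutoff Cutoff frequency (Hz); must be below Nyquist.
#' @param order Butterworth order (default 4).
#' @return Filtered numeric vector, same length as `x`.
#' @export
lowpass <- function(x, sample_rate = VOG_SAMPLE_RATE, cutoff = 30,
                    order = 4) {
  if (cutoff >= sample_rate / 2) {
    abort("`cutoff` must be below the Nyquist frequency.",
          class = "vog_bad_cutoff")
  }
  bf <- signal::butter(order, cutoff / (sample_rate / 2))
  out <- x
  runs <- finite_runs(x)
  for (r in runs) {
    seg <- x[r]
    n <- length(seg)
    if (n < 12) next  # too short to filter; left untouched
    npad <- min(100, n - 1)
    pre <- 2 * seg[1] - seg[(npad + 1):2]
    post <- 2 * seg[n] - seg[(n - 1):(n - npad)]
    y <- as.numeric(signal::filtfilt(bf, c(pre, seg, post)))
    out[r] <- y[(npad + 1):(npad + n)]
  }
  out
}

finite_runs <- function(x) {
  ok <- is.finite(x)
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  purrr::map2(starts[r$values], ends[r$values], seq)
}

#' Mark blink and saturation artifacts
#'
#' Samples in blink / saturated spans (non-finite or far outside the
#' physical gaze range) are marked invalid, together with a 25 ms guard
#' margin on each side (eyelid ramps corrupt velocity estimates).
#' Recordings with more than 50% invalid samples on a channel pair are
#' rejected.
#'
#' @param x Numeric channel.
#' @param sample_rate Sampling rate (Hz).
#' @param guard_s Guard margin (s) dilated around each invalid span.
#' @param range_deg Values with absolute value above this are treated as
#'   saturated/sentinel.
#' @return Logical vector, `TRUE` where the sample is valid.
#' @export
artifact_mask <- function(x, sample_rate = VOG_SAMPLE_RATE, guard_s = 0.025,
                          range_deg = 60) {
  invalid <- !is.finite(x) | abs(x) > range_deg
  g <- ceiling(guard_s * sample_rate)
  if (any(invalid) && g > 0) {
    idx <- which(invalid)
    lo <- pmax(1, idx - g)
    hi <- pmin(length(x), idx + g)
    for (k in seq_along(idx)) invalid[lo[k]:hi[k]] <- TRUE
  }
  !invalid
}

#' Fit the affine calibration model
#'
#' Least-squares affine map (offset + scale * raw) from the uncalibrated
#' channels to true degrees, fitted per eye and axis on the calibration
#' block (slow sinusoidal tracking, f = 0.125 Hz, +/-20 deg horizontal /
#' +/-15 deg vertical). The commanded target is taken as the true eye
#' position reference.
#'
#' @param rec A calibration `vog_recording` (see
#'   [simulate_calibration_recording()]).
#' @return A `vog_calibration` object: tibble with one row per
#'   (eye, axis), columns `offset`, `scale`, `rms` (residual RMS, deg).
#' @export
fit_calibration <- function(rec) {
  proto <- attr(rec, "protocol")
  dur <- max(rec$time_s) - min(rec$time_s)
  if (dur * 0.125 < 2) {
    abort("Calibration segment must cover at least 2 cycles (16 s).",
          class = "vog_calibration_error")
  }
  chans <- tibble(
    eye = c("left", "left", "right", "right"),
    axis = c("h", "v", "h", "v"),
    raw_col = c("left_h_deg", "left_v_deg", "right_h_deg", "right_v_deg"),
    true_col = c("target_h_deg", "target_v_deg",
                 "target_h_deg", "target_v_deg")
  )
  fits <- purrr::map_dfr(seq_len(nrow(chans)), function(i) {
    raw <- rec[[chans$raw_col[i]]]
    true <- rec[[chans$true_col[i]]]
    ok <- artifact_mask(raw) & is.finite(true)
    raw <- raw[ok]; true <- true[ok]
    if (length(raw) < 50 || sd(raw) < 1e-6) {
      abort("Degenerate (constant) raw calibration signal.",
            class = "vog_calibration_error")
    }
    fit <- lm(true ~ raw)
    tibble(eye = chans$eye[i], axis = chans$axis[i],
           offset = unname(coef(fit)[1]), scale = unname(coef(fit)[2]),
           rms = sqrt(mean(fit$residuals^2)))
  })
  structure(list(table = fits), class = "vog_calibration")
}

#' @export
print.vog_calibration <- function(x, ...) {
  cat("<vog_calibration>\n")
  print(x$table)
  invisible(x)
}

#' @rdname fit_calibration
#' @param x A `vog_calibration`.
#' @param ... Unused.
#' @export
tidy.vog_calibration <- function(x, ...) x$table

#' @rdname fit_calibration
#' @export
glance.vog_calibration <- function(x, ...) {
  tibble(n_channels = nrow(x$table), rms_max = max(x$table$rms))
}

apply_calibration <- function(raw, cal, eye, axis) {
  if (is.null(cal)) return(raw)
  row <- dplyr::filter(cal$table, .data$eye == !!eye, .data$axis == !!axis)
  if (nrow(row) != 1) return(raw)
  row$offset + row$scale * raw
}

#' Merge binocular channels into a cyclopean signal
#'
#' Sample-wise mean of the two eyes where both are valid, the single
#' valid eye where one is invalid, and invalid (`NA`) where both are.
#' Neither group in the target population shows systematic left/right
#' differences, which justifies the one-eye fallback.
#'
#' @param left,right Numeric monocular channels (equal length).
#' @param left_valid,right_valid Logical validity masks.
#' @return List with `gaze` (numeric) and `valid` (logical).
#' @export
cyclopean_merge <- function(left, right,
                            left_valid = is.finite(left),
                            right_valid = is.finite(right)) {
  if (length(left) != length(right)) {
    abort("Binocular channels must have equal length.",
          class = "vog_length_mismatch")
  }
  gaze <- dplyr::case_when(
    left_valid & right_valid ~ (left + right) / 2,
    left_valid ~ left,
    right_valid ~ right,
    TRUE ~ NA_real_
  )
  list(gaze = gaze, valid = left_valid | right_valid)
}

#' Preprocess a raw recording into a clean cyclopean trace
#'
#' Reproduces the standard preprocessing chain: artifact deletion
#' (blinks, saturated spans, with a 25 ms guard), zero-phase low-pass
#' filtering below 30 Hz, affine calibration, and cyclopean merging of
#' the binocular channels. Gaps of at most 100 ms are bridged by linear
#' interpolation *only* to stabilize the filter; they stay invalid in
#' the returned mask.
#'
#' @param rec A `vog_recording`.
#' @param calibration Optional `vog_calibration` to map raw channels to
#'   true degrees.
#' @param max_invalid Maximum tolerated invalid fraction before the
#'   recording is rejected with a quality error.
#' @return A `vog_trace` tibble: `time_s`, `gaze_h`, `gaze_v`,
#'   `target_h`, `target_v`, `valid`; the paradigm, protocol and truth
#'   attributes are carried over.
#' @export
preprocess_recording <- function(rec, calibration = NULL,
                                 max_invalid = 0.5) {
  fs <- attr(rec, "sample_rate") %||% VOG_SAMPLE_RATE
  masks <- list(
    lh = artifact_mask(rec$left_h_deg, fs),
    lv = artifact_mask(rec$left_v_deg, fs),
    rh = artifact_mask(rec$right_h_deg, fs),
    rv = artifact_mask(rec$right_v_deg, fs)
  )
  invalid_frac <- mean((!masks$lh & !masks$rh) | (!masks$lv & !masks$rv))
  if (invalid_frac > max_invalid) {
    abort(sprintf(
      "Recording rejected: %.0f%% of samples invalid (limit %.0f%%).",
      100 * invalid_frac, 100 * max_invalid), class = "vog_quality_error")
  }
  clean_chan <- function(x, mask, eye, axis) {
    x[!mask] <- NA_real_
    x <- bridge_short_gaps(x, fs, max_gap_s = 0.1)
    x <- lowpass(x, fs)
    apply_calibration(x, calibration, eye, axis)
  }
  lh <- clean_chan(rec$left_h_deg, masks$lh, "left", "h")
  lv <- clean_chan(rec$left_v_deg, masks$lv, "left", "v")
  rh <- clean_chan(rec$right_h_deg, masks$rh, "right", "h")
  rv <- clean_chan(rec$right_v_deg, masks$rv, "right", "v")
  mh <- cyclopean_merge(lh, rh, masks$lh, masks$rh)
  mv <- cyclopean_merge(lv, rv, masks$lv, masks$rv)
  out <- tibble(
    time_s = rec$time_s,
    gaze_h = mh$gaze, gaze_v = mv$gaze,
    target_h = rec$target_h_deg, target_v = rec$target_v_deg,
    valid = mh$valid & mv$valid
  )
  attr(out, "sample_rate") <- fs
  attr(out, "paradigm") <- attr(rec, "paradigm")
  attr(out, "protocol") <- attr(rec, "protocol")
  attr(out, "truth") <- attr(rec, "truth")
  class(out) <- c("vog_trace", class(out))
  out
}

# Linear interpolation across short NA gaps (filtering aid only; the
# validity mask is not altered by this).
bridge_short_gaps <- function(x, sample_rate, max_gap_s = 0.1) {
  if (!anyNA(x)) return(x)
  na <- is.na(x)
  if (all(na)) return(x)
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  max_gap <- max_gap_s * sample_rate
  filled <- x
  interp <- approx(which(!na), x[!na], xout = seq_along(x), rule = 2)$y
  for (k in which(r$values)) {
    if (r$lengths[k] <= max_gap) {
      filled[starts[k]:ends[k]] <- interp[starts[k]:ends[k]]
    }
  }
  filled
}

`%||%` <- function(a, b) if (is.null(a)) b else a
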