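#' Subject phenotype for the synthetic recording generator
#'
#' A phenotype bundles every generative parameter that shapes a
#' subject's synthetic recordings. The defaults describe a healthy
#' control performing well on all five paradigms; the presets
#' [phenotype_stage1()] and [phenotype_stage2()] overlay the executive
#' and executive-plus-brainstem deficit patterns used throughout the
#' package's synthetic cohorts.
#'
#' @param spem_gain_true Smooth-pursuit velocity gain (eye velocity /
#'   target velocity), in (0, 1.1].
#' @param pursuit_error_mode One of `"none"`, `"anticipatory"` (saccades
#'   jumping ahead of the target) or `"catchup"` (corrective saccades
#'   compensating a low gain).
#' @param n_anticipatory Number of anticipatory forward jumps injected
#'   into the pursuit record when `pursuit_error_mode = "anticipatory"`.
#' @param anticipatory_amplitude Amplitude (deg) of each anticipatory jump.
#' @param ms_vmax,ms_c Main-sequence parameters of the saturating
#'   exponential peak-velocity law `v(A) = ms_vmax * (1 - exp(-|A|/ms_c))`
#'   (deg/s and deg).
#' @param saccade_gain_true Primary-saccade gain (primary amplitude /
#'   target step).
#' @param latency_mean,latency_sd Mean and SD (s) of the saccade latency
#'   distribution (normal, truncated to \[0.12, 0.60\] s).
#' @param anti_error_prob,delayed_error_prob Per-trial probability of a
#'   directional error (pro-saccade) in the anti-saccade task and of a
#'   pre-cue saccade in the delayed-saccade task.
#' @param shift_rate Self-paced alternating gaze-shift rate (shifts/s).
#' @param intrusion_rate_true Saccadic intrusion rate during fixation
#'   (accumulated absolute intrusion amplitude per second, deg/s).
#' @param noise_sd SD (deg) of additive Gaussian measurement noise per
#'   monocular channel.
#' @param blink_rate Blink rate (1/s); blinks blank 150–300 ms spans.
#' @return A `vog_phenotype` object (named list).
#' @examples
#' ph <- phenotype(anti_error_prob = 0.4)
#' ph$anti_error_prob
#' @export
phenotype <- function(spem_gain_true = 0.92,
                      pursuit_error_mode = c("none", "anticipatory", "catchup"),
                      n_anticipatory = 3,
                      anticipatory_amplitude = 4,
                      ms_vmax = 470,
                      ms_c = 8,
                      saccade_gain_true = 0.92,
                      latency_mean = 0.235,
                      latency_sd = 0.03,
                      anti_error_prob = 0.15,
                      delayed_error_prob = 0.08,
                      shift_rate = 1.9,
                      intrusion_rate_true = 1.2,
                      noise_sd = 0.1,
                      blink_rate = 0.1) {
  pursuit_error_mode <- match.arg(pursuit_error_mode)
  ph <- list(
    spem_gain_true = spem_gain_true,
    pursuit_error_mode = pursuit_error_mode,
    n_anticipatory = n_anticipatory,
    anticipatory_amplitude = anticipatory_amplitude,
    ms_vmax = ms_vmax, ms_c = ms_c,
    saccade_gain_true = saccade_gain_true,
    latency_mean = latency_mean, latency_sd = latency_sd,
    anti_error_prob = anti_error_prob,
    delayed_error_prob = delayed_error_prob,
    shift_rate = shift_rate,
    intrusion_rate_true = intrusion_rate_true,
    noise_sd = noise_sd, blink_rate = blink_rate
  )
  validate_phenotype(ph)
  structure(ph, class = "vog_phenotype")
}

validate_phenotype <- function(ph) {
  stopifnot(
    is.numeric(ph$spem_gain_true), ph$spem_gain_true > 0,
    ph$spem_gain_true <= 1.1,
    ph$ms_vmax > 0, ph$ms_c > 0,
    ph$saccade_gain_true > 0,
    ph$latency_mean > 0, ph$latency_sd >= 0,
    ph$anti_error_prob >= 0, ph$anti_error_prob <= 1,
    ph$delayed_error_prob >= 0, ph$delayed_error_prob <= 1,
    ph$shift_rate >= 0, ph$intrusion_rate_true >= 0,
    ph$noise_sd >= 0, ph$blink_rate >= 0
  )
  invisible(ph)
}

#' @export
print.vog_phenotype <- function(x, ...) {
  cat("<vog_phenotype>\n")
  for (nm in names(x)) cat("  ", nm, ": ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

#' Phenotype presets for the staged deficit patterns
#'
#' `phenotype_stage1()` overlays an executive deficit pattern on the
#' control baseline: elevated anti- and delayed-saccade error
#' probabilities, a reduced voluntary shift rate, an elevated intrusion
#' rate and frequent anticipatory pursuit saccades, while brainstem
#' parameters (peak velocity, pursuit gain) remain normal.
#' `phenotype_stage2()` adds the brainstem/ponto-cerebellar pattern:
#' low-gain pursuit corrected by catch-up saccades and, for
#' `slowed = TRUE`, slowed saccades (reduced main-sequence `ms_vmax`,
#' i.e. gaze palsy).
#'
#' `severity` in \[0, 1\] scales the executive deficit continuously; the
#' mapping keeps every affected parameter at least about three control
#' standard deviations away from the control mean even at
#' `severity = 0`.
#'
#' @param severity Deficit severity in \[0, 1\].
#' @param slowed Logical; add slowed saccades (reduced `ms_vmax`) in
#'   stage 2.
#' @param ... Further overrides passed to [phenotype()].
#' @return A `vog_phenotype`.
#' @export
phenotype_stage1 <- function(severity = 0.5, ...) {
  stopifnot(severity >= 0, severity <= 1)
  defaults <- list(
    anti_error_prob = min(1, 0.42 + 0.45 * severity),
    delayed_error_prob = min(1, 0.30 + 0.50 * severity),
    shift_rate = max(0.3, 1.9 - (0.8 + 0.7 * severity)),
    intrusion_rate_true = 1.2 + 1.1 + 1.0 * severity,
    pursuit_error_mode = "anticipatory",
    n_anticipatory = round(12 + 10 * severity),
    anticipatory_amplitude = 4
  )
  do.call(phenotype, utils::modifyList(defaults, list(...)))
}

#' @rdname phenotype_stage1
#' @export
phenotype_stage2 <- function(severity = 0.75, slowed = TRUE, ...) {
  stopifnot(severity >= 0, severity <= 1)
  base <- phenotype_stage1(severity)
  defaults <- utils::modifyList(unclass(base)[
    c("anti_error_prob", "delayed_error_prob", "shift_rate",
      "intrusion_rate_true")
  ], list(
    pursuit_error_mode = "catchup",
    spem_gain_true = 0.60 - 0.15 * severity,
    ms_vmax = if (slowed) 300 else 470
  ))
  do.call(phenotype, utils::modifyList(defaults, list(...)))
}
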