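#' Closed-form saccade kinematics
#'
#' Synthetic saccades use a logistic (sigmoidal) position profile whose
#' peak velocity follows the saturating-exponential main-sequence law
#' `v(A) = ms_vmax * (1 - exp(-|A|/ms_c))`. The logistic time constant is
#' chosen so that the *discretely sampled* peak velocity (central
#' differences on the 220 Hz grid) matches the law, compensating the
#' finite-difference bias that would otherwise shave several percent off
#' short saccades.
#'
#' @param amplitude Signed saccade amplitude (deg); must be non-zero.
#' @param ms_vmax,ms_c Main-sequence parameters (deg/s, deg).
#' @param onset Movement onset time (s), defined as the instant the eye
#'   speed crosses the 10 deg/s movement-onset threshold (the boundary a
#'   velocity detector reports).
#' @param sample_rate Sampling rate (Hz).
#' @param pad Flat padding (s) before onset and after offset.
#' @return A tibble with `time` (s) and `position` (deg, starting at 0).
#' @examples
#' w <- simulate_saccade_waveform(20, 500, 8, onset = 0.1)
#' max(abs(diff(w$position)) * 220)  # close to 500*(1 - exp(-2.5))
#' @export
simulate_saccade_waveform <- function(amplitude, ms_vmax, ms_c, onset = 0,
                                      sample_rate = VOG_SAMPLE_RATE,
                                      pad = 0.15) {
  if (!is.numeric(amplitude) || length(amplitude) != 1 || amplitude == 0) {
    abort("`amplitude` must be a single non-zero number.")
  }
  k <- saccade_kinematics(amplitude, ms_vmax, ms_c, sample_rate)
  center <- onset + k$lead
  time <- seq(0, center + 7 * k$tau + pad, by = 1 / sample_rate)
  tibble(time = time,
         position = amplitude * plogis((time - center) / k$tau))
}

# tau solving A * tanh(dt/(2 tau)) / (2 dt) = v(A) (sampled peak velocity
# equals the main-sequence law), plus the onset->center lead: the time
# from the movement-onset threshold crossing to the logistic midpoint.
# Vectorized over `amplitude`.
saccade_kinematics <- function(amplitude, ms_vmax, ms_c,
                               sample_rate = VOG_SAMPLE_RATE) {
  a <- abs(amplitude)
  vp <- ms_vmax * (1 - exp(-a / ms_c))
  dt <- 1 / sample_rate
  x <- pmin(0.98, 2 * dt * vp / a)
  tau <- dt / (2 * atanh(x))
  # onset convention: the 10 deg/s crossing, matching the boundary the
  # detector reports as movement onset
  p <- (1 - sqrt(pmax(0, 1 - 10 / vp))) / 2
  lead <- ifelse(vp > 10, tau * log((1 - p) / p), 4 * tau)
  list(tau = tau, vp = vp, lead = lead, duration = 7 * tau)
}

# Superpose logistic saccades (optionally with a slow exponential
# decay back, used for anticipatory pursuit jumps) onto a time grid.
saccades_to_position <- function(time, sched) {
  n <- length(time)
  pos <- numeric(n)
  if (is.null(sched) || nrow(sched) == 0) return(pos)
  dt <- if (n > 1) time[2] - time[1] else 1
  for (i in seq_len(nrow(sched))) {
    if (is.na(sched$decay[i])) {
      # logistic tails are negligible beyond ~12 tau; add the full step
      # beyond the right edge of the evaluation window
      half <- max(12 * sched$tau[i], 2 * dt)
      i0 <- max(1L, ceiling((sched$center[i] - half - time[1]) / dt) + 1L)
      i1 <- min(n, floor((sched$center[i] + half - time[1]) / dt) + 1L)
      if (i0 <= i1) {
        pos[i0:i1] <- pos[i0:i1] + sched$amplitude[i] *
          plogis((time[i0:i1] - sched$center[i]) / sched$tau[i])
      }
      if (i1 < n) {
        pos[(i1 + 1):n] <- pos[(i1 + 1):n] + sched$amplitude[i]
      }
    } else {
      contrib <- sched$amplitude[i] *
        plogis((time - sched$center[i]) / sched$tau[i]) *
        exp(-pmax(0, time - sched$center[i]) / sched$decay[i])
      pos <- pos + contrib
    }
  }
  pos
}

# One truth-log / schedule row per injected saccade (vectorized).
# `onset` is the 10 deg/s threshold-crossing time a detector should
# report as movement onset.
schedule_saccade <- function(onset, amplitude, phen, kind, trial = NA_integer_,
                             decay = NA_real_) {
  k <- saccade_kinematics(amplitude, phen$ms_vmax, phen$ms_c)
  nr <- length(onset)
  tibble(kind = rep_len(kind, nr), trial = rep_len(trial, nr),
         onset = onset, center = onset + k$lead, amplitude = amplitude,
         tau = k$tau, peak_velocity = k$vp, decay = rep_len(decay, nr))
}

draw_latency <- function(n, phen) {
  pmin(0.60, pmax(0.12, rnorm(n, phen$latency_mean, phen$latency_sd)))
}

#' Generate the full protocol battery
#'
#' Convenience wrapper building one protocol per paradigm from a single
#' seed (each paradigm draws from its own derived stream).
#'
#' @param seed Integer seed.
#' @return Named list of seven `vog_protocol` objects.
#' @export
make_protocols <- function(seed = 1L) {
  paradigms <- c("spem", "vgrs_h", "vgrs_v", "delayed", "anti",
                 "alternating_h", "alternating_v")
  out <- lapply(seq_along(paradigms), function(i) {
    make_protocol(paradigms[i], seed = seed + i * 1013L)
  })
  names(out) <- paradigms
  out
}

#' Simulate the full recording battery for one subject
#'
#' Generates binocular 220 Hz recordings for every supplied protocol
#' under a subject phenotype: pursuit with gain deficit and
#' catch-up/anticipatory saccades, reactive saccades with latency, gain
#' and main-sequence kinematics plus scheduled saccadic intrusions,
#' delayed- and anti-saccade trials with Bernoulli directional errors
#' (errors rapidly corrected), self-paced alternating gaze shifts,
#' Gaussian channel noise, blink artifacts (sentinel-valued spans), and
#' an optional affine distortion of the raw channels (undone later by
#' calibration). Everything is reproducible from `seed`; each recording
#' carries a ground-truth log of every injected saccade, trial outcome
#' and blink span in `attr(rec, "truth")`.
#'
#' @param phen A [phenotype()].
#' @param protocols Named list of `vog_protocol` objects (see
#'   [make_protocols()]).
#' @param seed Integer seed.
#' @param paradigms Paradigms to simulate; defaults to all protocols
#'   supplied. A requested paradigm without a protocol is an error.
#' @param distortion Optional affine raw-channel distortion,
#'   `list(h = c(offset, scale), v = c(offset, scale))`: raw = offset +
#'   scale * true, applied to both eyes.
#' @return Named list of `vog_recording` tibbles (columns `time_s`,
#'   `left_h_deg`, `left_v_deg`, `right_h_deg`, `right_v_deg`,
#'   `target_h_deg`, `target_v_deg`, `marker`).
#' @examples
#' recs <- simulate_subject(phenotype(), make_protocols(1), seed = 1,
#'                          paradigms = "anti")
#' names(recs)
#' @export
simulate_subject <- function(phen, protocols, seed = 1L,
                             paradigms = names(protocols),
                             distortion = NULL) {
  stopifnot(inherits(phen, "vog_phenotype"))
  missing_pr <- setdiff(paradigms, names(protocols))
  if (length(missing_pr) > 0) {
    abort(paste0("No protocol supplied for paradigm: ",
                 paste(missing_pr, collapse = ", ")),
          class = "vog_missing_protocol")
  }
  order_all <- c("spem", "vgrs_h", "vgrs_v", "delayed", "anti",
                 "alternating_h", "alternating_v")
  paradigms <- order_all[order_all %in% paradigms]
  withr::with_seed(seed, {
    out <- lapply(paradigms, function(p) {
      sim <- switch(p,
        spem = gen_spem(phen, protocols[[p]]),
        vgrs_h = ,
        vgrs_v = gen_vgrs(phen, protocols[[p]]),
        delayed = gen_delayed(phen, protocols[[p]]),
        anti = gen_anti(phen, protocols[[p]]),
        alternating_h = ,
        alternating_v = gen_alternating(phen, protocols[[p]])
      )
      finalize_recording(sim, phen, protocols[[p]], distortion)
    })
    names(out) <- paradigms
    out
  })
}

time_grid <- function(duration, sample_rate = VOG_SAMPLE_RATE) {
  seq(0, duration - 1 / sample_rate, by = 1 / sample_rate)
}

# ---- per-paradigm generators -------------------------------------------
# Each returns list(time, eye, target, sched, trials, protocol-specific
# truth extras). `eye` is the noiseless cyclopean truth on the task axis.

gen_vgrs <- function(phen, protocol) {
  ev <- protocol$events
  time <- time_grid(protocol$duration)
  lat <- draw_latency(nrow(ev), phen)
  g <- phen$saccade_gain_true
  prim <- schedule_saccade(ev$onset + lat, g * ev$step, phen,
                           kind = "primary", trial = seq_len(nrow(ev)))
  sched <- bind_rows(prim,
                     schedule_corrections(ev$onset + lat, (1 - g) * ev$step,
                                          phen, seq_len(nrow(ev))),
                     schedule_intrusions(phen, ev, protocol$duration))
  list(time = time, eye = saccades_to_position(time, sched),
       target = target_position(protocol, time), sched = sched,
       trials = NULL)
}

# Hypometria is mopped up by small corrective saccades 250 ms after the
# primary, each below the 2 deg intrusion-analysis threshold but above
# 1 deg (smaller residuals stay uncorrected; their peak velocity would
# fall below the detection floor).
schedule_corrections <- function(prim_onset, resid, phen, trial) {
  keep <- abs(resid) >= 1.0
  if (!any(keep)) return(NULL)
  npc <- ceiling(abs(resid[keep]) / 1.9)
  idx <- rep(seq_along(npc), npc)
  piece <- rep(resid[keep] / npc, npc)
  offs <- unlist(lapply(npc, function(k) 0.18 * (seq_len(k) - 1)))
  schedule_saccade(rep(prim_onset[keep], npc) + 0.25 + offs, piece, phen,
                   kind = "corrective", trial = rep(trial[keep], npc))
}

# Saccadic intrusions: out-and-back pairs placed in fixation windows
# between target steps, with total absolute amplitude matching
# intrusion_rate_true * duration.
schedule_intrusions <- function(phen, ev, duration) {
  budget <- phen$intrusion_rate_true * duration
  if (budget <= 0) return(NULL)
  slots <- c(ev$onset + 1.45, ev$onset + 2.05)
  slots <- slots[slots < duration - 0.40 &
                   slots < rep(ev$onset + ev$duration, 2) - 0.35]
  n_pairs <- min(length(slots), max(1, round(budget / (2 * 3.0))))
  amp <- runif(n_pairs, 2.2, 3.8)
  amp <- pmin(4.8, pmax(2.05, amp * budget / (2 * sum(amp))))
  at <- sort(sample(slots, n_pairs))
  dir <- sample(c(-1, 1), n_pairs, replace = TRUE)
  schedule_saccade(c(rbind(at, at + 0.22)),
                   c(rbind(dir * amp, -dir * amp)),
                   phen, kind = "intrusion")
}

gen_spem <- function(phen, protocol) {
  time <- time_grid(protocol$duration)
  target <- target_position(protocol, time)
  g <- phen$spem_gain_true
  base <- g * target
  sched <- NULL
  if (phen$pursuit_error_mode == "catchup") {
    sched <- schedule_catchups(phen, time, target, base)
  } else if (phen$pursuit_error_mode == "anticipatory" &&
             phen$n_anticipatory > 0) {
    f <- protocol$frequency
    # candidate jump times: target zero crossings (peak target velocity)
    cand <- seq_len(2 * protocol$cycles - 2) / (2 * f)
    at <- sort(sample(cand, min(phen$n_anticipatory, length(cand))))
    vdir <- sign(cos(2 * pi * f * at))
    sched <- purrr::map_dfr(seq_along(at), function(j) {
      schedule_saccade(at[j], vdir[j] * phen$anticipatory_amplitude, phen,
                       kind = "anticipatory", decay = 1.2)
    })
  }
  eye <- base + saccades_to_position(time, sched)
  list(time = time, eye = eye, target = target, sched = sched, trials = NULL)
}

# Catch-up saccades fired whenever the position error exceeds 2 deg
# (treated as instantaneous position resets while scanning; rendered as
# logistic waveforms in the trace).
schedule_catchups <- function(phen, time, target, base, threshold = 2) {
  offset <- 0
  last_end <- -Inf
  rows <- list()
  i <- 1
  n <- length(time)
  while (i <= n) {
    e <- target[i] - (base[i] + offset)
    if (abs(e) > threshold && time[i] > last_end) {
      sc <- schedule_saccade(time[i], e, phen, kind = "catchup")
      rows[[length(rows) + 1]] <- sc
      offset <- offset + e
      last_end <- time[i] + 7 * sc$tau + 0.18
    }
    i <- i + 1
  }
  if (length(rows) == 0) NULL else bind_rows(rows)
}

gen_delayed <- function(phen, protocol) {
  ev <- protocol$events
  time <- time_grid(protocol$duration)
  lat <- draw_latency(nrow(ev), phen)
  err <- runif(nrow(ev)) < phen$delayed_error_prob
  g <- phen$saccade_gain_true
  t_move <- ifelse(err, ev$onset + lat, ev$onset + ev$cue_delay + lat)
  sched <- bind_rows(
    schedule_saccade(t_move, g * ev$step, phen,
                     kind = ifelse(err, "error_precue", "primary"),
                     trial = seq_len(nrow(ev))),
    schedule_corrections(t_move, (1 - g) * ev$step, phen,
                         seq_len(nrow(ev)))
  )
  trials <- tibble(trial = seq_len(nrow(ev)), is_error = err,
                   cue_delay = ev$cue_delay)
  list(time = time, eye = saccades_to_position(time, sched),
       target = target_position(protocol, time), sched = sched,
       trials = trials)
}

gen_anti <- function(phen, protocol) {
  ev <- protocol$events
  time <- time_grid(protocol$duration)
  lat <- draw_latency(nrow(ev), phen)
  err <- runif(nrow(ev)) < phen$anti_error_prob
  g <- phen$saccade_gain_true
  disp <- protocol$display_time
  ecc <- ev$position
  trial <- seq_len(nrow(ev))
  pro <- schedule_saccade(ev$onset[err] + lat[err], g * ecc[err], phen,
                          kind = "error_pro", trial = trial[err])
  # erroneous pro-saccades are rapidly corrected to the mirror position
  corr <- schedule_saccade(pro$onset + 7 * pro$tau + 0.15,
                           -ecc[err] - g * ecc[err], phen,
                           kind = "anti_correction", trial = trial[err])
  anti <- schedule_saccade(ev$onset[!err] + lat[!err], -ecc[!err], phen,
                           kind = "anti", trial = trial[!err])
  # re-fixation of the central target after the stimulus extinguishes
  refix <- schedule_saccade(ev$onset + disp + lat, ecc, phen,
                            kind = "refixation", trial = trial)
  sched <- arrange(bind_rows(pro, corr, anti, refix), .data$onset)
  trials <- tibble(trial = seq_len(nrow(ev)), is_error = err)
  list(time = time, eye = saccades_to_position(time, sched),
       target = target_position(protocol, time), sched = sched,
       trials = trials)
}

gen_alternating <- function(phen, protocol) {
  time <- time_grid(protocol$duration)
  sep <- diff(protocol$positions)  # 20 deg
  sched <- NULL
  if (phen$shift_rate > 0) {
    period <- 1 / phen$shift_rate
    n_max <- ceiling(protocol$duration / (0.9 * period)) + 2
    at <- 0.5 + cumsum(c(0, period * runif(n_max - 1, 0.9, 1.1)))
    at <- at[at < protocol$duration - 0.25]
    if (length(at) > 0) {
      dirn <- rep_len(c(1, -1), length(at))
      sched <- schedule_saccade(at, dirn * sep, phen, kind = "shift")
    }
  }
  eye <- protocol$positions[1] + saccades_to_position(time, sched)
  list(time = time, eye = eye, target = target_position(protocol, time),
       sched = sched, trials = NULL)
}

# ---- assembly ----------------------------------------------------------

finalize_recording <- function(sim, phen, protocol, distortion = NULL) {
  n <- length(sim$time)
  horizontal <- protocol$axis == "horizontal"
  on_axis <- sim$eye
  off_axis <- numeric(n)

  # binocular channels: cyclopean truth +/- slow vergence wobble, plus
  # independent per-eye measurement noise
  verg <- if (phen$noise_sd > 0) {
    0.2 * phen$noise_sd * sin(2 * pi * 0.05 * sim$time + runif(1, 0, 2 * pi))
  } else 0
  eye_chan <- function(truth, side_sign) {
    truth + side_sign * verg / 2 +
      if (phen$noise_sd > 0) rnorm(n, 0, phen$noise_sd) else 0
  }
  left_on <- eye_chan(on_axis, 1)
  right_on <- eye_chan(on_axis, -1)
  left_off <- eye_chan(off_axis, 1)
  right_off <- eye_chan(off_axis, -1)

  # optional affine raw-channel distortion (what calibration undoes)
  if (!is.null(distortion)) {
    ax_on <- if (horizontal) distortion$h else distortion$v
    ax_off <- if (horizontal) distortion$v else distortion$h
    if (!is.null(ax_on)) {
      left_on <- ax_on[1] + ax_on[2] * left_on
      right_on <- ax_on[1] + ax_on[2] * right_on
    }
    if (!is.null(ax_off)) {
      left_off <- ax_off[1] + ax_off[2] * left_off
      right_off <- ax_off[1] + ax_off[2] * right_off
    }
  }

  # blinks: sentinel-valued spans on all eye channels
  blinks <- NULL
  if (phen$blink_rate > 0) {
    nb <- rpois(1, phen$blink_rate * protocol$duration)
    if (nb > 0) {
      b_on <- sort(runif(nb, 0, protocol$duration - 0.35))
      b_dur <- runif(nb, 0.15, 0.30)
      blinks <- tibble(onset = b_on, offset = b_on + b_dur)
      for (k in seq_len(nb)) {
        idx <- sim$time >= blinks$onset[k] & sim$time <= blinks$offset[k]
        left_on[idx] <- right_on[idx] <- BLINK_SENTINEL
        left_off[idx] <- right_off[idx] <- BLINK_SENTINEL
      }
    }
  }

  df <- tibble(
    time_s = sim$time,
    left_h_deg = if (horizontal) left_on else left_off,
    left_v_deg = if (horizontal) left_off else left_on,
    right_h_deg = if (horizontal) right_on else right_off,
    right_v_deg = if (horizontal) right_off else right_on,
    target_h_deg = if (horizontal) sim$target else numeric(n),
    target_v_deg = if (horizontal) numeric(n) else sim$target,
    marker = ""
  )
  if (!is.null(protocol$events)) {
    idx <- findInterval(protocol$events$onset, sim$time)
    df$marker[pmax(idx, 1)] <- paste0("step:", seq_len(nrow(protocol$events)))
  }
  new_vog_recording(df, protocol,
                    truth = list(saccades = sim$sched, trials = sim$trials,
                                 blinks = blinks, phenotype = unclass(phen)))
}

new_vog_recording <- function(df, protocol, truth = NULL) {
  attr(df, "sample_rate") <- VOG_SAMPLE_RATE
  attr(df, "paradigm") <- protocol$paradigm
  attr(df, "protocol") <- protocol
  attr(df, "truth") <- truth
  class(df) <- c("vog_recording", class(df))
  df
}

#' Simulate a calibration recording
#'
#' The calibration block has the subject track a slow (f = 0.125 Hz)
#' sinusoidal single-spot target spanning +/-20 deg horizontally and
#' +/-15 deg vertically; the raw channels may carry an affine distortion
#' which [fit_calibration()] recovers.
#'
#' @inheritParams simulate_subject
#' @param duration Recording length (s); must cover at least 2 cycles
#'   (16 s) for a valid calibration fit.
#' @return A `vog_recording` with paradigm `"calibration"`.
#' @export
simulate_calibration_recording <- function(phen, seed = 1L, duration = 24,
                                           distortion = NULL) {
  withr::with_seed(seed, {
    time <- time_grid(duration)
    tgt_h <- 20 * sin(2 * pi * 0.125 * time)
    tgt_v <- 15 * sin(2 * pi * 0.125 * time + pi / 2)
    # tracking of the slow calibration target is essentially perfect
    # (pursuit gain ~ 1 at these target velocities)
    track <- function(tgt) tgt
    mk <- function(truth) {
      truth + if (phen$noise_sd > 0) rnorm(length(time), 0, phen$noise_sd)
      else 0
    }
    lh <- mk(track(tgt_h)); rh <- mk(track(tgt_h))
    lv <- mk(track(tgt_v)); rv <- mk(track(tgt_v))
    if (!is.null(distortion)) {
      if (!is.null(distortion$h)) {
        lh <- distortion$h[1] + distortion$h[2] * lh
        rh <- distortion$h[1] + distortion$h[2] * rh
      }
      if (!is.null(distortion$v)) {
        lv <- distortion$v[1] + distortion$v[2] * lv
        rv <- distortion$v[1] + distortion$v[2] * rv
      }
    }
    df <- tibble(time_s = time, left_h_deg = lh, left_v_deg = lv,
                 right_h_deg = rh, right_v_deg = rv,
                 target_h_deg = tgt_h, target_v_deg = tgt_v, marker = "")
    proto <- structure(list(paradigm = "calibration", axis = "horizontal",
                            frequency = 0.125, amplitude = 20, cycles =
                              duration * 0.125, duration = duration),
                       class = "vog_protocol")
    new_vog_recording(df, proto, truth = list(distortion = distortion))
  })
}

#' Write / read a recording as TSV (with a JSON protocol sidecar)
#'
#' @param rec A `vog_recording` (or clean trace tibble).
#' @param path TSV file path; the protocol sidecar is written next to it
#'   as `<path>.protocol.json`.
#' @return `write_recording()` returns `path` invisibly;
#'   `read_recording()` returns the recording with its protocol
#'   re-attached (truth logs are not serialized).
#' @export
write_recording <- function(rec, path) {
  readr::write_tsv(as_tibble(rec), path, progress = FALSE)
  proto <- attr(rec, "protocol")
  if (!is.null(proto)) write_protocol(proto, paste0(path, ".protocol.json"))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  sidecar <- paste0(path, ".protocol.json")
  proto <- if (file.exists(sidecar)) read_protocol(sidecar) else NULL
  if (is.null(proto)) {
    attr(df, "sample_rate") <- VOG_SAMPLE_RATE
    class(df) <- c("vog_recording", class(df))
    df
  } else {
    new_vog_recording(df, proto)
  }
}
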