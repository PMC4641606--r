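#' Stimulus protocol descriptors
#'
#' `make_protocol()` generates the stimulus descriptor for one of the seven
#' task blocks of the oculomotor battery:
#'
#' * `"spem"` — horizontal sinusoidal smooth pursuit, f = 0.375 Hz,
#'   amplitude +/-20 deg, 12 cycles (32 s), peak target velocity 47.1 deg/s.
#' * `"vgrs_h"` — 32 horizontal visually guided reactive target steps
#'   (three each of +/-5, +/-10, +/-15, +/-40 deg and four each of
#'   +/-20 deg), targets within +/-20 deg, presentation 2.9 s on average
#'   (range 2.1–3.5 s), 92.8 s acquisition time.
#' * `"vgrs_v"` — 36 vertical steps (four each of +/-5, +/-10, +/-15,
#'   +/-30 deg and two each of +/-20 deg), targets within +/-15 deg,
#'   presentation 2.6 s on average (2.1–3.5 s), 93.6 s acquisition time.
#' * `"delayed"` — 16 delayed-saccade trials (8 per side; steps of
#'   5, 10, 20, 40 deg), each with an acoustic go cue 1.1–2.3 s
#'   (mean 1.7 s) after target onset; the response must be withheld
#'   until the cue.
#' * `"anti"` — 16 anti-saccade trials (8 per side) with green targets at
#'   +/-5, +/-10, +/-15, +/-20 deg eccentricity, stimulus onset asynchrony
#'   2.1–3.0 s (mean 2.6 s); the instructed response is a gaze shift to
#'   the mirror position.
#' * `"alternating_h"`, `"alternating_v"` — 30 s of self-paced rapid
#'   alternating gaze shifts between two steady targets 20 deg apart.
#'
#' Step orderings and presentation jitter are pseudo-random but fully
#' reproducible from `seed`; the step-amplitude multisets, counts and
#' total acquisition times are exact.
#'
#' @param paradigm One of `"spem"`, `"vgrs_h"`, `"vgrs_v"`, `"delayed"`,
#'   `"anti"`, `"alternating_h"`, `"alternating_v"`.
#' @param seed Integer seed for the protocol's pseudo-random stream.
#' @return A `vog_protocol` object: a list with `paradigm`, `axis`,
#'   `duration` (s) and, for discrete-trial paradigms, an `events` tibble
#'   with one row per target step (`onset`, `duration`, `step`,
#'   `position`, `color`, `cue_delay`). Continuous paradigms carry
#'   `frequency`, `amplitude` and `cycles` (pursuit) or `positions`
#'   (alternating) instead.
#' @examples
#' pr <- make_protocol("vgrs_h", seed = 1)
#' nrow(pr$events)      # 32 steps
#' pr$duration          # 92.8 s
#' @export
make_protocol <- function(paradigm, seed = 1L) {
  paradigms <- c("spem", "vgrs_h", "vgrs_v", "delayed", "anti",
                 "alternating_h", "alternating_v")
  if (!is.character(paradigm) || length(paradigm) != 1 ||
      !paradigm %in% paradigms) {
    abort(paste0("Unknown paradigm: ", paste(paradigm, collapse = ", "),
                 ". Supported: ", paste(paradigms, collapse = ", ")),
          class = "vog_unknown_paradigm")
  }
  withr::with_seed(seed, protocol_build(paradigm))
}

protocol_build <- function(paradigm) {
  out <- switch(paradigm,
    spem = list(
      paradigm = "spem", axis = "horizontal",
      frequency = 0.375, amplitude = 20, cycles = 12,
      duration = 12 / 0.375
    ),
    vgrs_h = protocol_steps(
      paradigm = "vgrs_h", axis = "horizontal",
      steps = rep(c(-40, -20, -15, -10, -5, 5, 10, 15, 20, 40),
                  times = c(3, 4, 3, 3, 3, 3, 3, 3, 4, 3)),
      limit = 20, mean_dur = 2.9, range_dur = c(2.1, 3.5)
    ),
    vgrs_v = protocol_steps(
      paradigm = "vgrs_v", axis = "vertical",
      steps = rep(c(-30, -20, -15, -10, -5, 5, 10, 15, 20, 30),
                  times = c(4, 2, 4, 4, 4, 4, 4, 4, 2, 4)),
      limit = 15, mean_dur = 2.6, range_dur = c(2.1, 3.5)
    ),
    delayed = {
      pr <- protocol_steps(
        paradigm = "delayed", axis = "horizontal",
        steps = rep(c(-40, -20, -10, -5, 5, 10, 20, 40), each = 2),
        limit = 20, mean_dur = 4.0, range_dur = c(4.0, 4.0)
      )
      pr$events$cue_delay <- jitter_to_mean(nrow(pr$events), 1.7, c(1.1, 2.3))
      pr$events$color <- "red"
      pr
    },
    anti = {
      ecc <- sample(rep(c(-20, -15, -10, -5, 5, 10, 15, 20), each = 2))
      dur <- jitter_to_mean(length(ecc), 2.6, c(2.1, 3.0))
      onset <- cumsum(c(0, dur[-length(dur)]))
      list(
        paradigm = "anti", axis = "horizontal",
        duration = sum(dur),
        display_time = 1.5,
        events = tibble(
          onset = onset, duration = dur, step = ecc, position = ecc,
          color = "green", cue_delay = NA_real_
        )
      )
    },
    alternating_h = list(
      paradigm = "alternating_h", axis = "horizontal",
      positions = c(-10, 10), duration = 30
    ),
    alternating_v = list(
      paradigm = "alternating_v", axis = "vertical",
      positions = c(-10, 10), duration = 30
    )
  )
  structure(out, class = "vog_protocol")
}

# Discrete-step protocol: pseudo-random step order keeping the target on
# the screen, presentation durations jittered within the printed range
# but with the printed mean held exactly (so total acquisition time
# equals n * mean).
protocol_steps <- function(paradigm, axis, steps, limit, mean_dur, range_dur) {
  ord <- sample_step_sequence(steps, limit)
  dur <- jitter_to_mean(length(ord), mean_dur, range_dur)
  onset <- cumsum(c(0, dur[-length(dur)]))
  list(
    paradigm = paradigm, axis = axis,
    duration = sum(dur),
    events = tibble(
      onset = onset, duration = dur, step = ord,
      position = cumsum(ord),
      color = "red", cue_delay = NA_real_
    )
  )
}

# Random order of a step multiset such that the cumulative position never
# leaves [-limit, limit] (targets stay on the LED array). Greedy draw
# among feasible remaining steps with restart on dead ends.
sample_step_sequence <- function(steps, limit, max_tries = 1000) {
  for (try in seq_len(max_tries)) {
    remaining <- steps
    pos <- 0
    out <- numeric(0)
    repeat {
      feasible <- which(abs(pos + remaining) <= limit + 1e-9)
      if (length(feasible) == 0) break
      pick <- if (length(feasible) == 1) feasible else sample(feasible, 1)
      out <- c(out, remaining[pick])
      pos <- pos + remaining[pick]
      remaining <- remaining[-pick]
      if (length(remaining) == 0) return(out)
    }
  }
  abort("Could not order target steps within the screen range.")
}

# Uniform draws in [lo, hi] rescaled about their sample mean so the mean
# equals `target` exactly while every value stays inside the range.
jitter_to_mean <- function(n, target, range) {
  if (range[1] == range[2]) return(rep(target, n))
  u <- runif(n, range[1], range[2])
  dev <- u - mean(u)
  hi_room <- range[2] - target
  lo_room <- target - range[1]
  s <- min(1,
           if (max(dev) > 0) hi_room / max(dev) else 1,
           if (min(dev) < 0) lo_room / -min(dev) else 1)
  target + s * dev
}

#' @export
print.vog_protocol <- function(x, ...) {
  cat("<vog_protocol> ", x$paradigm, " (", x$axis, "), duration ",
      round(x$duration, 2), " s\n", sep = "")
  if (!is.null(x$events)) {
    cat("  ", nrow(x$events), " target steps, amplitudes {",
        paste(sort(unique(abs(x$events$step))), collapse = ", "),
        "} deg\n", sep = "")
  }
  if (!is.null(x$frequency)) {
    cat("  sinusoid f = ", x$frequency, " Hz, amplitude +/-", x$amplitude,
        " deg, ", x$cycles, " cycles\n", sep = "")
  }
  invisible(x)
}

#' Target position of a protocol over time
#'
#' Evaluates the stimulus position (deg, along the protocol's task axis)
#' on an arbitrary time grid: the sinusoid for pursuit, the piecewise
#' constant step sequence for the saccade tasks, and the two steady
#' targets (reported as their midpoint trajectory, i.e. both lit:
#' position 0 is returned with the pair in `positions`) for the
#' alternating task.
#'
#' @param protocol A `vog_protocol`.
#' @param time Numeric vector of times (s).
#' @return Numeric vector of target positions (deg).
#' @export
target_position <- function(protocol, time) {
  if (!is.null(protocol$frequency)) {
    return(protocol$amplitude * sin(2 * pi * protocol$frequency * time))
  }
  if (!is.null(protocol$positions)) {
    # both alternating targets are continuously lit; report midline
    return(rep(0, length(time)))
  }
  ev <- protocol$events
  pos <- rep(0, length(time))
  if (protocol$paradigm == "anti") {
    # target at eccentricity while displayed, otherwise central fixation
    for (i in seq_len(nrow(ev))) {
      on <- time >= ev$onset[i] &
        time < ev$onset[i] + min(protocol$display_time, ev$duration[i])
      pos[on] <- ev$position[i]
    }
  } else {
    idx <- findInterval(time, ev$onset)
    pos <- ifelse(idx == 0, 0, ev$position[pmax(idx, 1)])
  }
  pos
}

#' Serialize / read a protocol descriptor as JSON
#'
#' @param protocol A `vog_protocol`.
#' @param path File path for the JSON sidecar.
#' @return `write_protocol()` returns `path` invisibly; `read_protocol()`
#'   returns the `vog_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  x <- unclass(protocol)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$events)) x$events <- as_tibble(x$events)
  structure(x, class = "vog_protocol")
}
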