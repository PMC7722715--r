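#' Simulation parameters for the synthetic gaze generator
#'
#' Defaults describe a realistic video-oculography recording of a fixating
#' observer: Brownian fixational drift, microsaccades obeying the
#' amplitude--peak-velocity main sequence, blinks with pupil-trace
#' signatures, white measurement noise, and a hazard-driven pre-target
#' reduction of the saccade rate.
#'
#' @param base_saccade_rate Baseline (micro)saccade rate, saccades/s.
#' @param inhibition_depth Fractional pre-target rate reduction at full
#'   anticipation, in \[0, 1\]. The instantaneous rate during a foreperiod
#'   is `base_saccade_rate * (1 - inhibition_depth * anticipation(t))`
#'   where [anticipation()] is the conditional probability of the target
#'   arriving within `inhibition_window_ms`.
#' @param inhibition_window_ms Look-ahead of the anticipation function, ms.
#' @param drift_sd Fixational-drift random-walk scale, deg/sqrt(s) per axis.
#' @param noise_sd Per-sample, per-eye measurement noise, deg.
#' @param main_sequence_slope Peak velocity per unit amplitude,
#'   (deg/s)/deg, over the microsaccade range.
#' @param main_sequence_exponent Exponent of the amplitude term.
#' @param main_sequence_noise_sdlog SD of the multiplicative (log-normal)
#'   noise on peak velocity.
#' @param amplitude_meanlog,amplitude_sdlog Log-normal amplitude
#'   distribution of generated saccades (deg).
#' @param pupil_baseline Pupil-size baseline, arbitrary recorder units.
#' @param blink_rate Blink rate, blinks/s.
#' @param blink_duration_ms Range of blink durations, ms.
#' @param seed Integer seed; every random draw of the generator flows
#'   from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(base_saccade_rate = 1.8,
                       inhibition_depth = 0.8,
                       inhibition_window_ms = 300,
                       drift_sd = 0.08,
                       noise_sd = 0.01,
                       main_sequence_slope = 45,
                       main_sequence_exponent = 1,
                       main_sequence_noise_sdlog = 0.1,
                       amplitude_meanlog = log(0.35),
                       amplitude_sdlog = 0.45,
                       pupil_baseline = 1200,
                       blink_rate = 0.1,
                       blink_duration_ms = c(100, 300),
                       seed = 1) {
  p <- as.list(environment())
  stopifnot(base_saccade_rate >= 0, blink_rate >= 0,
            inhibition_depth >= 0, inhibition_depth <= 1,
            inhibition_window_ms >= 0, drift_sd >= 0, noise_sd >= 0,
            main_sequence_slope > 0, pupil_baseline > 0,
            length(blink_duration_ms) == 2)
  class(p) <- "sim_params"
  p
}

#' Simulate a binocular gaze recording for one block
#'
#' Produces a continuous 1000 Hz binocular recording covering the block's
#' trial schedule, plus the ground truth of every injected event. Saccade
#' onsets follow an inhomogeneous Bernoulli process whose per-ms rate is
#' `base_saccade_rate * (1 - inhibition_depth * anticipation(t - cue))`
#' during each foreperiod and the base rate elsewhere; the anticipation is
#' computed from the block's foreperiod distribution, so the pre-target
#' inhibition mirrors the conditional target probability (the
#' temporal-orienting generative law). Each saccade is a minimum-jerk
#' displacement whose peak velocity follows the main sequence with
#' multiplicative noise; its duration follows from the minimum-jerk identity
#' `duration = 1.875 * amplitude / peak_velocity`. Both eyes share the
#' drift and saccade signal (conjugate gaze) and receive independent
#' measurement noise. Blinks zero the pupil trace with 20 ms raised-cosine
#' ramps and blank the position channels.
#'
#' @param schedule A `trial_schedule` from [build_schedule()] (non-empty).
#' @param params A [sim_params()] object.
#' @return A list with elements `recording` (a `gaze_recording`: data frame
#'   `time_ms, xL_deg, yL_deg, pupilL, xR_deg, yR_deg, pupilR` with
#'   attribute `sampling_rate = 1000`) and `truth` (list with
#'   `saccade_onset_ms`, `saccade_amplitude_deg`,
#'   `saccade_peak_velocity_dps`, `saccade_duration_ms`, `blink_onset_ms`,
#'   `blink_offset_ms`).
#' @export
simulate_gaze <- function(schedule, params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.data.frame(schedule) || nrow(schedule) == 0) {
    stop("schedule must be a non-empty trial schedule")
  }
  fs <- 1000
  n <- ceiling(max(schedule$target_onset_ms) + 350)
  rng <- local_seed(params$seed)
  on.exit(rng(), add = TRUE)

  ## --- instantaneous saccade rate (per second) --------------------------
  rate <- rep(params$base_saccade_rate, n)
  if (params$inhibition_depth > 0) {
    for (bt in unique(schedule$block_type)) {
      dist <- block_distribution(bt)
      rows <- which(schedule$block_type == bt)
      fpmax <- max(schedule$foreperiod_ms[rows])
      antic <- anticipation(dist, 0:fpmax, params$inhibition_window_ms)
      gain <- 1 - params$inhibition_depth * antic
      for (i in rows) {
        fp <- schedule$foreperiod_ms[i]
        idx <- round(schedule$cue_onset_ms[i]) + 0:fp  # 0-based ms
        rate[idx + 1] <- params$base_saccade_rate * gain[1:(fp + 1)]
      }
    }
  }

  ## --- ground-truth saccades -------------------------------------------
  on_ms <- which(stats::runif(n) < rate / fs) - 1   # onset times, ms
  k <- length(on_ms)
  amp <- exp(stats::rnorm(k, params$amplitude_meanlog, params$amplitude_sdlog))
  pv <- params$main_sequence_slope * amp^params$main_sequence_exponent *
    exp(stats::rnorm(k, 0, params$main_sequence_noise_sdlog))
  dur <- pmin(pmax(round(1.875 * amp / pv * 1000), 10), 120)
  dirn <- stats::runif(k, 0, 2 * pi)

  dx <- numeric(n)
  dy <- numeric(n)
  for (i in seq_len(k)) {
    u <- seq_len(dur[i]) / dur[i]
    s <- amp[i] * (10 * u^3 - 15 * u^4 + 6 * u^5)
    inc <- diff(c(0, s))
    idx <- on_ms[i] + seq_len(dur[i])       # 1-based sample indices
    ok <- idx <= n
    dx[idx[ok]] <- dx[idx[ok]] + inc[ok] * cos(dirn[i])
    dy[idx[ok]] <- dy[idx[ok]] + inc[ok] * sin(dirn[i])
  }
  x <- cumsum(stats::rnorm(n, 0, params$drift_sd / sqrt(fs)) + dx)
  y <- cumsum(stats::rnorm(n, 0, params$drift_sd / sqrt(fs)) + dy)

  ## --- blinks -----------------------------------------------------------
  n_blinks <- stats::rpois(1, params$blink_rate * n / fs)
  blink_on <- blink_off <- numeric(0)
  if (n_blinks > 0) {
    bon <- sort(stats::runif(n_blinks, 0, n - 1))
    bdur <- stats::runif(n_blinks, params$blink_duration_ms[1],
                         params$blink_duration_ms[2])
    boff <- pmin(bon + bdur, n - 1)
    keep <- rep(TRUE, n_blinks)       # drop overlapping intervals
    last_off <- -Inf
    for (i in seq_len(n_blinks)) {
      if (bon[i] <= last_off + 1) keep[i] <- FALSE else last_off <- boff[i]
    }
    blink_on <- round(bon[keep])
    blink_off <- round(boff[keep])
  }

  ## --- pupil and measured channels --------------------------------------
  t_s <- (0:(n - 1)) / fs
  slow <- 0.01 * params$pupil_baseline *
    sin(2 * pi * 0.1 * t_s + stats::runif(1, 0, 2 * pi))
  pupil_gain <- rep(1, n)
  for (i in seq_along(blink_on)) {
    i0 <- blink_on[i] + 1
    i1 <- blink_off[i] + 1
    ramp <- min(20, floor((i1 - i0 + 1) / 2))
    g <- rep(0, i1 - i0 + 1)
    if (ramp > 0) {
      down <- (1 + cos(pi * seq_len(ramp) / ramp)) / 2
      g[seq_len(ramp)] <- down
      g[(length(g) - ramp + 1):length(g)] <- rev(down)
    }
    pupil_gain[i0:i1] <- pmin(pupil_gain[i0:i1], g)
  }
  psd <- 0.003 * params$pupil_baseline
  pupilL <- (params$pupil_baseline + slow + stats::rnorm(n, 0, psd)) * pupil_gain
  pupilR <- (params$pupil_baseline + slow + stats::rnorm(n, 0, psd)) * pupil_gain

  xL <- x + stats::rnorm(n, 0, params$noise_sd)
  yL <- y + stats::rnorm(n, 0, params$noise_sd)
  xR <- x + stats::rnorm(n, 0, params$noise_sd)
  yR <- y + stats::rnorm(n, 0, params$noise_sd)
  for (i in seq_along(blink_on)) {
    idx <- (blink_on[i]:blink_off[i]) + 1
    xL[idx] <- yL[idx] <- xR[idx] <- yR[idx] <- NA_real_
  }

  recording <- data.frame(time_ms = 0:(n - 1), xL_deg = xL, yL_deg = yL,
                          pupilL = pupilL, xR_deg = xR, yR_deg = yR,
                          pupilR = pupilR)
  attr(recording, "sampling_rate") <- fs
  class(recording) <- c("gaze_recording", "data.frame")

  truth <- list(saccade_onset_ms = on_ms,
                saccade_amplitude_deg = amp,
                saccade_peak_velocity_dps = pv,
                saccade_duration_ms = dur,
                blink_onset_ms = blink_on,
                blink_offset_ms = blink_off)
  list(recording = recording, truth = truth)
}
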