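#' Saccade detector parameters
#'
#' @param lambda_sd Velocity threshold in robust standard deviations.
#' @param min_duration_samples Minimum number of consecutive
#'   above-threshold samples.
#' @param isi_ms Minimum interval between a saccade offset and the next
#'   onset; later events violating it are discarded as overshoots.
#' @param velocity_window_samples Width (odd) of the moving-window velocity
#'   estimator.
#' @param threshold_mode `"component"` (default): threshold the norm of the
#'   component-wise median-standardized velocity at `lambda_sd` (the
#'   elliptic criterion of the classic velocity-threshold algorithm).
#'   `"norm"`: threshold the standardized-velocity norm at its median plus
#'   `lambda_sd` robust SDs of the norm. The norm mode is provided for
#'   comparison; because the median of the squared norm equals the squared
#'   median of the norm for Rayleigh-like velocity noise, its robust SD is
#'   near zero and the mode degenerates on typical fixation data (see the
#'   methods vignette).
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(lambda_sd = 6, min_duration_samples = 6,
                            isi_ms = 50, velocity_window_samples = 5,
                            threshold_mode = c("component", "norm")) {
  stopifnot(lambda_sd > 0, min_duration_samples > 0, isi_ms >= 0,
            velocity_window_samples >= 3,
            velocity_window_samples %% 2 == 1)
  p <- list(lambda_sd = lambda_sd,
            min_duration_samples = as.integer(min_duration_samples),
            isi_ms = isi_ms,
            velocity_window_samples = as.integer(velocity_window_samples),
            threshold_mode = match.arg(threshold_mode))
  class(p) <- "detector_params"
  p
}

#' Moving-window velocity estimate
#'
#' Centered moving-window finite difference: for window `2m + 1`,
#' `v_t = sum_\{j=1..m\}(x_\{t+j\} - x_\{t-j\}) / (m (m + 1) dt)`. For the
#' default 5-sample window this is the classic
#' `(x_\{t+2\} + x_\{t+1\} - x_\{t-1\} - x_\{t-2\}) / (6 dt)` estimator.
#' Near the edges the window shrinks symmetrically; the outermost samples
#' (width-1 window) get zero velocity.
#'
#' @param position Numeric matrix (n x 2) or vector of positions, deg.
#' @param sampling_rate Hz.
#' @param window Window width in samples (odd, >= 3).
#' @return Velocity in deg/s, same shape as `position`.
#' @export
compute_velocity <- function(position, sampling_rate = 1000, window = 5) {
  if (is.matrix(position)) {
    out <- position
    for (j in seq_len(ncol(position))) {
      out[, j] <- compute_velocity(position[, j], sampling_rate, window)
    }
    return(out)
  }
  n <- length(position)
  stopifnot(window %% 2 == 1, window >= 3)
  if (n <= window) stop("trace length (", n, ") must exceed window (", window, ")")
  m <- (window - 1) / 2
  dt <- 1 / sampling_rate
  v <- numeric(n)
  core <- (m + 1):(n - m)
  acc <- numeric(length(core))
  for (j in seq_len(m)) {
    acc <- acc + position[core + j] - position[core - j]
  }
  v[core] <- acc / (m * (m + 1) * dt)
  ## shrink window symmetrically at the edges
  for (mm in seq_len(m - 1)) {
    i <- mm + 1                       # left edge, window 2*mm+1
    v[i] <- sum(position[i + 1:mm] - position[i - 1:mm]) / (mm * (mm + 1) * dt)
    i <- n - mm
    v[i] <- sum(position[i + 1:mm] - position[i - 1:mm]) / (mm * (mm + 1) * dt)
  }
  v[c(1, n)] <- 0
  v
}

## median-based robust SD estimator: sqrt(median(v^2) - median(v)^2)
robust_sd <- function(v) {
  v <- v[is.finite(v)]
  sqrt(max(stats::median(v^2) - stats::median(v)^2, 0))
}

#' Detect saccades in one eye's trace
#'
#' Velocity components are standardized per segment using the median and
#' the median-based robust SD over valid samples; candidate samples exceed
#' the threshold (see [detector_params()] `threshold_mode`) and events are
#' runs of at least `min_duration_samples` consecutive candidates. Events
#' containing any invalid sample are discarded. Amplitude is the
#' straight-line displacement between onset and offset positions; peak
#' velocity is the maximum velocity norm within the event.
#'
#' @param position n x 2 matrix of positions, deg (one eye).
#' @param valid_mask Logical vector of valid samples.
#' @param params A [detector_params()].
#' @param time_ms Time axis (ms) for the trace; defaults to 0-based sample
#'   index.
#' @param sampling_rate Hz.
#' @return A data frame with columns `onset_ms`, `offset_ms`,
#'   `amplitude_deg`, `peak_velocity_dps`.
#' @export
detect_monocular <- function(position, valid_mask = NULL,
                             params = detector_params(),
                             time_ms = NULL, sampling_rate = 1000) {
  stopifnot(is.matrix(position), ncol(position) == 2)
  n <- nrow(position)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, n)
  if (is.null(time_ms)) time_ms <- 0:(n - 1)
  stopifnot(length(valid_mask) == n, length(time_ms) == n)
  valid_mask <- valid_mask & !is.na(position[, 1]) & !is.na(position[, 2])
  empty <- fast_df(list(onset_ms = numeric(0), offset_ms = numeric(0),
                        amplitude_deg = numeric(0),
                        peak_velocity_dps = numeric(0)))
  if (!any(valid_mask)) return(empty)

  vel <- compute_velocity(position, sampling_rate,
                          params$velocity_window_samples)
  vx <- vel[, 1]
  vy <- vel[, 2]
  vxv <- vx[valid_mask]
  vyv <- vy[valid_mask]
  vxv <- vxv[is.finite(vxv)]
  vyv <- vyv[is.finite(vyv)]
  mx <- stats::median(vxv)
  my <- stats::median(vyv)
  sx <- sqrt(max(stats::median(vxv^2) - mx^2, 0))
  sy <- sqrt(max(stats::median(vyv^2) - my^2, 0))
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) {
    warning("velocity variance is zero; threshold undefined, no detections")
    return(empty)
  }
  zx <- (vx - mx) / sx
  zy <- (vy - my) / sy
  zn2 <- zx^2 + zy^2
  thr2 <- if (params$threshold_mode == "component") {
    params$lambda_sd^2
  } else {
    zn <- sqrt(zn2[valid_mask])
    (stats::median(zn, na.rm = TRUE) + params$lambda_sd * robust_sd(zn))^2
  }
  cand <- zn2 > thr2
  cand[is.na(cand)] <- FALSE
  ev <- find_runs(cand, params$min_duration_samples)
  if (nrow(ev) == 0) return(empty)
  ## discard events overlapping invalid samples
  keep <- vapply(seq_len(nrow(ev)), function(i) {
    all(valid_mask[ev[i, 1]:ev[i, 2]])
  }, logical(1))
  ev <- ev[keep, , drop = FALSE]
  if (nrow(ev) == 0) return(empty)
  vnorm <- sqrt(vx^2 + vy^2)
  fast_df(list(
    onset_ms = time_ms[ev[, 1]],
    offset_ms = time_ms[ev[, 2]],
    amplitude_deg = sqrt(
      (position[ev[, 2], 1] - position[ev[, 1], 1])^2 +
        (position[ev[, 2], 2] - position[ev[, 1], 2])^2),
    peak_velocity_dps = vapply(seq_len(nrow(ev)), function(i) {
      max(vnorm[ev[i, 1]:ev[i, 2]])
    }, numeric(1))
  ))
}

#' Combine monocular detections into binocular saccades
#'
#' Left- and right-eye events with at least one sample of temporal overlap
#' are paired into one binocular event (onset = earlier onset, offset =
#' later offset, amplitude and peak velocity averaged across eyes);
#' monocular-only events are excluded. A minimum inter-saccade interval is
#' then enforced: an event whose onset falls within `isi_ms` of the
#' previous retained event's offset is discarded as an overshoot.
#'
#' @param left,right Event data frames from [detect_monocular()], sorted by
#'   onset.
#' @param params A [detector_params()].
#' @return A binocular event data frame (same columns).
#' @export
binocular_conjunction <- function(left, right, params = detector_params()) {
  on <- off <- amp <- pv <- numeric(0)
  i <- 1L
  j <- 1L
  while (i <= nrow(left) && j <= nrow(right)) {
    ov <- min(left$offset_ms[i], right$offset_ms[j]) -
      max(left$onset_ms[i], right$onset_ms[j])
    if (ov >= 0) {
      on <- c(on, min(left$onset_ms[i], right$onset_ms[j]))
      off <- c(off, max(left$offset_ms[i], right$offset_ms[j]))
      amp <- c(amp, (left$amplitude_deg[i] + right$amplitude_deg[j]) / 2)
      pv <- c(pv, (left$peak_velocity_dps[i] + right$peak_velocity_dps[j]) / 2)
      i <- i + 1L
      j <- j + 1L
    } else if (left$offset_ms[i] < right$onset_ms[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  out <- fast_df(list(onset_ms = on, offset_ms = off, amplitude_deg = amp,
                      peak_velocity_dps = pv))
  if (nrow(out) <= 1) return(out)
  out <- out[order(out$onset_ms), ]
  keep <- rep(TRUE, nrow(out))
  last_off <- -Inf
  for (k in seq_len(nrow(out))) {
    if (out$onset_ms[k] - last_off < params$isi_ms) {
      keep[k] <- FALSE
    } else {
      last_off <- out$offset_ms[k]
    }
  }
  out[keep, , drop = FALSE]
}

#' Main-sequence quality control
#'
#' Pearson correlation between saccade amplitude and peak velocity. A
#' lawful, tight main sequence (r > 0.9) indicates that detected events are
#' genuine saccades rather than noise.
#'
#' @param events Event data frame with `amplitude_deg` and
#'   `peak_velocity_dps`.
#' @return A list of class `main_sequence`: `r`, `n`, `computable`.
#' @export
main_sequence <- function(events) {
  n <- nrow(events)
  if (n < 3 || stats::var(events$amplitude_deg) == 0 ||
      stats::var(events$peak_velocity_dps) == 0) {
    return(structure(list(r = NA_real_, n = n, computable = FALSE),
                     class = "main_sequence"))
  }
  structure(list(r = stats::cor(events$amplitude_deg,
                                events$peak_velocity_dps),
                 n = n, computable = TRUE),
            class = "main_sequence")
}

#' @export
print.main_sequence <- function(x, ...) {
  if (x$computable) {
    cat(sprintf("Main sequence: r = %.3f over %d saccades\n", x$r, x$n))
  } else {
    cat("Main sequence: not computable (", x$n, "events )\n")
  }
  invisible(x)
}
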