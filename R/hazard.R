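#' Foreperiod distributions and hazard rates
#'
#' A foreperiod distribution is a discrete probability distribution over a
#' small set of possible cue-target intervals. The conditional probability
#' that the target occurs at time `t` given that it has not occurred earlier
#' (the hazard-rate function) is what a temporally orienting observer is
#' assumed to track.
#'
#' @param support Foreperiod durations in ms, strictly increasing.
#' @param probs Probability of each duration; must sum to 1.
#' @return An object of class `foreperiod_distribution`.
#' @examples
#' low <- foreperiod_distribution(seq(1000, 3000, by = 500), rep(0.2, 5))
#' hazard(low, 2000)  # 1/3
#' @export
foreperiod_distribution <- function(support, probs) {
  stopifnot(length(support) == length(probs), length(support) >= 1)
  if (any(probs < 0)) stop("probs must be nonnegative")
  if (abs(sum(probs) - 1) > 1e-12) stop("probs must sum to 1 (within 1e-12)")
  if (is.unsorted(support, strictly = TRUE)) {
    stop("support must be strictly increasing")
  }
  structure(list(support = as.numeric(support), probs = as.numeric(probs)),
            class = "foreperiod_distribution")
}

#' @export
print.foreperiod_distribution <- function(x, ...) {
  cat("Foreperiod distribution:\n")
  print(stats::setNames(x$probs, paste0(x$support, " ms")))
  invisible(x)
}

#' Block designs of the certainty/orienting paradigm
#'
#' The five block types used in the paradigm, as foreperiod distributions
#' over \{1000, 1500, 2000, 2500, 3000\} ms: two full-certainty designs
#' (a single foreperiod in 100% of trials), two high-certainty designs
#' (one foreperiod in 80% of trials and the other of 1/2 s in 20%), and a
#' low-certainty design (all five foreperiods equiprobable).
#'
#' @param block_type One of `"full_certainty_1s"`, `"full_certainty_2s"`,
#'   `"high_certainty_1s"`, `"high_certainty_2s"`, `"low_certainty"`.
#' @return A [foreperiod_distribution()].
#' @export
block_distribution <- function(block_type) {
  block_type <- match.arg(block_type, BLOCK_TYPES)
  switch(block_type,
    full_certainty_1s = foreperiod_distribution(1000, 1),
    full_certainty_2s = foreperiod_distribution(2000, 1),
    high_certainty_1s = foreperiod_distribution(c(1000, 2000), c(0.8, 0.2)),
    high_certainty_2s = foreperiod_distribution(c(1000, 2000), c(0.2, 0.8)),
    low_certainty = foreperiod_distribution(seq(1000, 3000, 500), rep(0.2, 5))
  )
}

BLOCK_TYPES <- c("full_certainty_1s", "full_certainty_2s",
                 "high_certainty_1s", "high_certainty_2s", "low_certainty")

CONDITIONS <- c("full_certainty", "high_certainty_frequent",
                "high_certainty_rare", "low_certainty")

#' Hazard rate of a foreperiod distribution
#'
#' `hazard(d, t)` is P(FP = t) / P(FP >= t): the probability that the target
#' occurs at `t` given that it has not occurred at any earlier possible time.
#' At the last support point of a proper distribution the hazard is 1.
#'
#' @param dist A [foreperiod_distribution()].
#' @param t A time in ms; must be one of the support points.
#' @return A probability in \[0, 1\], or `NaN` (with a warning) if no
#'   probability mass remains at or after `t`.
#' @export
hazard <- function(dist, t) {
  stopifnot(inherits(dist, "foreperiod_distribution"), length(t) == 1)
  i <- match(t, dist$support)
  if (is.na(i)) stop("t = ", t, " is not a support point of the distribution")
  surv <- sum(dist$probs[dist$support >= t])
  if (surv == 0) {
    warning("no probability mass at or beyond t = ", t, "; hazard undefined")
    return(NaN)
  }
  dist$probs[i] / surv
}

#' Hazard profile over all support points
#'
#' @inheritParams hazard
#' @return A data frame with columns `time_ms`, `prob`, `survival`, `hazard`.
#' @export
hazard_profile <- function(dist) {
  stopifnot(inherits(dist, "foreperiod_distribution"))
  surv <- rev(cumsum(rev(dist$probs)))
  data.frame(time_ms = dist$support, prob = dist$probs, survival = surv,
             hazard = ifelse(surv > 0, dist$probs / surv, NaN))
}

#' Anticipation function used by the generative inhibition law
#'
#' At elapsed time `t` since the cue, the anticipation is the conditional
#' probability that the target occurs within `window_ms` after `t`, given
#' that it has not occurred before `t`:
#' P(t <= FP <= t + window | FP >= t). At a possible target time `s` this
#' equals the hazard rate at `s`, and it converges to that hazard as `t`
#' approaches `s` from below. It drives the simulated pre-target inhibition
#' of saccades.
#'
#' @inheritParams hazard
#' @param t Vector of elapsed times since cue onset, ms.
#' @param window_ms Look-ahead window, ms.
#' @return Vector of probabilities in \[0, 1\] (0 where no mass remains).
#' @export
anticipation <- function(dist, t, window_ms = 300) {
  stopifnot(inherits(dist, "foreperiod_distribution"), window_ms >= 0)
  sup <- dist$support
  p <- dist$probs
  vapply(t, function(tt) {
    surv <- sum(p[sup >= tt])
    if (surv <= 0) return(0)
    sum(p[sup >= tt & sup <= tt + window_ms]) / surv
  }, numeric(1))
}
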