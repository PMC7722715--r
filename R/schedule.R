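#' Build a counterbalanced trial schedule for one block
#'
#' Foreperiod counts are exact multinomial fractions of the block design
#' (counterbalanced, not sampled): e.g. an 80-trial high-certainty-1s block
#' contains exactly 64 trials of 1000 ms and 16 of 2000 ms. Trial order is
#' shuffled and inter-trial intervals are drawn uniformly from
#' \[700, 1200\] ms. Cue and target onsets are laid out on a continuous
#' block timeline: the first cue occurs after an initial 300 ms margin plus
#' one ITI, and each later cue follows the previous target by 300 ms (the
#' post-target segment margin) plus one ITI.
#'
#' @param block_type One of the five block designs; see [block_distribution()].
#' @param n_trials Number of trials; must be divisible by the smallest
#'   denominator of the design's probabilities (5 for high- and low-certainty
#'   blocks).
#' @param seed Integer seed; all randomness in the schedule flows from it.
#' @return A data frame of class `trial_schedule` with columns `trial_id`,
#'   `block_type`, `foreperiod_ms`, `cue_onset_ms`, `target_onset_ms`,
#'   `iti_ms`.
#' @examples
#' sched <- build_schedule("high_certainty_1s", 80, seed = 1)
#' table(sched$foreperiod_ms)  # 64 x 1000, 16 x 2000
#' @export
build_schedule <- function(block_type, n_trials, seed) {
  block_type <- match.arg(block_type, BLOCK_TYPES)
  stopifnot(n_trials >= 1)
  dist <- block_distribution(block_type)
  counts <- dist$probs * n_trials
  if (any(abs(counts - round(counts)) > 1e-9)) {
    div <- min_divisor(dist$probs)
    stop("n_trials = ", n_trials, " is not divisible by ", div,
         ", required for exact foreperiod counts in block '", block_type, "'")
  }
  counts <- round(counts)
  fps <- rep(dist$support, counts)
  rng <- local_seed(seed)
  on.exit(rng(), add = TRUE)
  fps <- sample(fps, length(fps))
  iti <- stats::runif(n_trials, 700, 1200)
  ## continuous block timeline with 300 ms segment margins on both sides
  cue <- numeric(n_trials)
  t0 <- 300
  for (i in seq_len(n_trials)) {
    cue[i] <- t0 + iti[i]
    t0 <- cue[i] + fps[i] + 300
  }
  out <- data.frame(trial_id = seq_len(n_trials), block_type = block_type,
                    foreperiod_ms = fps, cue_onset_ms = cue,
                    target_onset_ms = cue + fps, iti_ms = iti)
  class(out) <- c("trial_schedule", "data.frame")
  out
}

## smallest n such that n * probs are all integers (probs are simple fractions)
min_divisor <- function(probs) {
  for (n in 1:100) if (all(abs(probs * n - round(probs * n)) < 1e-9)) return(n)
  stop("design probabilities are not simple fractions")
}

## Save/restore the caller's RNG state around a seeded computation, so that
## seeded generators do not disturb the global random stream.
local_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

## Derive a bounded child seed from a base seed and a stage counter;
## keeps every derived seed inside the 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483629
  for (k in idx) h <- (h * 48271 + as.double(k) * 8191 + 1) %% 2147483629
  as.integer(h)
}
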