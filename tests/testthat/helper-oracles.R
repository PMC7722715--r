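## Independent oracles used by the test suite. Everything here is written
## from first principles (loops, closed forms, naive scans) and must stay
## independent of the package's implementation paths.

## ---- within-subject ANOVA: brute-force sums of squares -------------------

orth_contrasts <- function(k) qr.Q(qr(stats::contr.helmert(k)))

## two-way within-subject ANOVA on Y (n x (a*b), factor A varying slowest)
oracle_rm_anova2 <- function(Y, a, b) {
  n <- nrow(Y)
  M <- mean(Y)
  Ai <- sapply(1:a, function(i) mean(Y[, ((i - 1) * b + 1):(i * b)]))
  Bj <- sapply(1:b, function(j) mean(Y[, seq(j, a * b, b)]))
  ABij <- matrix(colMeans(Y), a, b, byrow = TRUE)
  Ss <- rowMeans(Y)
  SA <- sapply(1:a, function(i) rowMeans(Y[, ((i - 1) * b + 1):(i * b), drop = FALSE]))
  SB <- sapply(1:b, function(j) rowMeans(Y[, seq(j, a * b, b), drop = FALSE]))
  SS_A <- n * b * sum((Ai - M)^2)
  SS_AS <- b * sum((SA - outer(Ss, rep(1, a)) - outer(rep(1, n), Ai) + M)^2)
  SS_B <- n * a * sum((Bj - M)^2)
  SS_BS <- a * sum((SB - outer(Ss, rep(1, b)) - outer(rep(1, n), Bj) + M)^2)
  SS_AB <- n * sum((ABij - outer(Ai, rep(1, b)) - outer(rep(1, a), Bj) + M)^2)
  resid <- Y
  for (s in 1:n) for (i in 1:a) for (j in 1:b) {
    cc <- (i - 1) * b + j
    resid[s, cc] <- Y[s, cc] - SA[s, i] - SB[s, j] - ABij[i, j] +
      Ai[i] + Bj[j] + Ss[s] - M
  }
  SS_ABS <- sum(resid^2)
  Ca <- orth_contrasts(a)
  Cb <- orth_contrasts(b)
  UAB <- t(sapply(1:n, function(s) {
    Ys <- matrix(Y[s, ], a, b, byrow = TRUE)
    as.vector(t(Ca) %*% Ys %*% Cb)
  }))
  list(A = oracle_effect(SS_A, a - 1, SS_AS, (a - 1) * (n - 1), SA %*% Ca, n),
       B = oracle_effect(SS_B, b - 1, SS_BS, (b - 1) * (n - 1), SB %*% Cb, n),
       AB = oracle_effect(SS_AB, (a - 1) * (b - 1), SS_ABS,
                          (a - 1) * (b - 1) * (n - 1), UAB, n))
}

## one-way within-subject ANOVA on Y (n x k)
oracle_rm_anova1 <- function(Y) {
  n <- nrow(Y)
  k <- ncol(Y)
  M <- mean(Y)
  Ai <- colMeans(Y)
  Ss <- rowMeans(Y)
  SS_A <- n * sum((Ai - M)^2)
  SS_AS <- sum((Y - outer(Ss, rep(1, k)) - outer(rep(1, n), Ai) + M)^2)
  oracle_effect(SS_A, k - 1, SS_AS, (k - 1) * (n - 1),
                Y %*% orth_contrasts(k), n)
}

oracle_effect <- function(ss, df1, sse, df2, U, n) {
  Fv <- if (ss == 0) 0 else (ss / df1) / (sse / df2)
  d <- ncol(U)
  out <- list(F = Fv, df1 = df1, df2 = df2,
              p = if (ss == 0) 1 else stats::pf(Fv, df1, df2, lower.tail = FALSE),
              pes = if (ss + sse > 0) ss / (ss + sse) else 0)
  if (d >= 2) {
    S <- stats::cov(U)
    eps <- sum(diag(S))^2 / (d * sum(S * S))
    W <- det(S) / (sum(diag(S)) / d)^d
    hf <- (n * d * eps - 2) / (d * (n - 1 - d * eps))
    out$eps <- eps
    out$W <- W
    out$p_gg <- stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
    out$p_hf <- stats::pf(Fv, df1 * min(hf, 1), df2 * min(hf, 1),
                          lower.tail = FALSE)
    nd <- n - 1
    rho <- 1 - (2 * d^2 + d + 2) / (6 * d * nd)
    w2 <- (d + 2) * (d - 1) * (d - 2) * (2 * d^3 + 6 * d^2 + 3 * d + 2) /
      (288 * d^2 * nd^2 * rho^2)
    z <- -nd * rho * log(W)
    f <- d * (d + 1) / 2 - 1
    out$mauchly_p <- stats::pchisq(z, f, lower.tail = FALSE) +
      w2 * (stats::pchisq(z, f + 4, lower.tail = FALSE) -
              stats::pchisq(z, f, lower.tail = FALSE))
  } else {
    out$eps <- 1
  }
  out
}

## long-format pre-target SR table from a subject x cell matrix
sr_table_from_matrix <- function(Y, conditions, fps) {
  n <- nrow(Y)
  grid <- expand.grid(foreperiod_ms = fps, condition = conditions,
                      stringsAsFactors = FALSE)[, 2:1]
  out <- do.call(rbind, lapply(1:n, function(s) {
    data.frame(subject_id = s, condition = grid$condition,
               foreperiod_ms = grid$foreperiod_ms, mean_sr = Y[s, ])
  }))
  class(out) <- c("pretarget_sr_table", "data.frame")
  out
}

## ---- JZS Bayes factor: noncentral-t mixture quadrature -------------------

## BF10 = integral dt(t; nu, delta*sqrt(n)) dCauchy(delta; 0, r) / dt(t; nu)
## -- a different derivation route than the package's g-integral.
oracle_bf01 <- function(t, n, r = sqrt(2) / 2) {
  nu <- n - 1
  num <- suppressWarnings(stats::integrate(function(delta) {
    stats::dt(t, nu, ncp = delta * sqrt(n)) * stats::dcauchy(delta, 0, r)
  }, -Inf, Inf, rel.tol = 1e-11, subdivisions = 1000L))$value
  den <- stats::dt(t, nu)
  den / num
}

## ---- saccade detector: naive window-scan oracle --------------------------

oracle_velocity <- function(x, fs = 1000, window = 5) {
  n <- length(x)
  m <- (window - 1) / 2
  v <- numeric(n)
  for (i in seq_len(n)) {
    mm <- min(m, i - 1, n - i)         # symmetric shrink at edges
    if (mm >= 1) {
      s <- 0
      for (j in 1:mm) s <- s + x[i + j] - x[i - j]
      v[i] <- s / (mm * (mm + 1) * (1 / fs))
    }
  }
  v
}

oracle_detect <- function(position, valid, params = detector_params(),
                          fs = 1000) {
  n <- nrow(position)
  valid <- valid & !is.na(position[, 1]) & !is.na(position[, 2])
  vx <- oracle_velocity(position[, 1], fs, params$velocity_window_samples)
  vy <- oracle_velocity(position[, 2], fs, params$velocity_window_samples)
  med_rsd <- function(v) {
    v <- v[is.finite(v)]
    c(stats::median(v), sqrt(max(stats::median(v^2) - stats::median(v)^2, 0)))
  }
  mx <- med_rsd(vx[valid])
  my <- med_rsd(vy[valid])
  if (mx[2] == 0 || my[2] == 0) return(cbind(onset = numeric(0), offset = numeric(0)))
  zn <- sqrt(((vx - mx[1]) / mx[2])^2 + ((vy - my[1]) / my[2])^2)
  zn[is.na(zn)] <- 0
  L <- params$min_duration_samples
  thr <- if (params$threshold_mode == "component") params$lambda_sd else {
    znv <- zn[valid]
    stats::median(znv) + params$lambda_sd *
      sqrt(max(stats::median(znv^2) - stats::median(znv)^2, 0))
  }
  cand <- zn > thr
  marked <- rep(FALSE, n)
  for (i in seq_len(n - L + 1)) {       # test every window of length L
    if (all(cand[i:(i + L - 1)])) marked[i:(i + L - 1)] <- TRUE
  }
  on <- off <- integer(0)
  i <- 1
  while (i <= n) {
    if (marked[i]) {
      j <- i
      while (j < n && marked[j + 1]) j <- j + 1
      if (all(valid[i:j])) {
        on <- c(on, i)
        off <- c(off, j)
      }
      i <- j + 1
    } else i <- i + 1
  }
  cbind(onset = on, offset = off)
}

## ---- simple event matching by interval overlap ---------------------------

intervals_overlap <- function(a_on, a_off, b_on, b_off) {
  vapply(seq_along(a_on), function(i) {
    any(b_on <= a_off[i] & b_off >= a_on[i])
  }, logical(1))
}

## ---- synthetic null SR tables (stats layer, no gaze simulation) ----------

## cell trial counts of a full 80-trial-per-block session
CELL_TRIALS <- c(full_certainty = 80, high_certainty_frequent = 320,
                 high_certainty_rare = 80, low_certainty = 80)

simulate_null_sr_table <- function(n_subjects = 20, base_rate = 1.8,
                                   subject_sdlog = 0.15, window_s = 0.101) {
  conds <- names(CELL_TRIALS)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    subj_rate <- base_rate * exp(stats::rnorm(1, 0, subject_sdlog))
    for (cond in conds) for (fp in c(1000, 2000)) {
      ntr <- CELL_TRIALS[[cond]]
      lambda <- subj_rate * window_s * ntr
      sr <- stats::rpois(1, lambda) / (window_s * ntr)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = s, condition = cond, foreperiod_ms = fp, mean_sr = sr)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pretarget_sr_table", "data.frame")
  out
}

## minimal hand-built processed-trial object for the rates layer
make_trial <- function(fp = 1000, valid = NULL, onsets = numeric(0),
                       block_type = "full_certainty_1s", id = 1L) {
  tt <- -300:(fp + 300)
  if (is.null(valid)) valid <- rep(TRUE, length(tt))
  seg <- list(trial_id = id, block_type = block_type, foreperiod_ms = fp,
              time_rel_ms = tt, cue_index = 301L,
              target_index = 301L + fp)
  class(seg) <- "trial_segment"
  ev <- data.frame(onset_ms = onsets, offset_ms = onsets + 10,
                   amplitude_deg = rep(0.3, length(onsets)),
                   peak_velocity_dps = rep(20, length(onsets)))
  list(segment = seg, valid = valid, events = ev,
       blinks = data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                           source = character(0)))
}
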