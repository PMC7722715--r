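test_that("two-way RM-ANOVA matches the brute-force SS decomposition", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 6
    Y <- matrix(rnorm(n * 8, mean = 2, sd = 0.8), n)   # 4 x 2 cells
    tab <- sr_table_from_matrix(Y, letters[1:4], c(1000, 2000))
    res <- rm_anova(tab)
    o <- oracle_rm_anova2(Y, 4, 2)
    for (pair in list(c("a", "A"), c("foreperiod_ms", "B"),
                      c("a:foreperiod_ms", "AB"))) {
      row <- res[grepl(if (pair[2] == "A") "^condition$"
                       else if (pair[2] == "B") "^foreperiod_ms$"
                       else "condition:foreperiod_ms", res$effect), ]
      oe <- o[[pair[2]]]
      expect_equal(row$F, oe$F, tolerance = 1e-8)
      expect_equal(row$df1, oe$df1)
      expect_equal(row$df2, oe$df2)
      expect_equal(row$p, oe$p, tolerance = 1e-8)
      expect_equal(row$pes, oe$pes, tolerance = 1e-8)
      expect_equal(row$epsilon, oe$eps, tolerance = 1e-8)
      if (!is.null(oe$W)) {
        expect_equal(row$mauchly_w, oe$W, tolerance = 1e-8)
        expect_equal(row$mauchly_p, oe$mauchly_p, tolerance = 2e-2)
        expected_pc <- if (oe$mauchly_p >= 0.05) oe$p
                       else if (oe$eps < 0.7) oe$p_gg else oe$p_hf
        expect_equal(row$p_corrected, expected_pc, tolerance = 1e-6)
      }
    }
  }
})

test_that("one-way RM-ANOVA over five levels matches the oracle", {
  set.seed(5)
  Y <- matrix(rnorm(8 * 5, 1.5, 0.5), 8)
  tab <- sr_table_from_matrix(Y, "low_certainty", seq(1000, 3000, 500))
  res <- rm_anova(tab, factors = "foreperiod_ms")
  o <- oracle_rm_anova1(Y)
  expect_equal(res$F, o$F, tolerance = 1e-8)
  expect_equal(res$p, o$p, tolerance = 1e-8)
  expect_equal(res$epsilon, o$eps, tolerance = 1e-8)
  expect_equal(res$mauchly_w, o$W, tolerance = 1e-8)
})

test_that("degenerate and two-level designs are handled", {
  ## no within-subject variation at all: F defined as 0
  Y0 <- matrix(rep(1:6, 8), 6)
  res0 <- rm_anova(sr_table_from_matrix(Y0, letters[1:4], c(1000, 2000)))
  expect_true(all(res0$F == 0))
  expect_true(all(res0$p == 1))
  ## two-level factor: sphericity vacuous, epsilon 1, no correction
  set.seed(6)
  Y2 <- matrix(rnorm(10 * 2), 10)
  res2 <- rm_anova(sr_table_from_matrix(Y2, "full_certainty", c(1000, 2000)),
                   factors = "foreperiod_ms")
  expect_equal(res2$epsilon, 1)
  expect_equal(res2$correction, "none")
  expect_equal(res2$p_corrected, res2$p)
})

test_that("incomplete tables are rejected naming the offending cell", {
  set.seed(7)
  Y <- matrix(rnorm(12), 3)
  tab <- sr_table_from_matrix(Y, c("a", "b"), c(1000, 2000))
  expect_error(rm_anova(tab[-5, ]), "not a complete balanced")
})

test_that("paired contrasts have the closed-form t and exact BH adjustment", {
  set.seed(8)
  n <- 12
  Y <- matrix(rnorm(n * 8, 1.5, 0.4), n)
  Y[, 7] <- Y[, 7] + 0.5          # low_certainty fp1000 shifted
  tab <- sr_table_from_matrix(
    Y, c("full_certainty", "high_certainty_frequent", "high_certainty_rare",
         "low_certainty"), c(1000, 2000))
  res <- planned_contrasts(tab)
  ## closed form for full_vs_low_1s
  a <- Y[, 1]
  b <- Y[, 7]
  d <- a - b
  expect_equal(res$t[res$label == "full_vs_low_1s"],
               mean(d) * sqrt(n) / sd(d), tolerance = 1e-12)
  expect_equal(res$estimate[res$label == "full_vs_low_1s"], mean(d))
  expect_equal(res$dz[res$label == "full_vs_low_1s"], mean(d) / sd(d))
  ## combined high-certainty cell is the within-subject average
  hc <- (Y[, 4] + Y[, 6]) / 2
  d2 <- Y[, 2] - hc
  expect_equal(res$t[res$label == "full_vs_high_combined_2s"],
               mean(d2) * sqrt(n) / sd(d2), tolerance = 1e-12)
  ## BH step-up within each foreperiod family (oracle formula)
  for (fp in c(1000, 2000)) {
    sel <- res$foreperiod_ms == fp
    p <- res$p_raw[sel]
    m <- length(p)
    o <- order(p)
    bh <- rev(cummin(rev(p[o] * m / seq_len(m))))
    bh <- pmin(bh, 1)[order(o)]
    expect_equal(res$p_fdr[sel], bh, tolerance = 1e-12)
    expect_true(all(res$p_fdr[sel] >= res$p_raw[sel] - 1e-15))
  }
})

test_that("BH adjustment reproduces the canonical step-up example", {
  ## raw p {0.01, 0.02, 0.03} in one family -> all adjusted to 0.03
  set.seed(9)
  tmpl <- planned_contrast_set()[1:3, ]
  tmpl$fam <- "one"
  ## build data whose three 1s-contrasts produce increasing p-values, then
  ## verify the BH identity on whatever p-values arise
  Y <- matrix(rnorm(10 * 8, 2, 0.5), 10)
  tab <- sr_table_from_matrix(
    Y, c("full_certainty", "high_certainty_frequent", "high_certainty_rare",
         "low_certainty"), c(1000, 2000))
  res <- planned_contrasts(tab, contrasts = tmpl, family = "fam")
  p <- res$p_raw
  expect_equal(res$p_fdr, stats::setNames(
    rev(cummin(rev(sort(p) * 3 / 1:3)))[rank(p)], NULL), tolerance = 1e-12)
  ## and the arithmetic of the canonical example itself
  expect_equal(max(0.01 * 3 / 1, 0.02 * 3 / 2, 0.03 * 3 / 3), 0.03)
})

test_that("identical cells give t = 0; zero-variance nonzero shifts are flagged", {
  Y <- matrix(rnorm(6 * 8), 6)
  Y[, 7] <- Y[, 1]                 # low(1s) identical to full(1s)
  tab <- sr_table_from_matrix(
    Y, c("full_certainty", "high_certainty_frequent", "high_certainty_rare",
         "low_certainty"), c(1000, 2000))
  res <- planned_contrasts(tab)
  r1 <- res[res$label == "full_vs_low_1s", ]
  expect_equal(r1$t, 0)
  expect_equal(r1$dz, 0)
  ## constant nonzero difference: dz undefined
  Y2 <- Y
  Y2[, 7] <- Y2[, 1] + 1
  tab2 <- sr_table_from_matrix(
    Y2, c("full_certainty", "high_certainty_frequent", "high_certainty_rare",
          "low_certainty"), c(1000, 2000))
  res2 <- planned_contrasts(tab2)
  r2 <- res2[res2$label == "full_vs_low_1s", ]
  expect_true(is.infinite(r2$t))
  expect_true(is.na(r2$dz))
})

test_that("JZS Bayes factors match an independent noncentral-t quadrature", {
  for (case in list(c(0, 20), c(1.5, 20), c(2.5, 12), c(10, 20), c(-3, 8))) {
    t <- case[1]
    n <- case[2]
    bf <- bf01_ttest(t, n)
    expect_equal(bf$bf01, oracle_bf01(t, n), tolerance = 1e-3,
                 label = sprintf("t=%g n=%g", t, n))
    expect_equal(bf$bf01 * bf$bf10, 1, tolerance = 1e-12)
  }
  expect_gt(bf01_ttest(0, 20)$bf01, 1)
  expect_lt(bf01_ttest(10, 20)$bf01, 0.01)
  ## continuous and strictly decreasing in |t|
  ts <- seq(0, 6, by = 0.25)
  bfs <- vapply(ts, function(t) bf01_ttest(t, 20)$bf01, numeric(1))
  expect_true(all(diff(bfs) < 0))
  expect_lt(max(abs(diff(log(bfs)))), 1.5)         # no jumps
  expect_error(bf01_ttest(Inf, 20), "finite")
})

test_that("within-subject SEM removes between-subject offsets", {
  set.seed(10)
  n <- 10
  base <- matrix(rnorm(n * 4, 0, 0.3), n)          # condition effects
  tabA <- sr_table_from_matrix(base, c("a", "b"), c(1000, 2000))
  offs <- base + rnorm(n, 0, 5)                    # huge per-subject offsets
  tabB <- sr_table_from_matrix(offs, c("a", "b"), c(1000, 2000))
  sA <- within_subject_sem(tabA)
  sB <- within_subject_sem(tabB)
  expect_equal(sA$sem, sB$sem, tolerance = 1e-12)
  ## all-identical data: zero SEM
  tab0 <- sr_table_from_matrix(matrix(2, n, 4), c("a", "b"), c(1000, 2000))
  expect_true(all(within_subject_sem(tab0)$sem == 0))
  ## M = 2 cells: bias-correction factor sqrt(2)
  Y2 <- matrix(rnorm(n * 2), n)
  tab2 <- sr_table_from_matrix(Y2, "a", c(1000, 2000))
  s2 <- within_subject_sem(tab2, cells = "foreperiod_ms")
  centered <- Y2 - rowMeans(Y2) + mean(Y2)
  manual <- apply(centered, 2, sd) / sqrt(n) * sqrt(2)
  expect_equal(s2$sem, unname(manual), tolerance = 1e-12)
  expect_error(within_subject_sem(tab2[tab2$subject_id == 1, ]),
               "two subjects")
})

test_that("the foreperiod trend is negative when rates fall with foreperiod", {
  set.seed(11)
  n <- 10
  fps <- seq(1000, 3000, 500)
  Y <- t(replicate(n, 2 - 0.3 * (1:5) + rnorm(5, 0, 0.05)))
  tab <- sr_table_from_matrix(Y, "low_certainty", fps)
  tr <- foreperiod_trend(tab)
  expect_lt(tr$slope, 0)
  expect_lt(tr$t, 0)
  expect_lt(tr$p, 0.05)
  expect_equal(tr$df, n - 1)
  ## flat data: zero trend statistic
  tab0 <- sr_table_from_matrix(matrix(1.5, n, 5), "low_certainty", fps)
  tr0 <- foreperiod_trend(tab0)
  expect_equal(tr0$slope, 0)
  expect_equal(tr0$t, 0)
  expect_error(foreperiod_trend(tab[tab$foreperiod_ms > 1000, ]),
               "five")
})

test_that("the hazard-driven inhibition law yields a recoverable negative trend", {
  ## stats-layer recovery: low-certainty cell means generated from the
  ## orienting law (anticipation at each foreperiod) plus Poisson trial
  ## noise at session-size trial counts, 100 seeded replicates
  low <- block_distribution("low_certainty")
  p <- sim_params()
  gen_rate <- vapply(seq(1000, 3000, 500), function(fp) {
    a <- mean(anticipation(low, (fp - 100):fp, p$inhibition_window_ms))
    p$base_saccade_rate * (1 - p$inhibition_depth * a)
  }, numeric(1))
  expect_true(all(diff(gen_rate) < 0))             # law implies the trend
  n_sub <- 20
  ntr <- 80
  hits <- 0
  set.seed(12)
  for (r in 1:100) {
    Y <- t(replicate(n_sub, rpois(5, gen_rate * 0.101 * ntr) / (0.101 * ntr)))
    tr <- foreperiod_trend(
      sr_table_from_matrix(Y, "low_certainty", seq(1000, 3000, 500)))
    if (tr$slope < 0 && tr$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 95)
})
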