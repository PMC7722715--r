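#' Repeated-measures ANOVA with sphericity handling
#'
#' Within-subject ANOVA on a complete balanced subject x cell table.
#' Sphericity of each multi-level effect is tested with Mauchly's test;
#' when violated (p < 0.05) the corrected p-value is reported, with the
#' correction chosen by the Greenhouse--Geisser epsilon: Greenhouse--Geisser
#' when epsilon < 0.7, Huynh--Feldt otherwise. Partial eta squared is
#' reported with a confidence interval from non-central-F inversion.
#'
#' @param table Data frame in long format.
#' @param dv,subject Column names of the dependent variable and the subject
#'   identifier.
#' @param factors Character vector of one or two within-subject factor
#'   column names.
#' @param conf Confidence level for the partial eta squared interval.
#' @return An object of class `rm_anova` (data frame): one row per effect
#'   with `effect`, `df1`, `df2`, `F`, `p`, `mauchly_w`, `mauchly_p`,
#'   `epsilon` (Greenhouse--Geisser), `correction` applied, `p_corrected`,
#'   `pes` (partial eta squared), `pes_lo`, `pes_hi`.
#' @export
rm_anova <- function(table, dv = "mean_sr", subject = "subject_id",
                     factors = c("condition", "foreperiod_ms"),
                     conf = 0.95) {
  stopifnot(length(factors) %in% 1:2)
  for (f in factors) table[[f]] <- factor(table[[f]])
  table[[subject]] <- factor(table[[subject]])
  check_complete(table, dv, subject, factors)

  levs <- lapply(factors, function(f) levels(table[[f]]))
  names(levs) <- factors
  idata <- rev(expand.grid(rev(levs)))      # first factor varies slowest
  subs <- levels(table[[subject]])
  Y <- matrix(NA_real_, length(subs), nrow(idata))
  key_tab <- interaction(table[factors], drop = FALSE, lex.order = TRUE)
  key_cells <- interaction(idata, drop = FALSE, lex.order = TRUE)
  for (s in seq_along(subs)) {
    rows <- table[[subject]] == subs[s]
    Y[s, ] <- table[[dv]][rows][match(key_cells, key_tab[rows])]
  }
  idesign <- stats::as.formula(paste("~", paste(factors, collapse = "*")))
  fit <- stats::lm(Y ~ 1)
  av <- car::Anova(fit, idata = idata, idesign = idesign, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  uni <- s$univariate.tests
  sph <- s$sphericity.tests
  adj <- s$pval.adjustments

  effects <- setdiff(rownames(uni), "(Intercept)")
  out <- do.call(rbind, lapply(effects, function(e) {
    ss <- uni[e, "Sum Sq"]
    ess <- uni[e, "Error SS"]
    df1 <- uni[e, "num Df"]
    df2 <- uni[e, "den Df"]
    Fv <- uni[e, "F value"]
    p <- uni[e, "Pr(>F)"]
    if (!is.finite(Fv)) {                 # 0/0: no effect, no error
      Fv <- 0
      p <- 1
    }
    mw <- mp <- NA_real_
    eps <- 1
    corr <- "none"
    pc <- p
    if (!is.null(sph) && e %in% rownames(sph)) {
      mw <- sph[e, 1]
      mp <- sph[e, 2]
      eps <- adj[e, "GG eps"]
      if (is.finite(mp) && mp < 0.05) {
        if (eps < 0.7) {
          corr <- "greenhouse_geisser"
          pc <- adj[e, "Pr(>F[GG])"]
        } else {
          corr <- "huynh_feldt"
          pc <- adj[e, "Pr(>F[HF])"]
        }
      }
    }
    pes <- if (ss + ess > 0) ss / (ss + ess) else 0
    ci <- pes_ci(Fv, df1, df2, conf)
    data.frame(effect = e, df1 = df1, df2 = df2, F = Fv, p = p,
               mauchly_w = mw, mauchly_p = mp, epsilon = eps,
               correction = corr, p_corrected = pc,
               pes = pes, pes_lo = ci[1], pes_hi = ci[2])
  }))
  rownames(out) <- NULL
  class(out) <- c("rm_anova", "data.frame")
  out
}

check_complete <- function(table, dv, subject, factors) {
  counts <- table(table[c(subject, factors)])
  if (any(counts != 1)) {
    bad <- which(counts != 1, arr.ind = TRUE)[1, ]
    stop("table is not a complete balanced subject x cell design; first ",
         "offending cell: ", paste(names(bad), "=",
         mapply(function(d, i) dimnames(counts)[[d]][i],
                seq_along(bad), bad), collapse = ", "))
  }
  if (any(!is.finite(table[[dv]]))) stop("non-finite values in '", dv, "'")
  invisible(TRUE)
}

#' Confidence interval for partial eta squared
#'
#' Non-central-F inversion: the confidence bounds on the non-centrality
#' parameter are mapped to partial eta squared via
#' `lambda / (lambda + df1 + df2 + 1)`.
#'
#' @param F,df1,df2 Observed F statistic and degrees of freedom.
#' @param conf Confidence level.
#' @return Numeric `c(lo, hi)`.
#' @export
pes_ci <- function(F, df1, df2, conf = 0.95) {
  a <- (1 - conf) / 2
  pf_q <- function(q, ncp) suppressWarnings(stats::pf(q, df1, df2, ncp = ncp))
  lam <- function(target) {
    if (pf_q(F, 0) < target) return(0)
    up <- 10
    while (pf_q(F, up) > target && up < 1e6) up <- up * 2
    stats::uniroot(function(l) pf_q(F, l) - target, c(0, up), tol = 1e-9)$root
  }
  lo <- lam(1 - a)
  hi <- lam(a)
  c(lo, hi) / (c(lo, hi) + df1 + df2 + 1)
}

#' Confidence interval for Cohen's dz
#'
#' Non-central-t inversion of the paired t statistic; bounds on the
#' non-centrality parameter divided by sqrt(n).
#'
#' @param t Paired t statistic.
#' @param n Number of subjects (pairs).
#' @param conf Confidence level.
#' @return Numeric `c(lo, hi)`.
#' @export
dz_ci <- function(t, n, conf = 0.95) {
  a <- (1 - conf) / 2
  df <- n - 1
  ncp_for <- function(target) {
    f <- function(d) suppressWarnings(stats::pt(t, df, ncp = d)) - target
    lo <- t - 10 - 10 * abs(t)
    hi <- t + 10 + 10 * abs(t)
    stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
  }
  c(ncp_for(1 - a), ncp_for(a)) / sqrt(n)
}

#' Planned contrasts on subject-level cell means
#'
#' Each contrast is a paired t-test across subjects between two cells of
#' the pre-target saccade-rate table (a combined cell is the within-subject
#' average of its member cells). p-values are Benjamini--Hochberg adjusted
#' within each contrast family (one family per foreperiod). Cohen's dz =
#' mean(diff)/SD(diff) with a non-central-t confidence interval, and the
#' JZS Bayes factor BF01 are reported for every contrast.
#'
#' @param table A `pretarget_sr_table` (subject x condition x foreperiod).
#' @param contrasts Contrast definitions; see [planned_contrast_set()].
#' @param conf Confidence level for the dz interval.
#' @param family Column of `contrasts` defining the FDR families
#'   (default `"foreperiod_ms"`); use a constant column to adjust across
#'   all contrasts as one family.
#' @return A data frame of class `contrast_results`: `label`,
#'   `foreperiod_ms`, `estimate` (mean difference a - b), `t`, `df`,
#'   `p_raw`, `p_fdr`, `dz`, `dz_lo`, `dz_hi`, `bf01`, `bf01_error_pct`.
#' @export
planned_contrasts <- function(table, contrasts = planned_contrast_set(),
                              conf = 0.95, family = "foreperiod_ms") {
  subs <- sort(unique(table$subject_id))
  cell <- function(cond, fp) {
    if (cond == "high_combined") {
      return((cell("high_certainty_frequent", fp) +
                cell("high_certainty_rare", fp)) / 2)
    }
    v <- table$mean_sr[match(
      paste(subs, cond, fp),
      paste(table$subject_id, table$condition, table$foreperiod_ms))]
    if (any(is.na(v))) {
      stop("missing cell '", cond, "' at foreperiod ", fp,
           " for some subject")
    }
    v
  }
  n <- length(subs)
  rows <- lapply(seq_len(nrow(contrasts)), function(i) {
    a <- cell(contrasts$a[i], contrasts$foreperiod_ms[i])
    b <- cell(contrasts$b[i], contrasts$foreperiod_ms[i])
    d <- a - b
    sdd <- stats::sd(d)
    if (sdd == 0) {
      est <- mean(d)
      tt <- if (est == 0) 0 else sign(est) * Inf
      p <- if (est == 0) 1 else 0
      dz <- if (est == 0) 0 else NA_real_   # dz undefined for sd 0, mean != 0
      dzci <- c(NA_real_, NA_real_)
    } else {
      ht <- stats::t.test(a, b, paired = TRUE)
      tt <- unname(ht$statistic)
      p <- ht$p.value
      est <- unname(ht$estimate)
      dz <- mean(d) / sdd
      dzci <- dz_ci(tt, n, conf)
    }
    bf <- if (is.finite(tt)) bf01_ttest(tt, n) else list(bf01 = 0, error_pct = 0)
    data.frame(label = contrasts$label[i],
               foreperiod_ms = contrasts$foreperiod_ms[i],
               estimate = est, t = tt, df = n - 1, p_raw = p,
               dz = dz, dz_lo = dzci[1], dz_hi = dzci[2],
               bf01 = bf$bf01, bf01_error_pct = bf$error_pct)
  })
  out <- do.call(rbind, rows)
  fam <- contrasts[[family]]
  out$p_fdr <- NA_real_
  for (f in unique(fam)) {
    sel <- fam == f
    out$p_fdr[sel] <- stats::p.adjust(out$p_raw[sel], method = "BH")
  }
  out <- out[, c("label", "foreperiod_ms", "estimate", "t", "df", "p_raw",
                 "p_fdr", "dz", "dz_lo", "dz_hi", "bf01", "bf01_error_pct")]
  class(out) <- c("contrast_results", "data.frame")
  out
}

#' JZS Bayes factor for a one-sample (paired) t statistic
#'
#' Jeffreys--Zellner--Siow Bayes factor with a Cauchy prior of scale
#' `cauchy_scale` on the standardized effect size under the alternative.
#' Computed by adaptive quadrature over the auxiliary scale parameter g
#' (inverse-gamma(1/2, scale^2/2) mixing density). Reported with the null
#' hypothesis in the numerator: BF01 > 1 favors the null.
#'
#' @param t Observed t statistic (finite).
#' @param n Sample size (number of pairs), >= 2.
#' @param cauchy_scale Cauchy prior scale (default sqrt(2)/2, the
#'   conventional "medium" prior).
#' @return List with `bf01`, `bf10` and `error_pct` (approximate
#'   percentage error of the quadrature).
#' @export
bf01_ttest <- function(t, n, cauchy_scale = sqrt(2) / 2) {
  if (!is.finite(t)) stop("t must be finite")
  stopifnot(n >= 2, cauchy_scale > 0)
  nu <- n - 1
  r <- cauchy_scale
  ## integrand on the log scale for numerical stability
  log_lik0 <- -(nu + 1) / 2 * log1p(t^2 / nu)
  f <- function(g) {
    ll <- -0.5 * log1p(n * g) -
      (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) - log_lik0
    dens <- r / sqrt(2 * pi) * g^(-1.5) * exp(-r^2 / (2 * g))
    exp(ll) * dens
  }
  q <- stats::integrate(f, 0, Inf, rel.tol = 1e-10, abs.tol = 0,
                        subdivisions = 500L)
  bf10 <- q$value
  list(bf01 = 1 / bf10, bf10 = bf10,
       error_pct = 100 * q$abs.error / q$value)
}

#' Within-subject standard error of the mean
#'
#' Between-subject offsets are removed by centering every subject's data on
#' its own mean (the grand mean is restored), the per-cell SD of the
#' centered values is divided by sqrt(n), and the result is multiplied by
#' the small-sample bias correction sqrt(M / (M - 1)) for M cells.
#'
#' @param table Long data frame with one row per subject x cell.
#' @param dv,subject Column names.
#' @param cells Character vector of columns defining the cells.
#' @return Data frame with the cell columns and `sem`.
#' @export
within_subject_sem <- function(table, dv = "mean_sr",
                               subject = "subject_id",
                               cells = c("condition", "foreperiod_ms")) {
  subs <- unique(table[[subject]])
  if (length(subs) < 2) stop("at least two subjects required")
  smean <- tapply(table[[dv]], table[[subject]], mean)
  centered <- table[[dv]] - smean[as.character(table[[subject]])] +
    mean(table[[dv]])
  key <- interaction(table[cells], drop = TRUE, lex.order = TRUE)
  M <- nlevels(key)
  agg <- tapply(centered, key, function(v) {
    stats::sd(v) / sqrt(length(v)) * sqrt(M / (M - 1))
  })
  cell_rows <- !duplicated(key)
  out <- table[cell_rows, cells, drop = FALSE]
  out$sem <- as.numeric(agg[as.character(key[cell_rows])])
  rownames(out) <- NULL
  out[do.call(order, out[cells]), , drop = FALSE]
}

#' Linear foreperiod trend in the low-certainty condition
#'
#' One-way repeated-measures ANOVA over the five low-certainty foreperiods
#' plus a linear trend contrast (weights -2, -1, 0, 1, 2 over increasing
#' foreperiod). A negative slope indicates decreasing pre-target saccade
#' rate with longer foreperiods (the classic foreperiod/hazard effect).
#'
#' @param table A `pretarget_sr_table` containing the `low_certainty`
#'   condition at all five foreperiods for every subject.
#' @return List of class `foreperiod_trend`: `anova` (an [rm_anova()]
#'   table), `slope` (mean per-subject trend score), `t`, `df`, `p`.
#' @export
foreperiod_trend <- function(table) {
  low <- table[table$condition == "low_certainty", ]
  fps <- sort(unique(low$foreperiod_ms))
  if (length(fps) != 5) {
    stop("expected five low-certainty foreperiods, found ", length(fps))
  }
  av <- rm_anova(low, dv = "mean_sr", subject = "subject_id",
                 factors = "foreperiod_ms")
  w <- c(-2, -1, 0, 1, 2)
  subs <- sort(unique(low$subject_id))
  scores <- vapply(subs, function(s) {
    v <- low$mean_sr[low$subject_id == s][order(low$foreperiod_ms[low$subject_id == s])]
    if (length(v) != 5 || any(is.na(v))) {
      stop("subject ", s, " is missing low-certainty foreperiod cells")
    }
    sum(w * v)
  }, numeric(1))
  if (stats::sd(scores) == 0) {
    tt <- 0
    p <- 1
  } else {
    ht <- stats::t.test(scores)
    tt <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(list(anova = av, slope = mean(scores), t = tt,
                 df = length(subs) - 1, p = p),
            class = "foreperiod_trend")
}

#' @export
print.foreperiod_trend <- function(x, ...) {
  cat(sprintf("Foreperiod linear trend: slope = %.4f, t(%d) = %.3f, p = %.4g\n",
              x$slope, x$df, x$t, x$p))
  invisible(x)
}
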