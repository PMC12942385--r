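#' Method-agreement statistics for paired acuity measurements
#'
#' The clinical validation suite: Bland-Altman bias and 95% limits of
#' agreement, two-way random-effects absolute-agreement single-measure ICC
#' (Shrout-Fleiss ICC(2,1)) with an F-based confidence interval, Wilcoxon
#' signed-rank (exact with mid-ranks for small n), Shapiro-Wilk normality,
#' Spearman rank correlation, and the participant-level outlier filter
#' (logMAR difference >= 0.4 in either eye).  Eyes are treated as
#' independent units.
#'
#' @name agreement_stats
NULL

pair_columns <- function(pairs, method_a_col, method_b_col) {
  a <- pairs[[method_a_col]]; b <- pairs[[method_b_col]]
  if (is.null(a) || is.null(b)) stop_domain("missing method columns")
  keep <- is.finite(a) & is.finite(b)
  list(a = a[keep], b = b[keep])
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`; bias is their mean, limits of agreement are
#' `mean(d) +/- 1.96 sd(d)` with the sample (n-1) standard deviation.  The
#' 1.96 multiplier is fixed (not a t quantile).
#'
#' @param pairs data.frame of paired measurements.
#' @param method_a_col,method_b_col Column names of the two methods
#'   (defaults: automated minus manual).
#' @return An object of class `bland_altman_result`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, and the differences in `diffs`.
#' @export
bland_altman <- function(pairs, method_a_col = "automated_logmar",
                         method_b_col = "manual_logmar") {
  cols <- pair_columns(pairs, method_a_col, method_b_col)
  d <- cols$a - cols$b
  n <- length(d)
  if (n < 2L) stop_domain("Bland-Altman needs at least 2 complete pairs")
  m <- mean(d); s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 n = n, diffs = d),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f, SD %.3f, 95%% LoA [%.3f, %.3f]\n",
              x$n, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Base-graphics difference-vs-mean plot with bias and LoA lines.
#'
#' @param result A `bland_altman_result`.
#' @param pairs,method_a_col,method_b_col The data used to compute it.
#' @param ... Passed to [plot()].
#' @return Invisibly, the result.
#' @export
plot_bland_altman <- function(result, pairs,
                              method_a_col = "automated_logmar",
                              method_b_col = "manual_logmar", ...) {
  cols <- pair_columns(pairs, method_a_col, method_b_col)
  avg <- (cols$a + cols$b) / 2
  plot(avg, cols$a - cols$b, xlab = "Mean of methods (logMAR)",
       ylab = "Difference (logMAR)", ...)
  graphics::abline(h = c(result$mean_diff, result$loa_low, result$loa_high),
                   lty = c(1, 2, 2))
  invisible(result)
}

#' Intraclass correlation between two measurement methods
#'
#' Single-measure ICC from the two-way ANOVA mean squares.  The default is
#' the two-way random-effects absolute-agreement form ICC(2,1)
#' (Shrout-Fleiss), appropriate for inter-method agreement of single
#' measurements; ICC(3,1) (consistency) is available via `model`.
#' Confidence limits follow the Shrout-Fleiss F-distribution construction.
#'
#' @param pairs data.frame of paired measurements (one row per subject/eye).
#' @param method_a_col,method_b_col Method columns.
#' @param model `"ICC2"` (absolute agreement, default) or `"ICC3"`
#'   (consistency).
#' @param conf Confidence level (default 0.95).
#' @return An object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `model`, `n`, and the ANOVA mean squares.
#' @export
icc_agreement <- function(pairs, method_a_col = "automated_logmar",
                          method_b_col = "manual_logmar",
                          model = c("ICC2", "ICC3"), conf = 0.95) {
  model <- match.arg(model)
  cols <- pair_columns(pairs, method_a_col, method_b_col)
  X <- cbind(cols$a, cols$b)
  n <- nrow(X); k <- 2L
  if (n < 5L) stop_domain("ICC needs at least 5 subjects")
  gm <- mean(X)
  rm_ <- rowMeans(X); cm <- colMeans(X)
  SST <- sum((X - gm)^2)
  if (SST < .Machine$double.eps * n)
    stop_domain("zero total variance: ICC undefined")
  SSR <- k * sum((rm_ - gm)^2); MSR <- SSR / (n - 1)
  SSC <- n * sum((cm - gm)^2); MSC <- SSC / (k - 1)
  SSE <- SST - SSR - SSC; MSE <- SSE / ((n - 1) * (k - 1))
  alpha <- 1 - conf
  if (model == "ICC2") {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  } else {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    Fobs <- MSR / MSE
    df2 <- (n - 1) * (k - 1)
    FL <- Fobs / stats::qf(1 - alpha / 2, n - 1, df2)
    FU <- Fobs * stats::qf(1 - alpha / 2, df2, n - 1)
    lo <- (FL - 1) / (FL + k - 1)
    hi <- (FU - 1) / (FU + k - 1)
  }
  structure(list(icc = icc, ci_low = lo, ci_high = hi, model = model,
                 n = n, MSR = MSR, MSC = MSC, MSE = MSE, conf = conf),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s = %.3f (%d%% CI %.3f-%.3f), n = %d\n", x$model, x$icc,
              round(100 * x$conf), x$ci_low, x$ci_high, x$n))
  invisible(x)
}

# Exact null distribution of the signed-rank statistic over all 2^n sign
# assignments, via convolution on doubled ranks (mid-ranks are halves).
signed_rank_exact_p <- function(W, ranks) {
  r2 <- as.integer(round(2 * ranks))
  tot <- sum(r2)
  f <- numeric(tot + 1L); f[1L] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1L):(tot + 1L)] <- g[(r + 1L):(tot + 1L)] + f[1L:(tot + 1L - r)]
    f <- g
  }
  f <- f / 2^length(r2)
  w2 <- round(2 * W)
  p_le <- sum(f[seq_len(w2 + 1L)])
  p_ge <- sum(f[(w2 + 1L):(tot + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test for paired measurements
#'
#' Zero differences are dropped; tied absolute differences get mid-ranks.
#' For n <= 25 the two-sided p-value comes from the exact permutation
#' distribution of the positive-rank sum (conditional on the observed
#' ranks); larger n uses the normal approximation with the tie-corrected
#' variance `sum(ranks^2)/4`.
#'
#' @param pairs data.frame, or a numeric vector of differences via `diffs`.
#' @param method_a_col,method_b_col Method columns (differences `a - b`).
#' @param diffs Optional precomputed differences (overrides columns).
#' @param exact_max Largest n for the exact path (default 25).
#' @return List with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n` (nonzero differences) and `method`.
#' @export
wilcoxon_signed_rank <- function(pairs = NULL,
                                 method_a_col = "automated_logmar",
                                 method_b_col = "manual_logmar",
                                 diffs = NULL, exact_max = 25L) {
  if (is.null(diffs)) {
    cols <- pair_columns(pairs, method_a_col, method_b_col)
    diffs <- cols$a - cols$b
  }
  d <- diffs[diffs != 0]
  if (!length(d)) {
    warning("all differences are zero; test degenerate")
    return(list(statistic = 0, p_value = 1, n = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  n <- length(d)
  if (n <= exact_max) {
    p <- signed_rank_exact_p(W, r)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    sigma <- sqrt(sum(r^2) / 4)
    z <- (W - mu) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = W, p_value = p, n = n, method = method)
}

#' Shapiro-Wilk normality test
#'
#' Delegates to the Royston algorithm in [stats::shapiro.test()]; valid for
#' sample sizes 3 to 5000.
#'
#' @param values Numeric vector.
#' @return List with `statistic` (W) and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop_domain("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0)
    stop_domain("constant input: normality test degenerate")
  res <- stats::shapiro.test(values)
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Spearman rank correlation
#'
#' Mid-ranks for ties, Pearson correlation on the ranks, p-value from the t
#' approximation with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L || length(y) != n) stop_domain("need equal lengths >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_domain("constant input: rho undefined")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p_value = 0, n = n))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * stats::pt(-abs(t), n - 2), n = n)
}

#' Participant-level outlier filter
#'
#' A participant is flagged when the absolute manual-automated difference is
#' at least `threshold` (default 0.4 logMAR, boundary inclusive) in either
#' eye; both eyes of a flagged participant move to the flagged table.
#'
#' @param pairs Cohort data.frame with `participant_id`, `manual_logmar`,
#'   `automated_logmar`.
#' @param threshold Positive flagging threshold (logMAR).
#' @return List with data.frames `kept` and `flagged`.
#' @export
outlier_filter <- function(pairs, threshold = 0.4) {
  if (threshold <= 0) stop_domain("`threshold` must be positive")
  if (!nrow(pairs))
    return(list(kept = pairs, flagged = pairs))
  d <- abs(pairs$manual_logmar - pairs$automated_logmar)
  # tolerance keeps the inclusive boundary robust to floating-point
  # representation of letter-grid values (e.g. 0.84 - 0.44 < 0.4 by one ulp)
  flagged_ids <- unique(pairs$participant_id[!is.na(d) & d >= threshold - 1e-9])
  flag <- pairs$participant_id %in% flagged_ids
  list(kept = pairs[!flag, , drop = FALSE],
       flagged = pairs[flag, , drop = FALSE])
}

#' Full agreement report for a cohort table
#'
#' Convenience wrapper running the outlier filter, Bland-Altman, ICC,
#' Wilcoxon, Shapiro-Wilk (on the differences) and Spearman correlation of
#' the differences against the means, on the unaided or pinhole columns.
#'
#' @param cohort Cohort data.frame (schema of [generate_cohort()]).
#' @param pinhole Use the pinhole columns instead of the unaided ones.
#' @param filter_outliers Apply [outlier_filter()] first (default TRUE).
#' @param icc_model Passed to [icc_agreement()].
#' @return List of results (class `agreement_report`).
#' @export
agreement_report <- function(cohort, pinhole = FALSE, filter_outliers = TRUE,
                             icc_model = "ICC2") {
  a_col <- if (pinhole) "automated_pinhole_logmar" else "automated_logmar"
  b_col <- if (pinhole) "manual_pinhole_logmar" else "manual_logmar"
  filt <- if (filter_outliers) outlier_filter(cohort)
          else list(kept = cohort, flagged = cohort[0, , drop = FALSE])
  kept <- filt$kept
  ba <- bland_altman(kept, a_col, b_col)
  icc <- icc_agreement(kept, a_col, b_col, model = icc_model)
  wil <- wilcoxon_signed_rank(kept, a_col, b_col)
  sw <- tryCatch(shapiro_wilk(ba$diffs), error = function(e) NULL)
  cols <- pair_columns(kept, a_col, b_col)
  sp <- tryCatch(spearman_rho((cols$a + cols$b) / 2, cols$a - cols$b),
                 error = function(e) NULL)
  structure(list(n_eyes = ba$n, n_flagged = nrow(filt$flagged),
                 bland_altman = ba, icc = icc, wilcoxon = wil,
                 shapiro = sw, spearman = sp,
                 flagged = filt$flagged, pinhole = pinhole),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report (%s VA, %d eyes, %d flagged eyes excluded)\n",
              if (x$pinhole) "pinhole" else "unaided", x$n_eyes, x$n_flagged))
  print(x$bland_altman)
  print(x$icc)
  cat(sprintf("Wilcoxon signed-rank: V = %.1f, p = %.4g (%s)\n",
              x$wilcoxon$statistic, x$wilcoxon$p_value, x$wilcoxon$method))
  if (!is.null(x$shapiro))
    cat(sprintf("Shapiro-Wilk on differences: W = %.3f, p = %.4g\n",
                x$shapiro$statistic, x$shapiro$p_value))
  if (!is.null(x$spearman))
    cat(sprintf("Spearman rho (diff vs mean) = %.3f, p = %.4g\n",
                x$spearman$rho, x$spearman$p_value))
  invisible(x)
}
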