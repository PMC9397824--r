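#' Intraclass correlation ICC(2,k): two-way random, absolute agreement,
#' average measures
#'
#' Test-retest reliability of averaged measurements from the two-way
#' random-effects ANOVA decomposition:
#' `ICC = (MS_R - MS_E) / (MS_R + (MS_C - MS_E) / n)`,
#' where `MS_R`, `MS_C`, `MS_E` are the row (subject), column (session) and
#' residual mean squares. The confidence interval uses the F-based bounds
#' of the single-measures absolute-agreement coefficient stepped up to
#' average measures (Spearman-Brown), and the p-value is the upper tail of
#' `F = MS_R / MS_E` on `(n - 1, (n - 1)(k - 1))` degrees of freedom.
#'
#' Reliability is conventionally read as excellent above 0.90, good in
#' (0.75, 0.90], moderate in (0.5, 0.75] and poor otherwise; the returned
#' object carries this label.
#'
#' @param measurements numeric matrix or data.frame, one row per subject and
#'   one column per session/rater; no missing cells, `n >= 3` rows.
#' @param conf confidence level (default 0.95).
#' @return Object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `p_value`, `n_subjects`, `k_raters`, `ms` (the three mean squares),
#'   `classification`.
#' @export
icc_2k <- function(measurements, conf = 0.95) {
  m <- as.matrix(measurements)
  if (any(is.na(m))) stop("missing cells are not allowed")
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2) stop("need at least 3 subjects and 2 sessions")
  gm <- mean(m)
  SSR <- k * sum((rowMeans(m) - gm)^2)
  SSC <- n * sum((colMeans(m) - gm)^2)
  SSE <- sum((m - gm)^2) - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR + (MSC - MSE) / n == 0 || all(abs(m - gm) < 1e-300))
    stop("zero total variance: ICC undefined")
  icc <- (MSR - MSE) / (MSR + (MSC - MSE) / n)

  # single-measures absolute-agreement bounds, then Spearman-Brown step-up
  icc1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  a <- 1 - (1 - conf) / 2
  if (MSE > 0) {
    Fj <- MSC / MSE
    vn <- ((k - 1) * (n - 1)) *
      (k * icc1 * Fj + n * (1 + (k - 1) * icc1) - k * icc1)^2
    vd <- (n - 1) * k^2 * icc1^2 * Fj^2 +
      (n * (1 + (k - 1) * icc1) - k * icc1)^2
    v <- vn / vd
    FL <- stats::qf(a, n - 1, v)
    FU <- stats::qf(a, v, n - 1)
    L1 <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    U1 <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(L1 * k / (1 + (k - 1) * L1), U1 * k / (1 + (k - 1) * U1))
    p <- stats::pf(MSR / MSE, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  } else {
    ci <- c(icc, icc)
    p <- 0
  }
  cls <- if (icc > 0.90) "excellent" else if (icc > 0.75) "good"
  else if (icc > 0.5) "moderate" else "poor"
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2], p_value = p,
                 n_subjects = n, k_raters = k,
                 ms = c(MSR = MSR, MSC = MSC, MSE = MSE),
                 classification = cls),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,%d) = %.3f, 95%% CI [%.3f, %.3f], p = %.3g (%s; n = %d)\n",
              x$k_raters, x$icc, x$ci_low, x$ci_high, x$p_value,
              x$classification, x$n_subjects))
  invisible(x)
}

#' Bland-Altman limits of agreement
#'
#' Paired-difference agreement between two measurement sessions: mean
#' difference and mean +/- 1.96 standard deviations of the differences.
#'
#' @param x1,x2 paired measurements (equal length, `>= 2`).
#' @return Object of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `differences`, `means`, `n_outside` (pairs
#'   outside the limits).
#' @export
bland_altman <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("`x1` and `x2` must have equal length")
  if (length(x1) < 2) stop("need at least 2 pairs")
  d <- x1 - x2
  md <- mean(d)
  sdd <- stats::sd(d)
  loa <- md + c(-1, 1) * 1.96 * sdd
  structure(list(mean_diff = md, sd_diff = sdd,
                 loa_low = loa[1], loa_high = loa[2],
                 differences = d, means = (x1 + x2) / 2,
                 n_outside = sum(d < loa[1] | d > loa[2])),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(paste0("Bland-Altman: mean diff %.4g, limits of agreement ",
                     "[%.4g, %.4g], %d of %d pairs outside\n"),
              x$mean_diff, x$loa_low, x$loa_high, x$n_outside,
              length(x$differences)))
  invisible(x)
}
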