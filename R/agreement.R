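#' Bland-Altman agreement analysis
#'
#' Classic method-comparison analysis for two measurements of the same
#' quantity on the same eyes: bias is the mean of the paired differences
#' `a - b`, and the 95% limits of agreement are `bias +/- 1.96 * SD` of the
#' differences (sample SD, n-1; multiplier fixed at 1.96 as in the classic
#' presentation, not a t quantile). Inputs must already be on common units;
#' apply [sr_to_deg2()] / [ms_to_area_units()] before differencing.
#'
#' @param a,b Paired numeric vectors (same eyes, same order, same units).
#' @param name_a,name_b Labels for reporting.
#' @return Object of class `hov_agreement`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, and per-pair `means`/`diffs` for plotting.
#' @export
bland_altman <- function(a, b, name_a = deparse(substitute(a)),
                         name_b = deparse(substitute(b))) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("paired vectors must have equal length", call. = FALSE)
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L)
    stop("need at least 2 complete pairs (SD of differences undefined)",
         call. = FALSE)
  d <- a - b
  bias <- mean(d)
  sdd <- stats::sd(d)
  structure(list(metric_a = name_a, metric_b = name_b, bias = bias,
                 sd_diff = sdd, loa_low = bias - 1.96 * sdd,
                 loa_high = bias + 1.96 * sdd, n = length(d),
                 means = (a + b) / 2, diffs = d),
            class = "hov_agreement")
}

#' @export
print.hov_agreement <- function(x, ...) {
  cat(sprintf(
    "<hov_agreement> %s - %s (n = %d)\n  bias %.4g [95%% LoA %.4g to %.4g]\n",
    x$metric_a, x$metric_b, x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Normality-gated paired comparison
#'
#' Tests whether two paired measurements differ systematically. The paired
#' differences are first checked for normality (D'Agostino-Pearson omnibus
#' test; Shapiro-Wilk for very small samples where that test is undefined).
#' Normal differences are compared with the paired t-test, non-normal ones
#' with the Wilcoxon matched-pairs signed rank test. If all differences are
#' zero the comparison is degenerate and reported with p = 1 and a flag.
#'
#' @param a,b Paired numeric vectors on common units.
#' @param alpha Significance level of the normality gate (default 0.05).
#' @return List with `test` (name), `statistic`, `p.value`,
#'   `normality_p`, `degenerate`, `n`.
#' @export
paired_comparison <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("paired vectors must have equal length", call. = FALSE)
  ok <- is.finite(a) & is.finite(b)
  d <- a[ok] - b[ok]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  if (all(d == 0))
    return(list(test = "degenerate", statistic = NA_real_, p.value = 1,
                normality_p = NA_real_, degenerate = TRUE, n = n))
  norm_p <- if (n >= 8L) dagostino_pearson(d)$p.value
            else stats::shapiro.test(d)$p.value
  if (norm_p >= alpha) {
    tt <- stats::t.test(a[ok], b[ok], paired = TRUE)
    list(test = "paired t-test", statistic = unname(tt$statistic),
         p.value = tt$p.value, normality_p = norm_p, degenerate = FALSE,
         n = n)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a[ok], b[ok], paired = TRUE,
                                              exact = FALSE))
    list(test = "Wilcoxon signed rank", statistic = unname(wt$statistic),
         p.value = wt$p.value, normality_p = norm_p, degenerate = FALSE,
         n = n)
  }
}
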