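#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino (1970) transformed skewness statistic and the
#' Anscombe-Glynn (1983) transformed kurtosis statistic into the omnibus
#' `K^2 = Z_skew^2 + Z_kurt^2`, referred to a chi-square distribution with
#' 2 degrees of freedom. Requires n >= 8 (the kurtosis transformation is
#' not defined below that).
#'
#' @param x Numeric sample.
#' @return `htest`-like list with `statistic` (K2), `p.value`, `z_skew`,
#'   `z_kurt`, `n`, `method`.
#' @references D'Agostino, Belanger & D'Agostino Jr (1990), The American
#'   Statistician 44(4), 316-321.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L)
    stop("D'Agostino-Pearson test requires at least 8 observations",
         call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 < .Machine$double.eps)
    stop("zero-variance sample", call. = FALSE)
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  # skewness: D'Agostino's transformation to approximate normality
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / alpha)

  # kurtosis: Anscombe-Glynn transformation
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n,
       method = "D'Agostino-Pearson omnibus normality test")
}
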