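#' Fit a thin-plate-spline hill-of-vision surface
#'
#' Solves the classical thin-plate-spline system for scattered 2D data with
#' radial kernel `phi(r) = r^2 log(r)` (with `phi(0) = 0`) and affine part
#' `a0 + a1*u + a2*v`:
#'
#' \deqn{f(q) = a_0 + a_1 u + a_2 v + \sum_i w_i \, \phi(\|q - p_i\|)}
#'
#' subject to the orthogonality side conditions `sum(w) = 0`,
#' `sum(w*u) = 0`, `sum(w*v) = 0`. With smoothing `lambda = 0` the surface
#' interpolates the data exactly; `lambda > 0` adds a ridge term on the
#' kernel block (diagonal `lambda`), trading fidelity for bending energy.
#'
#' Both volume engines fit in the same planar coordinates: the cartesian
#' engine in visual-field degrees directly, the polar engine in
#' azimuthal-equidistant coordinates `(theta*cos(phi), theta*sin(phi))`,
#' which are numerically identical to cartesian degrees at macular
#' eccentricities; the engines differ only in the area element used during
#' integration and in the unit of the result.
#'
#' @param positions Two-column matrix/data.frame of node positions (degrees).
#' @param values Numeric vector of sensitivities (dB) at the nodes.
#' @param lambda Non-negative smoothing parameter (default 0, exact
#'   interpolation).
#' @param engine `"cartesian"` or `"polar"`; recorded for downstream
#'   integration and unit bookkeeping.
#' @return Object of class `hov_tps` with fields `nodes`, `weights`,
#'   `affine` (a0, a1, a2), `lambda`, `engine`.
#' @seealso [integrate_hov()], [compute_vtot()]
#' @export
fit_tps <- function(positions, values, lambda = 0,
                    engine = c("cartesian", "polar")) {
  engine <- match.arg(engine)
  p <- as_point_matrix(positions)
  v <- as.numeric(values)
  n <- nrow(p)
  if (n != length(v)) stop("one value per position required", call. = FALSE)
  if (n < 3L) stop("need at least 3 positions", call. = FALSE)
  if (any(!is.finite(p)) || any(!is.finite(v)))
    stop("positions and values must be finite", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("lambda must be a single non-negative number", call. = FALSE)

  d <- as.matrix(stats::dist(p))
  dup <- which(d < 1e-9 & upper.tri(d), arr.ind = TRUE)
  if (nrow(dup) > 0)
    stop(sprintf("duplicate node positions: rows %s",
                 paste(apply(dup, 1, paste, collapse = "/"), collapse = ", ")),
         call. = FALSE)

  K <- tps_kernel(d)
  P <- cbind(1, p)
  A <- rbind(cbind(K + diag(lambda, n), P),
             cbind(t(P), matrix(0, 3, 3)))
  sol <- tryCatch(solve(A, c(v, 0, 0, 0)),
                  error = function(e)
                    stop(paste0("singular thin-plate-spline system ",
                                "(collinear or degenerate node layout): ",
                                conditionMessage(e)), call. = FALSE))
  structure(list(nodes = p, weights = sol[seq_len(n)],
                 affine = sol[n + 1:3], lambda = lambda, engine = engine,
                 values = v),
            class = "hov_tps")
}

# r^2 log r with the removable singularity at r = 0 set to 0.
tps_kernel <- function(r) {
  k <- r
  pos <- r > 0
  k[pos] <- r[pos]^2 * log(r[pos])
  k[!pos] <- 0
  k
}

#' Evaluate a fitted hill-of-vision surface
#'
#' @param object A fitted [fit_tps()] surface.
#' @param newdata Two-column matrix/data.frame of query positions (degrees).
#' @param ... Unused.
#' @return Numeric vector of surface heights (dB) at the queries.
#' @export
predict.hov_tps <- function(object, newdata, ...) {
  q <- as_point_matrix(newdata)
  n <- nrow(object$nodes)
  # squared distances query x node, fully vectorized
  d2 <- outer(q[, 1], object$nodes[, 1], "-")^2 +
        outer(q[, 2], object$nodes[, 2], "-")^2
  K <- tps_kernel(sqrt(d2))
  unname(drop(object$affine[1] + object$affine[2] * q[, 1] +
                object$affine[3] * q[, 2] + K %*% object$weights))
}

#' @export
print.hov_tps <- function(x, ...) {
  cat(sprintf(
    "<hov_tps> %s engine, %d nodes, lambda = %g, affine = (%.4g, %.4g, %.4g)\n",
    x$engine, nrow(x$nodes), x$lambda,
    x$affine[1], x$affine[2], x$affine[3]))
  invisible(x)
}
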