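#' Square degrees per steradian
#'
#' The exact conversion between solid-angle and planar visual-field units:
#' `1 sr = (180/pi)^2` (approximately 3282.8) square degrees.
#' @export
DEG2_PER_SR <- (180 / pi)^2

#' Define an integration domain for hill-of-vision volumes
#'
#' Volumes are integrated either over the convex hull of the test points
#' (the default: no extrapolation beyond tested retina) or over a disc of
#' given angular radius centered on fixation (explicit extrapolation, useful
#' for exploring domain sensitivity). Both are represented as convex
#' polygons; the disc as a fine regular polygon.
#'
#' @param kind `"convex_hull"` or `"disc"`.
#' @param points Test-point positions (required for `convex_hull`).
#' @param radius_deg Disc radius in degrees (required for `disc`).
#' @param n_arc Number of polygon vertices approximating the disc boundary.
#' @return Object of class `hov_domain`: list with `kind`, `polygon`
#'   (counter-clockwise convex vertices), and `radius_deg` (discs only).
#' @export
integration_domain <- function(kind = c("convex_hull", "disc"),
                               points = NULL, radius_deg = NULL,
                               n_arc = 1440L) {
  kind <- match.arg(kind)
  if (kind == "convex_hull") {
    if (is.null(points))
      stop("convex_hull domain requires the test points", call. = FALSE)
    poly <- convex_hull(points)
    radius_deg <- NA_real_
  } else {
    if (is.null(radius_deg) || radius_deg <= 0)
      stop("disc domain requires a positive radius_deg", call. = FALSE)
    ang <- 2 * pi * (seq_len(n_arc) - 1) / n_arc
    poly <- cbind(x = radius_deg * cos(ang), y = radius_deg * sin(ang))
  }
  structure(list(kind = kind, polygon = poly, radius_deg = radius_deg),
            class = "hov_domain")
}

# ---- raster quadrature --------------------------------------------------
#
# Midpoint rule on a regular raster. Interior cells get full weight h^2;
# cells straddling the domain boundary are clipped exactly against the
# convex polygon (Sutherland-Hodgman) so each boundary cell contributes its
# true overlap area. This removes the boundary bias of a binary
# center-in-polygon mask (the grid hull's diagonal edges are commensurate
# with any raster anchored at the bounding box, so on-edge ties would
# otherwise be systematic) and makes constant fields integrate exactly at
# any resolution. Weights depend only on (polygon, resolution) and are
# cached across calls.

.weight_cache <- new.env(parent = emptyenv())

# Clip convex polygon (px, py) to the half-plane left of segment a->b.
clip_halfplane <- function(px, py, ax, ay, bx, by) {
  n <- length(px)
  if (n == 0L) return(list(x = numeric(), y = numeric()))
  ex <- bx - ax; ey <- by - ay
  s <- ex * (py - ay) - ey * (px - ax)
  keep_x <- numeric(n + 4L); keep_y <- numeric(n + 4L); m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (s[i] >= 0) { m <- m + 1L; keep_x[m] <- px[i]; keep_y[m] <- py[i] }
    if ((s[i] >= 0) != (s[j] >= 0)) {
      t <- s[i] / (s[i] - s[j])
      m <- m + 1L
      keep_x[m] <- px[i] + t * (px[j] - px[i])
      keep_y[m] <- py[i] + t * (py[j] - py[i])
    }
  }
  list(x = keep_x[seq_len(m)], y = keep_y[seq_len(m)])
}

# Area of rect [x0,x1]x[y0,y1] clipped to convex polygon `poly` (CCW).
# Edges whose supporting line cannot intersect the cell (signed distance of
# the cell center beyond half the cell diagonal) are resolved without
# clipping; matters for fine polygonal discs with hundreds of edges.
clipped_cell_area <- function(x0, x1, y0, y1, poly, edges = polygon_edges(poly)) {
  mx <- (x0 + x1) / 2; my <- (y0 + y1) / 2
  half_diag <- sqrt((x1 - x0)^2 + (y1 - y0)^2) / 2
  # signed distance of the cell center to every edge line, vectorized
  s <- (edges$ex * (my - edges$ay) - edges$ey * (mx - edges$ax)) / edges$len
  if (any(s <= -half_diag)) return(0)   # fully outside some half-plane
  active <- which(s < half_diag)        # edges that can cross the cell
  cx <- c(x0, x1, x1, x0); cy <- c(y0, y0, y1, y1)
  for (i in active) {
    cl <- clip_halfplane(cx, cy, edges$ax[i], edges$ay[i],
                         edges$bx[i], edges$by[i])
    cx <- cl$x; cy <- cl$y
    if (length(cx) < 3L) return(0)
  }
  abs(polygon_area(cbind(cx, cy)))
}

polygon_edges <- function(poly) {
  j <- c(seq_len(nrow(poly))[-1], 1L)
  ex <- poly[j, 1] - poly[, 1]; ey <- poly[j, 2] - poly[, 2]
  list(ax = poly[, 1], ay = poly[, 2], bx = poly[j, 1], by = poly[j, 2],
       ex = ex, ey = ey, len = sqrt(ex^2 + ey^2))
}

# Cell centers and overlap-area weights for a convex polygon at a given
# raster resolution. Returns list(x, y, w) for cells with positive weight.
domain_weights <- function(domain, resolution) {
  stopifnot(inherits(domain, "hov_domain"))
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("resolution must be a single positive number", call. = FALSE)
  poly <- domain$polygon
  key <- paste(c(format(poly, digits = 15), format(resolution, digits = 15)),
               collapse = "|")
  if (is.null(.weight_cache$keys)) {
    .weight_cache$keys <- character()
    .weight_cache$vals <- list()
  }
  hit <- match(key, .weight_cache$keys)
  if (!is.na(hit)) return(.weight_cache$vals[[hit]])

  h <- resolution
  x0 <- min(poly[, 1]); x1 <- max(poly[, 1])
  y0 <- min(poly[, 2]); y1 <- max(poly[, 2])
  nx <- max(1L, ceiling((x1 - x0) / h)); ny <- max(1L, ceiling((y1 - y0) / h))
  gx <- x0 + h * (0:nx); gy <- y0 + h * (0:ny)       # corner lines
  cxs <- rep(gx, times = ny + 1L); cys <- rep(gy, each = nx + 1L)
  corner_in <- if (domain$kind == "disc") {
    # inscribed-circle shortcut: corners inside the apothem circle are
    # inside the polygonal disc; only the annulus needs the edge test
    r2 <- cxs^2 + cys^2
    apo2 <- (domain$radius_deg * cos(pi / nrow(poly)))^2
    res <- r2 <= apo2
    ann <- !res & r2 <= domain$radius_deg^2
    res[ann] <- in_convex_polygon(cxs[ann], cys[ann], poly)
    matrix(res, nrow = nx + 1L)
  } else {
    matrix(in_convex_polygon(cxs, cys, poly), nrow = nx + 1L)
  }
  cnt <- corner_in[1:nx, 1:ny] + corner_in[2:(nx + 1L), 1:ny] +
         corner_in[1:nx, 2:(ny + 1L)] + corner_in[2:(nx + 1L), 2:(ny + 1L)]
  # cells containing a polygon vertex can intersect with all corners outside
  vi <- pmin(pmax(floor((poly[, 1] - x0) / h) + 1L, 1L), nx)
  vj <- pmin(pmax(floor((poly[, 2] - y0) / h) + 1L, 1L), ny)
  vert_cell <- matrix(FALSE, nx, ny)
  vert_cell[cbind(vi, vj)] <- TRUE

  full <- cnt == 4L
  partial <- (!full) & (cnt > 0L | vert_cell)

  ij_full <- which(full, arr.ind = TRUE)
  ij_part <- which(partial, arr.ind = TRUE)
  wx <- c(x0 + h * (ij_full[, 1] - 0.5), x0 + h * (ij_part[, 1] - 0.5))
  wy <- c(y0 + h * (ij_full[, 2] - 0.5), y0 + h * (ij_part[, 2] - 0.5))
  edges <- polygon_edges(poly)
  w <- c(rep(h * h, nrow(ij_full)),
         vapply(seq_len(nrow(ij_part)), function(k) {
           cx0 <- x0 + h * (ij_part[k, 1] - 1L)
           cy0 <- y0 + h * (ij_part[k, 2] - 1L)
           clipped_cell_area(cx0, cx0 + h, cy0, cy0 + h, poly, edges)
         }, numeric(1)))
  pos <- w > 0
  out <- list(x = wx[pos], y = wy[pos], w = w[pos])
  .weight_cache$keys <- c(.weight_cache$keys, key)
  .weight_cache$vals <- c(.weight_cache$vals, list(out))
  out
}

# Solid-angle correction per cell: dOmega = (pi/180)^2 * sin(theta)/theta * dA
# with theta the angular eccentricity of the cell center (radians).
solid_angle_factor <- function(x, y) {
  theta <- sqrt(x^2 + y^2) * pi / 180
  f <- rep(1, length(theta))
  pos <- theta > 0
  f[pos] <- sin(theta[pos]) / theta[pos]
  f / DEG2_PER_SR
}

#' Integrate a hill-of-vision surface to a total volume
#'
#' Approximates the volume beneath a fitted surface over a convex domain by
#' midpoint-rule raster quadrature with exact-overlap boundary weights. The
#' cartesian engine integrates `f(x, y) dx dy` (dB deg^2); the polar engine
#' integrates the same planar fit against the solid-angle element
#' `sin(theta) dtheta dphi` (dB sr), which at macular eccentricities differs
#' from the planar element by the factor `sin(theta)/theta <= 1`.
#'
#' @param interp Fitted [fit_tps()] surface.
#' @param domain [integration_domain()]; defaults to the convex hull of the
#'   interpolant's nodes.
#' @param resolution Raster cell size in degrees (default 0.05).
#' @param check_convergence If `TRUE` (default) also integrates at half the
#'   resolution and reports the relative difference.
#' @param clamp_floor If `TRUE`, surface values below 0 dB (spline
#'   overshoot) are clamped to 0 before integration; default integrates the
#'   surface as-is.
#' @return Object of class `hov_volume`: `value`, `units`, `engine`,
#'   `domain_kind`, `resolution`, `convergence_estimate`, and the converted
#'   `twin` value in the other unit system.
#' @export
integrate_hov <- function(interp, domain = NULL, resolution = 0.05,
                          check_convergence = TRUE, clamp_floor = FALSE) {
  stopifnot(inherits(interp, "hov_tps"))
  if (is.null(domain))
    domain <- integration_domain("convex_hull", points = interp$nodes)
  one <- function(h) {
    wt <- domain_weights(domain, h)
    f <- predict(interp, cbind(wt$x, wt$y))
    if (clamp_floor) f <- pmax(f, 0)
    if (interp$engine == "polar")
      sum(f * wt$w * solid_angle_factor(wt$x, wt$y))
    else
      sum(f * wt$w)
  }
  value <- one(resolution)
  conv <- NA_real_
  if (check_convergence) {
    v2 <- one(resolution / 2)
    conv <- abs(value - v2) / max(abs(v2), 1e-12)
  }
  units <- if (interp$engine == "polar") "dB.sr" else "dB.deg2"
  twin <- if (interp$engine == "polar")
    list(value = sr_to_deg2(value), units = "dB.deg2")
  else
    list(value = deg2_to_sr(value), units = "dB.sr")
  structure(list(value = value, units = units, engine = interp$engine,
                 domain_kind = domain$kind, resolution = resolution,
                 convergence_estimate = conv, twin = twin),
            class = "hov_volume")
}

#' @rdname integrate_hov
#' @export
integrate_cartesian <- function(interp, domain = NULL, resolution = 0.05,
                                check_convergence = TRUE, clamp_floor = FALSE) {
  if (interp$engine != "cartesian")
    stop("interpolant was not fitted with the cartesian engine", call. = FALSE)
  integrate_hov(interp, domain, resolution, check_convergence, clamp_floor)
}

#' @rdname integrate_hov
#' @export
integrate_polar <- function(interp, domain = NULL, resolution = 0.05,
                            check_convergence = TRUE, clamp_floor = FALSE) {
  if (interp$engine != "polar")
    stop("interpolant was not fitted with the polar engine", call. = FALSE)
  integrate_hov(interp, domain, resolution, check_convergence, clamp_floor)
}

#' @export
print.hov_volume <- function(x, ...) {
  cat(sprintf("<hov_volume> VTOT = %.6g %s (%s engine, %s domain, res %g deg",
              x$value, x$units, x$engine, x$domain_kind, x$resolution))
  if (!is.na(x$convergence_estimate))
    cat(sprintf(", conv %.2g", x$convergence_estimate))
  cat(sprintf(")\n  twin: %.6g %s\n", x$twin$value, x$twin$units))
  invisible(x)
}

#' Total volume beneath an exam's hill of vision
#'
#' Convenience pipeline: validates the exam, fits the thin-plate-spline
#' surface, and integrates it over the configured domain. Both unit systems
#' are always reported (the engine's native unit as `value`, the converted
#' twin alongside).
#'
#' @param exam An [mp_exam()].
#' @param engine `"cartesian"` (dB deg^2) or `"polar"` (dB sr).
#' @param lambda TPS smoothing (default 0, exact interpolation).
#' @param domain `NULL` for the convex hull of the exam's points, or an
#'   [integration_domain()].
#' @param resolution Raster resolution in degrees.
#' @param check_convergence,clamp_floor Passed to [integrate_hov()].
#' @return An `hov_volume`.
#' @export
compute_vtot <- function(exam, engine = c("cartesian", "polar"), lambda = 0,
                         domain = NULL, resolution = 0.05,
                         check_convergence = TRUE, clamp_floor = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(exam, "mp_exam"))
  issues <- validate_exam(exam)
  issues <- issues[issues$code != "no_fixation", , drop = FALSE]
  if (nrow(issues) > 0)
    stop(sprintf("exam fails validation: %s",
                 paste(issues$code, collapse = ", ")), call. = FALSE)
  interp <- fit_tps(exam$points, exam$thresholds, lambda = lambda,
                    engine = engine)
  integrate_hov(interp, domain = domain, resolution = resolution,
                check_convergence = check_convergence,
                clamp_floor = clamp_floor)
}
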