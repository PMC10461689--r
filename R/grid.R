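#' Canonical 24-point PINNACLE microperimetry grid
#'
#' Builds the standard 24-point macular test grid used on the MAIA device:
#' test points lie on the -5, -3, -1, 1, 3, 5 degree positions of both axes,
#' restricted to locations with `|x| + |y| <= 6` so that the pattern covers
#' the central 10 degrees of visual field (maximum eccentricity 5.1 deg).
#' Points are returned in a deterministic order: by `y` descending, then `x`
#' ascending.
#'
#' @param name Label attached to the grid.
#' @return An object of class `mp_grid`: a list with `points` (data.frame
#'   with columns `x`, `y` in degrees of visual angle) and `name`.
#' @examples
#' g <- pinnacle_grid()
#' nrow(g$points)          # 24
#' convex_hull_area(g$points)  # 68
#' @export
pinnacle_grid <- function(name = "PINNACLE-24") {
  pos <- c(-5, -3, -1, 1, 3, 5)
  pts <- expand.grid(x = pos, y = pos)
  pts <- pts[abs(pts$x) + abs(pts$y) <= 6, , drop = FALSE]
  pts <- pts[order(-pts$y, pts$x), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(points = pts, name = name), class = "mp_grid")
}

#' @export
print.mp_grid <- function(x, ...) {
  cat(sprintf("<mp_grid> %s: %d points, hull area %.6g deg^2\n",
              x$name, nrow(x$points), convex_hull_area(x$points)))
  invisible(x)
}

as_point_matrix <- function(points) {
  if (is.matrix(points)) {
    m <- points
  } else if (is.data.frame(points)) {
    cols <- if (all(c("x", "y") %in% names(points))) c("x", "y") else 1:2
    m <- as.matrix(points[, cols, drop = FALSE])
  } else {
    stop("points must be a two-column matrix or data.frame", call. = FALSE)
  }
  if (ncol(m) != 2L) stop("points must have exactly two columns", call. = FALSE)
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  m
}

#' Convex hull area of a planar point set
#'
#' Area of the convex hull via the shoelace formula applied to the hull
#' vertices; exact for rational coordinates up to floating tolerance.
#'
#' @param points Two-column matrix or data.frame of positions (degrees).
#' @return Hull area in squared degrees.
#' @export
convex_hull_area <- function(points) {
  abs(polygon_area(convex_hull(points)))
}

#' Convex hull vertices in counter-clockwise order
#'
#' @param points Two-column matrix or data.frame of positions.
#' @return Matrix of hull vertices (counter-clockwise, no repeated closing
#'   vertex).
#' @export
convex_hull <- function(points) {
  m <- as_point_matrix(points)
  if (nrow(m) < 3L) stop("need at least 3 points for a convex hull", call. = FALSE)
  idx <- grDevices::chull(m[, 1], m[, 2])   # clockwise order
  hull <- m[rev(idx), , drop = FALSE]       # counter-clockwise
  if (nrow(hull) < 3L || abs(polygon_area(hull)) < 1e-12)
    stop("degenerate geometry: points are collinear", call. = FALSE)
  hull
}

# Signed shoelace area; positive for counter-clockwise vertex order.
polygon_area <- function(vertices) {
  v <- as_point_matrix(vertices)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Exact polygon moments by Green's theorem: integrals of 1, x, y, x^2, y^2
# over the polygon interior. Vertices counter-clockwise.
polygon_moments <- function(vertices) {
  v <- as_point_matrix(vertices)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  list(
    area = sum(cr) / 2,
    ix   = sum(cr * (x^2 + x * xn + xn^2)) / 12,   # integral of x^2
    iy   = sum(cr * (y^2 + y * yn + yn^2)) / 12,   # integral of y^2
    mx   = sum(cr * (x + xn)) / 6,                 # integral of x
    my   = sum(cr * (y + yn)) / 6                  # integral of y
  )
}

# Vectorized point-in-convex-polygon test. `vertices` counter-clockwise;
# points on the boundary count as inside. Returns logical vector.
in_convex_polygon <- function(px, py, vertices, tol = 1e-12) {
  v <- as_point_matrix(vertices)
  inside <- rep(TRUE, length(px))
  n <- nrow(v)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- v[j, 1] - v[i, 1]; ey <- v[j, 2] - v[i, 2]
    s <- ex * (py - v[i, 2]) - ey * (px - v[i, 1])
    inside <- inside & (s >= -tol)
    if (!any(inside)) break
  }
  inside
}

# Match exam points to canonical grid points within `tol` degrees.
# Returns the index of the matching grid point for each row, NA if off-grid.
match_grid_points <- function(points, grid, tol = 0.25) {
  m <- as_point_matrix(points)
  g <- as_point_matrix(grid$points)
  idx <- integer(nrow(m))
  for (k in seq_len(nrow(m))) {
    d2 <- (g[, 1] - m[k, 1])^2 + (g[, 2] - m[k, 2])^2
    j <- which.min(d2)
    idx[k] <- if (d2[j] <= tol^2) j else NA_integer_
  }
  idx
}
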