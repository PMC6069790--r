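# Planar polygon primitives.
#
# All coordinates are planar meters in an equal-area projection; no geodesic
# math is done anywhere in the package. Polygons are simple (non-self-
# intersecting) rings given as an n x 2 matrix of vertices, closed implicitly
# (last vertex need not repeat the first).

ring_closed <- function(p) {
  if (all(p[1, ] == p[nrow(p), ])) p else rbind(p, p[1, ])
}

#' Signed and absolute polygon area (shoelace formula)
#'
#' @param polygon n x 2 numeric matrix of ring vertices in meters.
#' @return Area in square meters (absolute value).
#' @export
polygon_area <- function(polygon) {
  p <- ring_closed(as_polygon(polygon))
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

as_polygon <- function(polygon) {
  p <- as.matrix(polygon)
  if (ncol(p) != 2 || nrow(p) < 3 || !is.numeric(p) || anyNA(p))
    stop("polygon must be a numeric n x 2 matrix with n >= 3 and no NAs")
  p
}

#' Area-weighted centroid of a simple polygon
#'
#' For a rectangle this is its center; in general the first moment of area
#' divided by area (shoelace moments).
#'
#' @param polygon n x 2 numeric matrix of ring vertices in meters.
#' @return length-2 numeric `c(x, y)`.
#' @export
polygon_centroid <- function(polygon) {
  p <- ring_closed(as_polygon(polygon))
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  cross <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps * max(abs(p)) ^ 2)
    stop("degenerate polygon: zero area")
  cx <- sum((x[-n] + x[-1]) * cross) / (6 * a)
  cy <- sum((y[-n] + y[-1]) * cross) / (6 * a)
  c(x = cx, y = cy)
}

#' Point-in-polygon test (ray casting)
#'
#' Boundary points count as inside (within floating-point behaviour of the
#' crossing test); intended for blocks that tile a parent unit, where each
#' interior point lies in exactly one block up to measure zero.
#'
#' @param polygon n x 2 vertex matrix.
#' @param x,y point coordinates (vectors of equal length).
#' @return logical vector.
#' @export
point_in_polygon <- function(polygon, x, y) {
  p <- as_polygon(polygon)
  n <- nrow(p)
  px <- p[, 1]; py <- p[, 2]
  jx <- px[c(n, seq_len(n - 1L))]
  jy <- py[c(n, seq_len(n - 1L))]
  vapply(seq_along(x), function(k) {
    crosses <- ((py > y[k]) != (jy > y[k])) &
      (x[k] < (jx - px) * (y[k] - py) / (jy - py) + px)
    sum(crosses) %% 2L == 1L
  }, logical(1))
}

#' Polygon bounding box
#' @param polygon n x 2 vertex matrix.
#' @return named numeric `c(xmin, xmax, ymin, ymax)`.
#' @export
polygon_bbox <- function(polygon) {
  p <- as_polygon(polygon)
  c(xmin = min(p[, 1]), xmax = max(p[, 1]),
    ymin = min(p[, 2]), ymax = max(p[, 2]))
}

#' Uniform random point inside a polygon
#'
#' Bounding-box rejection sampling: draw uniform points in the bbox until one
#' falls inside. Deterministic given the R RNG state (call `set.seed()`
#' first); for rectangles the first draw always lands.
#'
#' @param polygon n x 2 vertex matrix.
#' @param n number of points to draw.
#' @param max_attempts rejection cap per requested point; exceeded for
#'   pathologically thin polygons only.
#' @return n x 2 matrix of points strictly inside the polygon.
#' @export
random_point_in_polygon <- function(polygon, n = 1L, max_attempts = 10000L) {
  p <- as_polygon(polygon)
  bb <- polygon_bbox(p)
  out <- matrix(NA_real_, n, 2)
  need <- n
  got <- 0L
  attempts <- 0L
  while (need > 0L) {
    m <- max(need * 2L, 16L)
    attempts <- attempts + m
    if (attempts > max_attempts * n)
      stop("rejection sampling failed after ", attempts, " attempts")
    xs <- stats::runif(m, bb["xmin"], bb["xmax"])
    ys <- stats::runif(m, bb["ymin"], bb["ymax"])
    ok <- point_in_polygon(p, xs, ys)
    take <- min(sum(ok), need)
    if (take > 0L) {
      idx <- which(ok)[seq_len(take)]
      out[got + seq_len(take), ] <- cbind(xs[idx], ys[idx])
      got <- got + take
      need <- need - take
    }
  }
  colnames(out) <- c("x", "y")
  out
}

#' Axis-aligned rectangle as a polygon ring
#' @param xmin,ymin,xmax,ymax rectangle corners in meters.
#' @return 4 x 2 vertex matrix (counter-clockwise).
#' @export
rect_polygon <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

#' Planar Euclidean distance in meters
#'
#' @param a,b points as length-2 vectors, or matrices with columns x, y
#'   (rows paired).
#' @return numeric distance(s), meters.
#' @export
error_distance <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 2)
  if (is.null(dim(b))) b <- matrix(b, ncol = 2)
  if (anyNA(a) || anyNA(b)) stop("missing coordinates in distance computation")
  sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
}
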