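#' Closed planar contour of an apical plane
#'
#' Constructs a validated closed polygon (in micrometres) describing the
#' outline of a cell's apical surface. Vertices are normalized to
#' counter-clockwise order and an explicit duplicate closing vertex is
#' dropped. The polygon must be simple (non-self-intersecting), have at
#' least 4 vertices and positive area.
#'
#' @param vertices two-column numeric matrix (or data.frame) of (x, y)
#'   coordinates in micrometres; the last vertex connects back to the first.
#' @param label free-text label (e.g. a lineage name such as "a6.8").
#' @return An object of class \code{contour2d} with elements
#'   \code{vertices} (CCW matrix) and \code{label}.
#' @examples
#' sq <- contour2d(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' area_centroid(sq)
#' @export
contour2d <- function(vertices, label = "") {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L)
    stop("invalid shape: vertices must be a numeric n x 2 matrix")
  if (anyNA(v) || any(!is.finite(v)))
    stop("invalid shape: non-finite vertex coordinates")
  # drop explicit closing vertex and zero-length edges
  n <- nrow(v)
  if (n >= 2L && all(abs(v[n, ] - v[1, ]) < 1e-12)) v <- v[-n, , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(v))) > 1e-12)
  v <- v[keep, , drop = FALSE]
  if (nrow(v) < 4L)
    stop("invalid shape: a contour needs at least 4 distinct vertices")
  a <- signed_area(v)
  if (abs(a) < 1e-12)
    stop("invalid shape: zero enclosed area")
  if (a < 0) v <- v[nrow(v):1, , drop = FALSE]  # normalize to CCW
  if (!cpp_is_simple(v))
    stop("invalid shape: contour is self-intersecting")
  dimnames(v) <- list(NULL, c("x", "y"))
  structure(list(vertices = v, label = as.character(label)[1]),
            class = "contour2d")
}

signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' @export
print.contour2d <- function(x, ...) {
  ac <- area_centroid(x)
  cat(sprintf("contour2d%s: %d vertices, area %.2f um^2, centroid (%.2f, %.2f)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              nrow(x$vertices), ac$area, ac$centroid[1], ac$centroid[2]))
  invisible(x)
}

#' @export
plot.contour2d <- function(x, add = FALSE, col = "grey30", fill = NA, ...) {
  v <- x$vertices
  if (!add)
    plot(v, type = "n", asp = 1, xlab = "x (um)", ylab = "y (um)", ...)
  polygon(v[, 1], v[, 2], border = col, col = fill)
  invisible(x)
}

#' Area and centroid of a contour
#'
#' Shoelace area and first-moment centroid of the filled polygon.
#'
#' @param contour a \code{\link{contour2d}}.
#' @return list with \code{area} (um^2, positive) and \code{centroid}
#'   (length-2 numeric, um).
#' @export
area_centroid <- function(contour) {
  stopifnot(inherits(contour, "contour2d"))
  v <- contour$vertices
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  list(area = a, centroid = c(x = cx, y = cy))
}

#' Principal axes of a filled polygon
#'
#' Orientation and equivalent-ellipse axis lengths from the second area
#' moments of the filled polygon (robust to uneven vertex spacing from
#' manual tracing, unlike vertex PCA). The major-axis angle follows the
#' axial convention: degrees in [0, 180), counter-clockwise from +x.
#' \code{length_major}/\code{length_minor} are the full axis lengths of the
#' ellipse with the same area and second moments (for an exact ellipse they
#' equal its axis lengths).
#'
#' @param contour a \code{\link{contour2d}}.
#' @param tol isotropy tolerance: the shape is flagged degenerate when the
#'   moment eigenvalue ratio is below \code{1 + tol}, in which case
#'   \code{angle_major} is \code{NA}.
#' @return list of class \code{principal_axes}: \code{angle_major} (deg),
#'   \code{length_major}, \code{length_minor} (um), \code{aspect_ratio},
#'   \code{centroid}, \code{degenerate}.
#' @export
principal_axes <- function(contour, tol = 0.01) {
  stopifnot(inherits(contour, "contour2d"))
  v <- contour$vertices
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  # second moments about the origin, then centralized
  ixx <- sum((y^2 + y * yn + yn^2) * cr) / 12          # integral of y^2 dA
  iyy <- sum((x^2 + x * xn + xn^2) * cr) / 12          # integral of x^2 dA
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  ixx <- ixx - a * cy^2
  iyy <- iyy - a * cx^2
  ixy <- ixy - a * cx * cy
  J <- matrix(c(iyy, ixy, ixy, ixx), 2, 2)  # [int x^2, int xy; int xy, int y^2]
  e <- eigen(J, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  len <- 4 * sqrt(lam / a)  # full axis lengths of the moment-equivalent ellipse
  ar <- if (lam[2] > 0) sqrt(lam[1] / lam[2]) else Inf
  degenerate <- is.finite(ar) && (lam[1] / lam[2] < 1 + tol)
  ang <- if (degenerate) NA_real_ else (atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi) %% 180
  structure(list(angle_major = ang, length_major = len[1], length_minor = len[2],
                 aspect_ratio = ar, centroid = c(x = cx, y = cy),
                 degenerate = degenerate),
            class = "principal_axes")
}

#' @export
print.principal_axes <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("principal axes: degenerate (near-isotropic), lengths %.2f/%.2f um\n",
                x$length_major, x$length_minor))
  else
    cat(sprintf("principal axes: %.1f deg, lengths %.2f/%.2f um (aspect %.2f)\n",
                x$angle_major, x$length_major, x$length_minor, x$aspect_ratio))
  invisible(x)
}

#' Distance from an interior point to the cell cortex along a direction
#'
#' Length of the first intersection of the ray from \code{origin} along
#' \code{direction} with the contour boundary — the length an astral
#' microtubule would grow before reaching the cortex. Non-convex safe: the
#' nearest boundary hit is returned.
#'
#' @param contour a \code{\link{contour2d}}.
#' @param origin numeric (x, y), strictly inside the contour.
#' @param direction numeric (x, y); normalized internally.
#' @return positive length in um.
#' @export
ray_to_boundary <- function(contour, origin, direction) {
  stopifnot(inherits(contour, "contour2d"))
  origin <- as.numeric(origin); direction <- as.numeric(direction)
  if (length(origin) != 2L || length(direction) != 2L)
    stop("origin and direction must be length-2 numeric")
  if (sqrt(sum(direction^2)) < 1e-300) stop("zero direction vector")
  p <- matrix(origin, 1, 2)
  if (!cpp_points_in_polygon(contour$vertices, p) ||
      cpp_dist_to_boundary(contour$vertices, p) < 1e-9)
    stop("origin must be strictly inside the contour")
  L <- cpp_ray_lengths(contour$vertices, origin, matrix(direction, 1, 2))
  if (is.na(L)) stop("ray does not reach the boundary (degenerate geometry)")
  as.numeric(L)
}

# vectorized strict interior test used across the package
points_inside <- function(contour, pts, margin = 1e-9) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  inside <- cpp_points_in_polygon(contour$vertices, pts)
  if (margin > 0) {
    d <- cpp_dist_to_boundary(contour$vertices, pts)
    inside <- inside & d > margin
  }
  inside
}

#' Read a contour from a two-column CSV file
#'
#' @param path CSV with columns x, y (um); a header is auto-detected.
#' @param label contour label.
#' @return a \code{\link{contour2d}}.
#' @export
read_contour_csv <- function(path, label = "") {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[-0-9.]", first)
  d <- read.csv(path, header = has_header)
  contour2d(as.matrix(d[, 1:2]), label = label)
}

#' Write a contour to a two-column CSV file
#'
#' @param contour a \code{\link{contour2d}}.
#' @param path output path.
#' @export
write_contour_csv <- function(contour, path) {
  d <- as.data.frame(contour$vertices)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
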