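#' Triangulated blastomere surface with apical/basolateral face labels
#'
#' Validates a closed triangle mesh: every edge must be shared by exactly two
#' faces with opposite orientation (watertight, orientable, consistent
#' winding). Winding is normalized so the signed volume is positive
#' (outward-facing normals). Every face carries a label, "apical" or
#' "basolateral".
#'
#' @param vertices numeric n x 3 matrix (um).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param face_label character vector of length m with values "apical" or
#'   "basolateral" (recycled if length 1).
#' @return object of class \code{labeled_mesh}.
#' @export
labeled_mesh <- function(vertices, faces, face_label = "basolateral") {
  v <- as.matrix(vertices)
  f <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(v) != 3L || !is.numeric(v)) stop("vertices must be n x 3 numeric")
  if (anyNA(f) || any(f < 1L) || any(f > nrow(v)))
    stop("faces reference vertices out of range")
  face_label <- rep_len(as.character(face_label), nrow(f))
  bad <- !face_label %in% c("apical", "basolateral")
  if (any(bad))
    stop("every face must be labeled 'apical' or 'basolateral'; ",
         sum(bad), " faces are not")
  # watertight + consistent winding: each directed edge appears exactly once
  de <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(de[, 1], de[, 2])
  rkey <- paste(de[, 2], de[, 1])
  if (anyDuplicated(key))
    stop("mesh has inconsistently wound or duplicated faces")
  open_edges <- sum(!(rkey %in% key)) / 1L
  if (open_edges > 0)
    stop("mesh is not watertight: ", open_edges, " open edges")
  m <- structure(list(vertices = v, faces = f, face_label = face_label),
                 class = "labeled_mesh")
  if (mesh_signed_volume(m) < 0) {  # flip to outward winding
    m$faces <- f[, c(1, 3, 2)]
  }
  m
}

mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

face_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' @export
print.labeled_mesh <- function(x, ...) {
  va <- mesh_volume_area(x)
  cat(sprintf(paste0("labeled_mesh: %d vertices, %d faces (%d apical), ",
                     "V %.1f um^3, A %.1f um^2, sphericity %.3f\n"),
              nrow(x$vertices), nrow(x$faces), sum(x$face_label == "apical"),
              va$volume, va$area, sphericity(x)))
  invisible(x)
}

#' Enclosed volume and total surface area of a mesh
#'
#' Volume by the signed tetrahedron sum (positive for outward winding,
#' which the constructor enforces); area as the sum of triangle areas.
#'
#' @param mesh a \code{\link{labeled_mesh}}.
#' @return list with \code{volume} (um^3) and \code{area} (um^2).
#' @export
mesh_volume_area <- function(mesh) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  list(volume = mesh_signed_volume(mesh), area = sum(face_areas(mesh)))
}

#' Sphericity of a closed surface
#'
#' \eqn{\Psi = \pi^{1/3} (6V)^{2/3} / A}: 1 for a sphere, smaller for more
#' complex polyhedral shapes; scale-invariant. Used to quantify how far a
#' blastomere deviates from a round (mitotically rounded) cell.
#'
#' @param mesh a \code{\link{labeled_mesh}}.
#' @return sphericity in (0, 1].
#' @export
sphericity <- function(mesh) {
  va <- mesh_volume_area(mesh)
  pi^(1 / 3) * (6 * va$volume)^(2 / 3) / va$area
}

#' Apical surface ratio
#'
#' Area of the apical (cell-contact-free) surface divided by the total cell
#' surface area. Rises as a blastomere rounds up at mitosis and expands its
#' apical surface.
#'
#' @param mesh a \code{\link{labeled_mesh}}.
#' @return ratio in [0, 1].
#' @export
apical_surface_ratio <- function(mesh) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  ar <- face_areas(mesh)
  sum(ar[mesh$face_label == "apical"]) / sum(ar)
}

#' Extract the apical plane through the spindle poles
#'
#' Among the one-parameter family of planes containing the pole-to-pole
#' axis, finds the plane that best separates apical from basolateral
#' membrane (area-weighted, faces assigned by which side their centroid
#' falls on). The rotation angle about the pole axis is scanned on a 1
#' degree grid and refined by golden-section search. The mesh cross-section
#' in the chosen plane becomes the 2D cell outline handed to the spindle
#' model, with the poles projected into plane coordinates.
#'
#' @param mesh a \code{\link{labeled_mesh}}.
#' @param poles 2 x 3 matrix of the two spindle-pole coordinates (um), both
#'   strictly inside the mesh.
#' @param phi_step scan resolution about the pole axis, degrees.
#' @return list with \code{plane} (point, normal oriented toward the apical
#'   side, separation_score in [0.5, 1]), \code{contour}
#'   (\code{\link{contour2d}} of the cross-section, plane coordinates with
#'   the pole axis along +x and origin at the pole midpoint), and
#'   \code{poles2d} (\code{\link{spindle_axis}} of the projected poles).
#' @export
extract_apical_plane <- function(mesh, poles, phi_step = 1) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  poles <- matrix(as.numeric(poles), ncol = 3)
  if (nrow(poles) != 2L) stop("poles must be a 2 x 3 matrix")
  axis_vec <- poles[2, ] - poles[1, ]
  len <- sqrt(sum(axis_vec^2))
  if (len < 1e-9) stop("coincident spindle poles")
  u <- axis_vec / len
  mid <- colMeans(poles)
  # orthonormal frame (u, v0, w0)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v0 <- ref - sum(ref * u) * u
  v0 <- v0 / sqrt(sum(v0^2))
  w0 <- c(u[2] * v0[3] - u[3] * v0[2],
          u[3] * v0[1] - u[1] * v0[3],
          u[1] * v0[2] - u[2] * v0[1])
  fc <- face_centroids(mesh)
  ar <- face_areas(mesh)
  apical <- mesh$face_label == "apical"
  total <- sum(ar)
  dv <- sweep(fc, 2, mid)          # centroid offsets from the pole midpoint
  pv <- as.numeric(dv %*% v0)
  pw <- as.numeric(dv %*% w0)
  score_phi <- function(phi) {
    # plane normal n(phi) = cos(phi) v0 + sin(phi) w0 (always orthogonal to u)
    s <- pv * cos(phi) + pw * sin(phi)   # signed side of each face centroid
    apical_pos <- sum(ar[apical & s > 0]) + sum(ar[!apical & s <= 0])
    max(apical_pos, total - apical_pos) / total
  }
  phis <- seq(0, pi, by = phi_step * pi / 180)
  scores <- vapply(phis, score_phi, numeric(1))
  best <- which.max(scores)
  # golden-section refinement in the bracketing interval
  lo <- phis[max(best - 1, 1)]; hi <- phis[min(best + 1, length(phis))]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- score_phi(x1); f2 <- score_phi(x2)
  for (i in seq_len(40)) {
    if (f1 >= f2) { b <- x2; x2 <- x1; f2 <- f1; x1 <- b - gr * (b - a); f1 <- score_phi(x1) }
    else { a <- x1; x1 <- x2; f1 <- f2; x2 <- a + gr * (b - a); f2 <- score_phi(x2) }
  }
  phi <- (a + b) / 2
  sc <- score_phi(phi)
  if (scores[best] > sc) { phi <- phis[best]; sc <- scores[best] }
  n <- cos(phi) * v0 + sin(phi) * w0
  # orient the normal toward the apical side
  s <- pv * cos(phi) + pw * sin(phi)
  if (sum(ar[apical & s > 0]) + sum(ar[!apical & s <= 0]) < total / 2) n <- -n
  if (sc < 0.6)
    warning("low separation score (", sprintf("%.2f", sc),
            "): face labels carry little planar apical/basolateral signal")
  cs <- cross_section(mesh, mid, n, u)
  list(plane = list(point = mid, normal = n, separation_score = sc),
       contour = cs$contour,
       poles2d = spindle_axis(c(-len / 2, 0), c(len / 2, 0)))
}

# Cross-section of the mesh with the plane (point p0, normal n); returns the
# loop containing the pole midpoint as a contour2d in (e1, e2) = (u, n x u)
# plane coordinates with origin at p0.
cross_section <- function(mesh, p0, n, u) {
  v <- mesh$vertices; f <- mesh$faces
  s <- as.numeric(sweep(v, 2, p0) %*% n)
  # avoid vertices lying exactly in the plane
  if (any(abs(s) < 1e-9)) {
    eps <- 1e-7 * max(abs(s), 1)
    s <- as.numeric(sweep(v, 2, p0 + eps * n) %*% n) + eps
    s[abs(s) < 1e-12] <- 1e-12
  }
  sf <- matrix(s[f], ncol = 3)
  crossed <- which(apply(sf, 1, function(r) any(r > 0) && any(r < 0)))
  if (length(crossed) < 3) stop("plane does not cross the mesh")
  edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  # per crossed face: the two crossed (sign-change) edges
  face_edges <- lapply(crossed, function(fi) {
    idx <- f[fi, ]
    pairs <- rbind(idx[c(1, 2)], idx[c(2, 3)], idx[c(3, 1)])
    hit <- s[pairs[, 1]] * s[pairs[, 2]] < 0
    pairs[hit, , drop = FALSE]
  })
  keys <- lapply(face_edges, function(p) edge_key(p[, 1], p[, 2]))
  edge2face <- new.env(parent = emptyenv())
  for (k in seq_along(crossed)) {
    for (ek in keys[[k]]) {
      assign(ek, c(if (exists(ek, edge2face)) get(ek, edge2face), k), edge2face)
    }
  }
  ipoint <- function(i, j) {
    t <- s[i] / (s[i] - s[j])
    v[i, ] + t * (v[j, ] - v[i, ])
  }
  visited <- logical(length(crossed))
  loops <- list()
  for (start in seq_along(crossed)) {
    if (visited[start]) next
    loop_pts <- list()
    k <- start
    ek <- keys[[k]][1]
    repeat {
      visited[k] <- TRUE
      pair <- face_edges[[k]][match(ek, keys[[k]]), ]
      loop_pts[[length(loop_pts) + 1L]] <- ipoint(pair[1], pair[2])
      ek_next <- setdiff(keys[[k]], ek)[1]
      pair2 <- face_edges[[k]][match(ek_next, keys[[k]]), ]
      loop_pts[[length(loop_pts) + 1L]] <- ipoint(pair2[1], pair2[2])
      nb <- setdiff(get(ek_next, edge2face), k)
      if (length(nb) == 0 || visited[nb[1]]) break
      k <- nb[1]
      ek <- ek_next
    }
    loops[[length(loops) + 1L]] <- do.call(rbind, loop_pts)
  }
  e1 <- u
  e2 <- c(n[2] * u[3] - n[3] * u[2],
          n[3] * u[1] - n[1] * u[3],
          n[1] * u[2] - n[2] * u[1])
  to2d <- function(P) {
    d <- sweep(P, 2, p0)
    cbind(as.numeric(d %*% e1), as.numeric(d %*% e2))
  }
  polys <- lapply(loops, function(L) {
    P <- to2d(L)
    keep <- c(TRUE, rowSums(abs(diff(P))) > 1e-9)
    P[keep, , drop = FALSE]
  })
  polys <- Filter(function(P) nrow(P) >= 4, polys)
  if (length(polys) == 0) stop("degenerate cross-section")
  if (length(polys) > 1) {
    contains <- vapply(polys, function(P) {
      as.logical(cpp_points_in_polygon(P, matrix(c(0, 0), 1, 2)))
    }, logical(1))
    if (any(contains)) {
      if (sum(!contains) > 0)
        warning("cross-section has ", length(polys),
                " loops; keeping the loop containing the spindle poles")
      polys <- polys[contains][1]
    } else {
      warning("no cross-section loop contains the pole midpoint; keeping the largest")
      polys <- polys[order(-vapply(polys, function(P) abs(signed_area(P)), numeric(1)))][1]
    }
  }
  list(contour = contour2d(polys[[1]]))
}
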