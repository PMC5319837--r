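#' Generate blastomere-like apical contours
#'
#' Seeded generator of simple, counter-clockwise polygons emulating the
#' apical outlines of cleavage-stage blastomeres: anisotropic convex-ish
#' shapes with aspect ratios of roughly 1.1-3 and major-axis lengths of a
#' few tens of micrometres. Four families: \code{"ellipse"},
#' \code{"superellipse"} (boxier outline, exponent 2.5-4),
#' \code{"fourier_blob"} (ellipse with low-order radial harmonics, the
#' closest mimic of manually traced outlines) and \code{"flattened"}
#' (strongly elongated superellipse). Each contour records its ground-truth
#' construction angle and aspect ratio.
#'
#' @param n number of contours.
#' @param family shape family.
#' @param aspect_range range of aspect ratios (>= 1).
#' @param size_range range of major-axis lengths, um.
#' @param fourier_noise amplitude of the radial harmonics (fourier_blob).
#' @param n_points vertices per contour.
#' @param seed integer seed; identical seeds give identical output.
#' @return list of \code{\link{contour2d}} with attribute \code{truth}, a
#'   data.frame with columns \code{label}, \code{angle}, \code{aspect},
#'   \code{length_major}.
#' @export
make_contours <- function(n, family = c("fourier_blob", "ellipse",
                                        "superellipse", "flattened"),
                          aspect_range = c(1.1, 3), size_range = c(18, 30),
                          fourier_noise = 0.04, n_points = 48, seed = NULL) {
  family <- match.arg(family)
  stopifnot(n >= 1, aspect_range[1] >= 1, diff(aspect_range) >= 0,
            all(size_range > 0), n_points >= 8)
  with_seed(seed, {
    out <- vector("list", n)
    truth <- data.frame(label = character(n), angle = numeric(n),
                        aspect = numeric(n), length_major = numeric(n))
    t <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
    for (i in seq_len(n)) {
      lab <- sprintf("syn%03d", i)
      for (attempt in seq_len(100)) {
        aspect <- runif(1, aspect_range[1], aspect_range[2])
        size <- runif(1, size_range[1], size_range[2])
        ang <- runif(1, 0, 180)
        if (family == "flattened")
          aspect <- runif(1, max(2, mean(aspect_range)), max(aspect_range, 2.2))
        a <- size / 2
        b <- a / aspect
        base <- switch(family,
          ellipse = cbind(a * cos(t), b * sin(t)),
          flattened = ,
          superellipse = {
            p <- runif(1, 2.5, 4)
            r <- (abs(cos(t) / a)^p + abs(sin(t) / b)^p)^(-1 / p)
            cbind(r * cos(t), r * sin(t))
          },
          fourier_blob = {
            pert <- rep(0, length(t))
            for (k in 2:5)
              pert <- pert + runif(1, -1, 1) * fourier_noise * (2 / k) *
                cos(k * t + runif(1, 0, 2 * pi))
            cbind(a * cos(t) * (1 + pert), b * sin(t) * (1 + pert))
          })
        th <- ang * pi / 180
        R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
        v <- base %*% t(R)
        ok <- tryCatch({ c2 <- contour2d(v, label = lab); TRUE },
                       error = function(e) FALSE)
        if (ok) break
        if (attempt == 100) stop("could not generate a simple contour after 100 tries")
      }
      out[[i]] <- c2
      truth$label[i] <- lab
      truth$angle[i] <- ang
      truth$aspect[i] <- aspect
      truth$length_major[i] <- size
    }
    attr(out, "truth") <- truth
    out
  })
}

#' Synthesize noisy spindle observations with planted structure
#'
#' For each contour, runs the pulling-force model to obtain the predicted
#' spindle, then emits a prophase and a metaphase observation per cell. The
#' metaphase observed axis is the model prediction perturbed by wrapped
#' axial normal noise, and its center by isotropic Gaussian noise. A
#' fraction of cells are planted "rotators" (mimicking cells undergoing
#' oriented cell division, whose spindle only aligns with the apical long
#' axis at metaphase): their prophase axis is offset from the metaphase
#' axis by Uniform(45, 90) degrees with random sign; all other cells keep
#' their metaphase axis at prophase.
#'
#' @param contours list of \code{\link{contour2d}} (see
#'   \code{\link{make_contours}}).
#' @param params \code{\link{model_params}}; the generator always uses
#'   \code{spindle_length_mode = "fraction"} since no observation exists yet.
#' @param angular_noise_sd axial angular noise s.d., degrees.
#' @param rotating_fraction proportion of planted rotating (OCD) cells.
#' @param center_noise_sd center noise s.d., um.
#' @param seed integer seed.
#' @return list with \code{cells} (list of \code{\link{cell_record}}, two
#'   phases per cell) and \code{ground_truth} (data.frame: label,
#'   true_angle, true_center_x/y, rotates, meta_angle, pro_angle).
#' @export
synthesize_observations <- function(contours, params = model_params(),
                                    angular_noise_sd = 15,
                                    rotating_fraction = 0,
                                    center_noise_sd = 1, seed = NULL) {
  stopifnot(angular_noise_sd >= 0, rotating_fraction >= 0, rotating_fraction <= 1)
  params$spindle_length_mode <- "fraction"
  lineages <- c("a6.5", "a6.6", "a6.7", "a6.8", "b6.5", "b6.6",
                "A6.1", "A6.2", "A6.4", "B6.1", "B6.2", "B6.4")
  preds <- lapply(contours, predict_spindle, params = params)
  with_seed(seed, {
    cells <- list()
    gt <- data.frame(label = character(0), true_angle = numeric(0),
                     true_center_x = numeric(0), true_center_y = numeric(0),
                     rotates = logical(0), meta_angle = numeric(0),
                     pro_angle = numeric(0))
    for (i in seq_along(contours)) {
      ct <- contours[[i]]
      pred <- preds[[i]]
      tru_ang <- axis_angle(pred$axis)
      tru_ctr <- axis_center(pred$axis)
      len <- axis_length(pred$axis)
      rotates <- runif(1) < rotating_fraction
      make_axis <- function(ang) {
        # redraw center noise until both poles are interior
        for (try in seq_len(100)) {
          ctr <- tru_ctr + rnorm(2, 0, center_noise_sd / max(1, try %/% 20))
          ax <- axis_from_cal(ctr, ang, len)
          if (all(points_inside(ct, rbind(ax$pole_a, ax$pole_b), margin = 1e-6)))
            return(ax)
        }
        axis_from_cal(tru_ctr, ang, len)  # fall back to the noiseless center
      }
      meta_ang <- (tru_ang + rnorm(1, 0, angular_noise_sd)) %% 180
      pro_ang <- if (rotates)
        (meta_ang + sample(c(-1, 1), 1) * runif(1, 45, 90)) %% 180 else meta_ang
      lab <- ct$label
      lin <- lineages[(i - 1) %% length(lineages) + 1]
      cells[[length(cells) + 1L]] <- cell_record(
        cell_id = paste0(lab, "_prophase"), lineage = lin, stage = 32,
        phase = "prophase", group = "control", contour = ct,
        observed = make_axis(pro_ang))
      cells[[length(cells) + 1L]] <- cell_record(
        cell_id = paste0(lab, "_metaphase"), lineage = lin, stage = 32,
        phase = "metaphase", group = "control", contour = ct,
        observed = make_axis(meta_ang))
      gt <- rbind(gt, data.frame(label = lab, true_angle = tru_ang,
                                 true_center_x = tru_ctr[1],
                                 true_center_y = tru_ctr[2],
                                 rotates = rotates, meta_angle = meta_ang,
                                 pro_angle = pro_ang))
    }
    list(cells = cells, ground_truth = gt)
  })
}

# icosahedron subdivided k times and projected onto the unit sphere
icosphere_unit <- function(subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(parent = emptyenv())
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (exists(key, midcache)) return(get(key, midcache))
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- m
      assign(key, nv, midcache)
      nv
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (t in seq_len(nrow(f))) {
      i <- f[t, 1]; j <- f[t, 2]; k <- f[t, 3]
      a <- midpoint(i, j); b <- midpoint(j, k); c_ <- midpoint(k, i)
      nf[4 * t - 3, ] <- c(i, a, c_)
      nf[4 * t - 2, ] <- c(j, b, a)
      nf[4 * t - 1, ] <- c(k, c_, b)
      nf[4 * t, ] <- c(a, b, c_)
    }
    v <- do.call(rbind, vlist)
    v <- v / sqrt(rowSums(v^2))
    f <- nf
  }
  list(vertices = v, faces = f)
}

#' Generate a labeled test mesh with a known apical/basolateral partition
#'
#' Fixture meshes for the 3D shape metrics: a subdivided icosphere, a box,
#' a 2:1:1 ellipsoid or a 2:2:1 flattened ellipsoid, each with per-face
#' apical/basolateral labels. Labeling rules: \code{"hemisphere"} (apical =
#' faces whose centroid has z > 0), \code{"cap_fraction"} (apical = a polar
#' cap holding a given fraction of the surface area; exact for the sphere),
#' or \code{"random"} (no planar signal). For the planar rules the
#' ground-truth separating plane is recorded.
#'
#' @param kind mesh shape.
#' @param label_rule labeling rule.
#' @param radius base radius, um.
#' @param subdivisions icosphere subdivision level.
#' @param cap_fraction target apical area fraction for
#'   \code{"cap_fraction"}.
#' @param seed seed (used by \code{"random"} labels).
#' @return a \code{\link{labeled_mesh}} with attribute \code{ground_truth}
#'   (list with \code{plane_point}, \code{plane_normal}, or NULL for random
#'   labels).
#' @export
make_labeled_mesh <- function(kind = c("icosphere", "box", "ellipsoid", "flattened"),
                              label_rule = c("hemisphere", "cap_fraction", "random"),
                              radius = 10, subdivisions = 4,
                              cap_fraction = 0.2, seed = NULL) {
  kind <- match.arg(kind)
  label_rule <- match.arg(label_rule)
  if (kind == "box") {
    r <- radius
    v <- r * rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
                   c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
    f <- rbind(c(1, 4, 3), c(1, 3, 2), c(5, 6, 7), c(5, 7, 8),
               c(1, 2, 6), c(1, 6, 5), c(3, 4, 8), c(3, 8, 7),
               c(1, 5, 8), c(1, 8, 4), c(2, 3, 7), c(2, 7, 6))
    unitv <- v / r
  } else {
    ico <- icosphere_unit(subdivisions)
    unitv <- ico$vertices
    f <- ico$faces
    scale <- switch(kind, icosphere = c(1, 1, 1), ellipsoid = c(2, 1, 1),
                    flattened = c(2, 2, 1))
    v <- sweep(unitv, 2, radius * scale, `*`)
  }
  cent_unit <- (unitv[f[, 1], ] + unitv[f[, 2], ] + unitv[f[, 3], ]) / 3
  lab <- switch(label_rule,
    hemisphere = ifelse(cent_unit[, 3] > 0, "apical", "basolateral"),
    cap_fraction = {
      z0 <- 1 - 2 * cap_fraction  # spherical cap: area fraction = (1 - z0)/2
      ifelse(cent_unit[, 3] > z0, "apical", "basolateral")
    },
    random = with_seed(seed,
      ifelse(runif(nrow(f)) < 0.5, "apical", "basolateral")))
  m <- labeled_mesh(v, f, lab)
  attr(m, "ground_truth") <- switch(label_rule,
    hemisphere = list(plane_point = c(0, 0, 0), plane_normal = c(0, 0, 1)),
    cap_fraction = list(plane_point = c(0, 0, (1 - 2 * cap_fraction) * radius),
                        plane_normal = c(0, 0, 1)),
    random = NULL)
  m
}

#' Generate two-hemisphere mitotic-entry timing data
#'
#' Vegetal entry times ~ Normal(t0, jitter_sd); animal entry times ~
#' Normal(t0 + dt, jitter_sd): the animal hemisphere enters mitosis
#' \code{dt} minutes after the vegetal one (about 15 min in control
#' embryos, 6-8 min when the asynchrony is experimentally reduced).
#'
#' @param dt planted asynchrony in minutes.
#' @param jitter_sd per-cell jitter s.d., minutes.
#' @param n_per_group cells per hemisphere.
#' @param t0 vegetal mean entry time, minutes.
#' @param seed integer seed.
#' @return list with numeric vectors \code{animal} and \code{vegetal}.
#' @export
make_timing_data <- function(dt = 15, jitter_sd = 1, n_per_group = 10,
                             t0 = 30, seed = NULL) {
  stopifnot(n_per_group >= 1, jitter_sd >= 0)
  with_seed(seed, list(
    animal = rnorm(n_per_group, t0 + dt, jitter_sd),
    vegetal = rnorm(n_per_group, t0, jitter_sd)))
}
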