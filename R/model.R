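#' Parameters of the cortical pulling-force model
#'
#' The model places a spindle (two poles joined by an axis) inside the 2D
#' apical outline. Astral microtubules radiate from each pole along
#' \code{n_rays} fixed, equally spaced lab-frame directions, reach the
#' cortex, and pull the pole toward it with a force that scales with
#' microtubule length L as \eqn{f = L^\beta}. For each candidate
#' orientation the spindle center is placed at mechanical (net-force)
#' equilibrium; the torque about the spindle center then defines an
#' orientation energy landscape whose minima are the stable spindle
#' orientations.
#'
#' @param beta force-length exponent (>= 0). Default 1: forces proportional
#'   to microtubule length. In a planar ray fan the exponent 3 produces a
#'   net force that is exactly proportional to the centroid offset and
#'   torque-free (a parallel-axis identity), so shape can only be sensed
#'   for beta below 3; predictions are insensitive to beta within 1-2.
#' @param n_rays rays per pole over 360 degrees (>= 16).
#' @param dtheta orientation grid step in degrees (0, 10].
#' @param spindle_length_mode \code{"observed"} (use the observed pole
#'   separation) or \code{"fraction"} (use \code{spindle_fraction} of the
#'   contour's major-axis length).
#' @param spindle_fraction fraction of \code{length_major} used when
#'   \code{spindle_length_mode = "fraction"}.
#' @param center_mode \code{"optimize"} (center balanced per orientation by
#'   minimizing the net-force magnitude, seeded at the centroid) or
#'   \code{"centroid"} (fixed at the centroid).
#' @param relief_tol minimum relative landscape relief, (max E - min E)
#'   divided by the mean astral potential, below which the landscape is
#'   flagged degenerate. Circles sit at ~1e-9 (discretization noise);
#'   shapes with aspect ratio 1.1 around 1e-3; default 1e-4.
#' @return object of class \code{model_params}.
#' @export
model_params <- function(beta = 1, n_rays = 180, dtheta = 1,
                         spindle_length_mode = c("observed", "fraction"),
                         spindle_fraction = 0.4,
                         center_mode = c("optimize", "centroid"),
                         relief_tol = 1e-4) {
  spindle_length_mode <- match.arg(spindle_length_mode)
  center_mode <- match.arg(center_mode)
  stopifnot(beta >= 0, n_rays >= 16, dtheta > 0, dtheta <= 10,
            spindle_fraction > 0, spindle_fraction < 1, relief_tol >= 0)
  structure(list(beta = beta, n_rays = as.integer(n_rays), dtheta = dtheta,
                 spindle_length_mode = spindle_length_mode,
                 spindle_fraction = spindle_fraction,
                 center_mode = center_mode, relief_tol = relief_tol),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(paste0("model_params: beta %g, %d rays/pole, dtheta %g deg, ",
                     "length %s%s, center %s\n"),
              x$beta, x$n_rays, x$dtheta, x$spindle_length_mode,
              if (x$spindle_length_mode == "fraction")
                sprintf(" (%.2f of major axis)", x$spindle_fraction) else "",
              x$center_mode))
  invisible(x)
}

#' Undirected spindle axis defined by its two pole positions
#'
#' @param pole_a,pole_b numeric (x, y) pole coordinates in um; must differ.
#' @return object of class \code{spindle_axis}.
#' @export
spindle_axis <- function(pole_a, pole_b) {
  pole_a <- as.numeric(pole_a); pole_b <- as.numeric(pole_b)
  stopifnot(length(pole_a) == 2L, length(pole_b) == 2L)
  if (sqrt(sum((pole_b - pole_a)^2)) < 1e-12)
    stop("spindle poles must be distinct")
  structure(list(pole_a = pole_a, pole_b = pole_b), class = "spindle_axis")
}

#' @rdname spindle_axis
#' @param axis a \code{spindle_axis}.
#' @export
axis_center <- function(axis) (axis$pole_a + axis$pole_b) / 2

#' @rdname spindle_axis
#' @export
axis_length <- function(axis) sqrt(sum((axis$pole_b - axis$pole_a)^2))

#' @rdname spindle_axis
#' @export
axis_angle <- function(axis) {
  d <- axis$pole_b - axis$pole_a
  (atan2(d[2], d[1]) * 180 / pi) %% 180
}

#' @export
print.spindle_axis <- function(x, ...) {
  cat(sprintf("spindle_axis: center (%.2f, %.2f), angle %.1f deg, length %.2f um\n",
              axis_center(x)[1], axis_center(x)[2], axis_angle(x), axis_length(x)))
  invisible(x)
}

# spindle_axis from center/angle/length
axis_from_cal <- function(center, angle_deg, length) {
  u <- c(cos(angle_deg * pi / 180), sin(angle_deg * pi / 180))
  spindle_axis(center - length / 2 * u, center + length / 2 * u)
}

#' Total astral potential of one spindle placement
#'
#' Sums \eqn{L_i^{\beta+1}/(\beta+1)} over all 2 \code{n_rays} astral rays
#' (both poles, fixed equally spaced lab-frame directions), where L_i is
#' the distance from the pole to the first cortex intersection — the
#' potential whose per-ray derivative along the microtubule is the pulling
#' force \eqn{f = L^\beta}.
#'
#' Note two exact identities of the uniform planar fan: at beta = 1 the sum
#' approximates \eqn{2 \times} the cell area regardless of placement, and
#' at beta = 3 it approximates four times the polar second area moment
#' about the pole, which by the parallel-axis theorem depends on the pole
#' only through its distance to the centroid. This scalar therefore cannot
#' orient a spindle at those exponents, which is why predictions are
#' computed from the net force and torque (see
#' \code{\link{placement_force}}, \code{\link{predict_spindle}}) rather
#' than by minimizing it.
#'
#' @param contour a \code{\link{contour2d}}.
#' @param center numeric (x, y) spindle center, um.
#' @param angle axial orientation in degrees.
#' @param length pole-to-pole distance, um.
#' @param params a \code{\link{model_params}}.
#' @return potential (arbitrary units, positive). Errors if either pole
#'   falls on or outside the boundary.
#' @export
placement_energy <- function(contour, center, angle, length,
                             params = model_params()) {
  stopifnot(inherits(contour, "contour2d"), inherits(params, "model_params"))
  E <- cpp_placement_potential(contour$vertices, center[1], center[2],
                               angle, length, params$beta, params$n_rays)
  if (!is.finite(E))
    stop("infeasible placement: a spindle pole lies on or outside the contour")
  E
}

#' Net astral force and torque of one spindle placement
#'
#' The net pulling force \eqn{F = \sum_i L_i^\beta \hat d_i} summed over
#' both poles' ray fans, and the torque of those forces about the spindle
#' center. At mechanical equilibrium both vanish.
#'
#' @inheritParams placement_energy
#' @return named numeric: \code{Fx}, \code{Fy}, \code{torque},
#'   \code{potential}.
#' @export
placement_force <- function(contour, center, angle, length,
                            params = model_params()) {
  stopifnot(inherits(contour, "contour2d"), inherits(params, "model_params"))
  out <- cpp_placement_force(contour$vertices, center[1], center[2],
                             angle, length, params$beta, params$n_rays)
  if (anyNA(out))
    stop("infeasible placement: a spindle pole lies on or outside the contour")
  out
}

#' Orientation energy landscape of a contour
#'
#' For each axial orientation on the [0, 180) grid the spindle center is
#' balanced (net astral force minimized; \code{center_mode = "centroid"}
#' keeps it fixed) and the torque about the spindle center is recorded.
#' The landscape is the rotational potential
#' \eqn{E(\theta) = -\int \tau\, d\theta} (drift-corrected so E is
#' 180-degree periodic; \eqn{\tau = -dE/d\theta} holds exactly on the
#' grid). Stable orientations are minima of E.
#'
#' @inheritParams placement_energy
#' @param length spindle length in um.
#' @return object of class \code{energy_landscape}: \code{angles},
#'   \code{energies} (<= 0, max pinned at 0), \code{torques} (per radian),
#'   \code{centers}, \code{potentials}, \code{force_residual},
#'   \code{feasible}, \code{relief}, \code{degenerate}.
#' @export
energy_landscape <- function(contour, length, params = model_params()) {
  stopifnot(inherits(contour, "contour2d"), inherits(params, "model_params"))
  pa <- principal_axes(contour, tol = 0)
  angles <- seq(0, 180 - params$dtheta / 2, by = params$dtheta)
  sc <- cpp_force_scan(contour$vertices, angles, length, params$beta,
                       params$n_rays, params$center_mode == "optimize",
                       pa$centroid[1], pa$centroid[2],
                       0.05 * pa$length_major, 0.5, 0.005)
  tau <- sc$torque
  feasible <- sc$feasible
  if (all(feasible)) {
    taut <- tau - mean(tau)                    # enforce periodic closure
    dth <- params$dtheta * pi / 180            # integrate over radians
    E <- -c(0, cumsum((taut[-length(taut)] + taut[-1]) / 2 * dth))
    E <- E - max(E)
    relief <- (max(E) - min(E)) / mean(sc$potential)
  } else {
    E <- rep(NA_real_, length(angles))
    relief <- NA_real_
  }
  structure(list(angles = angles, energies = E, torques = tau,
                 centers = cbind(x = sc$cx, y = sc$cy),
                 potentials = sc$potential, force_residual = sc$force_residual,
                 feasible = feasible, relief = relief,
                 degenerate = !all(feasible) || relief < params$relief_tol,
                 length = length, params = params),
            class = "energy_landscape")
}

#' Torque profile of an energy landscape
#'
#' Central-difference torque \eqn{\tau(\theta) = -dE/d\theta} on the
#' periodic (180 degree) orientation grid, in energy units per radian.
#' Zero crossings with positive energy curvature are stable equilibria.
#'
#' @param landscape an \code{\link{energy_landscape}}.
#' @return data.frame with columns \code{angle} and \code{torque}.
#' @export
torque <- function(landscape) {
  stopifnot(inherits(landscape, "energy_landscape"))
  E <- landscape$energies
  n <- length(E)
  dth <- diff(landscape$angles[1:2]) * pi / 180
  Em <- E[c(n, 1:(n - 1))]
  Ep <- E[c(2:n, 1)]
  data.frame(angle = landscape$angles, torque = -(Ep - Em) / (2 * dth))
}

#' @export
print.energy_landscape <- function(x, ...) {
  if (all(x$feasible)) {
    i <- which.min(x$energies)
    cat(sprintf(paste0("energy_landscape: %d orientations, relief %.2e%s, ",
                       "minimum at %.1f deg\n"),
                length(x$angles), x$relief,
                if (x$degenerate) " (degenerate)" else "", x$angles[i]))
  } else {
    cat(sprintf("energy_landscape: %d orientations, %d infeasible\n",
                length(x$angles), sum(!x$feasible)))
  }
  invisible(x)
}

#' @export
plot.energy_landscape <- function(x, ...) {
  plot(x$angles, x$energies, type = "l", xlab = "orientation (deg)",
       ylab = "rotational energy (a.u.)", ...)
  if (all(x$feasible)) {
    i <- which.min(x$energies)
    points(x$angles[i], x$energies[i], pch = 19, col = "firebrick")
  }
  invisible(x)
}

#' Write an energy landscape as CSV
#'
#' Columns: theta_deg, energy, center_x, center_y.
#'
#' @param landscape an \code{\link{energy_landscape}}.
#' @param path output path.
#' @export
write_landscape_csv <- function(landscape, path) {
  d <- data.frame(theta_deg = landscape$angles, energy = landscape$energies,
                  center_x = landscape$centers[, 1],
                  center_y = landscape$centers[, 2])
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Predict spindle position and orientation from the apical outline
#'
#' Assays all orientations in the 2D shape: per orientation the spindle
#' center is placed at net-force balance, the torque about the center is
#' integrated into the rotational energy landscape, and the prediction is
#' the orientation of minimum energy (the stable mechanical equilibrium,
#' where the torque crosses zero), refined by linear interpolation of the
#' torque between the bracketing grid points. The spindle length is the
#' observed pole separation (\code{spindle_length_mode = "observed"}) or a
#' fixed fraction of the major-axis length (\code{"fraction"}); either way
#' it is shrunk in 5\% steps until both poles are interior at every
#' orientation on the grid.
#'
#' @param contour a \code{\link{contour2d}}.
#' @param observed observed \code{\link{spindle_axis}} (required when
#'   \code{spindle_length_mode = "observed"}).
#' @param params a \code{\link{model_params}}.
#' @return object of class \code{spindle_prediction}: \code{axis} (the
#'   predicted \code{\link{spindle_axis}}), \code{landscape},
#'   \code{params}, \code{contour}, \code{degenerate}. Near-isotropic
#'   shapes are flagged degenerate; the reported angle (lowest-energy grid
#'   angle, ties broken toward 0) is then unreliable.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 49)[-49]
#' ell <- contour2d(cbind(20 * cos(th), 10 * sin(th)))
#' p <- predict_spindle(ell, params = model_params(spindle_length_mode = "fraction"))
#' coef(p)
#' @export
predict_spindle <- function(contour, observed = NULL, params = model_params()) {
  stopifnot(inherits(contour, "contour2d"), inherits(params, "model_params"))
  pa <- principal_axes(contour, tol = 0)
  len <- if (params$spindle_length_mode == "observed") {
    if (is.null(observed))
      stop("spindle_length_mode = 'observed' requires an observed spindle_axis")
    axis_length(observed)
  } else params$spindle_fraction * pa$length_major
  ls <- NULL
  for (i in seq_len(200)) {
    ls <- energy_landscape(contour, len, params)
    if (all(ls$feasible)) break
    len <- len * 0.95
  }
  if (!all(ls$feasible))
    stop("no feasible placement: spindle longer than any interior chord")
  if (i > 1) {
    # clamped lengths get one extra step so feasibility is not knife-edge
    len <- len * 0.95
    ls <- energy_landscape(contour, len, params)
  }
  E <- ls$energies
  i <- which.min(E)  # first minimum: exact ties break toward 0 degrees
  ang <- ls$angles[i]
  ctr <- ls$centers[i, ]
  if (!ls$degenerate) {
    # refine by the torque zero crossing bracketing the energy minimum
    n <- length(E)
    taut <- ls$torques - mean(ls$torques)
    im <- if (i == 1) n else i - 1
    ip <- if (i == n) 1 else i + 1
    ref <- NA_real_
    if (is.finite(taut[im]) && taut[im] > 0 && taut[i] <= 0)
      ref <- ls$angles[im] + params$dtheta * taut[im] / (taut[im] - taut[i])
    else if (is.finite(taut[ip]) && taut[i] > 0 && taut[ip] <= 0)
      ref <- ls$angles[i] + params$dtheta * taut[i] / (taut[i] - taut[ip])
    if (is.finite(ref)) {
      ang <- ref %% 180
      sc <- cpp_force_scan(contour$vertices, ang, ls$length, params$beta,
                           params$n_rays, params$center_mode == "optimize",
                           ctr[1], ctr[2], 0.5, 0.5, 0.005)
      if (sc$feasible[1]) ctr <- c(sc$cx[1], sc$cy[1])
    }
  }
  structure(list(axis = axis_from_cal(ctr, ang, ls$length),
                 landscape = ls, params = params, contour = contour,
                 degenerate = ls$degenerate),
            class = "spindle_prediction")
}

#' @export
print.spindle_prediction <- function(x, ...) {
  cat(sprintf("spindle_prediction%s: angle %.1f deg, center (%.2f, %.2f), length %.2f um%s\n",
              if (nzchar(x$contour$label)) paste0(" [", x$contour$label, "]") else "",
              axis_angle(x$axis), axis_center(x$axis)[1], axis_center(x$axis)[2],
              axis_length(x$axis),
              if (x$degenerate) " (degenerate: near-isotropic shape)" else ""))
  invisible(x)
}

#' @export
summary.spindle_prediction <- function(object, ...) {
  pa <- principal_axes(object$contour)
  cat("Spindle prediction from apical cell shape\n")
  print(object$contour)
  print(pa)
  print(object$landscape)
  print(object)
  if (!object$degenerate && !pa$degenerate)
    cat(sprintf("deviation from shape long axis: %.1f deg\n",
                axial_difference(axis_angle(object$axis), pa$angle_major)))
  invisible(object)
}

#' @export
coef.spindle_prediction <- function(object, ...) {
  c(angle = axis_angle(object$axis),
    center_x = axis_center(object$axis)[[1]],
    center_y = axis_center(object$axis)[[2]],
    length = axis_length(object$axis),
    relief = object$landscape$relief)
}

#' @export
plot.spindle_prediction <- function(x, observed = NULL, ...) {
  plot(x$contour, ...)
  draw_axis <- function(ax, col) {
    segments(ax$pole_a[1], ax$pole_a[2], ax$pole_b[1], ax$pole_b[2],
             col = col, lwd = 2)
    points(rbind(ax$pole_a, ax$pole_b), col = col, pch = 19)
  }
  draw_axis(x$axis, "forestgreen")
  if (!is.null(observed)) draw_axis(observed, "steelblue")
  invisible(x)
}

# Dense reference scan: every 0.5 um lattice center x every 0.25 deg
# orientation (defaults); per angle the lattice center of best force
# balance, then the same torque-integrated landscape as the gridded path.
brute_force_prediction <- function(contour, length, params = model_params(),
                                   dtheta = 0.25, grid_step = 0.5) {
  for (gs in grid_step / c(1, 2, 4)) {  # refine if the spindle only fits off-lattice
    r <- cpp_force_brute(contour$vertices, length, params$beta, params$n_rays,
                         dtheta, gs)
    if (all(r$feasible)) break
  }
  if (!all(r$feasible)) stop("infeasible placements on the reference lattice")
  taut <- r$torque - mean(r$torque)
  dth <- dtheta * pi / 180
  E <- -c(0, cumsum((taut[-length(taut)] + taut[-1]) / 2 * dth))
  i <- which.min(E)
  list(angle = r$angles[i], center = c(r$cx[i], r$cy[i]), energy = E[i] - max(E))
}
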