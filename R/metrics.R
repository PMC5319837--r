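#' Acute angle between two axial orientations
#'
#' Orientations are undirected (defined mod 180 degrees); the difference is
#' folded into [0, 90].
#'
#' @param a,b angles in degrees.
#' @return difference in degrees, [0, 90]. Vectorized.
#' @export
axial_difference <- function(a, b) {
  d <- abs((a - b) %% 180)
  pmin(d, 180 - d)
}

#' Orienting deviation between observed and predicted spindles
#'
#' The acute angle (0-90 degrees) between the two undirected spindle axes;
#' symmetric in its arguments.
#'
#' @param observed,predicted \code{\link{spindle_axis}} objects.
#' @return deviation in degrees.
#' @export
orienting_deviation <- function(observed, predicted) {
  stopifnot(inherits(observed, "spindle_axis"), inherits(predicted, "spindle_axis"))
  axial_difference(axis_angle(observed), axis_angle(predicted))
}

#' Centering deviation between observed and predicted spindles
#'
#' Distance between the observed and predicted spindle centers, expressed
#' as a percentage of the cell's major-axis length (so "centered within
#' 20\%" means within 20\% of the cell's long length). The normalization is
#' configurable: \code{"major_axis"} (default) or \code{"equiv_diameter"}
#' (diameter of the equal-area circle).
#'
#' @param observed,predicted \code{\link{spindle_axis}} objects with
#'   centers inside \code{contour}.
#' @param contour the cell's \code{\link{contour2d}}.
#' @param normalization length scale for the percentage.
#' @return deviation in percent (>= 0).
#' @export
centering_deviation <- function(observed, predicted, contour,
                                normalization = c("major_axis", "equiv_diameter")) {
  stopifnot(inherits(observed, "spindle_axis"), inherits(predicted, "spindle_axis"),
            inherits(contour, "contour2d"))
  normalization <- match.arg(normalization)
  d <- sqrt(sum((axis_center(observed) - axis_center(predicted))^2))
  scale <- if (normalization == "major_axis") {
    pa <- principal_axes(contour, tol = 0)
    if (!is.finite(pa$length_major) || pa$length_major <= 0)
      stop("degenerate contour principal axis")
    pa$length_major
  } else {
    2 * sqrt(area_centroid(contour)$area / pi)
  }
  100 * d / scale
}

#' Classify the clone pattern of four grand-daughter cells
#'
#' Two successive divisions from one mother produce four grand-daughters
#' whose spatial arrangement reflects the daughters' division orientations:
#' both daughters dividing orthogonally to the mother gives a square, one
#' parallel daughter gives a T, and two parallel daughters give a line. A
#' daughter dividing parallel to its mother (axial difference below
#' \code{threshold}) is an oriented cell division (OCD).
#'
#' @param mother_axis mother division axis, degrees (axial).
#' @param daughter_axes numeric length-2: the two daughter division axes.
#' @param threshold parallel/orthogonal cutoff in degrees (default 45, the
#'   midpoint of the axial range).
#' @return list of class \code{clone_pattern}: \code{pattern} ("square",
#'   "T" or "line"), \code{n_ocd}, \code{parallel} (logical per daughter).
#' @export
classify_clone_pattern <- function(mother_axis, daughter_axes, threshold = 45) {
  stopifnot(length(daughter_axes) == 2L)
  par <- axial_difference(daughter_axes, mother_axis) < threshold
  structure(list(pattern = c("square", "T", "line")[sum(par) + 1L],
                 n_ocd = sum(par), parallel = par,
                 mother_axis = mother_axis %% 180,
                 daughter_axes = daughter_axes %% 180),
            class = "clone_pattern")
}

#' @export
print.clone_pattern <- function(x, ...) {
  cat(sprintf("clone pattern: %s (%d OCD)\n", x$pattern, x$n_ocd))
  invisible(x)
}

#' Incidence of misoriented cell divisions per lineage
#'
#' The percentage of misoriented divisions (divisions whose axis differs
#' from the lineage's invariant-pattern reference axis by more than a
#' threshold) among all divisions analysed, per lineage.
#'
#' @param misoriented logical vector, one entry per analysed division.
#' @param lineage character vector of lineage names, same length.
#' @return data.frame with columns \code{lineage}, \code{incidence}
#'   (percent) and \code{n}. Empty lineage groups are omitted with a
#'   warning.
#' @export
misorientation_incidence <- function(misoriented, lineage) {
  stopifnot(length(misoriented) == length(lineage))
  keep <- !is.na(misoriented)
  if (!all(keep)) {
    warning("omitting ", sum(!keep), " divisions with undefined orientation")
    misoriented <- misoriented[keep]; lineage <- lineage[keep]
  }
  if (length(misoriented) == 0) stop("no divisions to score")
  n <- tapply(misoriented, lineage, length)
  inc <- tapply(misoriented, lineage, function(z) 100 * sum(z) / length(z))
  data.frame(lineage = names(n), incidence = as.numeric(inc),
             n = as.integer(n), row.names = NULL)
}

#' Percent increase of a cell cycle relative to the previous one
#'
#' 100 (curr - prev)/prev: +20 means the cycle lengthened by 20 percent
#' compared to the previous cycle; negative values mean speeding up.
#'
#' @param prev_duration,curr_duration cycle durations in minutes (> 0).
#' @return percent change. Vectorized.
#' @export
percent_cycle_increase <- function(prev_duration, curr_duration) {
  if (any(prev_duration <= 0) || any(curr_duration <= 0))
    stop("cycle durations must be positive")
  100 * (curr_duration - prev_duration) / prev_duration
}

#' Mitotic-entry asynchrony between the animal and vegetal hemispheres
#'
#' Difference of mean mitotic-entry times, animal minus vegetal; positive
#' means the animal hemisphere enters mitosis later.
#'
#' @param entry_times_animal,entry_times_vegetal entry times in minutes.
#' @return asynchrony dt in minutes.
#' @export
asynchrony <- function(entry_times_animal, entry_times_vegetal) {
  if (length(entry_times_animal) == 0 || length(entry_times_vegetal) == 0)
    stop("both hemisphere groups must be non-empty")
  mean(entry_times_animal) - mean(entry_times_vegetal)
}
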