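#' Fractions of deviations below angular thresholds
#'
#' Proportion of orienting deviations strictly below each threshold
#' (e.g. the fraction of divisions predicted to within 10, 20 and 30
#' degrees).
#'
#' @param deviations orienting deviations in degrees, each in [0, 90].
#' @param thresholds thresholds in degrees.
#' @return named numeric vector of proportions, monotone in threshold.
#' @export
threshold_fractions <- function(deviations, thresholds = c(10, 20, 30)) {
  if (length(deviations) == 0) stop("no deviations supplied")
  if (any(deviations < 0 | deviations > 90))
    stop("deviations must lie in [0, 90] degrees")
  setNames(vapply(thresholds, function(t) mean(deviations < t), numeric(1)),
           paste0("lt", thresholds))
}

#' Uniform random axial deviations (the null distribution)
#'
#' i.i.d. Uniform(0, 90) angles, the null used to test whether observed
#' orienting deviations could arise without any shape-spindle coupling.
#'
#' @param n number of draws.
#' @param seed optional integer seed (the caller's RNG state is preserved).
#' @return numeric vector of angles in degrees.
#' @export
random_angle_null <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, runif(n, 0, 90))
}

#' One-sample Kolmogorov-Smirnov test against Uniform(0, 90)
#'
#' Two-sided test of the observed orienting deviations against the uniform
#' null. The exact null distribution of D is used for n <= 150 and the
#' asymptotic one beyond.
#'
#' @param deviations deviations in degrees, each in [0, 90]; n >= 5.
#' @return list with \code{D}, \code{p} and \code{n}.
#' @export
ks_uniform_test <- function(deviations) {
  if (any(deviations < 0 | deviations > 90))
    stop("deviations must lie in [0, 90] degrees")
  n <- length(deviations)
  if (n < 5) stop("need at least 5 deviations")
  kt <- ks.test(deviations, "punif", 0, 90, exact = n <= 150)
  list(D = unname(kt$statistic), p = kt$p.value, n = n)
}

#' Two-group comparison: rank-sum or Student t
#'
#' \code{"rank_sum"}: Wilcoxon rank-sum with continuity correction (normal
#' approximation, matching the convention under which identical groups give
#' p = 1). \code{"t_two_tailed"}: unpaired two-tailed Student t-test
#' (pooled variance).
#'
#' @param group_a,group_b numeric samples (n >= 2 each).
#' @param test which test to run.
#' @return list with \code{statistic}, \code{p}, \code{test}.
#' @export
group_compare <- function(group_a, group_b,
                          test = c("rank_sum", "t_two_tailed")) {
  test <- match.arg(test)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("both groups need at least 2 observations")
  if (test == "rank_sum") {
    ht <- suppressWarnings(
      wilcox.test(group_a, group_b, exact = FALSE, correct = TRUE))
    list(statistic = unname(ht$statistic), p = ht$p.value, test = "rank_sum")
  } else {
    if (sd(group_a) == 0 && sd(group_b) == 0)
      stop("degenerate t-test: both groups have zero variance")
    ht <- t.test(group_a, group_b, var.equal = TRUE)
    list(statistic = unname(ht$statistic), p = ht$p.value, test = "t_two_tailed")
  }
}

#' Distributional summary of orienting deviations
#'
#' Pools deviations, computes the fractions under each threshold, the KS
#' test against the uniform null, and per-lineage means with standard
#' errors.
#'
#' @param deviations deviations in degrees, [0, 90].
#' @param lineage optional lineage labels (same length) for per-lineage
#'   summaries.
#' @param thresholds threshold grid in degrees.
#' @return object of class \code{deviation_summary}: \code{n},
#'   \code{fractions}, \code{ks} (D, p), \code{per_lineage} (data.frame
#'   lineage/n/mean/sem or NULL).
#' @export
deviation_summary <- function(deviations, lineage = NULL,
                              thresholds = c(10, 20, 30)) {
  fr <- threshold_fractions(deviations, thresholds)
  ks <- ks_uniform_test(deviations)
  per <- NULL
  if (!is.null(lineage)) {
    stopifnot(length(lineage) == length(deviations))
    per <- do.call(rbind, lapply(split(deviations, lineage), function(z) {
      data.frame(n = length(z), mean = mean(z),
                 sem = if (length(z) > 1) sd(z) / sqrt(length(z)) else NA_real_)
    }))
    per <- data.frame(lineage = rownames(per), per, row.names = NULL)
  }
  structure(list(n = length(deviations), fractions = fr, ks = ks,
                 per_lineage = per),
            class = "deviation_summary")
}

#' @export
print.deviation_summary <- function(x, ...) {
  cat(sprintf("deviation_summary: n = %d divisions\n", x$n))
  cat("  fractions under thresholds: ",
      paste(sprintf("%s: %.2f", names(x$fractions), x$fractions), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  KS vs Uniform(0,90): D = %.3f, p = %.3g\n", x$ks$D, x$ks$p))
  if (!is.null(x$per_lineage))
    cat(sprintf("  %d lineages (means +/- s.e.m. in $per_lineage)\n",
                nrow(x$per_lineage)))
  invisible(x)
}

#' Empirical cumulative curve of deviations
#'
#' @param deviations deviations in degrees.
#' @return data.frame (deviation, empirical_cdf) sorted by deviation.
#' @export
cumulative_curve <- function(deviations) {
  s <- sort(deviations)
  data.frame(deviation = s, empirical_cdf = seq_along(s) / length(s))
}
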