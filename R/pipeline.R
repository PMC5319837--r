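#' One analyzed division: labels, contour and observed spindle
#'
#' @param cell_id unique record id.
#' @param lineage blastomere name (e.g. "a6.8").
#' @param stage embryo stage (cell count: 8, 16, 24, 32 or 44).
#' @param phase mitotic phase.
#' @param group experimental condition label.
#' @param contour the cell's apical \code{\link{contour2d}}.
#' @param observed observed \code{\link{spindle_axis}}; both poles must lie
#'   inside the contour.
#' @param entry_time optional mitotic-entry time, minutes.
#' @param reference_axis optional invariant-pattern reference axis
#'   (degrees) for misorientation scoring.
#' @return object of class \code{cell_record}.
#' @export
cell_record <- function(cell_id, lineage, stage, phase, group, contour,
                        observed, entry_time = NULL, reference_axis = NULL) {
  stopifnot(inherits(contour, "contour2d"), inherits(observed, "spindle_axis"))
  phase <- match.arg(phase, c("interphase", "prophase", "prometaphase",
                              "metaphase", "anaphase"))
  if (!all(points_inside(contour, rbind(observed$pole_a, observed$pole_b),
                         margin = 0)))
    stop("record ", cell_id, ": observed spindle poles fall outside the contour")
  structure(list(cell_id = as.character(cell_id), lineage = as.character(lineage),
                 stage = as.integer(stage), phase = phase,
                 group = as.character(group), contour = contour,
                 observed = observed,
                 entry_time = if (is.null(entry_time)) NULL else as.numeric(entry_time),
                 reference_axis = if (is.null(reference_axis)) NULL
                                  else as.numeric(reference_axis) %% 180),
            class = "cell_record")
}

#' @export
print.cell_record <- function(x, ...) {
  cat(sprintf("cell_record %s: %s, %d-cell, %s, group %s\n",
              x$cell_id, x$lineage, x$stage, x$phase, x$group))
  invisible(x)
}

#' Analysis run configuration
#'
#' @param model \code{\link{model_params}} for the predictions.
#' @param thresholds ascending angular thresholds (degrees) for the
#'   cumulative fractions.
#' @param misorientation_threshold axial threshold (degrees) against the
#'   reference axis above which a division counts as misoriented.
#' @param centering_normalization passed to
#'   \code{\link{centering_deviation}}.
#' @param exclude_lineages lineages excluded from the pooled statistics
#'   (defaults to the unequally cleaving germ-line precursors).
#' @param phases_pooled mitotic phases entering the pooled statistics.
#' @param tests group-comparison tests to run when several groups are
#'   present.
#' @param seed integer seed recorded with the run.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(model = model_params(), thresholds = c(10, 20, 30),
                       misorientation_threshold = 45,
                       centering_normalization = "major_axis",
                       exclude_lineages = c("B5.2", "B6.3", "B4.1"),
                       phases_pooled = "metaphase",
                       tests = "rank_sum", seed = 1L) {
  stopifnot(inherits(model, "model_params"), !is.unsorted(thresholds))
  structure(list(model = model, thresholds = thresholds,
                 misorientation_threshold = misorientation_threshold,
                 centering_normalization = centering_normalization,
                 exclude_lineages = exclude_lineages,
                 phases_pooled = phases_pooled, tests = tests,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read per-cell records from a cells.json file
#'
#' Schema: \code{{"cells": [{"cell_id", "lineage", "stage", "phase",
#' "group", "contour_um": [[x,y],...], "poles_um": [[x,y],[x,y]],
#' "entry_time_min", "reference_axis_deg"}]}}. A record may replace
#' \code{contour_um} with \code{contour_csv}, a path (relative to the JSON
#' file) to a two-column x,y CSV. Units are micrometres and minutes.
#' Invalid records are collected and reported together by id.
#'
#' @param path path to the JSON file.
#' @return list of \code{\link{cell_record}}.
#' @export
load_cells <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$cells) || length(j$cells) == 0)
    stop("no cells in ", path)
  errs <- character(0)
  out <- list()
  ids <- character(0)
  for (rec in j$cells) {
    id <- if (is.null(rec$cell_id)) "<missing id>" else as.character(rec$cell_id)
    res <- tryCatch({
      need <- c("cell_id", "lineage", "stage", "phase", "group")
      miss <- need[!need %in% names(rec)]
      if (length(miss))
        stop("missing fields: ", paste(miss, collapse = ", "))
      cm <- if (!is.null(rec$contour_um)) {
        do.call(rbind, lapply(rec$contour_um, unlist))
      } else if (!is.null(rec$contour_csv)) {
        as.matrix(read_contour_csv(file.path(dirname(path), rec$contour_csv))$vertices)
      } else stop("missing fields: contour_um (or contour_csv)")
      if (is.null(rec$poles_um)) stop("missing fields: poles_um")
      poles <- do.call(rbind, lapply(rec$poles_um, unlist))
      cell_record(rec$cell_id, rec$lineage, rec$stage, rec$phase, rec$group,
                  contour2d(cm, label = rec$lineage),
                  spindle_axis(poles[1, ], poles[2, ]),
                  entry_time = rec$entry_time_min,
                  reference_axis = rec$reference_axis_deg)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) errs <- c(errs, paste0(id, ": ", res))
    else { out[[length(out) + 1L]] <- res; ids <- c(ids, res$cell_id) }
  }
  if (length(errs))
    stop("invalid records in ", path, ":\n  ", paste(errs, collapse = "\n  "))
  if (anyDuplicated(ids))
    stop("duplicate cell_id values: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out
}

#' Write cell records (and optional ground truth) as cells.json
#'
#' @param cells list of \code{\link{cell_record}}.
#' @param path output JSON path.
#' @param ground_truth optional data.frame written alongside as
#'   \code{<path>.ground_truth.json}.
#' @export
write_cells <- function(cells, path, ground_truth = NULL) {
  enc <- lapply(cells, function(r) {
    x <- list(cell_id = r$cell_id, lineage = r$lineage, stage = r$stage,
              phase = r$phase, group = r$group,
              contour_um = unname(apply(r$contour$vertices, 1, c, simplify = FALSE)),
              poles_um = list(r$observed$pole_a, r$observed$pole_b))
    if (!is.null(r$entry_time)) x$entry_time_min <- r$entry_time
    if (!is.null(r$reference_axis)) x$reference_axis_deg <- r$reference_axis
    x
  })
  jsonlite::write_json(list(cells = enc), path, auto_unbox = TRUE, digits = NA)
  if (!is.null(ground_truth))
    jsonlite::write_json(ground_truth, paste0(path, ".ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Run the full spindle-prediction analysis over a set of cells
#'
#' For every record: predict the spindle from the apical contour (one
#' prediction per unique contour; prophase and metaphase observations of
#' the same cell share it when \code{spindle_length_mode = "fraction"}),
#' then score the centering and orienting deviations against the observed
#' spindle. Pooled statistics (threshold fractions, KS test against the
#' uniform null, per-lineage means with s.e.m.) use the configured phases,
#' exclude the configured lineages and drop degenerate (near-isotropic)
#' cells, which stay in the table flagged. With several experimental
#' groups, group comparisons of the orienting deviations are run per the
#' configured tests. Deterministic for a fixed config.
#'
#' @param cells list of \code{\link{cell_record}}.
#' @param config a \code{\link{run_config}}.
#' @return object of class \code{spindle_analysis}: \code{table}
#'   (data.frame: cell_id, lineage, stage, phase, group, centering_pct,
#'   orienting_deg, predicted_angle, degenerate, misoriented), \code{summary}
#'   (\code{\link{deviation_summary}} or NULL if everything is degenerate),
#'   \code{group_tests}, \code{misorientation} (per-lineage incidence or
#'   NULL), \code{config}.
#' @export
run_analysis <- function(cells, config = run_config()) {
  stopifnot(length(cells) >= 1, inherits(config, "run_config"))
  preds <- new.env(parent = emptyenv())
  predict_cached <- function(ct, obs) {
    key <- if (config$model$spindle_length_mode == "fraction")
      paste(ct$label, paste(signif(ct$vertices[1:2, ], 12), collapse = ","))
    else NA_character_
    if (!is.na(key) && exists(key, preds)) return(get(key, preds))
    p <- predict_spindle(ct, observed = obs, params = config$model)
    if (!is.na(key)) assign(key, p, preds)
    p
  }
  rows <- lapply(cells, function(r) {
    p <- predict_cached(r$contour, r$observed)
    mis <- if (!is.null(r$reference_axis))
      axial_difference(axis_angle(r$observed), r$reference_axis) >
        config$misorientation_threshold
    else NA
    data.frame(cell_id = r$cell_id, lineage = r$lineage, stage = r$stage,
               phase = r$phase, group = r$group,
               centering_pct = centering_deviation(
                 r$observed, p$axis, r$contour,
                 normalization = config$centering_normalization),
               orienting_deg = orienting_deviation(r$observed, p$axis),
               predicted_angle = axis_angle(p$axis),
               degenerate = p$degenerate, misoriented = mis)
  })
  tab <- do.call(rbind, rows)
  pool <- !tab$degenerate & tab$phase %in% config$phases_pooled &
    !tab$lineage %in% config$exclude_lineages
  summ <- NULL
  if (any(pool))
    summ <- deviation_summary(tab$orienting_deg[pool], tab$lineage[pool],
                              thresholds = config$thresholds)
  gtests <- NULL
  groups <- unique(tab$group[pool])
  if (length(groups) > 1) {
    prs <- utils::combn(sort(groups), 2, simplify = FALSE)
    gtests <- do.call(rbind, lapply(prs, function(pr) {
      do.call(rbind, lapply(config$tests, function(tst) {
        a <- tab$orienting_deg[pool & tab$group == pr[1]]
        b <- tab$orienting_deg[pool & tab$group == pr[2]]
        gc <- group_compare(a, b, test = tst)
        data.frame(group_a = pr[1], group_b = pr[2], test = tst,
                   statistic = gc$statistic, p = gc$p)
      }))
    }))
  }
  misinc <- if (any(!is.na(tab$misoriented)))
    misorientation_incidence(tab$misoriented[!is.na(tab$misoriented)],
                             tab$lineage[!is.na(tab$misoriented)])
  else NULL
  structure(list(table = tab, summary = summ, group_tests = gtests,
                 misorientation = misinc, config = config,
                 all_degenerate = !any(pool)),
            class = "spindle_analysis")
}

#' @export
print.spindle_analysis <- function(x, ...) {
  cat(sprintf("spindle_analysis: %d records (%d pooled phases: %s)\n",
              nrow(x$table), sum(x$table$phase %in% x$config$phases_pooled),
              paste(x$config$phases_pooled, collapse = ", ")))
  if (x$all_degenerate)
    cat("  all pooled cells degenerate: statistics skipped\n")
  else print(x$summary)
  if (!is.null(x$group_tests)) {
    cat("  group comparisons:\n")
    print(x$group_tests)
  }
  invisible(x)
}

#' @export
summary.spindle_analysis <- function(object, ...) {
  print(object)
  if (!is.null(object$summary$per_lineage)) {
    cat("\nPer-lineage orienting deviation (mean +/- s.e.m.):\n")
    print(object$summary$per_lineage, digits = 3)
  }
  if (!is.null(object$misorientation)) {
    cat("\nMisorientation incidence:\n")
    print(object$misorientation, digits = 3)
  }
  invisible(object)
}

#' Write analysis outputs to a directory
#'
#' Emits \code{deviations.csv} (the per-record table) and
#' \code{summary.json} (n, threshold fractions, KS, per-lineage means,
#' group tests, config echo) plus \code{cumulative.csv}. Byte-identical
#' across reruns with the same inputs and config.
#'
#' @param analysis a \code{spindle_analysis}.
#' @param dir output directory (created if needed).
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- analysis$table
  num <- vapply(tab, is.numeric, logical(1)) & !vapply(tab, is.integer, logical(1))
  tab[num] <- lapply(tab[num], function(z) sprintf("%.10g", z))
  write.csv(tab, file.path(dir, "deviations.csv"), row.names = FALSE)
  cfg <- analysis$config
  rep <- list(
    n = if (is.null(analysis$summary)) 0L else analysis$summary$n,
    fractions = if (!is.null(analysis$summary))
      as.list(analysis$summary$fractions) else NULL,
    ks = if (!is.null(analysis$summary)) analysis$summary$ks else NULL,
    groups = if (!is.null(analysis$summary$per_lineage))
      analysis$summary$per_lineage else NULL,
    tests = analysis$group_tests,
    misorientation = analysis$misorientation,
    note = "raw p-values; no multiple-testing correction applied",
    config = list(beta = cfg$model$beta, n_rays = cfg$model$n_rays,
                  dtheta = cfg$model$dtheta,
                  spindle_length_mode = cfg$model$spindle_length_mode,
                  spindle_fraction = cfg$model$spindle_fraction,
                  center_mode = cfg$model$center_mode,
                  relief_tol = cfg$model$relief_tol,
                  thresholds = cfg$thresholds,
                  misorientation_threshold = cfg$misorientation_threshold,
                  centering_normalization = cfg$centering_normalization,
                  exclude_lineages = cfg$exclude_lineages,
                  phases_pooled = cfg$phases_pooled, seed = cfg$seed,
                  package_version = as.character(utils::packageVersion("spindle2d"))))
  jsonlite::write_json(rep, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")
  if (!is.null(analysis$summary)) {
    pool <- !analysis$table$degenerate &
      analysis$table$phase %in% cfg$phases_pooled &
      !analysis$table$lineage %in% cfg$exclude_lineages
    cc <- cumulative_curve(analysis$table$orienting_deg[pool])
    cc[] <- lapply(cc, function(z) sprintf("%.10g", z))
    write.csv(cc, file.path(dir, "cumulative.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' 3D shape stage: sphericity, apical ratio and apical-plane extraction
#'
#' For each labeled mesh with its 3D spindle poles: computes sphericity and
#' the apical surface ratio, extracts the apical plane through the poles,
#' and returns the cross-section contour (with in-plane poles) ready for
#' \code{\link{run_analysis}}. Cells whose mesh fails validation are
#' skipped with a logged reason; the run continues.
#'
#' @param meshes named list of \code{\link{labeled_mesh}} (or raw
#'   vertex/face/label lists, validated here).
#' @param poles list of 2 x 3 pole matrices, same length/names.
#' @return list with \code{table} (data.frame: cell, sphericity,
#'   apical_ratio, separation_score, skipped, reason), \code{contours}
#'   (named list of \code{\link{contour2d}}), \code{poles2d} (named list
#'   of \code{\link{spindle_axis}}).
#' @export
run_mesh_stage <- function(meshes, poles) {
  stopifnot(length(meshes) == length(poles))
  nm <- names(meshes)
  if (is.null(nm)) nm <- sprintf("mesh%03d", seq_along(meshes))
  rows <- list(); contours <- list(); poles2d <- list()
  for (i in seq_along(meshes)) {
    res <- tryCatch({
      m <- meshes[[i]]
      if (!inherits(m, "labeled_mesh"))
        m <- labeled_mesh(m$vertices, m$faces, m$face_label)
      ap <- extract_apical_plane(m, poles[[i]])
      contours[[nm[i]]] <- ap$contour
      poles2d[[nm[i]]] <- ap$poles2d
      data.frame(cell = nm[i], sphericity = sphericity(m),
                 apical_ratio = apical_surface_ratio(m),
                 separation_score = ap$plane$separation_score,
                 skipped = FALSE, reason = "")
    }, error = function(e) {
      message("skipping ", nm[i], ": ", conditionMessage(e))
      data.frame(cell = nm[i], sphericity = NA_real_, apical_ratio = NA_real_,
                 separation_score = NA_real_, skipped = TRUE,
                 reason = conditionMessage(e))
    })
    rows[[i]] <- res
  }
  list(table = do.call(rbind, rows), contours = contours, poles2d = poles2d)
}
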