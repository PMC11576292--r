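# Per-cell and per-cohort metric tables.

#' Analyze one cell's compartment traces
#'
#' Computes percent change from baseline for every compartment trace,
#' detects depolarization states on the whole-cell trace, and evaluates the
#' per-state metrics of every compartment within the whole-cell state
#' windows (so compartments share a common temporal frame, as when states
#' are identified on the cell and then examined per subcellular domain).
#' Also reports an `overall` percent change per compartment: the mean
#' smoothed percent change over the final `overall_window` seconds of the
#' recording.
#'
#' @param traces Named list of [fluorescence_trace()] objects keyed by
#'   compartment (`whole_cell`, `soma`, `branches`, `endfeet`; a lone `soma`
#'   entry is treated as the reference trace, as for neurons).
#' @param cell_id,condition,cell_class Metadata for the output rows
#'   (defaulting to the first trace's metadata).
#' @param baseline_window Baseline window (s) for [percent_change()].
#' @param overall_window Length (s) of the end-of-recording window defining
#'   the overall percent change.
#' @param ... Detection parameters passed to [detect_states()].
#' @return data.frame with columns `cell_id`, `condition`, `cell_class`,
#'   `compartment`, `state` (`"S1"`..., or `"overall"`), `metric`
#'   (`pct_change`, `max_slope_angle`, `mean_rate`), `value`. Cells with no
#'   detected states contribute only `overall` rows.
#' @export
analyze_cell <- function(traces, cell_id = NULL, condition = NULL,
                         cell_class = NULL, baseline_window = c(-300, 0),
                         overall_window = 60, ...) {
  md <- traces[[1]]$metadata
  cell_id <- cell_id %||% md$roi_id %||% "cell"
  condition <- condition %||% md$condition %||% NA_character_
  cell_class <- cell_class %||% md$cell_class %||% NA_character_
  pcts <- lapply(traces, percent_change, baseline_window = baseline_window)
  ref <- pcts[["whole_cell"]] %||% pcts[[1]]
  seg <- detect_states(ref, ...)
  rows <- list()
  for (cp in names(pcts)) {
    rt <- rate_of_change(pcts[[cp]])
    endsel <- pcts[[cp]]$time >= max(pcts[[cp]]$time) - overall_window
    rows[[length(rows) + 1]] <- data.frame(
      compartment = cp, state = "overall", metric = "pct_change",
      value = mean(rt$smoothed[endsel]))
    if (nrow(seg$states)) {
      sm <- state_metrics(pcts[[cp]], seg$states)
      for (m in c("pct_change", "max_slope_angle", "mean_rate"))
        rows[[length(rows) + 1]] <- data.frame(
          compartment = cp, state = paste0("S", sm$state), metric = m,
          value = sm[[m]])
    }
  }
  out <- do.call(rbind, rows)
  cbind(data.frame(cell_id = cell_id, condition = condition,
                   cell_class = cell_class), out)
}

#' Analyze every cell of a generated cohort
#'
#' Applies [analyze_cell()] to each cell of a [generate_cohort()] result (or
#' any list of cell records with `traces`, `cell_id`, `condition`,
#' `cell_class`).
#'
#' @param cohort Cohort object (`$cells` list) or the cell list itself.
#' @param ... Passed to [analyze_cell()].
#' @return Long-format metrics data.frame (one row per cell, compartment,
#'   state, metric).
#' @export
analyze_cohort <- function(cohort, ...) {
  cells <- cohort$cells %||% cohort
  out <- lapply(cells, function(cl)
    analyze_cell(cl$traces, cell_id = cl$cell_id, condition = cl$condition,
                 cell_class = cl$cell_class, ...))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group means and standard errors of state metrics
#'
#' Aggregates a long-format metrics table (see [analyze_cell()]) into group
#' means, standard errors of the mean and group sizes. Cells missing a state
#' simply contribute no row for it (absent, not zero).
#'
#' @param metrics Long-format metrics data.frame.
#' @param by Grouping columns.
#' @return data.frame with `n`, `mean`, `sem` per group.
#' @export
summarize_states <- function(metrics,
                             by = c("condition", "cell_class", "compartment",
                                    "state", "metric")) {
  if (!nrow(metrics)) stop("metrics table is empty")
  by <- intersect(by, names(metrics))
  f <- metrics[by]
  agg <- stats::aggregate(metrics$value, f, function(v)
    c(n = length(v), mean = mean(v),
      sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0))
  out <- cbind(agg[by], as.data.frame(agg$x))
  out[order(out$compartment %||% 0, out$state %||% 0), ]
}
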