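#' @name pulldown
#' @title Ecto-Fc pull-down spectral-count hit filters
#'
#' @description
#' Two deterministic filters identify candidate binding partners captured
#' by an ectodomain-Fc bait from synaptosome lysate, read out by spectral
#' counts against an Fc-only control. The whole-brain variant demands
#' complete absence from the control; the mossy-fiber-synaptosome variant
#' tolerates a single control count. Both demand at least `min_bait`
#' spectral counts in every bait experiment. Hits are ranked by total bait
#' spectral counts, descending, ties broken by protein identifier.
NULL

bait_columns <- function(table) grep("^spc_bait_", names(table), value = TRUE)
ctrl_columns <- function(table) grep("^spc_ctrl_", names(table), value = TRUE)

check_pulldown_table <- function(table) {
  if (!is.data.frame(table) || !"protein_id" %in% names(table)) {
    stop_field("table", "must be a data.frame with a protein_id column")
  }
  if (!length(bait_columns(table))) {
    stop_field("table", "needs at least one spc_bait_* column")
  }
  cols <- c(bait_columns(table), ctrl_columns(table))
  if (nrow(table) && any(as.matrix(table[, cols, drop = FALSE]) < 0)) {
    stop_field("table", "spectral counts must be >= 0")
  }
  invisible(table)
}

filter_pulldown <- function(table, max_control, min_bait) {
  check_pulldown_table(table)
  check_scalar_num(max_control, "max_control", nonneg = TRUE, integer = TRUE)
  check_scalar_num(min_bait, "min_bait", nonneg = TRUE, integer = TRUE)
  bait <- as.matrix(table[, bait_columns(table), drop = FALSE])
  ctrl_cols <- ctrl_columns(table)
  ctrl_ok <- if (length(ctrl_cols)) {
    apply(as.matrix(table[, ctrl_cols, drop = FALSE]) <= max_control, 1, all)
  } else {
    rep(TRUE, nrow(table))
  }
  keep <- ctrl_ok & apply(bait >= min_bait, 1, all)
  hits <- table[keep, , drop = FALSE]
  total <- rowSums(as.matrix(hits[, bait_columns(hits), drop = FALSE]))
  hits <- hits[order(-total, hits$protein_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Whole-brain pull-down filter
#'
#' Retains proteins absent from every Fc control (zero counts) and present
#' with at least `min_bait` spectral counts in every bait experiment.
#'
#' @param table Pull-down data.frame with `protein_id`, `spc_bait_*` and
#'   `spc_ctrl_*` columns.
#' @param min_bait Per-bait-experiment minimum spectral count (default 2).
#' @return The retained rows, sorted by total bait counts descending
#'   (ties by `protein_id`).
#' @export
filter_whole_brain <- function(table, min_bait = 2) {
  filter_pulldown(table, max_control = 0L, min_bait = min_bait)
}

#' Mossy-fiber-synaptosome pull-down filter
#'
#' Retains proteins with at most `max_control` spectral counts in every Fc
#' control and at least `min_bait` counts in every bait experiment.
#'
#' @inheritParams filter_whole_brain
#' @param max_control Per-control maximum spectral count (default 1).
#' @return The retained rows, sorted as in [filter_whole_brain()].
#' @export
filter_mf <- function(table, max_control = 1, min_bait = 2) {
  filter_pulldown(table, max_control = max_control, min_bait = min_bait)
}
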