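# Shared fixtures, built in code.

# Four-protein count table with hand-checkable NSAF arithmetic; protein D
# falls to the peptide filter (summed peptides = 2 < 3).
toy_count_table <- function() {
  data.frame(
    protein_id = c("A", "B", "C", "D"),
    length_aa = c(100L, 200L, 100L, 400L),
    spc_MF_1 = c(10L, 4L, 6L, 0L),
    spc_MF_2 = c(12L, 0L, 6L, 1L),
    spc_P2_1 = c(2L, 4L, 0L, 1L),
    spc_P2_2 = c(4L, 8L, 0L, 0L),
    pep_MF_1 = c(5L, 2L, 3L, 0L),
    pep_MF_2 = c(6L, 0L, 3L, 1L),
    pep_P2_1 = c(1L, 2L, 0L, 1L),
    pep_P2_2 = c(2L, 4L, 0L, 0L),
    stringsAsFactors = FALSE
  )
}

# Minimal screen experiment: explicit OD matrix over a 3-construct panel.
toy_screen_experiment <- function(od = NULL, blanks = rep(0.07, 30),
                                  id = "exp1") {
  constructs <- c("X", "Y", "Z")
  if (is.null(od)) {
    od <- matrix(0.07, 3, 4, dimnames = list(constructs,
                                             c(constructs, AP_ONLY)))
  }
  screen_experiment(id, od, blanks)
}

# Independent brute-force pull-down filter used as an oracle: row-by-row
# loops, no vectorized shortcuts shared with the implementation.
brute_force_pulldown <- function(table, max_control, min_bait) {
  bait_cols <- grep("^spc_bait_", names(table), value = TRUE)
  ctrl_cols <- grep("^spc_ctrl_", names(table), value = TRUE)
  keep <- logical(nrow(table))
  for (i in seq_len(nrow(table))) {
    ok <- TRUE
    for (cc in ctrl_cols) if (table[i, cc] > max_control) ok <- FALSE
    for (bc in bait_cols) if (table[i, bc] < min_bait) ok <- FALSE
    keep[i] <- ok
  }
  ids <- table$protein_id[keep]
  totals <- sapply(ids, function(id) {
    sum(unlist(table[table$protein_id == id, bait_cols]))
  })
  ids[order(-totals, ids)]
}
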