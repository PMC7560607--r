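#' @name enrichment
#' @title Label-free NSAF enrichment analysis
#'
#' @description
#' The enrichment stage compares sorted mossy-fiber (MF) synaptosomes to the
#' P2 reference by a label-free semiquantitative route: proteins must carry
#' at least `min_peptides` peptide identifications summed over all samples;
#' spectral counts are converted per sample to the normalized spectral
#' abundance factor, NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j); missing
#' observations are imputed as exactly 0; log2 fold change is taken on the
#' group means of NSAF; per-protein two-sided Student's t tests give p
#' values; Benjamini-Hochberg q values define the high-confidence set at a
#' 5 percent FDR.
NULL

# ---- column helpers ------------------------------------------------------

spc_columns <- function(table) grep("^spc_", names(table), value = TRUE)
pep_columns <- function(table) grep("^pep_", names(table), value = TRUE)

sample_groups <- function(cols) {
  sub("^(spc_|pep_)?([^_]+)_.*$", "\\2", cols)
}

check_count_table <- function(table) {
  if (!is.data.frame(table)) stop_field("table", "must be a data.frame")
  need <- c("protein_id", "length_aa")
  if (!all(need %in% names(table))) {
    stop_field("table", "must have protein_id and length_aa columns")
  }
  if (nrow(table) && any(table$length_aa <= 0)) {
    stop_field("length_aa", "protein lengths must be > 0")
  }
  spc <- spc_columns(table)
  if (!length(spc)) stop_field("table", "has no spc_* sample columns")
  invisible(table)
}

# ---- operations ----------------------------------------------------------

#' Filter proteins by total peptide identifications
#'
#' Retains proteins whose peptide identifications summed across all samples
#' reach `min_peptides` ("at least three" under the default). Row order is
#' preserved; an empty table passes through unchanged.
#'
#' @param table Spectral-count data.frame with `pep_*` columns.
#' @param min_peptides Minimum summed peptide count (default 3).
#' @return The filtered table.
#' @export
filter_by_peptides <- function(table, min_peptides = 3) {
  check_count_table(table)
  check_scalar_num(min_peptides, "min_peptides", min = 1)
  pep <- pep_columns(table)
  if (!length(pep)) stop_field("table", "has no pep_* peptide-count columns")
  if (!nrow(table)) return(table)
  keep <- rowSums(table[, pep, drop = FALSE]) >= min_peptides
  table[keep, , drop = FALSE]
}

#' Compute the NSAF matrix
#'
#' Per sample, each protein's spectral count is divided by its length (the
#' spectral abundance factor, SAF) and normalized by the sample's SAF total,
#' so each sample column sums to 1 over detected proteins. A sample with no
#' counts at all yields an all-zero column and a warning.
#'
#' @param table Spectral-count data.frame (`protein_id`, `length_aa`,
#'   `spc_*` columns).
#' @return Numeric matrix (proteins x samples) with `protein_id` row names
#'   and sample names such as `"MF_1"`.
#' @export
compute_nsaf <- function(table) {
  check_count_table(table)
  if (!nrow(table)) stop_field("table", "must be nonempty")
  spc_cols <- spc_columns(table)
  spc <- as.matrix(table[, spc_cols, drop = FALSE])
  saf <- spc / table$length_aa
  totals <- colSums(saf)
  if (any(totals == 0)) {
    warning("sample(s) with all-zero counts: ",
            paste(spc_cols[totals == 0], collapse = ", "))
    totals[totals == 0] <- 1  # keeps the column at exact zeros
  }
  nsaf <- sweep(saf, 2, totals, "/")
  dimnames(nsaf) <- list(table$protein_id, sub("^spc_", "", spc_cols))
  nsaf
}

#' Impute missing observations as zero
#'
#' Forces NSAF to exactly 0 wherever the protein was not identified in that
#' sample (spectral count 0), the convention used for all downstream
#' calculations. `compute_nsaf()` already maps zero counts to zero NSAF;
#' this enforces the contract explicitly and validates alignment.
#'
#' @param nsaf NSAF matrix from [compute_nsaf()].
#' @param table The matching spectral-count table.
#' @return The NSAF matrix with exact zeros at unidentified positions.
#' @export
impute_missing <- function(nsaf, table) {
  check_count_table(table)
  spc <- as.matrix(table[, spc_columns(table), drop = FALSE])
  if (!identical(dim(nsaf), dim(spc))) {
    stop_field("nsaf", "shape does not match the count table")
  }
  nsaf[spc == 0] <- 0
  nsaf
}

#' Per-protein log2 fold change of group-mean NSAF
#'
#' `log2(mean_MF / mean_P2)`. Proteins absent from the reference group but
#' present in the target return `+Inf` (the exclusive-detection sentinel);
#' proteins absent from both return `NaN`.
#'
#' @param nsaf NSAF matrix with sample columns named `<group>_<rep>`.
#' @param target,reference Group labels (defaults `"MF"`, `"P2"`).
#' @return Named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(nsaf, target = "MF", reference = "P2") {
  groups <- sample_groups(colnames(nsaf))
  if (!all(c(target, reference) %in% groups)) {
    stop_field("nsaf", "target and reference groups must both be present")
  }
  m_t <- rowMeans(nsaf[, groups == target, drop = FALSE])
  m_r <- rowMeans(nsaf[, groups == reference, drop = FALSE])
  lfc <- log2(m_t / m_r)  # yields +Inf when m_r = 0 < m_t, NaN when both 0
  names(lfc) <- rownames(nsaf)
  lfc
}

#' Per-protein two-sample t test on NSAF values
#'
#' Two-sided Student's t test (equal variance by default; Welch behind
#' `welch = TRUE`) on per-group NSAF values, zeros included per the
#' imputation rule. Degenerate rows where both groups are constant return
#' p = 1 when the constants are equal and p = 0 (flagged) when they differ,
#' so exclusively detected proteins with reproducible signal remain
#' testable. `log_transform = TRUE` tests log2(NSAF + p0) instead, with p0
#' half the smallest nonzero NSAF in the matrix.
#'
#' @param nsaf NSAF matrix with sample columns named `<group>_<rep>`.
#' @param target,reference Group labels (defaults `"MF"`, `"P2"`).
#' @param welch Use the Welch (unequal-variance) statistic.
#' @param log_transform Test on log2-transformed NSAF.
#' @return Named numeric vector of p values, with attribute `"degenerate"`
#'   marking rows decided by the constant-row policy.
#' @export
protein_t_test <- function(nsaf, target = "MF", reference = "P2",
                           welch = FALSE, log_transform = FALSE) {
  groups <- sample_groups(colnames(nsaf))
  x_idx <- which(groups == target)
  y_idx <- which(groups == reference)
  if (length(x_idx) < 2 || length(y_idx) < 2) {
    stop_field("nsaf", "each group needs at least 2 samples")
  }
  m <- nsaf
  if (log_transform) {
    nz <- m[m > 0]
    p0 <- if (length(nz)) min(nz) / 2 else 1
    m <- log2(m + p0)
  }
  p <- numeric(nrow(m))
  degenerate <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    x <- m[i, x_idx]; y <- m[i, y_idx]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      degenerate[i] <- TRUE
      p[i] <- if (x[1] == y[1]) 1 else 0
    } else {
      p[i] <- stats::t.test(x, y, var.equal = !welch)$p.value
    }
  }
  names(p) <- rownames(m)
  attr(p, "degenerate") <- degenerate
  p
}

#' Benjamini-Hochberg q values and FDR cutoff rank
#'
#' Computes BH q values and the deepest rank (in ascending-p order) whose q
#' value stays within `alpha`; every protein at or above that rank is a
#' high-confidence measurement at the corresponding FDR.
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return List with `q` (q values, input order), `cutoff_rank` (0 when no
#'   rank qualifies), and `high_confidence` (logical, input order).
#' @export
bh_adjust <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) {
    return(list(q = numeric(0), cutoff_rank = 0L, high_confidence = logical(0)))
  }
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_field("p_values", "must all be in [0, 1]")
  }
  q <- stats::p.adjust(p_values, method = "BH")
  ord <- order(p_values)
  admissible <- which(q[ord] <= alpha)
  cutoff_rank <- if (length(admissible)) max(admissible) else 0L
  high_confidence <- logical(length(q))
  if (cutoff_rank > 0) high_confidence[ord[seq_len(cutoff_rank)]] <- TRUE
  list(q = q, cutoff_rank = as.integer(cutoff_rank),
       high_confidence = high_confidence)
}

detection_class <- function(table, target = "MF", reference = "P2") {
  spc_cols <- spc_columns(table)
  groups <- sample_groups(spc_cols)
  spc <- as.matrix(table[, spc_cols, drop = FALSE])
  t_any <- rowSums(spc[, groups == target, drop = FALSE]) > 0
  r_any <- rowSums(spc[, groups == reference, drop = FALSE]) > 0
  out <- character(nrow(table))
  out[t_any & r_any] <- "shared"
  out[t_any & !r_any] <- sprintf("%s-exclusive", target)
  out[!t_any & r_any] <- sprintf("%s-exclusive", reference)
  out[!t_any & !r_any] <- "undetected-after-filter"
  out
}

#' Assemble the enrichment result table
#'
#' Combines counts, fold changes and test results into one table per
#' protein, with the detection class, the p <= alpha significance flag and
#' the BH high-confidence flag. A summary of class counts (including the
#' "significantly enriched" and "exclusive significant" tallies and the
#' exclusive/shared detection partition) is attached as the `"summary"`
#' attribute and available via [enrichment_summary()].
#'
#' @param table Filtered spectral-count table.
#' @param nsaf Matching NSAF matrix.
#' @param log2fc,p,q Per-protein vectors aligned with `table`.
#' @param high_confidence Logical vector from [bh_adjust()].
#' @param alpha Significance threshold applied inclusively (default 0.05).
#' @return An `enrichment_table` data.frame with columns `protein_id`,
#'   `log2fc`, `p_value`, `q_value`, `detection_class`, `significant`,
#'   `high_confidence`.
#' @export
classify_and_report <- function(table, nsaf, log2fc, p, q, high_confidence,
                                alpha = 0.05) {
  n <- nrow(table)
  if (nrow(nsaf) != n || length(log2fc) != n || length(p) != n ||
      length(q) != n || length(high_confidence) != n) {
    stop_field("table", "inputs are not aligned by protein")
  }
  if (!identical(rownames(nsaf), table$protein_id)) {
    stop_field("nsaf", "row names must match table$protein_id")
  }
  cls <- detection_class(table)
  res <- data.frame(protein_id = table$protein_id,
                    log2fc = as.numeric(log2fc),
                    p_value = as.numeric(p),
                    q_value = as.numeric(q),
                    detection_class = cls,
                    significant = as.numeric(p) <= alpha,
                    high_confidence = high_confidence,
                    stringsAsFactors = FALSE)
  summary <- list(
    n_proteins = n,
    n_shared = sum(cls == "shared"),
    n_mf_exclusive = sum(cls == "MF-exclusive"),
    n_p2_exclusive = sum(cls == "P2-exclusive"),
    frac_mf_exclusive = mean(cls == "MF-exclusive"),
    frac_p2_exclusive = mean(cls == "P2-exclusive"),
    n_significant_enriched = sum(cls == "shared" & res$log2fc > 0 &
                                   res$significant),
    n_exclusive_significant = sum(cls == "MF-exclusive" & res$significant),
    n_high_confidence = sum(res$high_confidence),
    alpha = alpha
  )
  attr(res, "summary") <- summary
  class(res) <- c("enrichment_table", "data.frame")
  res
}

#' @rdname classify_and_report
#' @param x An `enrichment_table`.
#' @export
enrichment_summary <- function(x) attr(x, "summary")

#' Run the full enrichment pipeline
#'
#' Peptide filter, NSAF, zero imputation, log2 fold change, t tests, BH
#' adjustment and classification, in order.
#'
#' @param table Spectral-count data.frame (see [gen_spectral_counts()] for
#'   the column contract).
#' @param min_peptides Peptide filter threshold (default 3).
#' @param alpha Significance / FDR level (default 0.05, inclusive).
#' @param welch,log_transform Passed to [protein_t_test()].
#' @return An `enrichment_table` (see [classify_and_report()]).
#' @examples
#' sim <- gen_spectral_counts(count_sim_config(seed = 1, n_proteins = 60,
#'                                             n_enriched = 6, n_exclusive = 4))
#' res <- run_enrichment(sim$counts)
#' enrichment_summary(res)$n_significant_enriched
#' @export
run_enrichment <- function(table, min_peptides = 3, alpha = 0.05,
                           welch = FALSE, log_transform = FALSE) {
  filtered <- filter_by_peptides(table, min_peptides)
  if (!nrow(filtered)) {
    res <- data.frame(protein_id = character(0), log2fc = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      detection_class = character(0),
                      significant = logical(0), high_confidence = logical(0))
    class(res) <- c("enrichment_table", "data.frame")
    return(res)
  }
  nsaf <- impute_missing(compute_nsaf(filtered), filtered)
  lfc <- log2_fold_change(nsaf)
  p <- protein_t_test(nsaf, welch = welch, log_transform = log_transform)
  bh <- bh_adjust(p, alpha = alpha)
  classify_and_report(filtered, nsaf, lfc, p, bh$q, bh$high_confidence,
                      alpha = alpha)
}
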