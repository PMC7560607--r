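#' Simulate an ecto-Fc pull-down spectral-count table
#'
#' Emulates the input of the pull-down hit filters: per-protein spectral
#' counts across one or more bait (ectodomain-Fc) pull-down experiments and
#' one Fc-only control. Planted hits are captured by the bait (>= 2 counts
#' in every bait experiment) and essentially absent from the control;
#' contaminants bind the resin and appear in bait and control alike; the
#' remaining background proteins carry sparse low counts in either column.
#'
#' @param seed Integer seed.
#' @param n_proteins Number of proteins in the table.
#' @param n_bait_experiments Number of independent bait pull-downs (>= 1).
#' @param hit_fraction Fraction of proteins planted as true hits.
#' @param contaminant_fraction Fraction planted as contaminants.
#' @param hit_mean Mean bait spectral count of a hit (default 8).
#'
#' @return A list with `table` (data.frame: `protein_id`,
#'   `spc_bait_1..k`, `spc_ctrl_1`), `truth` (data.frame with per-protein
#'   `class`: `"hit"`, `"contaminant"` or `"background"`), and the call
#'   parameters.
#' @examples
#' pd <- gen_pulldown(seed = 3, n_proteins = 40, n_bait_experiments = 2,
#'                    hit_fraction = 0.1, contaminant_fraction = 0.2)
#' head(pd$table)
#' @export
gen_pulldown <- function(seed, n_proteins, n_bait_experiments = 2L,
                         hit_fraction = 0.1, contaminant_fraction = 0.2,
                         hit_mean = 8) {
  check_scalar_num(seed, "seed", integer = TRUE)
  check_scalar_num(n_proteins, "n_proteins", positive = TRUE, integer = TRUE)
  check_scalar_num(n_bait_experiments, "n_bait_experiments",
                   positive = TRUE, integer = TRUE)
  check_prob(hit_fraction, "hit_fraction")
  check_prob(contaminant_fraction, "contaminant_fraction")
  if (hit_fraction + contaminant_fraction > 1) {
    stop_field("hit_fraction", "hit_fraction + contaminant_fraction must be <= 1")
  }
  check_scalar_num(hit_mean, "hit_mean", positive = TRUE)

  set.seed(seed)
  n_hit <- round(n_proteins * hit_fraction)
  n_cont <- round(n_proteins * contaminant_fraction)
  class <- rep("background", n_proteins)
  if (n_hit > 0) class[seq_len(n_hit)] <- "hit"
  if (n_cont > 0) class[n_hit + seq_len(n_cont)] <- "contaminant"
  protein_id <- sprintf("Q%04d", seq_len(n_proteins))

  bait <- matrix(0L, n_proteins, n_bait_experiments)
  for (k in seq_len(n_bait_experiments)) {
    # hits: guaranteed >= 2 per bait experiment; contaminants abundant;
    # background: mostly zero with an occasional single count
    bait[class == "hit", k] <- 2L + stats::rpois(sum(class == "hit"),
                                                 hit_mean - 2)
    bait[class == "contaminant", k] <- stats::rpois(sum(class == "contaminant"), 5)
    bait[class == "background", k] <- stats::rbinom(sum(class == "background"),
                                                    1, 0.15)
  }
  ctrl <- integer(n_proteins)
  ctrl[class == "contaminant"] <- 1L + stats::rpois(sum(class == "contaminant"), 4)
  ctrl[class == "background"] <- stats::rbinom(sum(class == "background"), 1, 0.15)
  # hits stay at <= 1 in the control (mostly 0)
  ctrl[class == "hit"] <- stats::rbinom(sum(class == "hit"), 1, 0.1)

  table <- data.frame(protein_id = protein_id, stringsAsFactors = FALSE)
  for (k in seq_len(n_bait_experiments)) {
    table[[sprintf("spc_bait_%d", k)]] <- bait[, k]
  }
  table[["spc_ctrl_1"]] <- ctrl

  list(table = table,
       truth = data.frame(protein_id = protein_id, class = class,
                          stringsAsFactors = FALSE),
       seed = as.integer(seed))
}
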