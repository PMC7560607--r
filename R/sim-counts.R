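#' Configuration for the spectral-count simulator
#'
#' Bundles and validates the parameters of the negative-binomial
#' spectral-count generator. The defaults emulate a 3-vs-3 replicate design
#' comparing sorted mossy-fiber (MF) synaptosomes against the crude P2
#' synaptosome reference, with a subset of proteins planted as MF-enriched
#' and a subset detectable only in MF samples.
#'
#' @param seed Integer seed; identical configs produce identical tables.
#' @param n_proteins Number of simulated proteins.
#' @param n_replicates_per_group Samples per group (default 3, the study
#'   design of three independent experiments).
#' @param length_range_aa Integer pair: protein lengths are drawn uniformly
#'   from this range (amino acids).
#' @param baseline_mean Expected spectral count of an unperturbed protein.
#' @param dispersion Negative-binomial size parameter; counts have variance
#'   `mu + mu^2 / dispersion`, so smaller values mean noisier replicates.
#' @param n_enriched Number of proteins with an MF-enriched mean.
#' @param enrichment_fold Multiplicative MF effect for enriched proteins.
#' @param n_exclusive Number of proteins detected only in MF samples
#'   (all P2 counts zero).
#' @param detect_dropout Probability that a (protein, sample) observation is
#'   zeroed, emulating stochastic missingness of low-abundance proteins.
#'
#' @return An object of class `count_sim_config`.
#' @seealso [gen_spectral_counts()]
#' @export
count_sim_config <- function(seed,
                             n_proteins,
                             n_replicates_per_group = 3L,
                             length_range_aa = c(100L, 2000L),
                             baseline_mean = 20,
                             dispersion = 10,
                             n_enriched = 0L,
                             enrichment_fold = 8,
                             n_exclusive = 0L,
                             detect_dropout = 0) {
  check_scalar_num(seed, "seed", integer = TRUE)
  check_scalar_num(n_proteins, "n_proteins", positive = TRUE, integer = TRUE)
  check_scalar_num(n_replicates_per_group, "n_replicates_per_group",
                   integer = TRUE, min = 2)
  if (!is.numeric(length_range_aa) || length(length_range_aa) != 2L ||
      any(length_range_aa <= 0) || length_range_aa[1] > length_range_aa[2]) {
    stop_field("length_range_aa", "must be an increasing pair of positive integers")
  }
  check_scalar_num(baseline_mean, "baseline_mean", positive = TRUE)
  check_scalar_num(dispersion, "dispersion", positive = TRUE)
  check_scalar_num(n_enriched, "n_enriched", nonneg = TRUE, integer = TRUE)
  check_scalar_num(enrichment_fold, "enrichment_fold", positive = TRUE)
  check_scalar_num(n_exclusive, "n_exclusive", nonneg = TRUE, integer = TRUE)
  check_prob(detect_dropout, "detect_dropout")
  if (n_enriched + n_exclusive > n_proteins) {
    stop_field("n_enriched", "n_enriched + n_exclusive must be <= n_proteins")
  }
  structure(list(seed = as.integer(seed),
                 n_proteins = as.integer(n_proteins),
                 n_replicates_per_group = as.integer(n_replicates_per_group),
                 length_range_aa = as.integer(length_range_aa),
                 baseline_mean = baseline_mean,
                 dispersion = dispersion,
                 n_enriched = as.integer(n_enriched),
                 enrichment_fold = enrichment_fold,
                 n_exclusive = as.integer(n_exclusive),
                 detect_dropout = detect_dropout),
            class = "count_sim_config")
}

#' Simulate a spectral-count table with planted effects
#'
#' Draws per-protein, per-sample spectral counts from a negative-binomial
#' model. The first `n_enriched` proteins carry an `enrichment_fold`-times
#' larger MF mean; the next `n_exclusive` proteins have all-zero P2 counts
#' and at least one nonzero MF count; the remainder are null. Peptide counts
#' accompany the spectral counts (at least 1 wherever a protein is detected)
#' because the enrichment stage's peptide filter consumes them.
#'
#' @param config A [count_sim_config()].
#'
#' @return A list with components:
#'   \describe{
#'     \item{counts}{data.frame with `protein_id`, `length_aa`, one
#'       `spc_<group>_<rep>` and one `pep_<group>_<rep>` column per sample
#'       (groups `MF`, `P2`).}
#'     \item{truth}{data.frame with `protein_id` and `class`
#'       (`"null"`, `"enriched"` or `"mf_exclusive"`).}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- gen_spectral_counts(count_sim_config(seed = 1, n_proteins = 50,
#'                                             n_enriched = 5))
#' head(sim$counts)
#' table(sim$truth$class)
#' @export
gen_spectral_counts <- function(config) {
  if (!inherits(config, "count_sim_config")) {
    stop_field("config", "must be a count_sim_config")
  }
  set.seed(config$seed)
  n <- config$n_proteins
  nrep <- config$n_replicates_per_group

  protein_id <- sprintf("P%04d", seq_len(n))
  length_aa <- sample(seq(config$length_range_aa[1], config$length_range_aa[2]),
                      n, replace = TRUE)

  class <- rep("null", n)
  if (config$n_enriched > 0) class[seq_len(config$n_enriched)] <- "enriched"
  if (config$n_exclusive > 0) {
    class[config$n_enriched + seq_len(config$n_exclusive)] <- "mf_exclusive"
  }

  mu_mf <- rep(config$baseline_mean, n)
  mu_mf[class == "enriched"] <- config$baseline_mean * config$enrichment_fold
  mu_p2 <- rep(config$baseline_mean, n)
  mu_p2[class == "mf_exclusive"] <- 0

  draw <- function(mu) {
    counts <- matrix(0L, nrow = n, ncol = nrep)
    nz <- mu > 0
    for (j in seq_len(nrep)) {
      counts[nz, j] <- stats::rnbinom(sum(nz), size = config$dispersion,
                                      mu = mu[nz])
    }
    counts
  }
  spc_mf <- draw(mu_mf)
  spc_p2 <- draw(mu_p2)

  if (config$detect_dropout > 0) {
    spc_mf[matrix(stats::runif(n * nrep) < config$detect_dropout, n, nrep)] <- 0L
    spc_p2[matrix(stats::runif(n * nrep) < config$detect_dropout, n, nrep)] <- 0L
  }

  # exclusive proteins must remain detectable in MF: re-seed a single count
  # in the first replicate if dropout/NB sampling zeroed the whole row
  excl <- which(class == "mf_exclusive" & rowSums(spc_mf) == 0)
  if (length(excl)) spc_mf[excl, 1] <- 1L

  # peptide identifications: roughly half the spectra map to distinct
  # peptides; a detected protein always has >= 1 peptide
  pep_from <- function(spc) {
    pep <- ceiling(spc / 2)
    pep[spc >= 1 & pep < 1] <- 1
    storage.mode(pep) <- "integer"
    pep
  }

  counts <- data.frame(protein_id = protein_id, length_aa = length_aa,
                       stringsAsFactors = FALSE)
  for (j in seq_len(nrep)) counts[[sprintf("spc_MF_%d", j)]] <- spc_mf[, j]
  for (j in seq_len(nrep)) counts[[sprintf("spc_P2_%d", j)]] <- spc_p2[, j]
  pep_mf <- pep_from(spc_mf); pep_p2 <- pep_from(spc_p2)
  for (j in seq_len(nrep)) counts[[sprintf("pep_MF_%d", j)]] <- pep_mf[, j]
  for (j in seq_len(nrep)) counts[[sprintf("pep_P2_%d", j)]] <- pep_p2[, j]

  list(counts = counts,
       truth = data.frame(protein_id = protein_id, class = class,
                          stringsAsFactors = FALSE),
       config = config)
}
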