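#' Configuration for the ELISA interaction-screen simulator
#'
#' Parameters of the synthetic 384-well-style extracellular interaction
#' screen: a panel of ectodomain constructs each produced as an AP-tagged
#' bait (plate columns) and an Fc-tagged prey (plate rows), read out as
#' OD650. Background defaults reproduce the plate model of the assay this
#' emulates: blank wells with mean OD650 0.07 and SD 0.027, and a dynamic
#' range of roughly 50-fold over background.
#'
#' @param seed Integer seed.
#' @param n_constructs Panel size (default 73 constructs, i.e. 146 tagged
#'   proteins counting both AP and Fc fusions).
#' @param n_experiments Independent screen repeats (default 3).
#' @param true_pairs List of length-2 integer vectors: unordered construct
#'   index pairs that truly interact. Self-pairs (homophilic) are allowed.
#' @param bg_mean,bg_sd Background OD650 mean and SD (defaults 0.07, 0.027).
#' @param max_fob Upper end of the plate dynamic range in fold-over-background
#'   units (default 50).
#' @param n_blanks Blank wells per experiment (default 100; must be >= 30,
#'   the minimum the background estimator accepts).
#' @param n_sticky_preys Number of promiscuous preys whose Fc fusion sticks
#'   to every bait including the AP-only control.
#' @param detection_prob Probability that a true pair produces signal in a
#'   given (experiment, orientation) well.
#'
#' @return An object of class `screen_sim_config`.
#' @seealso [gen_elisa_screen()]
#' @export
screen_sim_config <- function(seed,
                              n_constructs = 73L,
                              n_experiments = 3L,
                              true_pairs = list(),
                              bg_mean = 0.07,
                              bg_sd = 0.027,
                              max_fob = 50,
                              n_blanks = 100L,
                              n_sticky_preys = 0L,
                              detection_prob = 0.95) {
  check_scalar_num(seed, "seed", integer = TRUE)
  check_scalar_num(n_constructs, "n_constructs", positive = TRUE, integer = TRUE)
  check_scalar_num(n_experiments, "n_experiments", positive = TRUE, integer = TRUE)
  check_scalar_num(bg_mean, "bg_mean", positive = TRUE)
  check_scalar_num(bg_sd, "bg_sd", nonneg = TRUE)
  check_scalar_num(max_fob, "max_fob", min = 6)
  check_scalar_num(n_blanks, "n_blanks", integer = TRUE)
  if (n_blanks < 30) stop_field("n_blanks", "must be >= 30 blank wells")
  check_scalar_num(n_sticky_preys, "n_sticky_preys", nonneg = TRUE, integer = TRUE)
  check_prob(detection_prob, "detection_prob")
  if (!is.list(true_pairs) ||
      !all(vapply(true_pairs, function(p) {
        is.numeric(p) && length(p) == 2L && all(p >= 1) && all(p <= n_constructs)
      }, logical(1)))) {
    stop_field("true_pairs", "must be a list of index pairs within 1..n_constructs")
  }
  structure(list(seed = as.integer(seed),
                 n_constructs = as.integer(n_constructs),
                 n_experiments = as.integer(n_experiments),
                 true_pairs = lapply(true_pairs, function(p) sort(as.integer(p))),
                 bg_mean = bg_mean, bg_sd = bg_sd, max_fob = max_fob,
                 n_blanks = as.integer(n_blanks),
                 n_sticky_preys = as.integer(n_sticky_preys),
                 detection_prob = detection_prob),
            class = "screen_sim_config")
}

#' Label of the negative-control bait column
#'
#' The AP-only construct (alkaline phosphatase without an ectodomain) is the
#' screen's negative-control bait, used to expose promiscuous preys.
#' @export
AP_ONLY <- "AP-only"

#' Construct a single screen experiment object
#'
#' A `screen_experiment` holds one experiment's prey-by-bait OD650 matrix
#' (rows = Fc-fusion preys; columns = AP-fusion baits plus the AP-only
#' negative-control column) and the blank-well OD values used for
#' background estimation.
#'
#' @param experiment_id Identifier.
#' @param od_matrix Numeric matrix, rows named by prey constructs and columns
#'   by bait constructs plus `"AP-only"`; all values must be >= 0.
#' @param blank_values Numeric vector of blank-well OD650 values (>= 30).
#' @return An object of class `screen_experiment`.
#' @export
screen_experiment <- function(experiment_id, od_matrix, blank_values) {
  if (!is.matrix(od_matrix) || !is.numeric(od_matrix) ||
      is.null(rownames(od_matrix)) || is.null(colnames(od_matrix))) {
    stop_field("od_matrix", "must be a numeric matrix with prey row names and bait column names")
  }
  if (any(od_matrix < 0)) stop_field("od_matrix", "OD650 values must be >= 0")
  if (!AP_ONLY %in% colnames(od_matrix)) {
    stop_field("od_matrix", sprintf("must contain an '%s' control column", AP_ONLY))
  }
  baits <- setdiff(colnames(od_matrix), AP_ONLY)
  if (!setequal(baits, rownames(od_matrix))) {
    stop_field("od_matrix", "bait set (excluding control) must equal prey set")
  }
  if (length(blank_values) < 30) {
    stop_field("blank_values", "needs at least 30 blank wells")
  }
  if (any(blank_values < 0)) stop_field("blank_values", "OD650 values must be >= 0")
  structure(list(experiment_id = experiment_id,
                 od_matrix = od_matrix,
                 blank_values = as.numeric(blank_values)),
            class = "screen_experiment")
}

#' Simulate an ELISA interaction screen
#'
#' Generates `n_experiments` independent screen experiments. Every well
#' starts from the Gaussian plate-background model (truncated at zero).
#' Each true pair lights up each of its two orientation wells
#' (AP-X vs Fc-Y and AP-Y vs Fc-X; one diagonal well for self-pairs) with
#' probability `detection_prob` per experiment, at an OD drawn uniformly in
#' 8 to `max_fob` times the background mean. Sticky preys receive elevated
#' OD (6 to `max_fob` fold) against every bait including the AP-only
#' control, in every experiment.
#'
#' @param config A [screen_sim_config()].
#' @return A list with components `experiments` (list of
#'   [screen_experiment()] objects), `truth` (list with `true_pairs` as a
#'   two-column character matrix of construct labels and `sticky_preys`),
#'   and `config`.
#' @examples
#' cfg <- screen_sim_config(seed = 7, n_constructs = 10,
#'                          true_pairs = list(c(1, 4), c(2, 2)))
#' scr <- gen_elisa_screen(cfg)
#' dim(scr$experiments[[1]]$od_matrix)
#' @export
gen_elisa_screen <- function(config) {
  if (!inherits(config, "screen_sim_config")) {
    stop_field("config", "must be a screen_sim_config")
  }
  set.seed(config$seed)
  n <- config$n_constructs
  constructs <- sprintf("C%03d", seq_len(n))
  sticky <- if (config$n_sticky_preys > 0) {
    sort(sample(constructs, config$n_sticky_preys))
  } else character(0)

  experiments <- vector("list", config$n_experiments)
  for (e in seq_len(config$n_experiments)) {
    od <- matrix(pmax(stats::rnorm(n * (n + 1), config$bg_mean, config$bg_sd), 0),
                 nrow = n, ncol = n + 1,
                 dimnames = list(constructs, c(constructs, AP_ONLY)))
    for (pair in config$true_pairs) {
      i <- pair[1]; j <- pair[2]
      wells <- if (i == j) list(c(i, i)) else list(c(i, j), c(j, i))
      for (w in wells) {  # w = (bait index, prey index)
        if (stats::runif(1) < config$detection_prob) {
          od[w[2], w[1]] <- config$bg_mean * stats::runif(1, 8, config$max_fob)
        }
      }
    }
    for (p in sticky) {
      od[p, ] <- config$bg_mean * stats::runif(n + 1, 6, config$max_fob)
    }
    blanks <- pmax(stats::rnorm(config$n_blanks, config$bg_mean, config$bg_sd), 0)
    experiments[[e]] <- screen_experiment(sprintf("exp%d", e), od, blanks)
  }

  true_pairs <- if (length(config$true_pairs)) {
    t(vapply(config$true_pairs,
             function(p) sort(constructs[p]), character(2)))
  } else {
    matrix(character(0), ncol = 2)
  }
  colnames(true_pairs) <- c("construct_a", "construct_b")

  list(experiments = experiments,
       truth = list(true_pairs = true_pairs, sticky_preys = sticky),
       config = config)
}
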