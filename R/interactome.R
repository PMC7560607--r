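#' @name interactome
#' @title ELISA screen calling and interaction-network assembly
#'
#' @description
#' The screen caller turns per-experiment prey-by-bait OD650 matrices into
#' an interaction network. Per plate, the background is the mean of at
#' least 30 blank wells; each well's statistic is its fold over background
#' (FOB). A well is a positive only if FOB exceeds the threshold (strictly,
#' default 5) and its prey is not promiscuous: preys above threshold
#' against every bait, or positive against the AP-only negative-control
#' bait, are rejected for that experiment. Positive wells across
#' experiments and orientations are pooled per unordered construct pair,
#' and pairs detected at least twice (independent of orientation) are
#' accepted.
NULL

#' Estimate the plate background from blank wells
#'
#' Arithmetic mean of the blank-well OD650 values; at least 30 blanks are
#' required.
#'
#' @param experiment A [screen_experiment()].
#' @return Background OD650 (scalar).
#' @export
estimate_background <- function(experiment) {
  blanks <- if (inherits(experiment, "screen_experiment")) {
    experiment$blank_values
  } else {
    experiment
  }
  if (length(blanks) < 30) {
    stop("background estimation requires at least 30 blank wells (got ",
         length(blanks), ")", call. = FALSE)
  }
  mean(blanks)
}

#' Fold-over-background matrix
#'
#' Divides every well's OD650 by the plate background.
#'
#' @param experiment A [screen_experiment()].
#' @param background Plate background OD650 (> 0); defaults to
#'   [estimate_background()] on the experiment's blank wells.
#' @return An object of class `fob_matrix`: list with `fob` (numeric
#'   matrix, same dimnames as the OD matrix), `background`, and
#'   `experiment_id`.
#' @export
compute_fob <- function(experiment, background = estimate_background(experiment)) {
  if (!inherits(experiment, "screen_experiment")) {
    stop_field("experiment", "must be a screen_experiment")
  }
  check_scalar_num(background, "background")
  if (background <= 0) stop_field("background", "must be > 0")
  structure(list(fob = experiment$od_matrix / background,
                 background = background,
                 experiment_id = experiment$experiment_id),
            class = "fob_matrix")
}

#' Call positive wells in one experiment
#'
#' A well is positive iff its FOB strictly exceeds `threshold` and its prey
#' is not flagged as promiscuous. A prey is flagged for the experiment when
#' it exceeds threshold in at least `flag_fraction` of all bait columns
#' (including the AP-only control; default 1, i.e. present in every bait),
#' or when it is positive against the AP-only control at all. Control-column
#' wells never become pair calls.
#'
#' @param fob A `fob_matrix` from [compute_fob()].
#' @param threshold FOB cutoff, strict (default 5).
#' @param flag_fraction Fraction of bait columns above threshold that flags
#'   a prey as promiscuous (default 1).
#' @return List with `calls` (logical prey x bait matrix, control column
#'   excluded), `flagged_preys` (character), `threshold`, `experiment_id`.
#' @export
call_positives <- function(fob, threshold = 5, flag_fraction = 1) {
  if (!inherits(fob, "fob_matrix")) stop_field("fob", "must be a fob_matrix")
  check_scalar_num(threshold, "threshold", positive = TRUE)
  check_prob(flag_fraction, "flag_fraction")
  above <- fob$fob > threshold
  control_pos <- above[, AP_ONLY]
  every_bait <- rowMeans(above) >= flag_fraction
  flagged <- control_pos | every_bait
  baits <- setdiff(colnames(above), AP_ONLY)
  calls <- above[, baits, drop = FALSE]
  calls[flagged, ] <- FALSE
  list(calls = calls,
       flagged_preys = rownames(above)[flagged],
       threshold = threshold,
       experiment_id = fob$experiment_id)
}

#' Merge positive calls across experiments and orientations
#'
#' Each positive well (bait X, prey Y) is one detection event
#' `(experiment, AP-X/Fc-Y)` for the unordered pair \{X, Y\}; homophilic
#' pairs have a single diagonal well per experiment. A pair is accepted
#' when its total event count reaches `min_detections` (default 2),
#' regardless of how the events split across orientations or experiments.
#'
#' @param call_sets List of results from [call_positives()], one per
#'   experiment; all must share the same construct universe.
#' @param min_detections Acceptance threshold on the event count.
#' @return data.frame of interaction calls sorted by (construct_a,
#'   construct_b): columns `construct_a`, `construct_b`, `n_detections`,
#'   `orientations`, `experiments`, `accepted`.
#' @export
merge_experiments <- function(call_sets, min_detections = 2) {
  check_scalar_num(min_detections, "min_detections", positive = TRUE,
                   integer = TRUE)
  if (!length(call_sets)) {
    return(data.frame(construct_a = character(0), construct_b = character(0),
                      n_detections = integer(0), orientations = character(0),
                      experiments = character(0), accepted = logical(0),
                      stringsAsFactors = FALSE))
  }
  universe <- sort(rownames(call_sets[[1]]$calls))
  events <- list()
  for (cs in call_sets) {
    calls <- cs$calls
    if (!setequal(rownames(calls), universe) ||
        !setequal(colnames(calls), universe)) {
      stop("experiments do not share the same construct universe",
           call. = FALSE)
    }
    idx <- which(calls, arr.ind = TRUE)
    if (!nrow(idx)) next
    prey <- rownames(calls)[idx[, 1]]
    bait <- colnames(calls)[idx[, 2]]
    key <- paste(pmin(bait, prey), pmax(bait, prey), sep = "\r")
    orientation <- sprintf("AP-%s/Fc-%s", bait, prey)
    for (k in seq_along(key)) {
      ev <- paste(cs$experiment_id, orientation[k], sep = "|")
      events[[key[k]]] <- union(events[[key[k]]], ev)
    }
  }
  if (!length(events)) {
    return(data.frame(construct_a = character(0), construct_b = character(0),
                      n_detections = integer(0), orientations = character(0),
                      experiments = character(0), accepted = logical(0),
                      stringsAsFactors = FALSE))
  }
  pairs <- do.call(rbind, strsplit(names(events), "\r", fixed = TRUE))
  n_det <- vapply(events, length, integer(1))
  exps <- vapply(events, function(ev) {
    paste(sort(unique(sub("\\|.*$", "", ev))), collapse = ",")
  }, character(1))
  oris <- vapply(events, function(ev) {
    paste(sort(unique(sub("^.*\\|", "", ev))), collapse = ",")
  }, character(1))
  out <- data.frame(construct_a = pairs[, 1], construct_b = pairs[, 2],
                    n_detections = unname(n_det),
                    orientations = unname(oris),
                    experiments = unname(exps),
                    accepted = unname(n_det) >= min_detections,
                    stringsAsFactors = FALSE)
  out[order(out$construct_a, out$construct_b), , drop = FALSE]
}

#' Run the full screen caller over a set of experiments
#'
#' Background estimation, FOB, positive calling and cross-experiment
#' merging in one step.
#'
#' @param experiments List of [screen_experiment()] objects.
#' @param threshold,flag_fraction Passed to [call_positives()].
#' @param min_detections Passed to [merge_experiments()].
#' @return As [merge_experiments()].
#' @examples
#' scr <- gen_elisa_screen(screen_sim_config(seed = 2, n_constructs = 8,
#'                                           true_pairs = list(c(1, 5))))
#' calls <- run_screen_caller(scr$experiments)
#' calls[calls$accepted, ]
#' @export
run_screen_caller <- function(experiments, threshold = 5, flag_fraction = 1,
                              min_detections = 2) {
  call_sets <- lapply(experiments, function(e) {
    call_positives(compute_fob(e), threshold = threshold,
                   flag_fraction = flag_fraction)
  })
  merge_experiments(call_sets, min_detections = min_detections)
}

#' Assemble the interaction network from accepted calls
#'
#' Nodes and edges come from accepted pairs only; modules are the connected
#' components (each containing at least one edge, including self-loop
#' singletons). Ordering is lexicographic throughout for reproducible
#' output.
#'
#' @param calls data.frame from [merge_experiments()].
#' @return An `interaction_network`: list with `nodes`, `edges` (data.frame
#'   with any novelty annotation preserved), `modules` (list of sorted node
#'   vectors), and `graph` (the underlying igraph object).
#' @export
build_network <- function(calls) {
  accepted <- calls[calls$accepted, , drop = FALSE]
  nodes <- sort(unique(c(accepted$construct_a, accepted$construct_b)))
  g <- igraph::graph_from_data_frame(
    accepted[, c("construct_a", "construct_b"), drop = FALSE],
    directed = FALSE,
    vertices = if (length(nodes)) data.frame(name = nodes) else NULL
  )
  modules <- list()
  if (length(nodes)) {
    comp <- igraph::components(g)
    modules <- unname(split(names(comp$membership), comp$membership))
    modules <- lapply(modules, sort)
    modules <- modules[order(vapply(modules, `[`, character(1), 1))]
  }
  structure(list(nodes = nodes,
                 edges = accepted[order(accepted$construct_a,
                                        accepted$construct_b), , drop = FALSE],
                 modules = modules,
                 graph = g),
            class = "interaction_network")
}

#' Flag novel edges against a list of known pairs
#'
#' An edge is novel iff the unordered pair is absent from `known_pairs`.
#'
#' @param network An `interaction_network` from [build_network()].
#' @param known_pairs Two-column matrix or data.frame of construct pairs
#'   (order within a pair is irrelevant).
#' @return The network with a logical `novel` column added to `edges`.
#' @export
annotate_novelty <- function(network, known_pairs) {
  if (!inherits(network, "interaction_network")) {
    stop_field("network", "must be an interaction_network")
  }
  known <- character(0)
  if (length(known_pairs)) {
    kp <- as.matrix(known_pairs)
    if (ncol(kp) != 2) stop_field("known_pairs", "must have two columns")
    known <- paste(pmin(kp[, 1], kp[, 2]), pmax(kp[, 1], kp[, 2]), sep = "\r")
  }
  e <- network$edges
  key <- paste(pmin(e$construct_a, e$construct_b),
               pmax(e$construct_a, e$construct_b), sep = "\r")
  network$edges$novel <- !(key %in% known)
  network
}

#' Combinatorial layout of the pairwise screen
#'
#' For a panel of `n_constructs` ectodomains screened in both orientations,
#' returns the number of test wells per experiment (`n^2`, control column
#' excluded), the number of unique unordered pairs covered
#' (`n (n + 1) / 2`), and the total count of tagged constructs produced
#' (`2 n`: one AP and one Fc fusion each).
#'
#' @param n_constructs Panel size.
#' @return Named list: `wells_per_experiment`, `unique_pairs`,
#'   `total_tagged_constructs`.
#' @examples
#' screen_design(73)  # 5329 wells, 2701 unique pairs, 146 tagged constructs
#' @export
screen_design <- function(n_constructs) {
  check_scalar_num(n_constructs, "n_constructs", positive = TRUE,
                   integer = TRUE)
  n <- as.integer(n_constructs)
  list(wells_per_experiment = n * n,
       unique_pairs = n * (n + 1L) %/% 2L,
       total_tagged_constructs = 2L * n)
}
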