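test_that("background estimation is the blank-well mean, minimum 30 wells", {
  expect_equal(estimate_background(toy_screen_experiment(blanks = rep(0.05, 40))),
               0.05)
  expect_equal(estimate_background(0.01 * (1:30)), 0.155)
  expect_error(estimate_background(rep(0.07, 29)), "30")
})

test_that("FOB is OD over background, with exact boundary semantics", {
  od <- matrix(0.07, 3, 4, dimnames = list(c("X", "Y", "Z"),
                                           c("X", "Y", "Z", AP_ONLY)))
  od["Y", "X"] <- 0.35  # FOB exactly 5 under background 0.07
  od["Z", "X"] <- 0.42  # FOB 6
  exp1 <- toy_screen_experiment(od)
  fob <- compute_fob(exp1, background = 0.07)
  expect_equal(fob$fob["Y", "X"], 5)
  expect_equal(fob$fob["X", "X"], 1)
  expect_error(compute_fob(exp1, background = 0), "background")

  calls <- call_positives(fob)
  expect_false(calls$calls["Y", "X"])  # strict >5: boundary is negative
  expect_true(calls$calls["Z", "X"])
})

test_that("promiscuous preys are rejected; independent positives survive", {
  od <- matrix(0.07, 3, 4, dimnames = list(c("X", "Y", "Z"),
                                           c("X", "Y", "Z", AP_ONLY)))
  od["Y", ] <- 0.6          # prey Y lights up every bait incl. control
  od["Z", "X"] <- 0.5       # independent true positive
  calls <- call_positives(compute_fob(toy_screen_experiment(od),
                                      background = 0.07))
  expect_identical(calls$flagged_preys, "Y")
  expect_false(any(calls$calls["Y", ]))
  expect_true(calls$calls["Z", "X"])

  # positive against the AP-only control alone also flags the prey
  od2 <- matrix(0.07, 3, 4, dimnames = dimnames(od))
  od2["X", AP_ONLY] <- 0.6
  od2["X", "Y"] <- 0.6
  calls2 <- call_positives(compute_fob(toy_screen_experiment(od2),
                                       background = 0.07))
  expect_identical(calls2$flagged_preys, "X")
  expect_false(any(calls2$calls))

  # all-background plate: no calls at all
  calls3 <- call_positives(compute_fob(toy_screen_experiment(),
                                       background = 0.07))
  expect_false(any(calls3$calls))
})

test_that("merging counts (experiment, orientation) events per unordered pair", {
  mk_calls <- function(id, positives) {
    calls <- matrix(FALSE, 3, 3, dimnames = list(c("X", "Y", "Z"),
                                                 c("X", "Y", "Z")))
    for (p in positives) calls[p[2], p[1]] <- TRUE  # (bait, prey)
    list(calls = calls, flagged_preys = character(0), threshold = 5,
         experiment_id = id)
  }
  # one orientation in exp1, the opposite in exp3 -> 2 events, accepted
  merged <- merge_experiments(list(mk_calls("exp1", list(c("X", "Y"))),
                                   mk_calls("exp2", list()),
                                   mk_calls("exp3", list(c("Y", "X")))))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_detections, 2)
  expect_true(merged$accepted)
  expect_identical(merged$experiments, "exp1,exp3")

  # a single detection is rejected
  once <- merge_experiments(list(mk_calls("exp1", list(c("X", "Z")))))
  expect_false(once$accepted)

  # both orientations in all 3 experiments -> the full 3x2 event grid
  both <- list(c("X", "Y"), c("Y", "X"))
  full <- merge_experiments(list(mk_calls("exp1", both),
                                 mk_calls("exp2", both),
                                 mk_calls("exp3", both)))
  expect_equal(full$n_detections, 6)

  # homophilic pair: one diagonal well per experiment, at most 3 events
  homo <- merge_experiments(list(mk_calls("exp1", list(c("Z", "Z"))),
                                 mk_calls("exp2", list(c("Z", "Z"))),
                                 mk_calls("exp3", list(c("Z", "Z")))))
  expect_equal(homo$n_detections, 3)
  expect_identical(homo$construct_a, homo$construct_b)

  bad <- mk_calls("exp2", list())
  rownames(bad$calls) <- colnames(bad$calls) <- c("X", "Y", "W")
  expect_error(merge_experiments(list(mk_calls("exp1", list()), bad)),
               "universe")
})

test_that("accepted pairs are invariant under orientation relabeling", {
  scr <- gen_elisa_screen(screen_sim_config(
    seed = 31, n_constructs = 15, detection_prob = 0.7,
    true_pairs = list(c(1, 2), c(3, 9), c(5, 5), c(10, 14))))
  call_sets <- lapply(scr$experiments, function(e) call_positives(compute_fob(e)))
  flipped <- lapply(call_sets, function(cs) {
    cs$calls <- t(cs$calls)
    cs
  })
  a <- merge_experiments(call_sets)
  b <- merge_experiments(flipped)
  pick <- function(d) {
    d <- d[d$accepted, c("construct_a", "construct_b", "n_detections")]
    rownames(d) <- NULL
    d
  }
  expect_identical(pick(a), pick(b))
})

test_that("raising the FOB threshold never adds accepted pairs", {
  scr <- gen_elisa_screen(screen_sim_config(
    seed = 32, n_constructs = 12, detection_prob = 0.8,
    true_pairs = list(c(1, 4), c(2, 8), c(6, 11))))
  accepted_at <- function(thr) {
    calls <- run_screen_caller(scr$experiments, threshold = thr)
    acc <- calls[calls$accepted, ]
    paste(acc$construct_a, acc$construct_b)
  }
  prev <- accepted_at(5)
  for (thr in c(8, 12, 20, 45)) {
    cur <- accepted_at(thr)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("planted pairs are recovered exactly at high detection probability", {
  for (s in 1:20) {
    truth_idx <- list(c(1, 7), c(3, 12), c(5, 18))
    scr <- gen_elisa_screen(screen_sim_config(
      seed = 200 + s, n_constructs = 20, detection_prob = 0.9,
      true_pairs = truth_idx))
    calls <- run_screen_caller(scr$experiments)
    acc <- calls[calls$accepted, ]
    got <- sort(paste(acc$construct_a, acc$construct_b))
    want <- sort(paste(scr$truth$true_pairs[, 1], scr$truth$true_pairs[, 2]))
    expect_identical(got, want)
  }
})

test_that("a uniform sticky prey never produces accepted pairs", {
  for (s in 1:10) {
    scr <- gen_elisa_screen(screen_sim_config(seed = 300 + s,
                                              n_constructs = 15,
                                              n_sticky_preys = 2))
    calls <- run_screen_caller(scr$experiments)
    acc <- calls[calls$accepted, ]
    sticky <- scr$truth$sticky_preys
    expect_false(any(acc$construct_a %in% sticky | acc$construct_b %in% sticky))
  }
})

test_that("network assembly finds connected components deterministically", {
  empty <- build_network(merge_experiments(list()))
  expect_length(empty$nodes, 0)
  expect_length(empty$modules, 0)

  calls <- data.frame(construct_a = c("A", "B", "D", "X"),
                      construct_b = c("B", "C", "E", "X"),
                      n_detections = c(2L, 3L, 2L, 2L),
                      orientations = "", experiments = "",
                      accepted = TRUE, stringsAsFactors = FALSE)
  net <- build_network(calls)
  expect_identical(net$nodes, c("A", "B", "C", "D", "E", "X"))
  # union-find oracle: {A,B,C}, {D,E}, and the self-loop module {X}
  expect_identical(net$modules,
                   list(c("A", "B", "C"), c("D", "E"), "X"))
  expect_equal(igraph::ecount(net$graph), 4)

  # rejected calls contribute nothing
  calls$accepted[2] <- FALSE
  net2 <- build_network(calls)
  expect_false("C" %in% net2$nodes)
})

test_that("novelty is an unordered set difference against known pairs", {
  calls <- data.frame(construct_a = c("A", "B", "C", "D", "E"),
                      construct_b = c("B", "C", "D", "E", "A"),
                      n_detections = 2L, orientations = "", experiments = "",
                      accepted = TRUE, stringsAsFactors = FALSE)
  net <- build_network(calls)

  all_novel <- annotate_novelty(net, matrix(character(0), ncol = 2))
  expect_true(all(all_novel$edges$novel))

  # reversed order in the known list still matches (unordered comparison)
  known <- rbind(c("B", "A"), c("C", "D"))
  net2 <- annotate_novelty(net, known)
  expect_equal(sum(!net2$edges$novel), 2)
  expect_equal(sum(net2$edges$novel), 3)
})

test_that("screen design identities hold for the 73-construct panel", {
  d <- screen_design(73)
  expect_identical(d$wells_per_experiment, 5329L)
  expect_identical(d$unique_pairs, 2701L)
  expect_identical(d$total_tagged_constructs, 146L)
  # generic identities
  for (n in c(1L, 5L, 20L)) {
    dd <- screen_design(n)
    expect_identical(dd$wells_per_experiment, n * n)
    expect_identical(dd$unique_pairs, n * (n + 1L) %/% 2L)
  }
})
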