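test_that("peptide filter keeps proteins with >= min summed identifications", {
  tbl <- toy_count_table()
  kept <- filter_by_peptides(tbl)
  expect_identical(kept$protein_id, c("A", "B", "C"))  # D sums to 2

  # boundary: (1,1,1,0,0,0) sums to exactly 3 -> retained
  one <- data.frame(protein_id = "X", length_aa = 100L,
                    spc_MF_1 = 1L, spc_MF_2 = 1L, spc_MF_3 = 1L,
                    spc_P2_1 = 0L, spc_P2_2 = 0L, spc_P2_3 = 0L,
                    pep_MF_1 = 1L, pep_MF_2 = 1L, pep_MF_3 = 1L,
                    pep_P2_1 = 0L, pep_P2_2 = 0L, pep_P2_3 = 0L)
  expect_equal(nrow(filter_by_peptides(one)), 1)

  # hand enumeration: per-protein totals 0..4 -> exactly 2 retained
  totals <- data.frame(protein_id = paste0("P", 0:4), length_aa = 100L,
                       spc_MF_1 = 0:4, spc_P2_1 = 0L,
                       pep_MF_1 = 0:4, pep_P2_1 = 0L)
  expect_equal(nrow(filter_by_peptides(totals)), 2)

  # all-zero protein removed; empty table passes through
  expect_false("P0" %in% filter_by_peptides(totals)$protein_id)
  expect_equal(nrow(filter_by_peptides(totals[0, ])), 0)
})

test_that("NSAF matches hand-computed values and normalizes each sample to 1", {
  one <- data.frame(protein_id = "A", length_aa = 100L, spc_S_1 = 10L)
  expect_equal(unname(compute_nsaf(one)[, 1]), 1)

  two <- data.frame(protein_id = c("A", "B"), length_aa = c(100L, 200L),
                    spc_S_1 = c(10L, 20L))  # equal SpC/L
  expect_equal(unname(compute_nsaf(two)[, 1]), c(0.5, 0.5))

  # SAF = (0.1, 0.2, 0.1), total 0.4
  three <- data.frame(protein_id = c("A", "B", "C"),
                      length_aa = c(100L, 100L, 300L),
                      spc_S_1 = c(10L, 20L, 30L))
  expect_equal(unname(compute_nsaf(three)[, 1]), c(0.25, 0.50, 0.25))

  tbl <- filter_by_peptides(toy_count_table())
  nsaf <- compute_nsaf(tbl)
  expect_equal(unname(colSums(nsaf)), rep(1, 4), tolerance = 1e-9)
  expect_true(all(nsaf[as.matrix(tbl[, grep("^spc_", names(tbl))]) == 0] == 0))

  expect_error(compute_nsaf(data.frame(protein_id = "A", length_aa = 0L,
                                       spc_S_1 = 1L)), "length")
  zerocol <- data.frame(protein_id = "A", length_aa = 100L,
                        spc_S_1 = 1L, spc_S_2 = 0L)
  expect_warning(nz <- compute_nsaf(zerocol), "all-zero")
  expect_equal(unname(nz[1, ]), c(1, 0))
})

test_that("imputation zeroes exactly the unidentified positions", {
  tbl <- filter_by_peptides(toy_count_table())
  nsaf <- compute_nsaf(tbl)
  imp <- impute_missing(nsaf, tbl)
  spc <- as.matrix(tbl[, grep("^spc_", names(tbl))])
  for (i in seq_len(nrow(imp))) {
    for (j in seq_len(ncol(imp))) {
      if (spc[i, j] == 0) expect_identical(imp[i, j], 0)
      else expect_identical(imp[i, j], nsaf[i, j])
    }
  }
  expect_error(impute_missing(nsaf[1:2, ], tbl), "shape")
})

test_that("log2 fold change follows the group-mean ratio with Inf sentinels", {
  m <- matrix(c(0.02, 0.03, 0.01, 0.01, 0.01, 0.01), nrow = 1,
              dimnames = list("A", c("MF_1", "MF_2", "MF_3",
                                     "P2_1", "P2_2", "P2_3")))
  expect_equal(unname(log2_fold_change(m)), 1)  # log2(0.02/0.01)

  eq <- m; eq[1, ] <- 0.05
  expect_equal(unname(log2_fold_change(eq)), 0)

  x4 <- m; x4[1, 1:3] <- 0.04; x4[1, 4:6] <- 0.01
  expect_equal(unname(log2_fold_change(x4)), 2)

  excl <- m; excl[1, 4:6] <- 0
  expect_identical(unname(log2_fold_change(excl)), Inf)
  none <- m; none[1, ] <- 0
  expect_true(is.nan(log2_fold_change(none)))
})

test_that("t test agrees with the closed-form pooled-variance oracle", {
  cn <- c("MF_1", "MF_2", "MF_3", "P2_1", "P2_2", "P2_3")
  m <- matrix(c(1, 2, 3, 1, 2, 3), nrow = 1, dimnames = list("A", cn))
  expect_equal(as.numeric(protein_t_test(m)), 1)  # identical groups -> t = 0

  # closed-form equal-variance t with df = 4, computed independently
  x <- c(0, 0, 0); y <- c(4, 5, 6)
  m2 <- matrix(c(x, y), nrow = 1, dimnames = list("A", cn))
  sp2 <- ((3 - 1) * var(x) + (3 - 1) * var(y)) / 4
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 4)
  expect_equal(as.numeric(protein_t_test(m2)), p_oracle, tolerance = 1e-12)

  # degenerate policy: both groups constant
  zz <- matrix(0, nrow = 1, ncol = 6, dimnames = list("A", cn))
  p <- protein_t_test(zz)
  expect_equal(as.numeric(p), 1)
  expect_true(attr(p, "degenerate"))
  cc <- matrix(c(2, 2, 2, 5, 5, 5), nrow = 1, dimnames = list("A", cn))
  expect_equal(as.numeric(protein_t_test(cc)), 0)

  expect_error(protein_t_test(m2[, c(1, 4), drop = FALSE]), "2 samples")
})

test_that("Welch and log-transform variants run and differ where they should", {
  cn <- c("MF_1", "MF_2", "MF_3", "P2_1", "P2_2", "P2_3")
  m <- matrix(c(10, 11, 12, 1, 5, 9) / 100, nrow = 1, dimnames = list("A", cn))
  p_student <- as.numeric(protein_t_test(m))
  p_welch <- as.numeric(protein_t_test(m, welch = TRUE))
  expect_equal(p_welch, unname(t.test(m[1, 1:3], m[1, 4:6])$p.value))
  expect_false(isTRUE(all.equal(p_student, p_welch)))
  expect_true(is.finite(protein_t_test(m, log_transform = TRUE)))
})

test_that("BH adjustment matches the step-down oracle and flags the cutoff", {
  bh <- bh_adjust(c(0.01, 0.02, 0.03, 0.5))
  expect_equal(bh$q, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh$cutoff_rank, 3L)
  expect_identical(bh$high_confidence, c(TRUE, TRUE, TRUE, FALSE))

  expect_equal(bh_adjust(0.01)$q, 0.01)                # m = 1
  expect_equal(bh_adjust(rep(0.2, 5))$q, rep(0.2, 5))  # ties
  expect_equal(bh_adjust(numeric(0))$cutoff_rank, 0L)
  expect_error(bh_adjust(c(0.5, 1.2)), "p_values")

  # q >= p elementwise and q non-decreasing along the p ranking
  set.seed(42)
  for (rep in 1:5) {
    p <- runif(50)^2
    q <- bh_adjust(p)$q
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("full pipeline reproduces the hand-computed fixture table", {
  res <- run_enrichment(toy_count_table(), min_peptides = 3)
  expect_identical(res$protein_id, c("A", "B", "C"))

  # NSAF means by hand: A MF (5/9 + 2/3)/2 = 11/18, P2 1/2;
  # B MF 1/18, P2 1/2; C MF 1/3, P2 0
  expect_equal(res$log2fc,
               c(log2((11 / 18) / 0.5), log2((1 / 18) / 0.5), Inf))
  # closed-form two-sided p for df = 2: 1 - t / sqrt(2 + t^2), with
  # t = 2 (A) and t = 8 (B); C is degenerate with differing constants
  expect_equal(res$p_value,
               c(1 - 2 / sqrt(6), 1 - 8 / sqrt(66), 0), tolerance = 1e-12)
  p <- res$p_value
  expect_equal(res$q_value, c(p[1], min(p[2] * 3 / 2, p[1]), 0),
               tolerance = 1e-12)
  expect_identical(res$detection_class, c("shared", "shared", "MF-exclusive"))
  expect_identical(res$significant, c(FALSE, TRUE, TRUE))
  expect_identical(res$high_confidence, c(FALSE, TRUE, TRUE))

  s <- enrichment_summary(res)
  expect_equal(s$n_exclusive_significant, 1)
  expect_equal(s$n_high_confidence, 2)
})

test_that("pipeline is permutation-equivariant in the protein rows", {
  sim <- gen_spectral_counts(count_sim_config(seed = 21, n_proteins = 40,
                                              n_enriched = 5, n_exclusive = 3))
  res <- run_enrichment(sim$counts)
  set.seed(1)
  perm <- sample(nrow(sim$counts))
  res_perm <- run_enrichment(sim$counts[perm, ])
  reordered <- res_perm[match(res$protein_id, res_perm$protein_id), ]
  rownames(reordered) <- NULL
  attr(reordered, "summary") <- attr(res, "summary")
  expect_equal(reordered, res)
})

test_that("planted enrichment is recovered with controlled false discoveries", {
  # well-powered regime: 1000-protein panel, replicate CV ~20%, 20 planted
  # 8-fold enrichments; the high-confidence set should find >= 80% of them
  # with an observed false-discovery proportion <= 15%
  sens <- fdp <- numeric(20)
  for (s in 1:20) {
    sim <- gen_spectral_counts(count_sim_config(
      seed = s, n_proteins = 1000, n_enriched = 20, enrichment_fold = 8,
      baseline_mean = 30, dispersion = 100))
    res <- run_enrichment(sim$counts)
    truth <- sim$truth$class[match(res$protein_id, sim$truth$protein_id)]
    hc <- res$high_confidence
    sens[s] <- sum(hc & truth == "enriched") / 20
    fdp[s] <- if (sum(hc)) sum(hc & truth == "null") / sum(hc) else 0
  }
  expect_gte(mean(sens), 0.8)
  expect_lte(mean(fdp), 0.15)
})
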