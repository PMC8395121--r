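small_cfg <- function(...) {
  synthetic_config(n_genes = 800, n_gene_sets = 10,
                   set_size_range = c(10, 20), n_planted_sets = 2, ...)
}

test_that("invalid configurations are rejected with all violations listed", {
  err <- tryCatch(
    synthetic_config(n_genes = 0,
                     initial_state_probs = c(U = 0.5, D = 0.5, N = 0.5),
                     attenuation_micro = 1.5),
    error = function(e) conditionMessage(e))
  expect_match(err, "n_genes")
  expect_match(err, "initial_state_probs")
  expect_match(err, "attenuation_micro")
  expect_error(synthetic_config(transition_t1_t2 = diag(3) * 2),
               "row-stochastic")
  expect_error(synthetic_config(n_planted_sets = 200, n_gene_sets = 10),
               "n_planted_sets")
})

test_that("the same seed reproduces byte-identical tables", {
  cfg <- small_cfg(seed = 17)
  s1 <- simulate_paired_study(cfg)
  s2 <- simulate_paired_study(cfg)
  expect_identical(s1$tables, s2$tables)
  expect_identical(s1$truth$states, s2$truth$states)
  s3 <- simulate_paired_study(small_cfg(seed = 18))
  expect_false(identical(s1$tables$rnaseq[[1]]$log2fc,
                         s3$tables$rnaseq[[1]]$log2fc))
})

test_that("a degenerate config with shared noise makes the platforms identical", {
  cfg <- small_cfg(attenuation_micro = 1, shift_micro = 0,
                   dropout_up_micro = 0, se_rnaseq = 0.3, se_micro = 0.3,
                   share_noise = TRUE, seed = 4)
  sim <- simulate_paired_study(cfg)
  for (t in 1:3) {
    expect_equal(as.data.frame(sim$tables$rnaseq[[t]]),
                 as.data.frame(sim$tables$micro[[t]]))
  }
})

test_that("a pure-null config yields (almost) no discoveries after BH", {
  cfg <- small_cfg(initial_state_probs = c(U = 0, D = 0, N = 1),
                   transition_t1_t2 = diag(3),
                   transition_t2_t3 = diag(3),
                   shift_micro = 0, dropout_up_micro = 0,
                   timepoints = 1, seed = 23)
  # over replicates, the per-table false-positive rate after BH stays at
  # or below the nominal level (binomial slack on 20 tables)
  n_any <- 0
  for (i in 1:20) {
    cfg$seed <- 100 + i
    sim <- simulate_paired_study(cfg)
    expect_true(all(sim$truth$states == "N"))
    n_deg <- sum(sim$calls$rnaseq[[1]]$call %in% c("UP", "DOWN"))
    if (n_deg > 0) n_any <- n_any + 1
  }
  expect_lte(n_any / 20, 0.05 + 3 * sqrt(0.05 * 0.95 / 20))
})

test_that("calls-direct mode emits the Markov states as noise-free calls", {
  cfg <- small_cfg(seed = 6)
  sim <- simulate_paired_study(cfg, mode = "calls-direct")
  expect_null(sim$tables)
  expect_length(sim$calls, 3L)
  map <- c(U = "UP", D = "DOWN", N = "NS")
  for (t in 1:3) {
    expect_equal(sim$calls[[t]]$call,
                 unname(map[sim$truth$states[, t]]))
  }
  expect_false(any(sim$truth$dropout))
})

test_that("microarray dropout removes truly upregulated genes from the BH family", {
  cfg <- small_cfg(dropout_up_micro = 1, seed = 31)
  sim <- simulate_paired_study(cfg)
  for (t in 1:3) {
    up <- sim$truth$states[, t] == "U"
    expect_true(all(is.na(sim$tables$micro[[t]]$adj_pvalue[up])))
    expect_true(all(sim$truth$dropout[up, t]))
    # RNA-Seq is unaffected
    expect_false(anyNA(sim$tables$rnaseq[[t]]$adj_pvalue))
  }
})

test_that("latent effects always carry the sign of the true state", {
  sim <- simulate_paired_study(small_cfg(seed = 12))
  for (t in 1:3) {
    st <- sim$truth$states[, t]
    ef <- sim$truth$effects[, t]
    expect_true(all(ef[st == "U"] > 0))
    expect_true(all(ef[st == "D"] < 0))
    expect_true(all(ef[st == "N"] == 0))
  }
})

test_that("noise-free probe matrices are recovered exactly by median polish", {
  sim <- simulate_probe_matrix(n_genes = 20, n_samples = 4,
                               n_probes_per_gene = 3, affinity_sd = 0,
                               shift_sd = 0, noise_sd = 0, tail_frac = 0.5,
                               seed = 2)
  summarized <- rma_summarize(sim$matrix, sim$probe_gene, normalize = FALSE)
  ctrl <- sim$group == "ctrl"
  est <- rowMeans(summarized[, !ctrl, drop = FALSE]) -
    rowMeans(summarized[, ctrl, drop = FALSE])
  expect_equal(unname(est), unname(sim$truth$gene_effects),
               tolerance = 1e-10)
})

test_that("quantile normalization removes pure sample shifts", {
  sim <- simulate_probe_matrix(n_genes = 50, n_samples = 4,
                               n_probes_per_gene = 2, affinity_sd = 0.3,
                               shift_sd = 1, noise_sd = 0, tail_frac = 0,
                               seed = 3)
  qn <- quantile_normalize(sim$matrix)
  # all columns share the same empirical distribution afterwards
  for (j in 2:ncol(qn)) expect_equal(sort(qn[, 1]), sort(qn[, j]))
})

test_that("summaries track true gene effects under moderate noise", {
  # every gene carries a continuous effect so ranks are unambiguous
  sim <- simulate_probe_matrix(n_genes = 150, n_samples = 8,
                               n_probes_per_gene = 6, noise_sd = 0.2,
                               tail_frac = 1, seed = 9)
  summarized <- rma_summarize(sim$matrix, sim$probe_gene)
  ctrl <- sim$group == "ctrl"
  est <- rowMeans(summarized[, !ctrl]) - rowMeans(summarized[, ctrl])
  expect_gt(cor(est, sim$truth$gene_effects, method = "spearman"), 0.9)
})

test_that("gene set construction honours the plan and plants true signal", {
  cfg <- small_cfg(seed = 40)
  sim <- simulate_paired_study(cfg, mode = "calls-direct")
  sets <- make_gene_sets(sim$truth, cfg)
  expect_length(sets, 10L)
  expect_equal(attr(sets, "planted"), c("SET_001", "SET_002"))
  true_up <- sim$truth$gene_id[sim$truth$states[, 1] == "U"]
  for (nm in attr(sets, "planted")) {
    expect_true(all(sets[[nm]] %in% true_up))
  }
  # fixed sizes and no planting when so configured
  cfg2 <- synthetic_config(n_genes = 500, n_gene_sets = 5,
                           set_size_range = c(10, 10), n_planted_sets = 0,
                           seed = 41)
  sim2 <- simulate_paired_study(cfg2, mode = "calls-direct")
  sets2 <- make_gene_sets(sim2$truth, cfg2)
  expect_true(all(lengths(sets2) == 10L))
  expect_length(attr(sets2, "planted"), 0L)
  # planted sets larger than the true-positive pool are an error
  cfg3 <- synthetic_config(n_genes = 100, n_gene_sets = 2,
                           set_size_range = c(90, 90), n_planted_sets = 1,
                           seed = 42)
  sim3 <- simulate_paired_study(cfg3, mode = "calls-direct")
  expect_error(make_gene_sets(sim3$truth, cfg3), "not enough")
})

test_that("chromosome placement follows observable shares with planted odds", {
  cfg <- synthetic_config(n_genes = 6000, timepoints = 1,
                          initial_state_probs = c(U = 0.1, D = 0.1, N = 0.8),
                          enriched_chromosome = "9",
                          enrichment_multiplier = 4, seed = 50)
  sim <- simulate_paired_study(cfg, mode = "calls-direct")
  deg <- sim$truth$states[, 1] != "N"
  base_p <- cfg$chromosomes["9"] / sum(cfg$chromosomes)
  frac_null <- mean(sim$truth$chromosome[!deg] == "9")
  frac_deg <- mean(sim$truth$chromosome[deg] == "9")
  expect_lt(abs(frac_null - base_p), 3 * sqrt(base_p * (1 - base_p) /
                                                sum(!deg)))
  expect_gt(frac_deg, 2 * frac_null)
})
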