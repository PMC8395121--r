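test_that("regulation calls follow the strict-sign definition", {
  t <- make_deg(paste0("g", 1:6),
                log2fc = c(1.2, -3, 0.5, 0, -1, 2),
                adj_pvalue = c(0.01, 0.2, NA, 0.01, 0.05, 0.049))
  calls <- classify_regulation(t, alpha = 0.05)
  expect_equal(calls$call,
               c("UP",          # significant, positive
                 "NS",          # not significant despite big fold change
                 "UNOBSERVED",  # adj p missing
                 "NS",          # significant but fold change exactly 0
                 "NS",          # adj p == alpha is not < alpha
                 "UP"))
  expect_equal(attr(calls, "alpha"), 0.05)
})

test_that("directional overlap matches hand enumeration on the 6-gene fixture", {
  a <- regulation_calls(paste0("g", 1:6),
                        c("UP", "UP", "DOWN", "DOWN", "NS", "UP"))
  b <- regulation_calls(paste0("g", 1:6),
                        c("UP", "DOWN", "DOWN", "NS", "UP", "NS"))
  ov <- directional_overlap(a, b)
  expect_equal(ov$both_up, 1)
  expect_equal(ov$both_down, 1)
  expect_equal(ov$contradictory_AupBdown, 1)
  expect_equal(ov$contradictory_AdownBup, 0)
  expect_equal(ov$A_only_up, 1)
  expect_equal(ov$A_only_down, 1)
  expect_equal(ov$B_only_up, 1)
  # detection fractions: of 3 A-UP genes, 2 are significant in B, 1 same
  # direction
  expect_equal(ov$fraction_of_A_detected_in_B[["UP"]], 2 / 3)
  expect_equal(ov$fraction_of_A_same_direction_in_B[["UP"]], 1 / 3)
})

test_that("identical call sets give pure concordance; empty A gives B-only", {
  calls <- regulation_calls(paste0("g", 1:10),
                            c(rep("UP", 5), rep("DOWN", 3), "NS", "NS"))
  ov <- directional_overlap(calls, calls)
  expect_equal(ov$both_up, 5)
  expect_equal(ov$both_down, 3)
  expect_equal(ov$contradictory_AupBdown + ov$contradictory_AdownBup +
                 ov$A_only_up + ov$A_only_down + ov$B_only_up +
                 ov$B_only_down, 0)
  all_ns <- regulation_calls(paste0("g", 1:10), rep("NS", 10))
  ov2 <- directional_overlap(all_ns, calls)
  expect_equal(ov2$B_only_up, 5)
  expect_equal(ov2$B_only_down, 3)
  expect_equal(ov2$neither, 2)
  expect_true(is.na(ov2$fraction_of_A_detected_in_B[["UP"]]))
})

test_that("overlap counts match a naive per-gene loop on random fixtures", {
  set.seed(31)
  for (rep in 1:4) {
    n <- sample(100:1000, 1)
    idsA <- sprintf("g%04d", sample(1:1200, n))
    idsB <- sprintf("g%04d", sample(1:1200, n))
    a <- regulation_calls(idsA, sample(c("UP", "DOWN", "NS", "UNOBSERVED"),
                                       n, replace = TRUE))
    b <- regulation_calls(idsB, sample(c("UP", "DOWN", "NS", "UNOBSERVED"),
                                       n, replace = TRUE))
    ov <- directional_overlap(a, b)
    expected <- oracle_overlap(a, b)
    got <- unlist(ov[names(expected)])
    expect_equal(unname(got), unname(expected))
    # the eight called categories partition the union of called genes
    union_called <- length(unique(c(
      a$gene_id[a$call %in% c("UP", "DOWN")],
      b$gene_id[b$call %in% c("UP", "DOWN")])))
    expect_equal(ov$both_up + ov$both_down + ov$contradictory_AupBdown +
                   ov$contradictory_AdownBup + ov$A_only_up +
                   ov$A_only_down + ov$B_only_up + ov$B_only_down,
                 union_called)
  }
})

test_that("inclusion sweep halves the cutoff and counts overlap per step", {
  a <- make_deg(paste0("g", 1:10), log2fc = rep(c(1, -1), 5),
                adj_pvalue = c(0.001, 0.002, 0.004, 0.01, 0.02,
                               0.03, 0.04, 0.2, 0.5, NA))
  b <- make_deg(paste0("g", 1:10), log2fc = rep(c(1, -1), 5),
                adj_pvalue = c(0.002, 0.004, 0.008, 0.016, 0.024,
                               0.06, 0.2, 0.3, 0.4, 0.5))
  curve <- inclusion_sweep(a, b, alpha_fixed = 0.05, n_halvings = 4)
  expect_equal(curve$cutoff_swept,
               c(0.05, 0.025, 0.0125, 0.00625, 0.003125))
  # hand enumeration: A significant at 0.05 = g1..g7
  expect_equal(curve$n_fixed, rep(7L, 5))
  expect_equal(curve$n_swept, c(5L, 5L, 3L, 2L, 1L))
  expect_equal(curve$n_overlap, c(5L, 5L, 3L, 2L, 1L))
  expect_equal(curve$frequency, rep(1, 5))
  # identical tables give frequency 1 throughout
  curve2 <- inclusion_sweep(a, a)
  expect_equal(curve2$frequency, rep(1, nrow(curve2)))
})

test_that("inclusion sweep counts are non-increasing along the curve", {
  for (seed in c(5, 6)) {
    ta <- random_deg(400, seed)
    tb <- random_deg(400, seed + 100)
    curve <- inclusion_sweep(ta, tb, n_halvings = 6)
    expect_true(all(diff(curve$n_swept) <= 0))
    expect_true(all(diff(curve$n_overlap) <= 0))
  }
})

test_that("Spearman concordance reproduces the rank formula", {
  a <- make_deg(paste0("g", 1:5), log2fc = c(0.5, 1.8, -0.3, 2.5, -1.1))
  b_same <- make_deg(paste0("g", 1:5), log2fc = c(0.5, 1.8, -0.3, 2.5, -1.1))
  b_neg <- make_deg(paste0("g", 1:5), log2fc = -c(0.5, 1.8, -0.3, 2.5, -1.1))
  expect_equal(spearman_concordance(a, b_same), 1.0)
  expect_equal(spearman_concordance(a, b_neg), -1.0)
  # hand computation from rank covariance: ranks A = (3,4,2,5,1),
  # B = (2,5,3,1,4) -> rho = 1 - 6*sum(d^2)/(n(n^2-1))
  b <- make_deg(paste0("g", 1:5), log2fc = c(-0.2, 3.0, 0.1, -2.0, 1.0))
  d2 <- sum((c(3, 4, 2, 5, 1) - c(2, 5, 3, 1, 4))^2)
  expect_equal(spearman_concordance(a, b), 1 - 6 * d2 / (5 * 24))
  expect_error(spearman_concordance(
    make_deg(c("g1", "g2"), c(1, 2)), make_deg(c("g1", "g2"), c(1, 2))),
    "fewer than 3")
})

test_that("consensus keeps only same-direction significant genes", {
  a <- make_deg(paste0("g", 1:8),
                log2fc = c(2, -1, 1, -2, 0.5, -0.5, 1, -1),
                adj_pvalue = c(0.01, 0.01, 0.01, 0.01, 0.2, 0.01, NA, 0.04))
  b <- make_deg(paste0("g", 1:8),
                log2fc = c(1, -2, -1, -1, 1, -1, 1, 1),
                adj_pvalue = c(0.02, 0.02, 0.02, 0.2, 0.01, 0.01, 0.01, 0.04))
  cons <- consensus_degs(a, b)
  # g1 both up; g2, g6 both down; g3 contradictory; g4 not sig in B;
  # g5 not sig in A; g7 unobservable in A; g8 opposite signs
  expect_equal(cons$gene_id, c("g1", "g2", "g6"))
  expect_equal(cons$direction, c("UP", "DOWN", "DOWN"))
  expect_equal(cons$avg_log2fc, c(1.5, -1.5, -0.75))
  # symmetry up to field swap
  swapped <- consensus_degs(b, a)
  expect_equal(swapped$gene_id, cons$gene_id)
  expect_equal(swapped$log2fc_A, cons$log2fc_B)
  expect_equal(swapped$avg_log2fc, cons$avg_log2fc)
  # disjoint significant sets are empty
  c_dis <- consensus_degs(
    make_deg(c("g1", "g2"), c(1, 1), adj_pvalue = c(0.01, 0.9)),
    make_deg(c("g1", "g2"), c(1, 1), adj_pvalue = c(0.9, 0.01)))
  expect_equal(nrow(c_dis), 0L)
})

test_that("consensus membership matches the naive loop on random tables", {
  for (seed in c(41, 42)) {
    ta <- random_deg(600, seed)
    tb <- random_deg(600, seed + 7)
    cons <- consensus_degs(ta, tb)
    expect_equal(cons$gene_id, oracle_consensus_ids(ta, tb))
  }
})

test_that("top average-fold-change ranking sorts by magnitude with id ties", {
  set.seed(8)
  n <- 30
  a <- make_deg(sprintf("g%02d", 1:n), log2fc = -runif(n, 0.5, 4),
                adj_pvalue = rep(0.01, n))
  b <- make_deg(sprintf("g%02d", 1:n), log2fc = -runif(n, 0.5, 4),
                adj_pvalue = rep(0.01, n))
  cons <- consensus_degs(a, b)
  top <- rank_by_average_fc(cons, "DOWN", n = 21)
  expect_equal(nrow(top), 21L)
  # independent selection: order by decreasing magnitude then id
  ref <- cons[order(-abs(cons$avg_log2fc), cons$gene_id), ][1:21, ]
  expect_equal(top$gene_id, ref$gene_id)
  expect_true(all(diff(abs(top$avg_log2fc)) <= 0))
  # ties fall back to lexicographic order, short sets returned whole
  tie <- consensus_degs(
    make_deg(c("gB", "gA"), c(-2, -2), adj_pvalue = c(0.01, 0.01)),
    make_deg(c("gB", "gA"), c(-2, -2), adj_pvalue = c(0.01, 0.01)))
  expect_equal(rank_by_average_fc(tie, "DOWN", n = 21)$gene_id,
               c("gA", "gB"))
})

test_that("consensus calls cover the shared gene space", {
  a <- make_deg(paste0("g", 1:5), log2fc = c(2, -1, 1, 1, 1),
                adj_pvalue = c(0.01, 0.01, 0.2, NA, 0.01))
  b <- make_deg(paste0("g", c(1:4, 6)), log2fc = c(1, -2, 1, 1, 1),
                adj_pvalue = c(0.02, 0.02, 0.3, 0.01, 0.01))
  cc <- consensus_calls(a, b)
  expect_equal(cc$call[match(c("g1", "g2", "g3", "g4", "g5", "g6"),
                             cc$gene_id)],
               c("UP", "DOWN", "NS", "UNOBSERVED", "UNOBSERVED",
                 "UNOBSERVED"))
})

test_that("DEU overlap counts significant genes per list", {
  la <- deu_list(paste0("g", 1:5), c(0.01, 0.02, 0.2, 0.01, NA))
  expect_equal(deu_overlap(la, la)$fraction_of_B_in_A, 1.0)
  lb <- deu_list(paste0("g", 6:8), c(0.01, 0.01, 0.01))
  ov <- deu_overlap(la, lb)
  expect_equal(ov$n_overlap, 0L)
  empty <- deu_list(paste0("g", 1:3), c(0.5, 0.6, 0.7))
  expect_true(is.na(deu_overlap(la, empty)$fraction_of_B_in_A))
})
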