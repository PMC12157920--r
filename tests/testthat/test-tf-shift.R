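# Pathway-average profiles, Fisher-z correlation shifts, TF differential
# expression and cross-model overlap.

test_that("pathway_average reduces to the obvious special cases", {
  m <- toy_matrix(cbind(a = c(1, 2, 3, 4), b = c(9, 8, 7, 6)))
  single <- pathway_average(m, "a")
  expect_equal(as.numeric(single), c(1, 2, 3, 4))
  # b = -a + 10: the two-gene average is the constant 5
  both <- pathway_average(m, c("a", "b"))
  expect_equal(as.numeric(both), rep(5, 4))
  expect_equal(attr(both, "n_present"), 2L)
  expect_error(pathway_average(m, "zz"), "no gene")
})

test_that("pathway_average is linear over disjoint sets", {
  set.seed(12)
  m <- toy_matrix(matrix(rnorm(80), 8, 10))
  s1 <- paste0("g", 1:4)
  s2 <- paste0("g", 5:10)
  a1 <- pathway_average(m, s1)
  a2 <- pathway_average(m, s2)
  a12 <- pathway_average(m, c(s1, s2))
  expect_equal(as.numeric(a12), as.numeric((4 * a1 + 6 * a2) / 10),
               tolerance = 1e-12)
})

test_that("planted module average tracks the focal gene with flipped sign", {
  res <- simulate_panel(tiny_config(seed = 2, noise_sd = 0.2))
  prof <- pathway_average(res$matrix, sprintf("neg_mod_%03d", 1:10))
  r <- cor(prof, res$matrix$values[, "FOCAL"])
  expect_lt(r, -0.9)
})

test_that("shift_test reproduces the hand-worked Fisher-z case", {
  st <- shift_test(r_high = 0.0, n_high = 12, r_low = 0.8, n_low = 12)
  expect_equal(st$statistic, atanh(0.8) / sqrt(2 / 9), tolerance = 1e-12)
  expect_equal(st$statistic, 2.3305, tolerance = 1e-3)
  expect_equal(st$p_shift, 0.0198, tolerance = 1e-2)
  expect_identical(st$stars, "*")
  expect_equal(st$delta_r, 0.8)
})

test_that("shift_test trivial and degenerate branches", {
  expect_equal(shift_test(0.5, 30, 0.5, 50)$p_shift, 1)
  expect_equal(shift_test(0.2, 12, 0.2, 12)$statistic, 0)
  expect_error(shift_test(1, 12, 0.5, 12), "clamp")
  cl <- shift_test(1, 12, 0.5, 12, clamp = TRUE)
  expect_true(is.finite(cl$statistic))
  expect_error(shift_test(0.5, 3, 0.5, 12), "n_high")
})

test_that("shift_test is antisymmetric under stratum swap", {
  set.seed(88)
  for (i in 1:20) {
    rh <- runif(1, -0.9, 0.9)
    rl <- runif(1, -0.9, 0.9)
    a <- shift_test(rh, 12, rl, 15)
    b <- shift_test(rl, 15, rh, 12)
    expect_equal(a$delta_r, -b$delta_r, tolerance = 1e-12)
    expect_equal(a$p_shift, b$p_shift, tolerance = 1e-12)
  }
})

test_that("stratum correlations recover planted targets at large n", {
  cfg <- sim_config(
    n_strains = 800, n_genes = 30,
    module_specs = data.frame(name = "mod", size = 8L, beta = 0.8,
                              sign = "-", stringsAsFactors = FALSE),
    tf_specs = data.frame(name = "TFX", r_high = 0.8, r_low = -0.4),
    noise_sd = 0.5, seed = 19)
  res <- simulate_panel(cfg)
  s <- assign_strata(rank_focal(res$matrix, "FOCAL"), fraction = 0.25)
  prof <- pathway_average(res$matrix, sprintf("mod_%03d", 1:8))
  rc <- tf_stratum_correlations(res$matrix, "TFX", prof, s)
  expect_lt(abs(rc$r_high - 0.8), 0.15)
  expect_lt(abs(rc$r_low - (-0.4)), 0.15)
})

test_that("missing TFs are reported, tiny strata rejected", {
  res <- simulate_panel(tiny_config(seed = 1))
  s <- assign_strata(rank_focal(res$matrix, "FOCAL"), fraction = 0.25)
  prof <- pathway_average(res$matrix, sprintf("neg_mod_%03d", 1:10))
  rc <- tf_stratum_correlations(res$matrix, c("TF01", "ghost"), prof, s)
  expect_identical(rc$missing, c(FALSE, TRUE))
  expect_true(is.na(rc$r_high[2]))
  s_small <- assign_strata(rank_focal(res$matrix, "FOCAL"),
                           n_high = 3, n_low = 3)
  expect_error(tf_stratum_correlations(res$matrix, "TF01", prof, s_small),
               ">= 4")
})

test_that("a TF identical to the profile correlates perfectly", {
  res <- simulate_panel(tiny_config(seed = 1))
  s <- assign_strata(rank_focal(res$matrix, "FOCAL"), fraction = 0.25)
  prof <- pathway_average(res$matrix, "neg_mod_001")  # single-gene profile
  rc <- tf_stratum_correlations(res$matrix, "neg_mod_001", prof, s)
  expect_equal(rc$r_high, 1.0, tolerance = 1e-12)
  expect_equal(rc$r_low, 1.0, tolerance = 1e-12)
})

test_that("tf_differential_expression calls directions correctly", {
  m <- toy_matrix(matrix(rnorm(60, 8), 10, 6))
  # identical groups -> ns
  de <- tf_differential_expression(m, paste0("s", 1:5), paste0("s", 1:5),
                                   "g1")
  expect_identical(de$direction, "ns")
  expect_error(tf_differential_expression(m, "s1", paste0("s", 2:4), "g1"),
               ">= 2")

  res <- simulate_panel(tiny_config(seed = 10))
  s <- assign_strata(rank_focal(res$matrix, "FOCAL"), fraction = 0.25)
  de2 <- tf_differential_expression(
    res$matrix, stratum_samples(s, "LOW"), stratum_samples(s, "HIGH"),
    c("TF01", "ghost"))
  expect_identical(de2$direction[1], "depleted")  # planted de_panel = -2
  expect_true(de2$missing[2])
  expect_true(all(de2$p_adj >= de2$p, na.rm = TRUE))
})

test_that("n=3 groups detect a matched effect less often than n=12", {
  effect <- 1.0
  det <- function(n, s) {
    set.seed(s)
    g1 <- rnorm(n, 8 + effect, 0.5)
    g2 <- rnorm(n, 8, 0.5)
    t.test(g1, g2)$p.value < 0.05
  }
  rate3 <- mean(vapply(1:200, function(s) det(3, s), logical(1)))
  rate12 <- mean(vapply(1:200, function(s) det(12, 10000 + s), logical(1)))
  expect_lt(rate3, rate12)
  expect_gt(rate12, 0.9)
})

test_that("summarize_shifts counts planted negative shifts", {
  records <- data.frame(tf = paste0("T", 1:12),
                        delta_r = c(rep(-0.8, 10), 0.5, 0.2),
                        p_shift = c(rep(1e-4, 10), 0.5, 0.9))
  expect_equal(summarize_shifts(records),
               c(n_significant = 10L, n_negative = 10L, n_positive = 0L))
  expect_equal(summarize_shifts(records, alpha = 0),
               c(n_significant = 0L, n_negative = 0L, n_positive = 0L))
})

test_that("under equal coupling the shift-test null rate is calibrated", {
  set.seed(606)
  n <- 12
  reps <- 1500
  hits <- 0
  for (i in seq_len(reps)) {
    base <- rnorm(2 * n)
    x <- 0.5 * base + sqrt(1 - 0.25) * rnorm(2 * n)
    r1 <- cor(x[1:n], base[1:n])
    r2 <- cor(x[(n + 1):(2 * n)], base[(n + 1):(2 * n)])
    if (shift_test(r1, n, r2, n)$p_shift < 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.03)
  expect_lte(hits / reps, 0.07)
})

test_that("bootstrap shift test agrees with Fisher z on planted shifts", {
  cfg <- sim_config(
    n_strains = 80, n_genes = 30,
    module_specs = data.frame(name = "mod", size = 8L, beta = 0.8,
                              sign = "-", stringsAsFactors = FALSE),
    tf_specs = data.frame(name = c("TFS", "TFN"),
                          r_high = c(0.7, 0.2), r_low = c(-0.7, 0.2)),
    noise_sd = 0.5, seed = 3)
  res <- simulate_panel(cfg)
  s <- assign_strata(rank_focal(res$matrix, "FOCAL"), fraction = 0.25)
  prof <- pathway_average(res$matrix, sprintf("mod_%03d", 1:8))
  fis <- tf_shift_table(res$matrix, c("TFS", "TFN"), prof, s)
  boo <- tf_shift_table(res$matrix, c("TFS", "TFN"), prof, s,
                        method = "bootstrap", n_boot = 500, seed = 1)
  expect_identical(attr(boo, "method"), "bootstrap")
  expect_equal(boo$delta_r, fis$delta_r, tolerance = 1e-12)
  # planted strong shift detected by both; null TF by neither
  expect_lt(fis$p_shift[1], 0.05)
  expect_lt(boo$p_shift[1], 0.05)
  expect_gt(boo$p_shift[2], 0.05)
  # deterministic under the same seed
  boo2 <- tf_shift_table(res$matrix, c("TFS", "TFN"), prof, s,
                         method = "bootstrap", n_boot = 500, seed = 1)
  expect_identical(boo$p_shift, boo2$p_shift)
})

test_that("mean-per-gene-correlation aggregation is available as a flag", {
  res <- simulate_panel(tiny_config(seed = 2))
  s <- assign_strata(rank_focal(res$matrix, "FOCAL"), fraction = 0.25)
  gene_set <- sprintf("neg_mod_%03d", 1:10)
  prof <- pathway_average(res$matrix, gene_set)
  a <- tf_stratum_correlations(res$matrix, "TF01", prof, s)
  b <- tf_stratum_correlations(res$matrix, "TF01", prof, s,
                               aggregate = "mean_r", gene_set = gene_set)
  # same qualitative coupling, different estimator
  expect_identical(sign(a$r_low), sign(b$r_low))
  expect_false(isTRUE(all.equal(a$r_low, b$r_low)))
  # single-gene set: the two readings coincide exactly
  p1 <- pathway_average(res$matrix, "neg_mod_001")
  a1 <- tf_stratum_correlations(res$matrix, "TF01", p1, s)
  b1 <- tf_stratum_correlations(res$matrix, "TF01", p1, s,
                                aggregate = "mean_r",
                                gene_set = "neg_mod_001")
  expect_equal(a1$r_high, b1$r_high, tolerance = 1e-12)
  expect_error(
    tf_stratum_correlations(res$matrix, "TF01", p1, s,
                            aggregate = "mean_r"), "gene_set")
})

test_that("overlap_tfs requires direction concordance", {
  a <- data.frame(tf = c("T1", "T2"), direction = c("depleted", "enriched"))
  b <- data.frame(tf = c("T3", "T4"), direction = c("depleted", "enriched"))
  expect_length(overlap_tfs(a, b), 0)
  b2 <- data.frame(tf = c("T1", "T2"),
                   direction = c("enriched", "depleted"))
  expect_length(overlap_tfs(a, b2), 0)
  b3 <- data.frame(gene = c("T2", "T1"),
                   direction = c("enriched", "depleted"))
  expect_identical(overlap_tfs(a, b3), c("T1", "T2"))
})
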