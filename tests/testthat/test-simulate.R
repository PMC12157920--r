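# Generator contracts: determinism, planted structure, calibration.

test_that("identical config and seed reproduce bit-identical output", {
  a <- simulate_panel(tiny_config(seed = 11))
  b <- simulate_panel(tiny_config(seed = 11))
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth$module_membership, b$truth$module_membership)
  ka <- simulate_ko(tiny_config(seed = 11))
  kb <- simulate_ko(tiny_config(seed = 11))
  expect_identical(ka$values, kb$values)
  # different seed -> different noise
  c_ <- simulate_panel(tiny_config(seed = 12))
  expect_false(identical(a$matrix$values, c_$matrix$values))
})

test_that("adding genes does not perturb existing columns", {
  small <- simulate_panel(tiny_config(seed = 5))
  big <- simulate_panel(tiny_config(seed = 5, n_genes = 90))
  shared <- colnames(small$matrix$values)
  expect_identical(small$matrix$values[, shared],
                   big$matrix$values[, shared])
})

test_that("focal gene spans the configured fold range exactly", {
  res <- simulate_panel(tiny_config(seed = 2))
  f <- res$matrix$values[, "FOCAL"]
  expect_equal(2^(max(f) - min(f)), 3.22, tolerance = 1e-9)
  expect_equal(max(f) / min(f) > 1, TRUE)
  # evenly spaced on log2 scale
  expect_lt(max(abs(diff(sort(f)) - log2(3.22) / (20 - 1))), 1e-12)
})

test_that("every gene appears exactly once across focal/modules/TFs/nulls", {
  res <- simulate_panel(tiny_config())
  tr <- res$truth
  all_genes <- c(tr$focal_gene, names(tr$module_membership),
                 tr$tf_coupling$name, tr$null_genes)
  expect_identical(sort(all_genes), sort(colnames(res$matrix$values)))
  expect_false(anyDuplicated(all_genes) > 0)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_strains = 4), "n_strains")
  expect_error(sim_config(focal_fold_range = 1), "focal_fold_range")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(n_genes = 50), "planted")
  expect_error(
    sim_config(tf_specs = data.frame(name = "T1", r_high = 1, r_low = 0)),
    "infeasible")
  expect_error(
    sim_config(module_specs = data.frame(name = c("m", "m"), size = 2L,
                                         beta = 1, sign = "+")),
    "unique")
})

test_that("all-null world is marginally calibrated", {
  cfg <- sim_config(n_strains = 42, n_genes = 5000,
                    module_specs = data.frame(name = character(0),
                                              size = integer(0),
                                              beta = numeric(0),
                                              sign = character(0)),
                    tf_specs = data.frame(name = character(0),
                                          r_high = numeric(0),
                                          r_low = numeric(0)),
                    seed = 31)
  v <- simulate_panel(cfg)$matrix$values
  nulls <- v[, -1]  # drop the deterministic focal column
  tol <- 3 * 2 / sqrt(length(nulls))
  expect_lt(abs(mean(nulls) - 8), tol)
  expect_lt(abs(sd(as.vector(nulls)) - 2) / 2, 0.02)
})

test_that("planted module-gene correlation converges to the closed form", {
  cfg <- sim_config(n_strains = 500, n_genes = 40,
                    module_specs = data.frame(name = "mod", size = 6L,
                                              beta = 0.8,
                                              sign = c("-"),
                                              stringsAsFactors = FALSE),
                    tf_specs = data.frame(name = "T1", r_high = 0.2,
                                          r_low = 0.2),
                    noise_sd = 0.5, seed = 13)
  res <- simulate_panel(cfg)
  f <- res$matrix$values[, "FOCAL"]
  sdf <- sd(f)
  expected <- -0.8 * sdf / sqrt(0.8^2 * sdf^2 + 0.5^2)
  rr <- cor(f, res$matrix$values[, sprintf("mod_%03d", 1:6)])
  expect_lt(max(abs(rr - expected)), 0.05)
})

test_that("knockout arm silences focal and shifts module genes by sign", {
  cfg <- tiny_config(seed = 9)
  res <- simulate_panel(cfg)
  ko <- simulate_ko(cfg, res$truth)
  ko_ids <- ko$sample_meta$sample[ko$sample_meta$genotype == "KO"]
  wt_ids <- ko$sample_meta$sample[ko$sample_meta$genotype == "WT"]
  expect_length(c(ko_ids, wt_ids), 2 * cfg$ko_replicates)
  expect_true(all(ko$values[ko_ids, "FOCAL"] <
                    min(res$matrix$values[, "FOCAL"])))
  # modules move in their loss direction: a negatively coupled module is
  # up in knockouts (as in low-expressing strains), a positive one down
  neg_fc <- mean(ko$values[ko_ids, "neg_mod_001"]) -
    mean(ko$values[wt_ids, "neg_mod_001"])
  pos_fc <- mean(ko$values[ko_ids, "pos_mod_001"]) -
    mean(ko$values[wt_ids, "pos_mod_001"])
  expect_gt(neg_fc, 0)
  expect_lt(pos_fc, 0)
  expect_error(simulate_ko(tiny_config(ko_replicates = 1)), "ko_replicates")
})

test_that("zero knockout effect yields uniform t-test p over seeds", {
  pvals <- vapply(1:100, function(s) {
    cfg <- tiny_config(seed = s, ko_effect = 0, ko_replicates = 5)
    ko <- simulate_ko(cfg)
    g <- ko$sample_meta$genotype
    t.test(ko$values[g == "KO", "neg_mod_001"],
           ko$values[g == "WT", "neg_mod_001"])$p.value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("strong knockout effect at low noise is always detected (BY)", {
  # "every module gene significant" is a worst-of-m order statistic, so the
  # seed-level rate depends on the module size; asserted for a single
  # 10-gene module (at 3 vs 3, effect 1.0, noise 0.1)
  ms <- data.frame(name = "mod", size = 10L, beta = 0.8, sign = "-",
                   stringsAsFactors = FALSE)
  detected <- vapply(1:50, function(s) {
    cfg <- sim_config(n_strains = 20, n_genes = 25, module_specs = ms,
                      tf_specs = data.frame(name = "T1", r_high = 0,
                                            r_low = 0),
                      ko_effect = 1, ko_replicates = 3, noise_sd = 0.1,
                      seed = s)
    ko <- simulate_ko(cfg)
    g <- ko$sample_meta$genotype
    de <- tf_differential_expression(ko, ko$sample_meta$sample[g == "KO"],
                                     ko$sample_meta$sample[g == "WT"],
                                     sprintf("mod_%03d", 1:10))
    all(de$p_adj < 0.05)
  }, logical(1))
  expect_gte(mean(detected), 0.9)
})

test_that("HFD arm shares focal values but redraws noise and TF coupling", {
  cfg <- tiny_config(seed = 21)
  cd <- simulate_panel(cfg, arm = "CD")
  hfd <- simulate_panel(cfg, arm = "HFD")
  expect_identical(cd$matrix$values[, "FOCAL"], hfd$matrix$values[, "FOCAL"])
  expect_false(identical(cd$matrix$values[, "neg_mod_001"],
                         hfd$matrix$values[, "neg_mod_001"]))
  expect_identical(hfd$matrix$sample_meta$diet, rep("HFD", 20))
})
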