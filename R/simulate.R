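#' Simulation configuration for the synthetic strain panel
#'
#' Describes a strain-panel world with planted, recoverable structure:
#' a focal gene whose log2 expression is evenly spaced across strains over a
#' prescribed linear fold range; gene modules linearly coupled (positively or
#' negatively) to the focal gene; transcription factors whose correlation to
#' the first module's average profile differs between the planted HIGH and
#' LOW expression strata (and may carry a planted expression shift in the
#' panel and/or knockout arms); and independent null genes.
#'
#' Defaults encode the stated study world: 42 strains, a 3.22-fold focal
#' span, residual noise SD 0.5 log2 units, an 81-gene and an 89-gene
#' negatively coupled module plus a 12-gene negatively coupled "fatty acid"
#' panel (coupling strength chosen so the planted module-gene/focal-gene
#' correlation is 0.6), 20 transcription factors of which seven carry a
#' concordant negative expression shift in both the panel (-2 log2 units)
#' and knockout (-4 log2 units) arms, and 3 replicates per genotype in the
#' knockout arm. The knockout-arm shift is deliberately large: a 3-vs-3
#' Welch test is the detection bottleneck, and the planted world is meant
#' to make the cross-arm TF overlap a deterministic truth, not a power
#' question.
#'
#' @param n_strains number of panel strains (>= 8).
#' @param n_genes total genes simulated (>= planted genes + 1).
#' @param focal_fold_range linear max/min fold span of the focal gene
#'   across strains (> 1).
#' @param module_specs data frame with columns `name`, `size`, `beta`
#'   (coupling per log2 unit of focal gene), `sign` (`"+"` or `"-"`), or
#'   `NULL` for the defaults.
#' @param tf_specs data frame with columns `name`, `r_high`, `r_low`
#'   (target Pearson r to the first module's average within the planted
#'   HIGH / LOW strata, each in (-1, 1)), and optionally `de_panel`,
#'   `de_ko` (planted LOW-minus-HIGH / KO-minus-WT log2 shifts, default 0),
#'   or `NULL` for the defaults.
#' @param noise_sd residual SD, log2 units (> 0).
#' @param baseline_mean,baseline_sd log2-scale location and spread of
#'   per-gene baselines and null genes (defaults 8 and 2).
#' @param ko_replicates replicates per genotype in the knockout arm (>= 2).
#' @param ko_effect log2 shift applied to module genes in knockouts.
#' @param diet_interaction multiplier applied to TF correlation targets in
#'   the HFD arm.
#' @param focal_gene symbol used for the focal gene column.
#' @param seed master seed; every gene draws from its own substream, so
#'   adding genes never perturbs existing columns.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 42, n_genes = 5000,
                       focal_fold_range = 3.22,
                       module_specs = NULL, tf_specs = NULL,
                       noise_sd = 0.5, baseline_mean = 8, baseline_sd = 2,
                       ko_replicates = 3, ko_effect = 1,
                       diet_interaction = 0.5,
                       focal_gene = "FOCAL", seed = 1) {
  if (n_strains < 8) stop("n_strains must be >= 8", call. = FALSE)
  if (focal_fold_range <= 1) stop("focal_fold_range must be > 1",
                                  call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (baseline_sd <= 0) stop("baseline_sd must be > 0", call. = FALSE)
  if (is.null(module_specs)) {
    b <- coupling_for_r(0.6, n_strains, focal_fold_range, noise_sd)
    module_specs <- data.frame(
      name = c("cyto_ribosome", "etc_oxphos", "fatty_acid"),
      size = c(81L, 89L, 12L),
      beta = b,
      sign = c("-", "-", "-"),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(module_specs),
            all(c("name", "size", "beta", "sign") %in% names(module_specs)))
  if (anyDuplicated(module_specs$name))
    stop("module names must be unique (modules must be disjoint)",
         call. = FALSE)
  if (!all(module_specs$sign %in% c("+", "-")))
    stop("module sign must be '+' or '-'", call. = FALSE)
  if (is.null(tf_specs)) {
    tf_specs <- data.frame(
      name = sprintf("TF%02d", 1:20),
      r_high = c(rep(0.1, 7), rep(0.6, 5), rep(0, 8)),
      r_low = c(rep(-0.7, 7), rep(0.6, 5), rep(0, 8)),
      de_panel = c(rep(-2, 7), rep(-1.5, 5), rep(0, 8)),
      de_ko = c(rep(-4, 7), rep(0, 13)),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(tf_specs),
            all(c("name", "r_high", "r_low") %in% names(tf_specs)))
  if (is.null(tf_specs$de_panel)) tf_specs$de_panel <- rep(0, nrow(tf_specs))
  if (is.null(tf_specs$de_ko)) tf_specs$de_ko <- rep(0, nrow(tf_specs))
  if (anyDuplicated(tf_specs$name))
    stop("TF names must be unique", call. = FALSE)
  if (any(abs(c(tf_specs$r_high, tf_specs$r_low)) >= 1))
    stop("infeasible r_target: |r| must be < 1", call. = FALSE)
  if (any(abs(c(tf_specs$r_high, tf_specs$r_low) * diet_interaction) >= 1))
    stop("infeasible r_target under diet_interaction: |r| must stay < 1",
         call. = FALSE)
  n_planted <- sum(module_specs$size) + nrow(tf_specs) + 1L
  if (n_genes < n_planted)
    stop(sprintf("n_genes (%d) < planted genes (%d)", n_genes, n_planted),
         call. = FALSE)
  structure(list(n_strains = as.integer(n_strains),
                 n_genes = as.integer(n_genes),
                 focal_fold_range = focal_fold_range,
                 module_specs = module_specs, tf_specs = tf_specs,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 ko_replicates = as.integer(ko_replicates),
                 ko_effect = ko_effect,
                 diet_interaction = diet_interaction,
                 focal_gene = focal_gene, seed = as.integer(seed)),
            class = "sim_config")
}

#' Coupling coefficient giving a target planted correlation
#'
#' For a module gene generated as `sign * beta * (focal - mean(focal)) +
#' noise`, the population Pearson correlation with the focal gene is
#' `beta * sd_f / sqrt(beta^2 sd_f^2 + noise_sd^2)` where `sd_f` is the SD of
#' the evenly spaced focal grid. This inverts that relation.
#'
#' @param r target absolute correlation, in (0, 1).
#' @param n_strains,focal_fold_range,noise_sd as in [sim_config()].
#' @return beta, log2 units of module gene per log2 unit of focal gene.
#' @export
coupling_for_r <- function(r, n_strains, focal_fold_range, noise_sd) {
  stopifnot(r > 0, r < 1)
  noise_sd * r / sqrt(1 - r^2) / sd(focal_grid(n_strains, focal_fold_range))
}

# Evenly spaced focal log2 values (ascending, centred at 0).
focal_grid <- function(n, fold_range) {
  span <- log2(fold_range)
  seq(-span / 2, span / 2, length.out = n)
}

# Planted quartile strata on the focal ordering (half-up rounding of n/4).
planted_quartiles <- function(focal) {
  n <- length(focal)
  q <- max(2L, as.integer(floor(n / 4 + 0.5)))
  ord <- order(focal, names(focal))
  list(low = names(focal)[ord[seq_len(q)]],
       high = names(focal)[ord[seq.int(n - q + 1L, n)]])
}

# One gene's worth of N(0,1) noise from its own substream.
sub_rnorm <- function(seed, key, n, mean = 0, sd = 1) {
  with_seed(substream_seed(seed, key), rnorm(n, mean, sd))
}

#' Simulate the strain panel
#'
#' Generates a samples x genes log2 expression matrix under `config` for one
#' diet arm, together with the truth table of the planted structure.
#' The focal gene takes evenly spaced log2 values spanning
#' `log2(focal_fold_range)`, centred at `baseline_mean` and assigned to
#' strains in a seed-determined shuffled order (shared between arms, so a
#' strain keeps its rank under both diets). Module genes follow
#' `baseline + sign * beta * (focal - mean(focal)) + noise`. TF genes are
#' built stratum-wise by mixing the first module's standardized average
#' profile with independent noise at the variance ratio implied by the
#' stratum's target correlation (MID strata use the mean of the two
#' targets); an arm-specific mean offset of `+/- de_panel / 2` plants the
#' LOW-minus-HIGH expression shift. Null genes are i.i.d.
#' `N(baseline_mean, baseline_sd^2)`. In the `"HFD"` arm TF correlation
#' targets are multiplied by `diet_interaction` and all noise is re-drawn
#' from arm-specific substreams.
#'
#' @param config a [sim_config()].
#' @param arm `"CD"` (default) or `"HFD"`.
#' @return list with elements `matrix` (an [expr_matrix]) and `truth`
#'   (a `truth_table`).
#' @export
simulate_panel <- function(config, arm = c("CD", "HFD")) {
  stopifnot(inherits(config, "sim_config"))
  arm <- match.arg(arm)
  n <- config$n_strains
  seed <- config$seed
  strains <- sprintf("BXD%03d", seq_len(n))

  grid <- focal_grid(n, config$focal_fold_range) + config$baseline_mean
  perm <- with_seed(substream_seed(seed, "focal_perm"), sample.int(n))
  focal <- setNames(grid[perm], strains)  # shuffled assignment
  fc <- focal - mean(focal)

  truth <- build_truth(config)
  vals <- matrix(NA_real_, n, config$n_genes,
                 dimnames = list(strains, truth$gene_order))
  ci <- col_index(truth$gene_order)  # O(1) hashed column lookup
  vals[, ci[[config$focal_gene]]] <- focal

  for (k in seq_len(nrow(config$module_specs))) {
    ms <- config$module_specs[k, ]
    sgn <- if (ms$sign == "+") 1 else -1
    gs <- names(truth$module_membership)[truth$module_membership == ms$name]
    for (g in gs) {
      b0 <- sub_rnorm(seed, paste0("baseline:", g), 1,
                      config$baseline_mean, config$baseline_sd)
      eps <- sub_rnorm(seed, paste0(arm, ":eps:", g), n, 0, config$noise_sd)
      vals[, ci[[g]]] <- b0 + sgn * ms$beta * fc + eps
    }
  }

  strata <- planted_quartiles(focal)
  mid <- setdiff(strains, c(strata$high, strata$low))
  pathway <- if (nrow(config$module_specs) > 0) {
    rowMeans(vals[, names(truth$module_membership)[
      truth$module_membership == config$module_specs$name[1]], drop = FALSE])
  } else setNames(numeric(n), strains)
  rmul <- if (arm == "HFD") config$diet_interaction else 1
  for (k in seq_len(nrow(config$tf_specs))) {
    tf <- config$tf_specs[k, ]
    b0 <- sub_rnorm(seed, paste0("baseline:", tf$name), 1,
                    config$baseline_mean, config$baseline_sd)
    col <- setNames(numeric(n), strains)
    groups <- list(HIGH = strata$high, LOW = strata$low, MID = mid)
    rr <- c(HIGH = tf$r_high * rmul, LOW = tf$r_low * rmul,
            MID = (tf$r_high + tf$r_low) / 2 * rmul)
    off <- c(HIGH = -tf$de_panel / 2, LOW = tf$de_panel / 2, MID = 0)
    for (gname in names(groups)) {
      ids <- groups[[gname]]
      if (!length(ids)) next
      a <- pathway[ids]
      az <- if (sd(a) > 0) (a - mean(a)) / sd(a) else rep(0, length(a))
      z <- sub_rnorm(seed, paste0(arm, ":tf:", tf$name, ":", gname),
                     length(ids))
      r <- rr[[gname]]
      col[ids] <- b0 + off[[gname]] +
        config$noise_sd * (r * az + sqrt(1 - r^2) * z)
    }
    vals[, ci[[tf$name]]] <- col
  }

  for (g in truth$null_genes)
    vals[, ci[[g]]] <- sub_rnorm(seed, paste0(arm, ":null:", g), n,
                                 config$baseline_mean, config$baseline_sd)

  meta <- data.frame(sample = strains, strain = strains, diet = arm,
                     genotype = NA_character_, stringsAsFactors = FALSE)
  truth$planted_high <- strata$high
  truth$planted_low <- strata$low
  list(matrix = expr_matrix(vals, meta), truth = truth)
}

# Gene layout + truth table shared by the panel and knockout generators.
build_truth <- function(config) {
  ms <- config$module_specs
  module_genes <- unlist(lapply(seq_len(nrow(ms)), function(k)
    sprintf("%s_%03d", ms$name[k], seq_len(ms$size[k]))), use.names = FALSE)
  membership <- setNames(rep(ms$name, ms$size), module_genes)
  tf_genes <- config$tf_specs$name
  n_null <- config$n_genes - 1L - length(module_genes) - length(tf_genes)
  null_genes <- if (n_null > 0) sprintf("null_%05d", seq_len(n_null))
                else character(0)
  gene_order <- c(config$focal_gene, module_genes, tf_genes, null_genes)
  stopifnot(!anyDuplicated(gene_order))
  structure(list(
    focal_gene = config$focal_gene,
    module_membership = membership,
    coupling_signs = setNames(ms$sign, ms$name),
    coupling_beta = setNames(ms$beta, ms$name),
    tf_coupling = config$tf_specs,
    null_genes = null_genes,
    gene_order = gene_order,
    config_hash = config_hash(unclass(config))), class = "truth_table")
}

#' Gene sets implied by a truth table
#'
#' Returns the planted modules as a GMT-style named list, ready for
#' [write_gmt()] or the enrichment functions.
#'
#' @param truth a `truth_table` from [simulate_panel()].
#' @return named list of character vectors.
#' @export
truth_gene_sets <- function(truth) {
  stopifnot(inherits(truth, "truth_table"))
  split(names(truth$module_membership), truth$module_membership)
}

#' Simulate the knockout arm
#'
#' Generates `2 * ko_replicates` samples (wildtype and knockout) on the
#' same gene universe as the panel. The focal gene is set, in knockouts, to
#' the panel minimum minus one log2 unit (silenced); each module gene is
#' shifted by `ko_effect` in its loss direction — opposite to its coupling
#' sign, so a negatively coupled module rises in knockouts exactly as it
#' does in low-expressing strains and the two contrasts are concordant by
#' construction; TF genes are shifted by their planted `de_ko`; null genes
#' are untouched. Per-gene baselines reuse the panel's
#' substreams, so a gene keeps its baseline across arms.
#'
#' @param config a [sim_config()].
#' @param truth the `truth_table` from [simulate_panel()] (or `NULL` to
#'   rebuild it from `config`).
#' @return an [expr_matrix] with genotype metadata `WT` / `KO`.
#' @export
simulate_ko <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$ko_replicates < 2)
    stop("ko_replicates must be >= 2", call. = FALSE)
  if (is.null(truth)) truth <- build_truth(config)
  k <- config$ko_replicates
  seed <- config$seed
  ids <- c(sprintf("WT_%02d", seq_len(k)), sprintf("KO_%02d", seq_len(k)))
  is_ko <- rep(c(FALSE, TRUE), each = k)
  n <- 2L * k
  vals <- matrix(NA_real_, n, config$n_genes,
                 dimnames = list(ids, truth$gene_order))
  ci <- col_index(truth$gene_order)

  span <- log2(config$focal_fold_range)
  focal_min <- config$baseline_mean - span / 2
  fwt <- sub_rnorm(seed, "KO:eps:focal", k, config$baseline_mean,
                   config$noise_sd)
  vals[, ci[[config$focal_gene]]] <- c(fwt, rep(focal_min - 1, k))

  for (m in names(truth$coupling_signs)) {
    # loss direction: module moves as it does in LOW-expression strains
    sgn <- if (truth$coupling_signs[[m]] == "+") -1 else 1
    gs <- names(truth$module_membership)[truth$module_membership == m]
    for (g in gs) {
      b0 <- sub_rnorm(seed, paste0("baseline:", g), 1,
                      config$baseline_mean, config$baseline_sd)
      eps <- sub_rnorm(seed, paste0("KO:eps:", g), n, 0, config$noise_sd)
      vals[, ci[[g]]] <- b0 + ifelse(is_ko, sgn * config$ko_effect, 0) + eps
    }
  }
  for (j in seq_len(nrow(config$tf_specs))) {
    tf <- config$tf_specs[j, ]
    b0 <- sub_rnorm(seed, paste0("baseline:", tf$name), 1,
                    config$baseline_mean, config$baseline_sd)
    eps <- sub_rnorm(seed, paste0("KO:eps:", tf$name), n, 0, config$noise_sd)
    vals[, ci[[tf$name]]] <- b0 + ifelse(is_ko, tf$de_ko, 0) + eps
  }
  for (g in truth$null_genes)
    vals[, ci[[g]]] <- sub_rnorm(seed, paste0("KO:null:", g), n,
                                 config$baseline_mean, config$baseline_sd)

  meta <- data.frame(sample = ids, strain = "BL6", diet = NA_character_,
                     genotype = ifelse(is_ko, "KO", "WT"),
                     stringsAsFactors = FALSE)
  expr_matrix(vals, meta)
}
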