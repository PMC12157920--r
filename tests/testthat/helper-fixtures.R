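# Shared fixtures: small planted worlds and brute-force oracles.

# A small, fast planted world: 20 strains, one negative and one positive
# module, four TFs (one with a strong negative shift + expression shifts).
tiny_config <- function(seed = 1, n_genes = 60, ...) {
  sim_config(
    n_strains = 20, n_genes = n_genes,
    module_specs = data.frame(
      name = c("neg_mod", "pos_mod"), size = c(10L, 8L),
      beta = 0.8, sign = c("-", "+"), stringsAsFactors = FALSE),
    tf_specs = data.frame(
      name = sprintf("TF%02d", 1:4),
      r_high = c(0.8, 0, 0, 0), r_low = c(-0.4, 0, 0, 0),
      de_panel = c(-2, 0, 0, 0), de_ko = c(-4, 0, 0, 0),
      stringsAsFactors = FALSE),
    seed = seed, ...)
}

# Deterministic toy matrix from explicit values; existing dimnames win.
toy_matrix <- function(values, sample_ids = NULL, gene_ids = NULL) {
  if (is.null(sample_ids))
    sample_ids <- if (!is.null(rownames(values))) rownames(values)
                  else paste0("s", seq_len(nrow(values)))
  if (is.null(gene_ids))
    gene_ids <- if (!is.null(colnames(values))) colnames(values)
                else paste0("g", seq_len(ncol(values)))
  dimnames(values) <- list(sample_ids, gene_ids)
  expr_matrix(values)
}

# Brute-force weighted KS running sum: the independent oracle for gsea_es.
# Recomputes every prefix sum with explicit loops, no shared code path.
gsea_oracle <- function(genes, scores, gene_set, w) {
  N <- length(genes)
  hit <- genes %in% gene_set
  K <- sum(hit)
  denom <- sum(abs(scores[hit])^w)
  running <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      acc <- acc + if (denom > 0) abs(scores[i])^w / denom else 1 / K
    } else {
      acc <- acc - 1 / (N - K)
    }
    running[i] <- acc
  }
  hi <- running[1]
  lo <- running[1]
  ih <- 1
  il <- 1
  for (i in seq_len(N)) {
    if (running[i] > hi) { hi <- running[i]; ih <- i }
    if (running[i] < lo) { lo <- running[i]; il <- i }
  }
  # equal-magnitude extrema resolve to whichever comes first in the walk
  if (abs(hi + lo) <= 1e-9) {
    if (ih < il) hi else lo
  } else if (hi > -lo) hi else lo
}

# Exact hypergeometric upper tail by combinatorial enumeration: the
# independent oracle for ora_test.
ora_oracle <- function(N, K, n, k) {
  ks <- k:min(n, K)
  ks <- ks[ks >= max(0, n - (N - K))]
  if (!length(ks)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Random ranked list for property tests.
random_ranked <- function(N, seed) {
  set.seed(seed)
  score <- sort(rnorm(N), decreasing = TRUE)
  out <- data.frame(gene = sprintf("g%03d", seq_len(N)), score = score,
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}
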