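#' Rank genes by low-minus-high log2 fold change
#'
#' The preranked-GSEA input: for every gene, the mean over LOW-stratum
#' samples minus the mean over HIGH-stratum samples of the (re)normalized
#' log2 values, sorted descending. Ties break by gene id. For a
#' knockout contrast pass the KO samples as `low` and WT as `high`
#' (KO - WT log2FC).
#'
#' @param x an [expr_matrix].
#' @param strata a `strata_assignment`, or `NULL` when `low` / `high`
#'   sample-id vectors are given directly.
#' @param low,high explicit sample-id vectors (used when `strata` is NULL).
#' @param contrast label recorded on the result (e.g. `"L-vs-H"`).
#' @return data frame of class `ranked_list` with columns `gene`, `score`,
#'   descending by score; attribute `contrast`.
#' @export
rank_by_log2fc <- function(x, strata = NULL, low = NULL, high = NULL,
                           contrast = "L-vs-H") {
  stopifnot(inherits(x, "expr_matrix"))
  if (!is.null(strata)) {
    low <- stratum_samples(strata, "LOW")
    high <- stratum_samples(strata, "HIGH")
  }
  if (!length(low) || !length(high))
    stop("both strata must be non-empty", call. = FALSE)
  vlow <- colMeans(x$values[low, , drop = FALSE])
  vhigh <- colMeans(x$values[high, , drop = FALSE])
  score <- vlow - vhigh
  ord <- order(-score, names(score))
  out <- data.frame(gene = names(score)[ord], score = unname(score[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: at each gene-set member ("hit") the running sum
#' increments by `|score|^w / sum_hits |score|^w`; at each non-member it
#' decrements by `1 / (N - K)`. The enrichment score is the running sum's
#' maximum-magnitude deviation from zero (sign retained; a positive and a
#' negative extremum of exactly equal magnitude resolve to whichever the
#' walk reaches first). `weight_exponent = 0` gives the classic unweighted
#' KS statistic, `1` the standard weighted form. When all hit weights are
#' zero (all-zero scores under `w = 1`) hits fall back to equal weights.
#'
#' @param ranked a `ranked_list` from [rank_by_log2fc()].
#' @param gene_set character vector of member genes.
#' @param weight_exponent score weight exponent (default 1).
#' @return list with `es`, `leading_edge` (set members at or before the
#'   extremum for positive ES, at or after it for negative) and
#'   `extremum_index`.
#' @export
gsea_es <- function(ranked, gene_set, weight_exponent = 1) {
  g <- ranked$gene
  s <- ranked$score
  N <- length(g)
  hit <- g %in% gene_set
  K <- sum(hit)
  if (K == 0) stop("gene set has no overlap with the ranked list",
                   call. = FALSE)
  if (K == N) stop("gene set covers the whole ranked universe",
                   call. = FALSE)
  w <- abs(s)^weight_exponent
  denom <- sum(w[hit])
  inc <- if (denom > 0) w / denom else rep(1 / K, N)
  step <- ifelse(hit, inc, -1 / (N - K))
  running <- cumsum(step)
  hi <- max(running)
  lo <- min(running)
  # a positive and a negative extremum of equal magnitude (possible for
  # the unweighted statistic) resolves to whichever is reached first, which
  # keeps complementation antisymmetric; the 1e-9 slack absorbs
  # accumulation-order rounding, far below the 1/K step size
  if (abs(hi + lo) <= 1e-9) {
    ih <- which.max(running)
    il <- which.min(running)
    positive <- ih < il
  } else {
    positive <- hi > -lo
  }
  es <- if (positive) hi else lo
  i <- if (positive) which.max(running) else which.min(running)
  le <- if (es >= 0) g[hit & seq_len(N) <= i] else g[hit & seq_len(N) >= i]
  list(es = es, leading_edge = le, extremum_index = i)
}

#' GSEA with a gene-sampling permutation null
#'
#' Scores a gene set on a ranked list and estimates significance from
#' `n_perm` random same-size gene sets drawn without replacement from the
#' ranked universe. The p-value uses the plus-one estimator over null
#' scores of the same sign as the observed ES; NES divides ES by the mean
#' |null ES| of matching sign. If no null score shares the observed sign,
#' p is reported as `1 / (1 + n_perm)` with a warning and NES falls back to
#' the mean |null ES| over all permutations.
#'
#' @inheritParams gsea_es
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed for the permutation draws.
#' @param set_name label recorded in the result.
#' @return one-row data frame: `set`, `set_size`, `es`, `nes`, `p`,
#'   `leading_edge` (comma-joined).
#' @export
gsea_pvalue <- function(ranked, gene_set, n_perm = 1000, seed = 1,
                        weight_exponent = 1, set_name = "set") {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  obs <- gsea_es(ranked, gene_set, weight_exponent)
  K <- sum(ranked$gene %in% gene_set)
  N <- nrow(ranked)
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(N, K)
    gsea_es(ranked, ranked$gene[idx], weight_exponent)$es
  }, numeric(1)))
  same <- null_es * sign(obs$es) > 0
  if (!any(same)) {
    warning("degenerate permutation null: no same-sign null scores; ",
            "p floored at 1/(1+n_perm)", call. = FALSE)
    p <- 1 / (1 + n_perm)
    nes <- obs$es / mean(abs(null_es))
  } else {
    p <- (1 + sum(abs(null_es[same]) >= abs(obs$es))) / (1 + sum(same))
    nes <- obs$es / mean(abs(null_es[same]))
  }
  out <- data.frame(set = set_name, set_size = K, es = obs$es, nes = nes,
                    p = p,
                    leading_edge = paste(obs$leading_edge, collapse = ","),
                    stringsAsFactors = FALSE)
  attr(out, "null_es") <- null_es
  out
}

#' Score a gene-set collection by GSEA
#'
#' Applies [gsea_pvalue()] to every set in a collection that intersects the
#' ranked universe within the size bounds, then adjusts p across the scored
#' sets with Benjamini-Yekutieli.
#'
#' @inheritParams gsea_pvalue
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param min_size,max_size bounds on the in-universe set size
#'   (defaults 5 and 500).
#' @return data frame of class `enrichment_result`, one row per scored set,
#'   with `p_adj` added.
#' @export
gsea_collection <- function(ranked, collection, n_perm = 1000, seed = 1,
                            weight_exponent = 1, min_size = 5,
                            max_size = 500) {
  stopifnot(is.list(collection), !is.null(names(collection)))
  rows <- list()
  for (nm in names(collection)) {
    K <- sum(ranked$gene %in% collection[[nm]])
    if (K < min_size || K > max_size || K == nrow(ranked)) next
    rows[[nm]] <- gsea_pvalue(ranked, collection[[nm]], n_perm = n_perm,
                              seed = substream_seed(seed, nm),
                              weight_exponent = weight_exponent,
                              set_name = nm)
  }
  if (!length(rows))
    stop("no gene set passed the size bounds", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- adjust_by(out$p)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of a hit list's overlap with each set of
#' a collection within a gene universe: `p = P(X >= k)` with
#' `X ~ Hypergeom(N, K, n)`, BY-adjusted across the collection.
#'
#' @param hits character vector of hit genes (must lie in `universe`).
#' @param universe character vector: all testable genes.
#' @param collection named list of gene sets; each is intersected with the
#'   universe before testing.
#' @return data frame of class `ora_result`: `set`, `k` (overlap), `K`
#'   (set size in universe), `n` (hit count), `N` (universe size), `p`,
#'   `p_adj`, `enrichment_ratio` (`k * N / (n * K)`).
#' @export
ora_test <- function(hits, universe, collection) {
  hits <- unique(hits)
  universe <- unique(universe)
  bad <- setdiff(hits, universe)
  if (length(bad))
    stop("hits outside the universe: ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(names(collection), function(nm) {
    set_u <- intersect(collection[[nm]], universe)
    K <- length(set_u)
    k <- length(intersect(set_u, hits))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = min(max(p, 0), 1),
               enrichment_ratio = if (n > 0 && K > 0) k * N / (n * K)
                                  else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  keep <- out$K > 0
  out$p_adj <- NA_real_
  if (any(keep)) out$p_adj[keep] <- adjust_by(out$p[keep])
  class(out) <- c("ora_result", "data.frame")
  out
}
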