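#' Pathway-average expression profile
#'
#' Per-sample arithmetic mean over the gene-set members present in the
#' matrix; the profile every TF is correlated against.
#'
#' @param x an [expr_matrix].
#' @param gene_set character vector of member symbols.
#' @return named numeric vector (one value per sample) with attribute
#'   `n_present`.
#' @export
pathway_average <- function(x, gene_set) {
  stopifnot(inherits(x, "expr_matrix"))
  present <- intersect(gene_set, genes(x))
  if (!length(present))
    stop("no gene of the set is present in the matrix", call. = FALSE)
  out <- rowMeans(x$values[, present, drop = FALSE])
  attr(out, "n_present") <- length(present)
  out
}

#' Per-stratum TF correlations to a pathway profile
#'
#' Pearson r between each transcription factor and the pathway-average
#' profile, computed separately within the HIGH and the LOW stratum.
#' TFs absent from the matrix are reported with `missing = TRUE`, never
#' dropped silently.
#'
#' The default correlates each TF with the averaged profile; set
#' `aggregate = "mean_r"` (and supply `gene_set`) for the alternative
#' reading that averages the TF's per-gene correlations over the set
#' members instead.
#'
#' @param x an [expr_matrix].
#' @param tf_list character vector of TF symbols.
#' @param profile per-sample profile from [pathway_average()] (ignored
#'   under `aggregate = "mean_r"`).
#' @param strata a `strata_assignment`.
#' @param aggregate `"profile"` (default) or `"mean_r"`.
#' @param gene_set pathway member symbols, required for `"mean_r"`.
#' @return data frame: `tf`, `r_high`, `r_low`, `n_high`, `n_low`,
#'   `missing`.
#' @export
tf_stratum_correlations <- function(x, tf_list, profile, strata,
                                    aggregate = c("profile", "mean_r"),
                                    gene_set = NULL) {
  aggregate <- match.arg(aggregate)
  if (aggregate == "mean_r") {
    if (is.null(gene_set))
      stop("aggregate = \"mean_r\" needs `gene_set`", call. = FALSE)
    gene_set <- intersect(gene_set, genes(x))
    if (!length(gene_set))
      stop("no gene of the set is present in the matrix", call. = FALSE)
  }
  hi <- stratum_samples(strata, "HIGH")
  lo <- stratum_samples(strata, "LOW")
  if (length(hi) < 4 || length(lo) < 4)
    stop("each stratum needs >= 4 samples for correlation", call. = FALSE)
  present <- tf_list %in% genes(x)
  r_in <- function(ids, tf) {
    v <- x$values[ids, tf]
    if (sd(v) == 0) return(NA_real_)
    if (aggregate == "mean_r") {
      rs <- vapply(gene_set, function(g) {
        gv <- x$values[ids, g]
        if (sd(gv) == 0) NA_real_ else cor(v, gv)
      }, numeric(1))
      return(mean(rs, na.rm = TRUE))
    }
    if (sd(profile[ids]) == 0) return(NA_real_)
    cor(v, profile[ids])
  }
  out <- data.frame(tf = tf_list,
                    r_high = NA_real_, r_low = NA_real_,
                    n_high = length(hi), n_low = length(lo),
                    missing = !present, stringsAsFactors = FALSE)
  for (i in which(present)) {
    out$r_high[i] <- r_in(hi, tf_list[i])
    out$r_low[i] <- r_in(lo, tf_list[i])
  }
  out
}

#' Fisher-z test for a correlation shift between strata
#'
#' Tests whether a correlation differs between two independent strata:
#' `z = atanh(r)`, statistic `(z_low - z_high) / sqrt(1/(n_low-3) +
#' 1/(n_high-3))`, two-sided normal p. The shift is oriented
#' `delta_r = r_low - r_high`. Stars follow the printed convention
#' (0.05 / 0.01 / 0.001). `|r| = 1` makes z infinite; set `clamp = TRUE`
#' to pull such values to `1 - 1e-6`.
#'
#' @param r_high,r_low stratum correlations (each |r| < 1 unless clamped).
#' @param n_high,n_low stratum sizes (each >= 4).
#' @param clamp clamp |r| = 1 instead of erroring.
#' @return list: `delta_r`, `statistic`, `p_shift`, `stars`.
#' @export
shift_test <- function(r_high, n_high, r_low, n_low, clamp = FALSE) {
  stopifnot(n_high >= 4, n_low >= 4)
  rs <- c(r_high, r_low)
  if (any(abs(rs) >= 1)) {
    if (!clamp)
      stop("|r| = 1 gives an infinite Fisher z; rerun with clamp = TRUE ",
           "to clamp at 1 - 1e-6", call. = FALSE)
    r_high <- sign(r_high) * min(abs(r_high), 1 - 1e-6)
    r_low <- sign(r_low) * min(abs(r_low), 1 - 1e-6)
  }
  stat <- (atanh(r_low) - atanh(r_high)) /
    sqrt(1 / (n_low - 3) + 1 / (n_high - 3))
  p <- 2 * pnorm(abs(stat), lower.tail = FALSE)
  list(delta_r = r_low - r_high, statistic = stat, p_shift = p,
       stars = significance_stars(p))
}

#' Bootstrap test for a correlation shift
#'
#' Sensitivity-analysis alternative to the asymptotic Fisher-z test:
#' strains are resampled with replacement within each stratum, the shift
#' `delta_r* = r_low* - r_high*` is recomputed `n_boot` times, and the
#' two-sided p-value is twice the smaller plus-one-smoothed tail
#' probability of the bootstrap distribution around zero.
#'
#' @param x an [expr_matrix].
#' @param tf one TF symbol.
#' @param profile per-sample profile from [pathway_average()].
#' @param strata a `strata_assignment`.
#' @param n_boot bootstrap replicates (>= 1000 recommended).
#' @param seed RNG seed.
#' @return list: `delta_r` (observed), `p_shift`, `stars`, `boot`
#'   (replicate shifts).
#' @export
shift_test_bootstrap <- function(x, tf, profile, strata, n_boot = 1000,
                                 seed = 1) {
  hi <- stratum_samples(strata, "HIGH")
  lo <- stratum_samples(strata, "LOW")
  if (length(hi) < 4 || length(lo) < 4)
    stop("each stratum needs >= 4 samples", call. = FALSE)
  v <- gene_column(x, tf)
  r_of <- function(ids) {
    if (sd(v[ids]) == 0 || sd(profile[ids]) == 0) return(NA_real_)
    cor(v[ids], profile[ids])
  }
  obs <- r_of(lo) - r_of(hi)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    r_of(sample(lo, replace = TRUE)) - r_of(sample(hi, replace = TRUE))
  }, numeric(1)))
  boot <- boot[is.finite(boot)]
  lower <- (1 + sum(boot <= 0)) / (1 + length(boot))
  upper <- (1 + sum(boot >= 0)) / (1 + length(boot))
  p <- min(1, 2 * min(lower, upper))
  list(delta_r = obs, p_shift = p, stars = significance_stars(p),
       boot = boot)
}

#' TF correlation-shift table
#'
#' Combines [tf_stratum_correlations()] with a shift test into the per-TF
#' shift record: stratum correlations, `delta_r = r_low - r_high`, the
#' shift p-value and its stars. The default test is the Fisher-z
#' comparison ([shift_test()]); `method = "bootstrap"` swaps in the
#' strain-resampling test ([shift_test_bootstrap()]) for sensitivity
#' analysis.
#'
#' @inheritParams tf_stratum_correlations
#' @param clamp passed to [shift_test()].
#' @param method `"fisher"` (default) or `"bootstrap"`.
#' @param n_boot,seed bootstrap parameters (used when
#'   `method = "bootstrap"`).
#' @return data frame of class `tf_shift_result`: `tf`, `r_high`, `r_low`,
#'   `delta_r`, `p_shift`, `stars`, `n_high`, `n_low`, `missing`, with
#'   attribute `method`.
#' @export
tf_shift_table <- function(x, tf_list, profile, strata, clamp = TRUE,
                           method = c("fisher", "bootstrap"),
                           n_boot = 1000, seed = 1) {
  method <- match.arg(method)
  rc <- tf_stratum_correlations(x, tf_list, profile, strata)
  rc$delta_r <- NA_real_
  rc$p_shift <- NA_real_
  rc$stars <- NA_character_
  for (i in seq_len(nrow(rc))) {
    if (rc$missing[i] || is.na(rc$r_high[i]) || is.na(rc$r_low[i])) next
    st <- if (method == "fisher") {
      shift_test(rc$r_high[i], rc$n_high[i], rc$r_low[i], rc$n_low[i],
                 clamp = clamp)
    } else {
      shift_test_bootstrap(x, rc$tf[i], profile, strata, n_boot = n_boot,
                           seed = substream_seed(seed, rc$tf[i]))
    }
    rc$delta_r[i] <- st$delta_r
    rc$p_shift[i] <- st$p_shift
    rc$stars[i] <- st$stars
  }
  out <- rc[, c("tf", "r_high", "r_low", "delta_r", "p_shift", "stars",
                "n_high", "n_low", "missing")]
  attr(out, "method") <- method
  class(out) <- c("tf_shift_result", "data.frame")
  out
}

#' TF differential expression between two groups
#'
#' Welch two-sided t-test per TF; `log2FC = mean(group1) - mean(group2)`
#' where group1 is the LOW stratum (or KO genotype) and group2 HIGH (or
#' WT). Direction is `"enriched"` / `"depleted"` by the sign of log2FC when
#' the raw p is below `alpha`, `"ns"` otherwise; BY-adjusted p is also
#' reported.
#'
#' @param x an [expr_matrix].
#' @param group1,group2 sample-id vectors (>= 2 samples each).
#' @param tf_list TF symbols to test (absent ones are skipped with a
#'   `missing` flag).
#' @param alpha raw-p significance threshold for the direction call.
#' @return data frame of class `deg_result`: `gene`, `log2fc`, `t`, `p`,
#'   `p_adj`, `direction`, `missing`.
#' @export
tf_differential_expression <- function(x, group1, group2, tf_list,
                                       alpha = 0.05) {
  stopifnot(inherits(x, "expr_matrix"))
  if (length(group1) < 2 || length(group2) < 2)
    stop("each group needs >= 2 samples", call. = FALSE)
  present <- tf_list %in% genes(x)
  out <- data.frame(gene = tf_list, log2fc = NA_real_, t = NA_real_,
                    p = NA_real_, p_adj = NA_real_,
                    direction = NA_character_, missing = !present,
                    stringsAsFactors = FALSE)
  for (i in which(present)) {
    v1 <- x$values[group1, tf_list[i]]
    v2 <- x$values[group2, tf_list[i]]
    out$log2fc[i] <- mean(v1) - mean(v2)
    if (sd(v1) == 0 && sd(v2) == 0) {
      out$t[i] <- 0
      out$p[i] <- 1
    } else {
      tt <- t.test(v1, v2)  # Welch
      out$t[i] <- unname(tt$statistic)
      out$p[i] <- max(tt$p.value, .Machine$double.xmin)
    }
  }
  tested <- which(!is.na(out$p))
  if (length(tested)) out$p_adj[tested] <- adjust_by(out$p[tested])
  out$direction[tested] <- ifelse(
    out$p[tested] >= alpha, "ns",
    ifelse(out$log2fc[tested] > 0, "enriched", "depleted"))
  class(out) <- c("deg_result", "data.frame")
  out
}

#' Summarize significant correlation shifts
#'
#' @param records a `tf_shift_result`.
#' @param alpha threshold on `p_shift`.
#' @return named integer vector `(n_significant, n_negative, n_positive)`
#'   where the sign split is on `delta_r` among significant TFs.
#' @export
summarize_shifts <- function(records, alpha = 0.05) {
  sig <- !is.na(records$p_shift) & records$p_shift < alpha
  c(n_significant = sum(sig),
    n_negative = sum(sig & records$delta_r < 0),
    n_positive = sum(sig & records$delta_r > 0))
}

#' Direction-concordant TF overlap between two contrasts
#'
#' Intersects two sets of significant TFs, keeping only those whose
#' direction labels match; returned in lexicographic order.
#'
#' @param setA,setB data frames with columns `tf` (or `gene`) and
#'   `direction`.
#' @return character vector of concordant TF symbols.
#' @export
overlap_tfs <- function(setA, setB) {
  norm <- function(d) {
    nm <- if ("tf" %in% names(d)) "tf" else "gene"
    data.frame(tf = d[[nm]], direction = d$direction,
               stringsAsFactors = FALSE)
  }
  a <- norm(setA); b <- norm(setB)
  shared <- merge(a, b, by = "tf", suffixes = c("_a", "_b"))
  sort(shared$tf[!is.na(shared$direction_a) & !is.na(shared$direction_b) &
                   shared$direction_a == shared$direction_b])
}
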