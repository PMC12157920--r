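#' Cross-platform renormalization
#'
#' Rescales a log2 expression matrix so that its *global* distribution —
#' all cells pooled — has a prescribed mean and standard deviation
#' (defaults 8 and 2, the convention used for RMA-summarised strain-panel
#' exports). This is a single affine map applied to every cell, so all
#' pairwise Pearson correlations, ranks and group contrasts are preserved
#' exactly; it only places two platforms on a common scale.
#'
#' A per-gene mode (z-score each gene column separately) is available via
#' `per_gene = TRUE` for exploratory use; the pipeline default is global.
#'
#' @param x an [expr_matrix].
#' @param target_mean,target_sd desired global mean and SD, log2 units.
#' @param per_gene if `TRUE`, standardise each gene column separately
#'   instead of the pooled cell distribution.
#' @return an [expr_matrix] of the same shape and ids.
#' @examples
#' m <- matrix(rnorm(200), 10, 20,
#'             dimnames = list(paste0("s", 1:10), paste0("g", 1:20)))
#' y <- renormalize(expr_matrix(m))
#' c(mean(y$values), sd(as.vector(y$values)))
#' @export
renormalize <- function(x, target_mean = 8, target_sd = 2,
                        per_gene = FALSE) {
  stopifnot(inherits(x, "expr_matrix"),
            is.numeric(target_mean), is.numeric(target_sd), target_sd > 0)
  v <- x$values
  if (per_gene) {
    sds <- apply(v, 2, sd)
    if (any(sds == 0))
      stop("per-gene normalization: constant gene column(s): ",
           paste(head(colnames(v)[sds == 0], 5), collapse = ", "),
           call. = FALSE)
    v <- sweep(sweep(v, 2, colMeans(v), "-"), 2, sds, "/") *
      target_sd + target_mean
  } else {
    mu <- mean(v)
    s <- sd(as.vector(v))
    if (s == 0)
      stop("cannot renormalize a constant matrix (global SD is zero)",
           call. = FALSE)
    v <- (v - mu) / s * target_sd + target_mean
  }
  expr_matrix(v, x$sample_meta)
}

#' Select a focal-gene probe
#'
#' Operationalises the probe-selection criteria used for exon-level array
#' exports: among the probes annotated to `gene` that are not flagged for
#' cross-hybridization, keep those whose expression distribution across
#' samples is compatible with normality (Shapiro-Wilk p >= `normality_alpha`)
#' and return the one with the widest dynamic range (max - min, log2 units).
#' If no unflagged probe passes the normality screen, the widest-range
#' unflagged probe is returned with a warning. Range ties break
#' lexicographically by probe id, for determinism.
#'
#' @param probes a probe table as returned by [read_probe_table()].
#' @param gene gene symbol to select a probe for.
#' @param normality_alpha Shapiro-Wilk threshold (default 0.05).
#' @return the selected probe id (character scalar), with attributes
#'   `range` and `normality_p`.
#' @export
select_probe <- function(probes, gene, normality_alpha = 0.05) {
  stopifnot(is.data.frame(probes))
  rows <- probes[probes$gene == gene, , drop = FALSE]
  if (nrow(rows) == 0)
    stop(sprintf("no probes annotated to gene '%s'", gene), call. = FALSE)
  rows <- rows[order(rows$probe_id), , drop = FALSE]
  unflagged <- rows[!rows$cross_hyb, , drop = FALSE]
  if (nrow(unflagged) == 0)
    stop(sprintf("all %d probes for '%s' are flagged for cross-hybridization",
                 nrow(rows), gene), call. = FALSE)
  value_cols <- setdiff(names(probes), c("probe_id", "gene", "cross_hyb"))
  vals <- as.matrix(unflagged[, value_cols, drop = FALSE])
  rng <- apply(vals, 1, function(v) max(v) - min(v))
  swp <- apply(vals, 1, function(v) {
    if (length(unique(v)) < 3) return(0)  # shapiro.test needs variation
    shapiro.test(v)$p.value
  })
  pass <- swp >= normality_alpha
  if (any(pass)) {
    cand <- which(pass)
  } else {
    warning(sprintf(
      "no probe for '%s' passes normality at alpha=%g; falling back to %s",
      gene, normality_alpha, "widest-range unflagged probe"), call. = FALSE)
    cand <- seq_len(nrow(unflagged))
  }
  best <- cand[which.max(rng[cand])]  # rows pre-sorted by id: ties -> lexicographic
  structure(unflagged$probe_id[best],
            range = unname(rng[best]), normality_p = unname(swp[best]))
}
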