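#' Genome-wide Pearson correlation against the focal gene
#'
#' Correlates every target gene with the focal gene across samples. The
#' two-sided p-value comes from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom. Genes with zero variance cannot be tested:
#' they are flagged `"constant"` and excluded from the multiple-testing
#' adjustment (so `m` reflects testable genes only). The focal gene itself
#' is reported (r = 1) but flagged `"focal"` and likewise excluded from
#' adjustment.
#'
#' @param x an [expr_matrix].
#' @param focal focal gene symbol.
#' @param targets character vector of genes to test, or `"all"`.
#' @return data frame of class `corr_screen` with columns `gene`, `r`, `n`,
#'   `p`, `p_adj` (Benjamini-Yekutieli) and `flag` (`"ok"`, `"constant"`,
#'   `"focal"`).
#' @export
correlate_focal <- function(x, focal, targets = "all") {
  stopifnot(inherits(x, "expr_matrix"))
  f <- gene_column(x, focal)
  n <- length(f)
  if (n < 4) stop("insufficient samples for correlation (n < 4)",
                  call. = FALSE)
  gene_ids <- if (identical(targets, "all")) genes(x) else {
    missing <- setdiff(targets, genes(x))
    if (length(missing))
      stop("genes not in matrix: ", paste(head(missing, 5), collapse = ", "),
           call. = FALSE)
    targets
  }
  m <- x$values[, gene_ids, drop = FALSE]
  sds <- apply(m, 2, sd)
  r <- rep(NA_real_, length(gene_ids))
  ok <- sds > 0 & sd(f) > 0
  if (any(ok)) r[ok] <- as.vector(cor(f, m[, ok, drop = FALSE]))
  flag <- ifelse(ok, "ok", "constant")
  flag[gene_ids == focal] <- "focal"
  p <- rep(NA_real_, length(gene_ids))
  testable <- flag == "ok"
  if (any(testable)) {
    rt <- pmin(pmax(r[testable], -1), 1)
    tt <- rt * sqrt((n - 2) / pmax(1 - rt^2, .Machine$double.eps))
    p[testable] <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
    p[testable] <- pmin(pmax(p[testable], .Machine$double.xmin), 1)
  }
  p_adj <- rep(NA_real_, length(gene_ids))
  if (any(testable)) p_adj[testable] <- adjust_by(p[testable])
  out <- data.frame(gene = gene_ids, r = r, n = n, p = p, p_adj = p_adj,
                    flag = flag, stringsAsFactors = FALSE)
  class(out) <- c("corr_screen", "data.frame")
  out
}

#' Benjamini-Yekutieli step-up adjustment
#'
#' FDR control valid under arbitrary dependence:
#' `p_adj(i) = min over j >= i of min(1, m * c(m) * p(j) / j)` on the
#' ascending ordering, with `c(m) = sum_{k=1..m} 1/k`. Input order is
#' preserved on return. Always at least as large, element-wise, as the
#' Benjamini-Hochberg adjustment.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values in the input order.
#' @export
adjust_by <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must be numeric in (0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 0) return(numeric(0))
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  raw <- pmin(1, m * cm * p[ord] / seq_len(m))
  adj <- rev(cummin(rev(raw)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Select significantly correlated genes
#'
#' Returns genes passing the significance threshold. The default uses raw
#' p-values (the convention of the genome-wide correlation screen);
#' `use_adjusted = TRUE` switches to the BY-adjusted p.
#'
#' @param records a `corr_screen` from [correlate_focal()].
#' @param alpha significance level (default 0.05).
#' @param use_adjusted use `p_adj` instead of `p`.
#' @return list with `genes` (character vector) and `count`.
#' @export
screen_significant <- function(records, alpha = 0.05, use_adjusted = FALSE) {
  stopifnot(nrow(records) > 0)
  pv <- if (use_adjusted) records$p_adj else records$p
  keep <- !is.na(pv) & pv < alpha & records$flag == "ok"
  list(genes = records$gene[keep], count = sum(keep))
}

#' Sign summary over a named gene panel
#'
#' Counts how many panel genes correlate negatively / positively with the
#' focal gene, and how many are absent from the screen.
#'
#' @param records a `corr_screen`.
#' @param panel character vector of gene symbols.
#' @return named integer vector `(n_negative, n_positive, n_missing)`.
#' @export
panel_sign_summary <- function(records, panel) {
  idx <- match(panel, records$gene)
  present <- !is.na(idx)
  rr <- records$r[idx[present]]
  c(n_negative = sum(rr < 0, na.rm = TRUE),
    n_positive = sum(rr > 0, na.rm = TRUE),
    n_missing = sum(!present) + sum(is.na(rr)))
}

#' Correlation between one pair of genes
#'
#' The independence check for a candidate partner gene: Pearson r and its
#' two-sided p for a single pair, same machinery as [correlate_focal()].
#'
#' @param x an [expr_matrix].
#' @param gene_a,gene_b gene symbols.
#' @return one-row data frame `gene`, `r`, `n`, `p`.
#' @export
pairwise_independence <- function(x, gene_a, gene_b) {
  rec <- correlate_focal(x, gene_a, targets = gene_b)
  rec[, c("gene", "r", "n", "p")]
}

#' Write a correlation screen as TSV
#' @param records a `corr_screen`.
#' @param path output path.
#' @export
write_corr_screen <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
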