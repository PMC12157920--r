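#' Expression matrix container
#'
#' The universal substrate of the pipeline: a samples x genes numeric matrix
#' of log2-scale expression values together with per-sample metadata
#' (strain id, diet arm, genotype). Values must be finite; sample and gene
#' ids must be unique.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   genes in columns (colnames = gene symbols), log2 scale.
#' @param sample_meta data frame with columns `sample`, `strain`, `diet`
#'   (one of `"CD"`, `"HFD"`, `NA`) and `genotype` (`"WT"`, `"KO"`, `NA`).
#'   Defaults to a skeleton built from the rownames.
#' @return an object of class `expr_matrix`: a list with elements `values`
#'   and `sample_meta`.
#' @examples
#' m <- matrix(rnorm(6, 8, 2), 2, 3,
#'             dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
#' em <- expr_matrix(m)
#' dim(em$values)
#' @export
expr_matrix <- function(values, sample_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x genes)", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample rownames and gene colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate gene ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (!all(is.finite(values)))
    stop("expression values must all be finite", call. = FALSE)
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample = rownames(values),
                              strain = rownames(values),
                              diet = NA_character_,
                              genotype = NA_character_,
                              stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(sample_meta),
            all(c("sample", "strain", "diet", "genotype") %in%
                  names(sample_meta)))
  if (!identical(sample_meta$sample, rownames(values)))
    stop("sample_meta$sample must match rownames(values) in order",
         call. = FALSE)
  structure(list(values = values, sample_meta = sample_meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d samples x %d genes (log2 scale)\n",
              nrow(x$values), ncol(x$values)))
  arms <- table(x$sample_meta$diet, useNA = "ifany")
  cat("  diet:", paste(names(arms), arms, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and sample accessors
#' @param x an [expr_matrix].
#' @return character vector of ids.
#' @export
genes <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  colnames(x$values)
}

#' @rdname genes
#' @export
samples <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  rownames(x$values)
}

# Fetch one gene column with a clear lookup error.
gene_column <- function(x, gene) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!gene %in% colnames(x$values))
    stop(sprintf("gene '%s' not found in matrix", gene), call. = FALSE)
  x$values[, gene]
}

# Subset samples, keeping metadata aligned.
subset_samples <- function(x, ids) {
  missing <- setdiff(ids, rownames(x$values))
  if (length(missing))
    stop("unknown sample ids: ", paste(missing, collapse = ", "),
         call. = FALSE)
  expr_matrix(x$values[ids, , drop = FALSE],
              x$sample_meta[match(ids, x$sample_meta$sample), , drop = FALSE])
}
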