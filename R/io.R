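#' Read an expression matrix from TSV
#'
#' The on-disk dialect is a tab-separated table whose first column holds
#' sample ids and whose header row holds gene symbols (samples x genes).
#' GeneNetwork-style exports are transposed (genes in rows); pass
#' `orientation = "genes_by_samples"` to accept those.
#'
#' @param path path to a TSV file.
#' @param meta_path optional path to a metadata TSV with columns
#'   `sample`, `strain`, `diet`, `genotype`.
#' @param orientation `"samples_by_genes"` (default) or `"genes_by_samples"`.
#' @return an [expr_matrix].
#' @export
read_expr_matrix <- function(path, meta_path = NULL,
                             orientation = c("samples_by_genes",
                                             "genes_by_samples")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
               stringsAsFactors = FALSE, fill = FALSE),
    error = function(e)
      stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE))
  if (ncol(df) < 2) stop("matrix TSV needs an id column plus data columns",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate row ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  cols <- names(df)[-1]
  if (anyDuplicated(cols))
    stop("duplicate column ids in ", path, ": ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "),
         call. = FALSE)
  for (j in seq_along(cols)) {
    v <- df[[j + 1]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   ids[bad], cols[j]), call. = FALSE)
    }
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (orientation == "genes_by_samples") m <- t(m)
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- read.delim(meta_path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    meta <- meta[match(rownames(m), meta$sample), , drop = FALSE]
    rownames(meta) <- NULL
  }
  expr_matrix(m, meta)
}

#' Write an expression matrix (and its metadata) as TSV
#'
#' Values are written with 8 significant digits, so write-then-read
#' round-trips to within 1e-5 in absolute value on log2-expression scales.
#'
#' @param x an [expr_matrix].
#' @param path output TSV path.
#' @param meta_path optional path for the metadata TSV.
#' @return `path`, invisibly.
#' @export
write_expr_matrix <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(sample = rownames(x$values),
                   signif(x$values, 8), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    write.table(x$sample_meta, meta_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Read / write gene-set collections in GMT format
#'
#' GMT is tab-separated: set name, description, then member gene symbols,
#' one set per line.
#'
#' @param path path to a `.gmt` file.
#' @return `read_gmt`: a named list of character vectors (the description is
#'   kept in attribute `"description"` of each element).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line (need name, description, >=1 member): ",
           substr(ln, 1, 60), call. = FALSE)
    members <- unique(f[-(1:2)])
    attr(members, "description") <- f[2]
    out[[f[1]]] <- members
  }
  if (anyDuplicated(names(out)))
    stop("duplicate set names in GMT", call. = FALSE)
  out
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a transcription-factor list
#'
#' Plain text, one gene symbol per line; blank lines and `#` comments are
#' ignored.
#'
#' @param path path to the list file.
#' @return character vector of symbols.
#' @export
read_tf_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Read a probe annotation table
#'
#' TSV with columns `probe_id`, `gene`, `cross_hyb` (logical or 0/1),
#' followed by one column per sample of log2 expression values.
#'
#' @param path path to the table.
#' @return data frame with those columns; sample columns are numeric.
#' @export
read_probe_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("probe_id", "gene", "cross_hyb")
  if (!all(need %in% names(df)))
    stop("probe table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$cross_hyb <- as.logical(df$cross_hyb)
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe ids in probe table", call. = FALSE)
  df
}
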