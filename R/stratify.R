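#' Rank samples by focal-gene expression
#'
#' Stable ascending sort of samples on the focal gene's log2 value; ties
#' break by sample id, for determinism.
#'
#' @param x an [expr_matrix].
#' @param focal focal gene symbol.
#' @return data frame with columns `sample`, `value`, `rank` (1 = lowest)
#'   and `percentile` (`100 * (rank - 1) / (n - 1)`).
#' @export
rank_focal <- function(x, focal) {
  v <- gene_column(x, focal)
  ord <- order(v, names(v))
  n <- length(v)
  out <- data.frame(sample = names(v)[ord], value = unname(v[ord]),
                    rank = seq_len(n),
                    stringsAsFactors = FALSE)
  out$percentile <- if (n > 1) 100 * (out$rank - 1) / (n - 1) else 50
  attr(out, "focal") <- focal
  out
}

#' Linear fold difference of a gene across samples
#'
#' For log2-scale values this is `2^(max - min)`; a constant column gives 1.
#'
#' @inheritParams rank_focal
#' @return a single dimensionless fold value.
#' @export
fold_difference <- function(x, focal) {
  v <- gene_column(x, focal)
  2^(max(v) - min(v))
}

#' Percentile rank of one sample in the focal ordering
#'
#' Uses `100 * (rank - 1) / (n - 1)` so the lowest sample sits at 0 and the
#' highest at 100; the reported value rounds to the nearest integer.
#'
#' @param ranking a ranking from [rank_focal()].
#' @param sample sample id.
#' @return list with `raw` (exact percentile) and `reported` (integer).
#' @export
percentile_rank <- function(ranking, sample) {
  i <- match(sample, ranking$sample)
  if (is.na(i)) stop(sprintf("sample '%s' not in ranking", sample),
                     call. = FALSE)
  raw <- ranking$percentile[i]
  list(raw = raw, reported = as.integer(round(raw)))
}

#' Assign HIGH / LOW / MID strata from a focal ranking
#'
#' The top `n_high` samples of the ranking become HIGH, the bottom `n_low`
#' LOW, and the remainder MID. Group sizes can be given explicitly, via a
#' named preset — `"paper-chow"` is (12, 12) and `"paper-hfd"` is (11, 10),
#' the printed quartile group sizes for 42- and 37-strain panels — or as a
#' `fraction` of n (rounded half-up, e.g. 0.25 for quartiles).
#'
#' @param ranking a ranking from [rank_focal()].
#' @param n_high,n_low explicit group sizes.
#' @param preset `"paper-chow"` or `"paper-hfd"`.
#' @param fraction fraction of samples per tail, e.g. `0.25`.
#' @return a `strata_assignment`: data frame with columns `sample`, `label`,
#'   `value`, `rank`, `percentile`, plus attributes `n_high`, `n_low`,
#'   `focal`.
#' @export
assign_strata <- function(ranking, n_high = NULL, n_low = NULL,
                          preset = NULL, fraction = NULL) {
  n <- nrow(ranking)
  if (!is.null(preset)) {
    sizes <- switch(preset,
                    "paper-chow" = c(12L, 12L),
                    "paper-hfd" = c(11L, 10L),
                    stop("unknown preset: ", preset, call. = FALSE))
    n_high <- sizes[1]; n_low <- sizes[2]
  } else if (!is.null(fraction)) {
    stopifnot(fraction > 0, fraction <= 0.5)
    n_high <- n_low <- as.integer(floor(n * fraction + 0.5))  # half-up
  }
  if (is.null(n_high) || is.null(n_low))
    stop("supply n_high/n_low, a preset, or a fraction", call. = FALSE)
  if (n_high + n_low > n)
    stop(sprintf("overlapping strata: n_high (%d) + n_low (%d) > n (%d)",
                 n_high, n_low, n), call. = FALSE)
  label <- rep("MID", n)
  label[seq_len(n_low)] <- "LOW"
  label[seq.int(n - n_high + 1L, n)] <- "HIGH"
  out <- ranking
  out$label <- label
  out <- out[, c("sample", "label", "value", "rank", "percentile")]
  structure(out, n_high = as.integer(n_high), n_low = as.integer(n_low),
            focal = attr(ranking, "focal"), class = c("strata_assignment",
                                                      "data.frame"))
}

#' Sample ids of one stratum
#' @param strata a `strata_assignment`.
#' @param label `"HIGH"`, `"LOW"` or `"MID"`.
#' @return character vector of sample ids.
#' @export
stratum_samples <- function(strata, label) {
  stopifnot(inherits(strata, "strata_assignment"),
            label %in% c("HIGH", "LOW", "MID"))
  strata$sample[strata$label == label]
}

#' Serialize a strata assignment as TSV
#' @param strata a `strata_assignment`.
#' @param path output path.
#' @export
write_strata <- function(strata, path) {
  write.table(as.data.frame(strata), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
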