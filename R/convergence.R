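#' Classify pathway overlap across contrasts
#'
#' Takes enrichment results from two or more contrasts (e.g. panel L-vs-H,
#' knockout KO-vs-WT, HFD L-vs-H), keeps the sets significant at `alpha` on
#' the adjusted p, and classifies every such pathway by name:
#' `"common-all"` if significant in every contrast, `"unique:<label>"` if
#' in exactly one, `"common-pair:<a>+<b>"` otherwise. Pathways whose NES
#' signs disagree between contrasts are flagged discordant, never silently
#' merged.
#'
#' @param results_by_contrast named list of `enrichment_result` data frames
#'   (names are the contrast labels).
#' @param alpha threshold on `p_adj` (default 0.05).
#' @return list of class `convergence_report`: `classification` (data frame
#'   `set`, `class`, `contrasts`, `discordant`), `significant_sets` (named
#'   list per contrast), `alpha`.
#' @export
classify_overlap <- function(results_by_contrast, alpha = 0.05) {
  stopifnot(is.list(results_by_contrast),
            length(results_by_contrast) >= 2,
            !is.null(names(results_by_contrast)))
  labels <- names(results_by_contrast)
  sig <- lapply(results_by_contrast, function(res) {
    if (anyDuplicated(res$set))
      stop("duplicate pathway names within one contrast: ",
           paste(unique(res$set[duplicated(res$set)]), collapse = ", "),
           call. = FALSE)
    res[!is.na(res$p_adj) & res$p_adj < alpha, , drop = FALSE]
  })
  all_sets <- sort(unique(unlist(lapply(sig, `[[`, "set"))))
  rows <- lapply(all_sets, function(s) {
    inlab <- labels[vapply(sig, function(d) s %in% d$set, logical(1))]
    cls <- if (length(inlab) == length(labels)) "common-all"
           else if (length(inlab) == 1) paste0("unique:", inlab)
           else paste0("common-pair:", paste(inlab, collapse = "+"))
    signs <- vapply(inlab, function(l)
      sign(sig[[l]]$nes[sig[[l]]$set == s]), numeric(1))
    data.frame(set = s, class = cls,
               contrasts = paste(inlab, collapse = "+"),
               discordant = length(unique(signs)) > 1,
               stringsAsFactors = FALSE)
  })
  classification <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(0), class = character(0),
               contrasts = character(0), discordant = logical(0))
  structure(list(classification = classification,
                 significant_sets = lapply(sig, `[[`, "set"),
                 alpha = alpha),
            class = "convergence_report")
}

#' Rank concordance of two contrasts within a gene set
#'
#' Spearman rank correlation of the log2FC scores of the shared set genes
#' between two ranked lists.
#'
#' @param ranked_a,ranked_b `ranked_list` objects.
#' @param gene_set character vector; at least 3 members must be shared by
#'   both rankings.
#' @return Spearman rho (numeric scalar).
#' @export
gene_rank_concordance <- function(ranked_a, ranked_b, gene_set) {
  shared <- intersect(intersect(gene_set, ranked_a$gene), ranked_b$gene)
  if (length(shared) < 3)
    stop("need >= 3 shared set genes for rank concordance", call. = FALSE)
  sa <- ranked_a$score[match(shared, ranked_a$gene)]
  sb <- ranked_b$score[match(shared, ranked_b$gene)]
  cor(sa, sb, method = "spearman")
}

#' Write a convergence report (JSON + TSV)
#'
#' @param report a `convergence_report`.
#' @param json_path,tsv_path output paths (either may be NULL).
#' @param provenance optional list (config hash, seed, timestamp) embedded
#'   in the JSON; a timestamp is added if absent.
#' @export
write_convergence_report <- function(report, json_path = NULL,
                                     tsv_path = NULL, provenance = NULL) {
  stopifnot(inherits(report, "convergence_report"))
  if (!is.null(json_path)) {
    if (!is.null(provenance) && is.null(provenance$timestamp))
      provenance$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    payload <- list(classification = report$classification,
                    significant_sets = report$significant_sets,
                    alpha = report$alpha, provenance = provenance)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(tsv_path))
    write.table(report$classification, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(report)
}
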