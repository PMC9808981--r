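# Exon-to-gene collapse and hypergeometric over-representation
# analysis against user-supplied GMT collections.

#' Collapse signature exons to genes
#'
#' Distinct `gene_id` values of the given exons; several exons of one
#' gene collapse to a single entry.
#'
#' @param exons character vector of exon ids.
#' @param catalog an [exon_catalog] containing every id.
#' @return Character vector of gene ids.
#' @export
map_exons_to_genes <- function(exons, catalog) {
  idx <- match(exons, catalog$exon_id)
  if (anyNA(idx))
    stop("exon ids missing from catalog: ",
         paste(utils::head(exons[is.na(idx)], 5), collapse = ", "))
  unique(catalog$gene_id[idx])
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the one-sided upper-tail hypergeometric
#' probability of observing at least the realized overlap between the
#' query list and the set, drawing `|list|` genes from the universe:
#' `P(X >= k)` with `k = |list intersect set|`. Sets are intersected
#' with the universe before testing; BH-FDR is applied across sets.
#' Both raw and adjusted p-values are always reported.
#'
#' @param gene_list character vector of query genes (must lie in the
#'   universe).
#' @param sets named list of gene-id vectors, as from [read_gmt].
#' @param universe character vector of background genes (default in
#'   the pipeline: all genes of the filtered exon catalog).
#' @return `data.frame` sorted by p-value with columns `set`,
#'   `overlap`, `set_size`, `list_size`, `universe_size`, `p_value`,
#'   `fdr`, `genes` (comma-separated overlap).
#' @export
ora_test <- function(gene_list, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, universe)
  if (length(outside))
    stop("query genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  n_list <- length(gene_list)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    hit <- intersect(gene_list, set)
    k <- length(hit)
    p <- stats::phyper(k - 1, length(set),
                       length(universe) - length(set), n_list,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(set),
               list_size = n_list, universe_size = length(universe),
               p_value = p, genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$set), ]
  rownames(out) <- NULL
  out[, c("set", "overlap", "set_size", "list_size", "universe_size",
          "p_value", "fdr", "genes")]
}
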