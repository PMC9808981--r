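#' Exon-by-sample count container
#'
#' Light-weight container holding a non-negative integer matrix of exon
#' counts (rows = exons, columns = samples) together with per-sample
#' library sizes. Library sizes default to column sums but are carried
#' separately so that row filtering can preserve the original assay
#' depth, as the low-presence filter requires.
#'
#' @param counts integer matrix, rows named by exon id, columns by
#'   sample id. Must be non-negative and whole-numbered.
#' @param lib_sizes numeric vector of positive library sizes, one per
#'   column. Defaults to `colSums(counts)`.
#' @return An object of class `dpe_counts`: a list with elements
#'   `counts` (the matrix) and `lib_sizes` (named numeric).
#' @export
dpe_counts <- function(counts, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0L)
    rownames(counts) <- paste0("exon_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)) && ncol(counts) > 0L)
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  if (anyNA(counts))
    stop("counts must not contain NA values")
  if (any(counts < 0))
    stop("counts must be non-negative")
  if (length(counts) && max(abs(counts - round(counts))) > 1e-8)
    stop("counts must be whole numbers")
  storage.mode(counts) <- "integer"
  lib_sizes <- as.numeric(lib_sizes)
  if (length(lib_sizes) != ncol(counts))
    stop("lib_sizes must have one entry per sample")
  if (any(!is.finite(lib_sizes)) || any(lib_sizes <= 0))
    stop("lib_sizes must be positive for every retained sample: ",
         paste(colnames(counts)[!is.finite(lib_sizes) | lib_sizes <= 0],
               collapse = ", "))
  names(lib_sizes) <- colnames(counts)
  structure(list(counts = counts, lib_sizes = lib_sizes),
            class = "dpe_counts")
}

#' @export
dim.dpe_counts <- function(x) dim(x$counts)

#' @export
dimnames.dpe_counts <- function(x) dimnames(x$counts)

#' @export
print.dpe_counts <- function(x, ...) {
  cat("dpe_counts: ", nrow(x$counts), " exons x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("library sizes: ", paste(signif(utils::head(x$lib_sizes, 5), 4),
                               collapse = ", "),
      if (ncol(x$counts) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Subset rows and/or columns of a count container
#'
#' Row subsetting keeps the stored library sizes untouched (depth is a
#' property of the assay, not of the retained rows); column subsetting
#' keeps the matching library sizes.
#'
#' @param x a `dpe_counts` object.
#' @param i,j row/column index vectors (logical, integer or character).
#' @param ... ignored.
#' @export
`[.dpe_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  dpe_counts(x$counts[i, j, drop = FALSE], lib_sizes = x$lib_sizes[j])
}

stopifnot_counts <- function(x) {
  if (!inherits(x, "dpe_counts"))
    stop("expected a 'dpe_counts' object; see dpe_counts()")
  invisible(x)
}
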