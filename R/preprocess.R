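#' Remove sex-chromosome exons
#'
#' Plasma cfDNA read representation on X and Y separates cohorts by
#' patient sex rather than disease, so exons on the sex chromosomes
#' are dropped before any group comparison. Chromosome names are
#' matched after stripping an optional "chr" prefix, case-insensitively.
#' Library sizes are recomputed as column sums of the retained rows so
#' that downstream normalization is sex-composition-free.
#'
#' @param x a [dpe_counts] object.
#' @param catalog an [exon_catalog] covering every exon in `x`.
#' @return A [dpe_counts] without X/Y exons.
#' @export
remove_sex_exons <- function(x, catalog) {
  stopifnot_counts(x)
  idx <- match(rownames(x$counts), catalog$exon_id)
  if (anyNA(idx))
    stop("exon ids missing from catalog: ",
         paste(utils::head(rownames(x$counts)[is.na(idx)], 5),
               collapse = ", "))
  chr <- tolower(sub("^chr", "", catalog$chrom[idx], ignore.case = TRUE))
  keep <- !(chr %in% c("x", "y"))
  kept <- x$counts[keep, , drop = FALSE]
  dpe_counts(kept, lib_sizes = pmax(colSums(kept), 1e-8))
}

#' Counts per million
#'
#' `cpm[g, s] = counts[g, s] / lib_sizes[s] * 1e6`. When library sizes
#' are the column sums every column of the result sums to one million.
#'
#' @param x a [dpe_counts] object.
#' @return A numeric matrix of the same shape as `x$counts`.
#' @export
compute_cpm <- function(x) {
  stopifnot_counts(x)
  bad <- which(x$lib_sizes <= 0)
  if (length(bad))
    stop("zero library size for sample: ",
         paste(names(x$lib_sizes)[bad], collapse = ", "))
  sweep(x$counts, 2L, x$lib_sizes, "/") * 1e6
}

#' Low-presence exon filter
#'
#' Implements the literal filtering rule: an exon is removed when its
#' CPM falls below `min_cpm` in at least `min_samples` samples. The
#' alternative convention common in count workflows (keep when at
#' least `min_samples` samples reach `min_cpm`) is available via
#' `convention = "keep-if-expressed"`. Library sizes are NOT recomputed
#' after filtering: they reflect the pre-filter assay depth.
#'
#' @param x a [dpe_counts] object.
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples sample-count threshold (default 20).
#' @param convention `"remove-if-low"` (default, the literal rule) or
#'   `"keep-if-expressed"`.
#' @return The filtered [dpe_counts], row order preserved.
#' @export
filter_low_presence <- function(x, min_cpm = 1, min_samples = 20,
                                convention = c("remove-if-low",
                                               "keep-if-expressed")) {
  stopifnot_counts(x)
  convention <- match.arg(convention)
  if (min_cpm < 0) stop("min_cpm must be >= 0")
  if (min_samples < 1 || min_samples > ncol(x$counts))
    stop("min_samples must be between 1 and the number of samples (",
         ncol(x$counts), ")")
  cpm <- compute_cpm(x)
  if (convention == "remove-if-low") {
    low <- rowSums(cpm < min_cpm)
    keep <- low < min_samples
  } else {
    keep <- rowSums(cpm >= min_cpm) >= min_samples
  }
  dpe_counts(x$counts[keep, , drop = FALSE], lib_sizes = x$lib_sizes)
}

# 75th-percentile CPM per sample, used to pick the TMM reference
upper_quartile_cpm <- function(x) {
  apply(sweep(x$counts, 2L, x$lib_sizes, "/"), 2L,
        stats::quantile, probs = 0.75, names = FALSE) * 1e6
}

# single pairwise TMM factor of sample `obs` against `ref`
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  pos <- obs > 0 & ref > 0
  obs <- obs[pos]; ref <- ref[pos]
  if (length(obs) == 0L) return(1)
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  ok <- is.finite(m) & is.finite(a) & is.finite(w) & w > 0
  m <- m[ok]; a <- a[ok]; w <- w[ok]
  n <- length(m)
  if (n == 0L) return(1)
  if (max(abs(m)) < 1e-6) return(1)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m)
  ra_ <- rank(a)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(keep)) return(1)
  # inverse asymptotic-variance weights
  f <- sum(m[keep] / w[keep]) / sum(1 / w[keep])
  if (!is.finite(f)) return(1)
  2^f
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each sample, the weighted mean of
#' per-exon log2 count ratios against a reference sample, after
#' discarding exons with a zero in either sample and trimming the
#' most extreme 30 percent of M-values (log-ratios) and 5 percent of
#' A-values (abundances) on each side is computed with inverse
#' asymptotic-variance weights. The reference is the sample whose
#' upper-quartile CPM is closest to the mean upper-quartile, unless
#' given. Factors are rescaled so their geometric mean is one.
#'
#' @param x a [dpe_counts] object with at least two samples.
#' @param ref_sample optional sample id to use as reference.
#' @param trim_m,trim_a two-sided trim fractions for M and A values
#'   (defaults 0.30 and 0.05).
#' @return Named numeric vector of positive factors, geometric mean 1.
#' @export
tmm_factors <- function(x, ref_sample = NULL, trim_m = 0.30,
                        trim_a = 0.05) {
  stopifnot_counts(x)
  n <- ncol(x$counts)
  if (n < 2L) stop("TMM needs at least two samples")
  if (any(colSums(x$counts) == 0))
    stop("sample with all-zero counts: ",
         paste(colnames(x$counts)[colSums(x$counts) == 0],
               collapse = ", "))
  if (is.null(ref_sample)) {
    uq <- upper_quartile_cpm(x)
    ref_i <- which.min(abs(uq - mean(uq)))
  } else {
    ref_i <- match(ref_sample, colnames(x$counts))
    if (is.na(ref_i)) stop("ref_sample '", ref_sample, "' not found")
  }
  f <- vapply(seq_len(n), function(j) {
    if (j == ref_i) return(1)
    tmm_pair(x$counts[, j], x$counts[, ref_i],
             x$lib_sizes[j], x$lib_sizes[ref_i], trim_m, trim_a)
  }, 0)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(x$counts)
  f
}

#' Normalized log2-CPM
#'
#' `log2((counts + prior) / (lib_size * factor + 2 * prior) * 1e6)`,
#' finite for every entry. This is the "normalized values" matrix fed
#' to clustering, ordination and classification.
#'
#' @param x a [dpe_counts] object.
#' @param factors normalization factors as from [tmm_factors]; default
#'   all ones.
#' @param prior_count positive stabilizing offset (default 0.5).
#' @return A numeric matrix, exons by samples.
#' @export
log_cpm <- function(x, factors = NULL, prior_count = 0.5) {
  stopifnot_counts(x)
  if (prior_count <= 0) stop("prior_count must be > 0")
  if (is.null(factors)) factors <- rep(1, ncol(x$counts))
  eff <- x$lib_sizes * factors
  log2(sweep(x$counts + prior_count, 2L, eff + 2 * prior_count, "/")
       * 1e6)
}

# average abundance per exon on the log2-CPM scale (reporting axis
# and binning variable for dispersion trends)
ave_log_cpm <- function(x, factors = NULL, prior_count = 0.5) {
  stopifnot_counts(x)
  if (is.null(factors)) factors <- rep(1, ncol(x$counts))
  eff <- x$lib_sizes * factors
  cpm <- sweep(x$counts + prior_count, 2L, eff + 2 * prior_count, "/") *
    1e6
  log2(rowMeans(cpm))
}
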