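# Differential-presence testing: one-factor NB GLM designs, the LRT
# and quasi-likelihood F tests, BH-FDR, and the consensus caller.

COMPARISONS <- c("M_vs_N", "C_vs_H", "M_vs_H")

comparison_groups <- function(comparison) {
  switch(comparison,
         M_vs_N = list(test = "M", base = "N",
                       test_codes = "M", base_codes = "N"),
         C_vs_H = list(test = "C", base = "H",
                       test_codes = c("M", "N"), base_codes = "H"),
         M_vs_H = list(test = "M", base = "H",
                       test_codes = "M", base_codes = "H"),
         stop("unknown comparison '", comparison, "'; expected one of ",
              paste(COMPARISONS, collapse = ", ")))
}

#' Build a one-factor design for a cohort comparison
#'
#' The study's three comparisons are metastatic vs non-metastatic
#' (`M_vs_N`), all cancer vs healthy (`C_vs_H`, where C pools M and N
#' at design time) and metastatic vs healthy (`M_vs_H`).
#' Unclassifiable (U) samples never enter any design. The design is
#' an intercept plus one indicator for the first-named (contrast)
#' group, so a positive coefficient means over-representation in that
#' group.
#'
#' @param samples sample sheet `data.frame` with `sample_id` and
#'   `group` columns (see [read_sample_sheet]).
#' @param comparison one of `"M_vs_N"`, `"C_vs_H"`, `"M_vs_H"`.
#' @return A list: `design` (matrix, retained samples x 2), `samples`
#'   (retained rows of the sheet, design order), `contrast` (column
#'   index of the group effect, always 2), `comparison`.
#' @export
build_design <- function(samples, comparison = COMPARISONS) {
  comparison <- match.arg(comparison)
  cg <- comparison_groups(comparison)
  keep <- samples$group %in% c(cg$test_codes, cg$base_codes)
  sub <- samples[keep, , drop = FALSE]
  is_test <- sub$group %in% cg$test_codes
  if (!any(is_test))
    stop("comparison ", comparison, ": no samples in group ", cg$test)
  if (all(is_test))
    stop("comparison ", comparison, ": no samples in group ", cg$base)
  design <- cbind("(Intercept)" = 1, as.numeric(is_test))
  colnames(design)[2] <- paste0("group", cg$test)
  rownames(design) <- sub$sample_id
  list(design = design, samples = sub, contrast = 2L,
       comparison = comparison)
}

# subset a count matrix to the samples of a design, in design order
align_counts_to_design <- function(x, dsg) {
  idx <- match(dsg$samples$sample_id, colnames(x$counts))
  if (anyNA(idx))
    stop("samples in design missing from count matrix: ",
         paste(dsg$samples$sample_id[is.na(idx)], collapse = ", "))
  x[, idx]
}

# stabilized log2 fold-change: refit with a small prior count added
# to the data (reporting only, never used for inference)
stabilized_logfc <- function(x, dsg, factors, dispersions,
                             prior_count = 0.125) {
  shifted <- x$counts + prior_count
  fit <- fit_nb_glm(
    structure(list(counts = shifted, lib_sizes = x$lib_sizes),
              class = "dpe_counts"),
    dsg$design, factors, dispersions)
  fit$coefficients[, dsg$contrast] / log(2)
}

new_test_result <- function(x, dsg, factors, statistic, p, logfc,
                            method) {
  res <- data.frame(
    exon_id = rownames(x$counts),
    logFC = logfc,
    avg_log_cpm = ave_log_cpm(x, factors),
    statistic = statistic,
    p_value = p,
    fdr = bh_adjust(p),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "method") <- method
  attr(res, "comparison") <- dsg$comparison
  class(res) <- c("dpe_test", "data.frame")
  res
}

# split rows into testable and all-zero (skipped) parts
split_zero_rows <- function(x) {
  zero <- rowSums(x$counts) == 0
  list(test = x[!zero, ], skipped = rownames(x$counts)[zero])
}

#' Likelihood-ratio test for differential presence
#'
#' Fits the full and the intercept-only reduced NB GLM per exon at the
#' tagwise dispersions and refers the deviance difference to
#' chi-square with one degree of freedom. The reported log2
#' fold-change comes from a refit with a 0.125 prior count added to
#' the counts, which keeps it finite; positive values mean
#' over-representation in the comparison's first-named group.
#' All-zero exons are skipped and listed in the `skipped` attribute.
#'
#' @param x a filtered [dpe_counts], columns matching the design's
#'   samples (use [align_counts_to_design]).
#' @param dsg design list from [build_design].
#' @param factors TMM factors for the design's samples.
#' @param dispersions per-exon tagwise dispersions (or a
#'   `dpe_dispersion` object, from which `tagwise` is taken).
#' @return A `data.frame` of class `dpe_test` with columns `exon_id`,
#'   `logFC`, `avg_log_cpm`, `statistic`, `p_value`, `fdr`; method tag
#'   `"LRT"` in `attr(, "method")`.
#' @export
lrt_test <- function(x, dsg, factors = NULL, dispersions) {
  stopifnot_counts(x)
  if (inherits(dispersions, "dpe_dispersion"))
    dispersions <- dispersions$tagwise
  if (is.null(factors)) factors <- rep(1, ncol(x$counts))
  parts <- split_zero_rows(x)
  xt <- parts$test
  phi <- rep_len(dispersions, nrow(x$counts))[
    !rownames(x$counts) %in% parts$skipped]
  full <- fit_nb_glm(xt, dsg$design, factors, phi)
  reduced <- fit_nb_glm(xt, dsg$design[, -dsg$contrast, drop = FALSE],
                        factors, phi)
  stat <- pmax(reduced$deviance - full$deviance, 0)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  logfc <- stabilized_logfc(xt, dsg, factors, phi)
  res <- new_test_result(xt, dsg, factors, stat, p, logfc, "LRT")
  attr(res, "skipped") <- parts$skipped
  res
}

# limma-style trigamma inverse (Newton on the trigamma function)
trigamma_inverse <- function(y) {
  out <- y
  lo <- y < 1e-6; out[lo] <- 1 / y[lo]
  hi <- y > 1e7; out[hi] <- 1 / sqrt(y[hi])
  mid <- which(!lo & !hi)
  x <- 0.5 + 1 / y[mid]
  for (i in seq_len(50)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (max(-dif / x) < 1e-8) break
  }
  out[mid] <- x
  out
}

# Empirical-Bayes squeeze of quasi-dispersions toward their abundance
# trend. Moment matching of log scaled-F: the excess variance of
# log s2 about the trend over trigamma(df/2) determines the prior df.
squeeze_quasi_disp <- function(s2, df, abundance, span = 0.5) {
  ok <- s2 > 1e-12 & is.finite(s2)
  z <- log(pmax(s2, 1e-12))
  ztrend <- NULL
  if (sum(ok) >= 30L && stats::sd(abundance[ok]) > 1e-3) {
    ztrend <- tryCatch({
      lo <- stats::loess(z[ok] ~ abundance[ok], span = span,
                         degree = 1,
                         control = stats::loess.control(surface =
                                                          "direct"))
      as.numeric(stats::predict(lo, newdata =
                                  data.frame(`abundance[ok]` =
                                               abundance,
                                             check.names = FALSE)))
    }, warning = function(w) NULL, error = function(e) NULL)
  }
  if (is.null(ztrend))
    ztrend <- rep(stats::median(z[ok]), length(z))
  resid_var <- stats::var(z[ok] - ztrend[ok])
  excess <- resid_var - trigamma(df / 2)
  if (!is.finite(excess) || excess < 1e-8) {
    d0 <- Inf
    s2_0 <- exp(ztrend - (digamma(df / 2) - log(df / 2)))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s2_0 <- exp(ztrend - (digamma(df / 2) - log(df / 2)) +
                  (digamma(d0 / 2) - log(d0 / 2)))
  }
  s2_post <- if (is.infinite(d0)) s2_0 else
    (df * s2 + d0 * s2_0) / (df + d0)
  list(s2_post = pmax(s2_post, 1e-12), prior_df = d0, s2_prior = s2_0)
}

#' Quasi-likelihood F test for differential presence
#'
#' Fits full and reduced NB GLMs at the trended dispersions, forms the
#' per-exon quasi-dispersion (residual deviance over residual df),
#' squeezes it toward its abundance trend with an empirical-Bayes
#' prior df estimated by moment matching, and refers
#' `F = (deviance difference / 1) / squeezed s2` to an F distribution
#' with `1` and `residual df + prior df` degrees of freedom.
#'
#' @inheritParams lrt_test
#' @param dispersions per-exon trended dispersions (or a
#'   `dpe_dispersion` object, from which `trended` is taken).
#' @param span loess span for the quasi-dispersion trend.
#' @return A `dpe_test` data frame, method tag `"QLF"`; the estimated
#'   prior df is in `attr(, "prior_df")`.
#' @export
qlf_test <- function(x, dsg, factors = NULL, dispersions,
                     span = 0.5) {
  stopifnot_counts(x)
  if (inherits(dispersions, "dpe_dispersion"))
    dispersions <- dispersions$trended
  if (is.null(factors)) factors <- rep(1, ncol(x$counts))
  parts <- split_zero_rows(x)
  xt <- parts$test
  phi <- rep_len(dispersions, nrow(x$counts))[
    !rownames(x$counts) %in% parts$skipped]
  full <- fit_nb_glm(xt, dsg$design, factors, phi)
  if (full$df_residual < 1L)
    stop("QLF needs at least 1 residual df")
  reduced <- fit_nb_glm(xt, dsg$design[, -dsg$contrast, drop = FALSE],
                        factors, phi)
  abundance <- ave_log_cpm(xt, factors)
  s2 <- full$deviance / full$df_residual
  sq <- squeeze_quasi_disp(s2, full$df_residual, abundance, span)
  stat <- pmax(reduced$deviance - full$deviance, 0) / 1 / sq$s2_post
  df2 <- full$df_residual + sq$prior_df
  p <- stats::pf(stat, df1 = 1, df2 = df2, lower.tail = FALSE)
  logfc <- stabilized_logfc(xt, dsg, factors, phi)
  res <- new_test_result(xt, dsg, factors, stat, p, logfc, "QLF")
  attr(res, "skipped") <- parts$skipped
  attr(res, "prior_df") <- sq$prior_df
  res
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min(1, min_{j >= i} p_(j) * m / j)`, returned in input
#' order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / seq(m, 1)))[ro]
}

#' Consensus DPE call from both tests
#'
#' A differentially present exon (DPE) is one that both the LRT and
#' the QLF flag at the FDR threshold; direction is the group the exon
#' is over-represented in, taken from the sign of the LRT logFC.
#'
#' @param lrt,qlf `dpe_test` results over the same exon universe.
#' @param fdr_threshold consensus threshold (default 0.001).
#' @return A list of class `dpe_calls`: `comparison`, `exons` (called
#'   ids), `direction` (named character, over-represented group per
#'   called exon), `n_up`/`n_down` (counts per direction),
#'   `fdr_threshold`, `universe`.
#' @export
call_dpe <- function(lrt, qlf, fdr_threshold = 0.001) {
  if (!setequal(lrt$exon_id, qlf$exon_id))
    stop("LRT and QLF results cover different exon universes")
  qlf <- qlf[match(lrt$exon_id, qlf$exon_id), ]
  called <- lrt$fdr <= fdr_threshold & qlf$fdr <= fdr_threshold
  comparison <- attr(lrt, "comparison")
  cg <- comparison_groups(comparison)
  direction <- ifelse(lrt$logFC[called] > 0, cg$test, cg$base)
  names(direction) <- lrt$exon_id[called]
  structure(list(comparison = comparison,
                 exons = lrt$exon_id[called],
                 direction = direction,
                 n_up = sum(direction == cg$test),
                 n_down = sum(direction == cg$base),
                 fdr_threshold = fdr_threshold,
                 universe = lrt$exon_id),
            class = "dpe_calls")
}

#' @export
print.dpe_calls <- function(x, ...) {
  cg <- comparison_groups(x$comparison)
  cat("DPE consensus calls, ", x$comparison, " (FDR <= ",
      x$fdr_threshold, ")\n", sep = "")
  cat("  ", length(x$exons), " DPE of ", length(x$universe),
      " tested exons: ", x$n_up, " over-represented in ", cg$test,
      ", ", x$n_down, " in ", cg$base, "\n", sep = "")
  invisible(x)
}

#' Cross-comparison exonic signature
#'
#' Intersects the called exon sets of several comparisons; the
#' intersection across the study's three comparisons is the exonic
#' signature. Venn region counts for the inputs are reported
#' alongside.
#'
#' @param callsets list of two or more [call_dpe] results.
#' @return A list of class `dpe_signature`: `signature` (exon ids in
#'   every callset) and `venn` (data frame of region membership
#'   patterns and counts).
#' @export
intersect_signature <- function(callsets) {
  if (length(callsets) < 2L)
    stop("need at least two callsets to intersect")
  sets <- lapply(callsets, `[[`, "exons")
  names(sets) <- vapply(callsets, `[[`, "", "comparison")
  signature <- Reduce(intersect, sets)
  all_ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  member <- matrix(member, nrow = length(all_ids),
                   dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1L, function(r)
    paste(ifelse(r, names(sets), ""), collapse = "|"))
  venn <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(venn) <- c("region", "count")
  structure(list(signature = signature, venn = venn),
            class = "dpe_signature")
}

#' MA-plot table for one test
#'
#' One row per tested exon with its average log2-CPM (x-axis), logFC
#' (y-axis), and a flag for membership in the consensus DPE set.
#'
#' @param result a `dpe_test` data frame.
#' @param called a [call_dpe] result on the same universe.
#' @return A `data.frame` with `exon_id`, `avg_log_cpm`, `logFC`,
#'   `is_dpe`.
#' @export
ma_plot_data <- function(result, called) {
  data.frame(exon_id = result$exon_id,
             avg_log_cpm = result$avg_log_cpm,
             logFC = result$logFC,
             is_dpe = result$exon_id %in% called$exons,
             stringsAsFactors = FALSE)
}
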