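# Shared fixtures: tiny catalogs, in-code SAM/BAM builders, a small
# adjusted-Rand-index helper. Everything is generated programmatically
# at test time.

toy_catalog <- function(n = 5, chrom = rep("chr1", n), width = 100L) {
  starts <- seq(0L, by = 1000L, length.out = n)
  exon_catalog(exon_id = paste0("e", seq_len(n)),
               gene_id = paste0("g", ceiling(seq_len(n) / 2)),
               chrom = chrom, start = starts, end = starts + width)
}

toy_counts <- function(mat, lib_sizes = colSums(mat)) {
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("e", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  dpe_counts(mat, lib_sizes = lib_sizes)
}

toy_samples <- function(groups) {
  data.frame(sample_id = sprintf("%s%02d", groups,
                                 ave(seq_along(groups), groups,
                                     FUN = seq_along)),
             group = groups,
             sex = "unknown", stringsAsFactors = FALSE)
}

# write single-end SAM reads (0-based starts) and convert to BAM
make_bam <- function(starts0, mapq, chrlen = 50000L, flags = NULL,
                     qnames = NULL, read_len = 100L) {
  n <- length(starts0)
  if (is.null(flags)) flags <- rep(0L, n)
  if (is.null(qnames)) qnames <- sprintf("r%05d", seq_len(n))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:chr1\tLN:", chrlen))
  mapped <- !bitwAnd(flags, 4L)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  qnames, flags,
                  ifelse(mapped, "chr1", "*"),
                  ifelse(mapped, starts0 + 1L, 0L), mapq,
                  ifelse(mapped, paste0(read_len, "M"), "*"),
                  strrep("A", read_len))
  ord <- order(!mapped, starts0)
  samf <- tempfile(fileext = ".sam")
  writeLines(c(hdr, body[ord]), samf)
  Rsamtools::asBam(samf, tempfile(), overwrite = TRUE)
}

# adjusted Rand index between two label vectors
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# two-group cohort used by several calibration tests
small_cohort <- function(seed, n_exons = 600, n_m = 15, n_n = 15,
                         n_u = 0, logfc = 3, fraction_dpe = 0.1) {
  simulate_cohort(sim_config(n_exons = n_exons, n_m = n_m, n_n = n_n,
                             n_h = 0, n_u = n_u,
                             fraction_dpe = fraction_dpe,
                             logfc_magnitude = logfc,
                             sex_exon_fraction = 0, seed = seed))
}
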