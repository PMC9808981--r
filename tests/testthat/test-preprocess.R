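# CPM, the low-presence filter, sex-exon removal, TMM, log-CPM.

test_that("CPM follows the definition and columns sum to 1e6", {
  x <- toy_counts(matrix(c(5L, 5L, 0L, 10L), 2, 2),
                  lib_sizes = c(10, 20))
  cpm <- compute_cpm(x)
  expect_equal(cpm[1, 1], 5e5)
  y <- toy_counts(matrix(rpois(60, 40), 10, 6))
  expect_equal(unname(colSums(compute_cpm(y))), rep(1e6, 6),
               tolerance = 1e-9)
  bad <- toy_counts(matrix(0:3, 2, 2), lib_sizes = c(10, 1))
  bad$lib_sizes[2] <- 0
  expect_error(compute_cpm(bad), "s2")
})

test_that("low-presence filter implements the literal removal rule", {
  # removed iff CPM < min_cpm in >= min_samples samples
  x1 <- toy_counts(matrix(c(1L, 1L, 4L), 1, 3), lib_sizes = rep(2e6, 3))
  # CPM = (0.5, 0.5, 2)
  expect_equal(nrow(filter_low_presence(x1, 1, 2)$counts), 0L)
  x2 <- toy_counts(matrix(c(4L, 4L, 1L), 1, 3), lib_sizes = rep(2e6, 3))
  expect_equal(nrow(filter_low_presence(x2, 1, 2)$counts), 1L)
  expect_error(filter_low_presence(x2, 1, 5), "min_samples")
})

test_that("filter survivors match a per-row census oracle; filter is idempotent and monotone", {
  set.seed(1)
  mat <- matrix(rnbinom(50 * 30, mu = 30, size = 2), 50, 30)
  x <- toy_counts(mat)
  for (ms in c(5, 15, 25)) {
    kept <- rownames(filter_low_presence(x, 1, ms)$counts)
    cpm <- compute_cpm(x)
    oracle <- rownames(x$counts)[rowSums(cpm < 1) < ms]
    expect_identical(kept, oracle)
  }
  f1 <- filter_low_presence(x, 1, 10)
  f2 <- filter_low_presence(f1, 1, 10)
  expect_identical(f2$counts, f1$counts)  # lib sizes kept => idempotent
  # raising min_cpm or lowering min_samples never grows the survivor set
  base_set <- rownames(filter_low_presence(x, 1, 10)$counts)
  expect_true(all(rownames(filter_low_presence(x, 2, 10)$counts)
                  %in% base_set))
  expect_true(all(rownames(filter_low_presence(x, 1, 5)$counts)
                  %in% base_set))
  # alternative convention keeps exons expressed in enough samples
  alt <- filter_low_presence(x, 1, 10, convention = "keep-if-expressed")
  cpm <- compute_cpm(x)
  expect_identical(rownames(alt$counts),
                   rownames(x$counts)[rowSums(cpm >= 1) >= 10])
})

test_that("sex-exon removal drops X/Y rows and recomputes library sizes", {
  cat <- exon_catalog(paste0("e", 1:4), "g",
                      c("chr1", "chrX", "Y", "chr2"),
                      c(0L, 0L, 0L, 0L), c(10L, 10L, 10L, 10L))
  mat <- matrix(c(10L, 20L, 30L, 40L,
                  1L, 2L, 3L, 4L), 4, 2)
  rownames(mat) <- paste0("e", 1:4)
  x <- toy_counts(mat)
  out <- remove_sex_exons(x, cat)
  expect_equal(rownames(out$counts), c("e1", "e4"))
  expect_equal(unname(out$lib_sizes),
               unname(colSums(mat[c(1, 4), ])))  # summation oracle
  # catalog without sex chromosomes: unchanged
  cat2 <- toy_catalog(4)
  expect_identical(remove_sex_exons(x, cat2)$counts, x$counts)
  # unknown exon -> error listing offenders
  expect_error(remove_sex_exons(x, cat2[1:2, ]), "e3")
})

test_that("TMM identities: identical, doubled, and shuffled columns", {
  set.seed(2)
  base <- rnbinom(200, mu = 100, size = 5) + 1L
  x_same <- toy_counts(matrix(rep(base, 4), ncol = 4))
  expect_equal(unname(tmm_factors(x_same)), rep(1, 4),
               tolerance = 1e-9)
  # doubled column with column-sum library sizes: scaling cancels
  x_dbl <- toy_counts(cbind(s1 = base, s2 = 2L * base,
                            s3 = base, s4 = base))
  expect_equal(unname(tmm_factors(x_dbl)), rep(1, 4),
               tolerance = 1e-6)
  # geometric mean is 1 on random data; row permutation is a no-op
  y <- matrix(rnbinom(200 * 6, mu = 80, size = 3) + 1L, 200, 6)
  xr <- toy_counts(y)
  f <- tmm_factors(xr)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
  perm <- sample(nrow(y))
  xp <- toy_counts(y[perm, ], lib_sizes = xr$lib_sizes)
  expect_equal(unname(tmm_factors(xp)), unname(f), tolerance = 1e-12)
  zero_col <- toy_counts(cbind(base, 0L * base),
                         lib_sizes = c(sum(base), 1))
  expect_error(tmm_factors(zero_col), "all-zero")
})

test_that("TMM matches the reference implementation on random data", {
  skip_if_not_installed("edgeR")
  set.seed(3)
  y <- matrix(rnbinom(500 * 8, mu = exp(rnorm(500, 4, 1)), size = 2),
              500, 8, dimnames = list(NULL, paste0("s", 1:8)))
  y <- y[rowSums(y) > 0, ]
  f_ref <- edgeR::calcNormFactors(edgeR::DGEList(y),
                                  method = "TMM")$samples$norm.factors
  expect_equal(unname(tmm_factors(toy_counts(y))), f_ref,
               tolerance = 1e-10)
})

test_that("log-CPM matches direct formula evaluation and is monotone", {
  mat <- matrix(c(0L, 3L, 10L, 0L, 7L, 2L), 3, 2)
  x <- toy_counts(mat, lib_sizes = c(100, 200))
  fac <- c(1.1, 0.9)
  lc <- log_cpm(x, fac, prior_count = 0.5)
  manual <- log2((mat + 0.5) /
                   rep(c(100 * 1.1, 200 * 0.9) + 1, each = 3) * 1e6)
  expect_equal(unname(lc), unname(manual), tolerance = 1e-12)
  expect_true(all(is.finite(lc)))
  # larger count => larger log-CPM within a sample
  expect_true(lc[3, 1] > lc[2, 1] && lc[2, 1] > lc[1, 1])
  # all-zero matrix: constant finite columns
  z <- toy_counts(matrix(0L, 3, 2), lib_sizes = c(10, 10))
  lz <- log_cpm(z)
  expect_true(all(is.finite(lz)))
  expect_equal(length(unique(lz[, 1])), 1L)
  expect_error(log_cpm(x, fac, prior_count = 0), "prior_count")
})
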