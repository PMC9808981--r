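# Reading annotations, sheets, matrices, GMT; fragment counting.

test_that("GTF exons convert to 0-based half-open with id dedup", {
  gtf <- c(
    'chr1\tsrc\tgene\t50\t400\t.\t+\t.\tgene_id "G1";',
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "G1"; exon_id "E";',
    'chr1\tsrc\texon\t300\t400\t.\t+\t.\tgene_id "G1"; exon_id "E";',
    'chr2\tsrc\texon\t10\t20\t.\t-\t.\tgene_id "G2"; exon_id "E2";')
  f <- tempfile(fileext = ".gtf"); writeLines(gtf, f)
  cat <- read_exon_annotation(f, "gtf")
  expect_equal(nrow(cat), 3L)  # gene row excluded
  expect_equal(cat$start[1], 99L)  # 1-based inclusive -> 0-based
  expect_equal(cat$end[1], 200L)
  expect_equal(cat$exon_id, c("E", "E_2", "E2"))
  expect_equal(cat$gene_id, c("G1", "G1", "G2"))
  expect_equal(cat$strand, c("+", "+", "-"))
})

test_that("BED intervals are used as-is and round-trip via BED", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t200\te1", "chrX\t0\t50\te2"), f)
  cat <- read_exon_annotation(f, "bed")
  expect_equal(cat$start, c(99L, 0L))
  expect_equal(cat$end, c(200L, 50L))
  expect_equal(cat$exon_id, c("e1", "e2"))
  # GTF -> internal -> BED preserves the genomic interval
  gtf <- 'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "G"; exon_id "E";'
  g <- tempfile(fileext = ".gtf"); writeLines(gtf, g)
  from_gtf <- read_exon_annotation(g, "gtf")
  b <- tempfile(fileext = ".bed")
  write_exon_bed(from_gtf, b)
  back <- read_exon_annotation(b, "bed")
  expect_equal(back$start, from_gtf$start)
  expect_equal(back$end, from_gtf$end)
})

test_that("malformed BED lines are rejected with a line number", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\te1", "chr1\toops"), f)
  expect_error(read_exon_annotation(f, "bed"), "line 2")
})

test_that("sample sheets validate ids and group codes", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,sex", "S1,M,male", "S2,N,female",
               "S3,U,unknown", "S4,H,male"), f)
  sheet <- read_sample_sheet(f)
  expect_equal(sheet$sample_id, c("S1", "S2", "S3", "S4"))
  expect_equal(as.character(sheet$group), c("M", "N", "U", "H"))

  writeLines(c("sample_id,group,sex", "S1,M,male", "S1,N,male"), f)
  expect_error(read_sample_sheet(f), "duplicate sample_id")
  writeLines(c("sample_id,group,sex", "S1,X,male"), f)
  expect_error(read_sample_sheet(f), "row 1")
})

test_that("count matrix writing then reading is the identity", {
  x <- toy_counts(matrix(c(0L, 5L, 2L, 7L), 2, 2))
  f <- tempfile(fileext = ".tsv")
  write_count_matrix(x, f, header = "exons=2 samples=2")
  y <- read_count_matrix(f)
  expect_identical(unname(y$counts), unname(x$counts))
  expect_equal(rownames(y$counts), rownames(x$counts))
  expect_equal(colnames(y$counts), colnames(x$counts))
})

test_that("non-integer and negative count cells are rejected by address", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("exon_id\ts1\ts2", "e1\t3\t-1"), f)
  expect_error(read_count_matrix(f), "e1.*s2")
  writeLines(c("exon_id\ts1\ts2", "e1\t3\t3.7"), f)
  expect_error(read_count_matrix(f), "3.7")
})

test_that("GMT parsing deduplicates members and flags short lines", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("SetA\tdesc\tG1\tG2", "SetB\tdesc\tG1\tG1"), f)
  sets <- read_gmt(f)
  expect_equal(sets$SetA, c("G1", "G2"))
  expect_equal(sets$SetB, "G1")
  writeLines("SetA\tdesc", f)
  expect_error(read_gmt(f), "line 1")
})

test_that("union counting assigns unique overlaps and drops ambiguous", {
  cat <- exon_catalog(c("e1", "e2"), c("g1", "g1"), "chr1",
                      c(1000L, 1150L), c(1100L, 1400L))
  # read inside e1; read spanning e1+e2; read outside; low-mapq read
  bam <- make_bam(starts0 = c(1000L, 1080L, 5000L, 1010L),
                  mapq = c(60L, 60L, 60L, 3L))
  res <- count_reads_per_exon(bam, cat, min_mapq = 10)
  expect_equal(as.integer(res$counts[, 1]), c(1L, 0L))
  tal <- attr(res, "assignment")
  expect_equal(unname(tal["ambiguous"]), 1L)
  expect_equal(unname(tal["unassigned"]), 1L)
  expect_equal(unname(res$lib_sizes), 1)
})

test_that("read pairs count once per fragment", {
  cat <- exon_catalog("e1", "g1", "chr1", 1000L, 1600L)
  # proper pair: both mates inside e1 -> one fragment counted once
  bam <- make_bam(starts0 = c(1000L, 1300L), mapq = c(60L, 60L),
                  flags = c(99L, 147L), qnames = c("p1", "p1"))
  res <- count_reads_per_exon(bam, cat)
  expect_equal(as.integer(res$counts[, 1]), 1L)
})

test_that("unmapped-only input warns and returns zeros", {
  cat <- toy_catalog(3)
  bam <- make_bam(starts0 = c(0L, 0L), mapq = c(0L, 0L),
                  flags = c(4L, 4L))
  expect_warning(res <- count_reads_per_exon(bam, cat),
                 "no usable alignments")
  expect_true(all(res$counts == 0L))
})

test_that("non-union assignment modes are rejected", {
  cat <- toy_catalog(2)
  expect_error(count_reads_per_exon("x.bam", cat,
                                    mode = "intersection-strict"),
               "union")
})

test_that("counting equals the brute-force per-read overlap oracle", {
  set.seed(42)
  n_exons <- 20; n_reads <- 200; chrlen <- 10000L
  starts <- sort(sample(seq(0L, chrlen - 400L, by = 13L), n_exons))
  cat <- exon_catalog(paste0("e", seq_len(n_exons)), "g", "chr1",
                      starts, starts + sample(40:250, n_exons, TRUE))
  rs <- sample(0:(chrlen - 100L), n_reads, replace = TRUE)
  mapq <- sample(c(0L, 30L), n_reads, replace = TRUE)
  bam <- make_bam(rs, mapq)
  res <- count_reads_per_exon(bam, cat, min_mapq = 10)
  oracle <- integer(n_exons); amb <- 0L; unas <- 0L
  for (i in seq_len(n_reads)) {
    if (mapq[i] < 10L) next
    hits <- which(rs[i] < cat$end & rs[i] + 100L > cat$start)
    if (length(hits) == 1L) oracle[hits] <- oracle[hits] + 1L
    else if (length(hits) >= 2L) amb <- amb + 1L
    else unas <- unas + 1L
  }
  expect_equal(as.integer(res$counts[, 1]), oracle)
  tal <- attr(res, "assignment")
  expect_equal(unname(tal["ambiguous"]), amb)
  expect_equal(unname(tal["unassigned"]), unas)
  # conservation: assigned + ambiguous + unassigned = eligible reads
  expect_equal(sum(tal), sum(mapq >= 10L))
  expect_equal(sum(res$counts), unname(tal["assigned"]))
})
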