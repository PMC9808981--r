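#' Exon catalog constructor
#'
#' An exon catalog is the coordinate backbone of counting and
#' sex-chromosome filtering: an ordered table of exon intervals with
#' gene linkage. Coordinates are 0-based half-open throughout the
#' package; GTF input is converted on read.
#'
#' @param exon_id character, unique exon identifiers.
#' @param gene_id character, gene identifier per exon.
#' @param chrom character, non-empty chromosome names.
#' @param start,end integer-like 0-based half-open interval bounds,
#'   `start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` per exon.
#' @return A `data.frame` of class `exon_catalog`.
#' @export
exon_catalog <- function(exon_id, gene_id, chrom, start, end,
                         strand = rep(".", length(exon_id))) {
  exon_id <- as.character(exon_id)
  chrom <- as.character(chrom)
  if (anyDuplicated(exon_id))
    stop("duplicate exon_id in catalog: ",
         paste(unique(exon_id[duplicated(exon_id)]), collapse = ", "))
  if (any(!nzchar(chrom))) stop("chrom must be non-empty")
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("exon intervals must satisfy start < end")
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  structure(
    data.frame(exon_id = exon_id, gene_id = as.character(gene_id),
               chrom = chrom, start = start, end = end,
               strand = as.character(strand),
               stringsAsFactors = FALSE),
    class = c("exon_catalog", "data.frame"))
}

# catalog -> GRanges (1-based closed, as GenomicRanges expects)
catalog_granges <- function(catalog) {
  GenomicRanges::GRanges(
    seqnames = catalog$chrom,
    ranges = IRanges::IRanges(start = catalog$start + 1L,
                              end = catalog$end),
    strand = ifelse(catalog$strand == ".", "*", catalog$strand),
    exon_id = catalog$exon_id, gene_id = catalog$gene_id)
}

# make ids unique by appending _2, _3, ... to repeats
dedup_ids <- function(ids) {
  tab <- ave(seq_along(ids), ids, FUN = seq_along)
  ifelse(tab > 1L, paste0(ids, "_", tab), ids)
}

#' Read an exon annotation into a catalog
#'
#' GTF rows with feature type `exon` become catalog records, converting
#' 1-based inclusive GTF coordinates to the package's 0-based half-open
#' convention. BED intervals are used as-is (BED is already 0-based
#' half-open). Exon ids come from the `exon_id` GTF attribute or the
#' BED name column; missing or duplicated ids are made unique with an
#' ordinal suffix.
#'
#' @param path path to the annotation file.
#' @param format `"gtf"` or `"bed"`.
#' @return An [exon_catalog] ordered as in the file.
#' @export
read_exon_annotation <- function(path, format = c("gtf", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "gtf") {
    gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                   error = function(e)
                     stop("failed to parse GTF '", path, "': ",
                          conditionMessage(e)))
    if (!is.null(gr$type)) gr <- gr[gr$type == "exon"]
    if (length(gr) == 0L) stop("no exon features found in ", path)
    ids <- if (!is.null(gr$exon_id)) as.character(gr$exon_id) else
      rep(NA_character_, length(gr))
    ids[is.na(ids) | !nzchar(ids)] <-
      paste0("exon_", which(is.na(ids) | !nzchar(ids)))
    genes <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else
      rep(NA_character_, length(gr))
    exon_catalog(exon_id = dedup_ids(ids),
                 gene_id = ifelse(is.na(genes), "", genes),
                 chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr),
                 strand = ifelse(as.character(GenomicRanges::strand(gr))
                                 == "*", ".",
                                 as.character(GenomicRanges::strand(gr))))
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
    if (length(lines) == 0L) stop("no intervals found in ", path)
    fields <- strsplit(lines, "\t| +")
    nf <- lengths(fields)
    if (any(nf < 3L))
      stop("malformed BED line ", which(nf < 3L)[1L],
           ": fewer than 3 fields")
    chrom <- vapply(fields, `[`, "", 1L)
    start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
    end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad))
      stop("malformed BED line ", bad[1L], ": non-integer coordinates")
    ids <- vapply(fields, function(f)
      if (length(f) >= 4L) f[4L] else NA_character_, "")
    ids[is.na(ids) | !nzchar(ids)] <-
      paste0("exon_", which(is.na(ids) | !nzchar(ids)))
    strand <- vapply(fields, function(f)
      if (length(f) >= 6L && f[6L] %in% c("+", "-")) f[6L] else ".", "")
    exon_catalog(exon_id = dedup_ids(ids), gene_id = "",
                 chrom = chrom, start = start, end = end,
                 strand = strand)
  }
}

#' Write an exon catalog as BED
#'
#' @param catalog an [exon_catalog].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_exon_bed <- function(catalog, path) {
  df <- data.frame(catalog$chrom, catalog$start, catalog$end,
                   catalog$exon_id, 0L, catalog$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Delimited text (comma or tab) with header columns `sample_id`,
#' `group` and `sex`. Groups are restricted to the four cohort codes:
#' `M` (metastatic), `N` (non-metastatic), `U` (unclassifiable) and
#' `H` (healthy control).
#'
#' @param path path to the sheet.
#' @return A `data.frame` with columns `sample_id`, `group`
#'   (factor with levels M, N, U, H) and `sex`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("sample_id", "group", "sex")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ",
         paste(need, collapse = ", "))
  validate_samples(df[need])
}

validate_samples <- function(df) {
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "))
  bad <- which(!df$group %in% c("M", "N", "U", "H"))
  if (length(bad))
    stop("unknown group code '", df$group[bad[1L]], "' in row ",
         bad[1L], " (sample ", df$sample_id[bad[1L]],
         "); expected one of M, N, U, H")
  df$group <- factor(df$group, levels = c("M", "N", "U", "H"))
  df$sex <- ifelse(df$sex %in% c("male", "female"), df$sex, "unknown")
  df
}

#' Count aligned fragments per exon (union mode)
#'
#' HTSeq-style union counting of a coordinate-sorted BAM against an
#' exon catalog. Each primary, non-duplicate alignment with mapping
#' quality at or above `min_mapq` contributes to its read pair's
#' fragment; a fragment overlapping exactly one distinct `exon_id` adds
#' one count to that exon, a fragment overlapping two or more distinct
#' exons is ambiguous and counted nowhere, and a fragment overlapping
#' none is unassigned. Read pairs are counted once (cfDNA fragments are
#' the biological unit); singletons count once on their own.
#'
#' @param bam path to an indexed BAM file.
#' @param catalog an [exon_catalog]; contigs absent from the catalog
#'   yield unassigned reads.
#' @param min_mapq minimum mapping quality (default 10).
#' @param mode assignment mode; only `"union"` is implemented.
#' @return A `dpe_counts` with one column named after the BAM file
#'   (sans extension); its library size is the number of assigned
#'   fragments. Attribute `assignment` tallies assigned, ambiguous and
#'   unassigned fragments.
#' @export
count_reads_per_exon <- function(bam, catalog, min_mapq = 10L,
                                 mode = "union") {
  if (!identical(mode, "union"))
    stop("only assignment mode 'union' is implemented; got '",
         mode, "'")
  if (!inherits(catalog, "exon_catalog")) stop("catalog must be an exon_catalog")
  if (nrow(catalog) == 0L) stop("catalog is empty")
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags, what = c("qname", "mapq"),
                                   mapqFilter = min_mapq)
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  counts <- integer(nrow(catalog))
  names(counts) <- catalog$exon_id
  tallies <- c(assigned = 0L, ambiguous = 0L, unassigned = 0L)
  if (length(aln) == 0L) {
    warning("no usable alignments in ", bam, "; returning zero counts")
  } else {
    gr <- GenomicRanges::granges(aln)
    GenomicRanges::strand(gr) <- "*"
    cat_gr <- catalog_granges(catalog)
    GenomicRanges::strand(cat_gr) <- "*"
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(gr, cat_gr, ignore.strand = TRUE))
    qname <- S4Vectors::mcols(aln)$qname
    # exon set per fragment = union over all alignments sharing qname
    frag_of_read <- match(qname, unique(qname))
    n_frag <- max(frag_of_read)
    hit_frag <- frag_of_read[S4Vectors::queryHits(hits)]
    hit_exon <- S4Vectors::subjectHits(hits)
    pair_key <- paste(hit_frag, hit_exon)
    keep <- !duplicated(pair_key)
    hit_frag <- hit_frag[keep]; hit_exon <- hit_exon[keep]
    n_exons_hit <- tabulate(hit_frag, nbins = n_frag)
    uniq <- which(n_exons_hit == 1L)
    assigned_exon <- hit_exon[match(uniq, hit_frag)]
    tab <- tabulate(assigned_exon, nbins = nrow(catalog))
    counts <- counts + tab
    tallies["assigned"] <- length(uniq)
    tallies["ambiguous"] <- sum(n_exons_hit >= 2L)
    tallies["unassigned"] <- sum(n_exons_hit == 0L)
  }
  sample_id <- sub("\\.bam$", "", basename(bam))
  mat <- matrix(counts, ncol = 1L,
                dimnames = list(catalog$exon_id, sample_id))
  out <- dpe_counts(mat, lib_sizes = max(sum(counts), 1L))
  attr(out, "assignment") <- tallies
  out
}

#' Read / write an exon count matrix (TSV)
#'
#' The on-disk format is tab-separated with exon ids in the first
#' column (`exon_id`) and one column per sample. Comment lines starting
#' with `#` are ignored on read. Writing then reading reproduces
#' counts, ids and ordering exactly.
#'
#' @param path file path.
#' @return For `read_count_matrix`, a [dpe_counts] with library sizes
#'   set to column sums.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("count matrix not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count matrix needs exon ids plus >=1 sample")
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  for (j in seq_len(ncol(mat))) {
    col <- suppressWarnings(as.numeric(mat[, j]))
    bad <- which(is.na(col) | col < 0 | col != round(col))
    if (length(bad))
      stop("invalid count '", mat[bad[1L], j], "' at exon ", ids[bad[1L]],
           ", sample ", colnames(mat)[j],
           ": counts must be non-negative integers")
  }
  storage.mode(mat) <- "numeric"
  rownames(mat) <- ids
  dpe_counts(mat)
}

#' @rdname read_count_matrix
#' @param x a [dpe_counts] object.
#' @param header optional character vector written as `#`-prefixed
#'   metadata lines.
#' @export
write_count_matrix <- function(x, path, header = NULL) {
  stopifnot_counts(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste0("# ", header), con)
  writeLines(paste(c("exon_id", colnames(x$counts)), collapse = "\t"),
             con)
  utils::write.table(
    data.frame(rownames(x$counts), x$counts, check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, all
#' tab-separated. Duplicate members within a line are collapsed.
#'
#' @param path path to a `.gmt` file.
#' @return A named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("GMT line ", which(nf < 3L)[1L],
         " has fewer than 3 fields (name, description, members)")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  sets
}
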