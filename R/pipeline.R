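# Full-study orchestration: three comparisons, signature
# intersection, exploration, classification, enrichment. All outputs
# are deterministic under a fixed seed; every TSV declares the
# exon/sample universe it was computed on in `#` header lines.

write_tsv_meta <- function(df, path, universe_note) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", universe_note), con)
  utils::write.table(format(df, digits = 12, trim = TRUE,
                            scientific = FALSE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run one cohort comparison end to end
#'
#' Executes the per-comparison pipeline: sex-exon removal (when a
#' catalog is given), low-presence filtering, TMM factors, design
#' construction, dispersion estimation, LRT and QLF testing, BH-FDR
#' and the consensus call. The consensus set is asserted to be a
#' subset of each single test's significant set.
#'
#' @param x raw [dpe_counts].
#' @param samples sample sheet (see [read_sample_sheet]).
#' @param comparison one of `"M_vs_N"`, `"C_vs_H"`, `"M_vs_H"`.
#' @param catalog optional [exon_catalog]; enables sex-exon removal.
#' @param min_cpm,min_samples low-presence filter thresholds
#'   (defaults 1 and 20; `min_samples` is capped at the number of
#'   retained samples).
#' @param filter_convention see [filter_low_presence].
#' @param fdr_threshold consensus threshold (default 0.001).
#' @param prior_df dispersion shrinkage weight (default 10).
#' @param out_dir optional directory for TSV artifacts.
#' @return List of class `dpe_comparison`: `calls` ([call_dpe]),
#'   `lrt`, `qlf` (test tables), `filtered` (the tested counts),
#'   `factors`, `dispersions`, `design`.
#' @export
run_comparison <- function(x, samples, comparison, catalog = NULL,
                           min_cpm = 1, min_samples = 20,
                           filter_convention = "remove-if-low",
                           fdr_threshold = 0.001, prior_df = 10,
                           out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' (", comparison, "): ",
           conditionMessage(e), call. = FALSE))
  }
  if (!is.null(catalog))
    x <- stage("sex-exon removal", remove_sex_exons(x, catalog))
  dsg <- stage("design", build_design(samples, comparison))
  xs <- stage("sample alignment", align_counts_to_design(x, dsg))
  ms <- min(min_samples, ncol(xs$counts))
  xf <- stage("low-presence filter",
              filter_low_presence(xs, min_cpm, ms,
                                  filter_convention))
  fac <- stage("TMM", tmm_factors(xf))
  disp <- stage("dispersion",
                estimate_dispersions(xf, dsg$design, fac,
                                     prior_df = prior_df))
  lrt <- stage("LRT", lrt_test(xf, dsg, fac, disp$tagwise))
  qlf <- stage("QLF", qlf_test(xf, dsg, fac, disp$trended))
  calls <- stage("consensus", call_dpe(lrt, qlf, fdr_threshold))
  stopifnot(all(calls$exons %in%
                  lrt$exon_id[lrt$fdr <= fdr_threshold]),
            all(calls$exons %in%
                  qlf$exon_id[qlf$fdr <= fdr_threshold]))
  res <- structure(list(calls = calls, lrt = lrt, qlf = qlf,
                        filtered = xf, factors = fac,
                        dispersions = disp, design = dsg),
                   class = "dpe_comparison")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tab <- merge(lrt, qlf, by = "exon_id",
                 suffixes = c("_lrt", "_qlf"))
    tab <- tab[match(lrt$exon_id, tab$exon_id), ]
    out <- data.frame(exon_id = tab$exon_id,
                      logFC = tab$logFC_lrt,
                      avgLogCPM = tab$avg_log_cpm_lrt,
                      stat_lrt = tab$statistic_lrt,
                      p_lrt = tab$p_value_lrt,
                      fdr_lrt = tab$fdr_lrt,
                      stat_qlf = tab$statistic_qlf,
                      p_qlf = tab$p_value_qlf,
                      fdr_qlf = tab$fdr_qlf,
                      is_dpe = tab$exon_id %in% calls$exons,
                      direction = ifelse(
                        tab$exon_id %in% calls$exons,
                        calls$direction[tab$exon_id], ""))
    note <- paste0("comparison=", comparison, " exons=", nrow(out),
                   " samples=", ncol(xf$counts))
    write_tsv_meta(out, file.path(out_dir,
                                  paste0("dpe_", comparison,
                                         ".tsv")), note)
    write_tsv_meta(ma_plot_data(lrt, calls),
                   file.path(out_dir,
                             paste0("ma_", comparison, ".tsv")),
                   note)
  }
  res
}

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647)
}

#' Run the full study design
#'
#' Runs the three comparisons, intersects their consensus callsets
#' into the exonic signature, explores the signature by Ward
#' clustering, PCA (with U samples projected, never fitted) and
#' leading-logFC MDS, trains and evaluates the random-forest
#' classifier on the signature with U samples classified by mean
#' probability, and optionally runs gene-set over-representation
#' against a GMT collection (universe: all genes of the filtered
#' catalog). A comparison whose groups are missing is skipped with a
#' warning and the signature intersects the remaining callsets.
#'
#' @param x raw [dpe_counts].
#' @param catalog an [exon_catalog].
#' @param samples sample sheet.
#' @param out_dir output directory (created if needed).
#' @param seed root seed; classifier substreams are derived from it.
#' @param gmt optional named list of gene sets (see [read_gmt]).
#' @param fdr_threshold consensus threshold (default 0.001).
#' @param min_cpm,min_samples filter thresholds.
#' @param rf an [rf_config]; its seed field is overridden by the
#'   derived substream seed.
#' @param mds_top_k leading exons per sample pair for MDS.
#' @return List of class `dpe_study` with elements `comparisons`,
#'   `signature`, `explore`, `rf`, `unknown_calls`, `enrichment`,
#'   `summary` (also written as JSON).
#' @export
run_full_study <- function(x, catalog, samples, out_dir,
                           seed = 1L, gmt = NULL,
                           fdr_threshold = 0.001, min_cpm = 1,
                           min_samples = 20,
                           rf = rf_config(n_trees = 500L),
                           mds_top_k = 500L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  comparisons <- list()
  for (cmp in COMPARISONS) {
    comparisons[[cmp]] <- tryCatch(
      run_comparison(x, samples, cmp, catalog, min_cpm, min_samples,
                     fdr_threshold = fdr_threshold,
                     out_dir = out_dir),
      error = function(e) {
        warning("comparison ", cmp, " skipped: ",
                conditionMessage(e))
        NULL
      })
  }
  done <- Filter(Negate(is.null), comparisons)
  if (length(done) < 2L)
    stop("fewer than two comparisons completed; no signature")
  sig <- intersect_signature(lapply(done, `[[`, "calls"))
  writeLines(sig$signature, file.path(out_dir, "signature.txt"))
  write_tsv_meta(sig$venn, file.path(out_dir, "venn_counts.tsv"),
                 paste0("callsets=", length(done)))

  # normalized values for exploration/classification: TMM log2-CPM
  # of the sex-filtered, fully filtered union matrix on all samples
  xa <- remove_sex_exons(x, catalog)
  xf <- filter_low_presence(xa, min_cpm,
                            min(min_samples, ncol(xa$counts)))
  fac <- tmm_factors(xf)
  lc <- log_cpm(xf, fac)
  sig_ids <- intersect(sig$signature, rownames(lc))

  explore <- NULL
  if (length(sig_ids) >= 2L) {
    sub <- lc[sig_ids, , drop = FALSE]
    non_u <- samples$sample_id[samples$group != "U"]
    non_u <- intersect(non_u, colnames(sub))
    u_ids <- intersect(samples$sample_id[samples$group == "U"],
                       colnames(sub))
    tree <- ward_cluster(sub)
    pca <- dpe_pca(sub[, non_u, drop = FALSE],
                   n_components = min(2L, length(non_u) - 1L))
    scores <- pca$scores
    if (length(u_ids))
      scores <- rbind(scores,
                      project_pca(pca, sub[, u_ids, drop = FALSE]))
    mds <- mds_leading_logfc(lc, top_k = min(mds_top_k, nrow(lc)))
    explore <- list(tree = tree, pca = pca, scores = scores,
                    mds = mds)
    merge_tab <- data.frame(merge1 = tree$merge[, 1],
                            merge2 = tree$merge[, 2],
                            height = tree$height)
    note <- paste0("exons=", length(sig_ids), " samples=",
                   ncol(sub))
    write_tsv_meta(merge_tab, file.path(out_dir, "linkage.tsv"),
                   note)
    write_tsv_meta(data.frame(sample_id = rownames(scores),
                              scores),
                   file.path(out_dir, "pca_scores.tsv"), note)
    write_tsv_meta(data.frame(sample_id = rownames(mds$coords),
                              mds$coords),
                   file.path(out_dir, "mds.tsv"),
                   paste0("exons=", nrow(lc), " samples=",
                          ncol(lc)))
  }

  rf_report <- NULL; unknown_calls <- NULL
  if (length(sig_ids) >= 2L) {
    fm <- build_feature_matrix(lc, sig_ids, samples)
    if (nlevels(droplevels(fm$labels)) >= 2L) {
      rf$seed <- derive_seed(seed, 101L)
      rf_report <- train_eval_split(fm$features, fm$labels, rf)
      if (nrow(fm$unknown) > 0L)
        unknown_calls <- classify_unknowns(rf_report, fm$unknown)
      rf_json <- list(
        oob_error = rf_report$oob_error,
        test_accuracy = rf_report$test_accuracy,
        oob_sd = rf_report$oob_sd,
        accuracy_sd = rf_report$accuracy_sd,
        per_class_sensitivity =
          as.list(rf_report$per_class_sensitivity),
        n_trees = rf$n_trees,
        mtry = if (identical(rf$mtry, "all")) "all" else rf$mtry,
        n_repeats = rf$n_repeats,
        unknown = unknown_calls)
      jsonlite::write_json(rf_json,
                           file.path(out_dir, "rf_report.json"),
                           auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
  }

  enrichment <- NULL
  if (!is.null(gmt) && length(sig_ids)) {
    genes <- map_exons_to_genes(sig_ids, catalog)
    universe <- unique(catalog$gene_id[catalog$exon_id %in%
                                         rownames(xf$counts)])
    enrichment <- ora_test(intersect(genes, universe), gmt,
                           universe)
    write_tsv_meta(enrichment, file.path(out_dir, "enrich.tsv"),
                   paste0("genes=", length(genes), " universe=",
                          length(universe)))
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("dpescan")),
    seed = seed,
    fdr_threshold = fdr_threshold,
    min_cpm = min_cpm,
    min_samples = min_samples,
    comparisons = lapply(done, function(cm)
      list(comparison = cm$calls$comparison,
           n_tested = length(cm$calls$universe),
           n_dpe = length(cm$calls$exons),
           n_up = cm$calls$n_up, n_down = cm$calls$n_down)),
    signature_size = length(sig$signature),
    signature_genes = if (length(sig_ids))
      length(map_exons_to_genes(sig_ids, catalog)) else 0L,
    rf = if (!is.null(rf_report))
      list(oob_error = rf_report$oob_error,
           test_accuracy = rf_report$test_accuracy) else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(comparisons = done, signature = sig,
                 explore = explore, rf = rf_report,
                 unknown_calls = unknown_calls,
                 enrichment = enrichment, summary = summary),
            class = "dpe_study")
}
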