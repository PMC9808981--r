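# Synthetic cfDNA cohort generator with known ground truth.
#
# The stated world mirrors the study cohort: 17 metastatic (M), 68
# non-metastatic (N), 11 unclassifiable (U) patients and 63 healthy
# controls (H); exon baseline abundances are truncated-normal on the
# log2-CPM scale; NB dispersion follows a mean-dispersion trend
# a/mu + b; library sizes are log-normal around 3e7 fragments; a
# fraction of exons sits on X/Y with sex-dependent presence; U
# samples draw each exon's mean from M or N with equal probability,
# so they land between the two groups in ordination.

#' Simulation configuration
#'
#' @param n_exons number of exons (default 5000, a desk-scale stand-in
#'   for the exome).
#' @param n_m,n_n,n_h,n_u group sizes (defaults 17, 68, 63, 11 - the
#'   study cohort).
#' @param baseline_mean,baseline_sd log2-CPM baseline distribution,
#'   normal truncated at 0 (defaults 4 and 2).
#' @param disp_a,disp_b dispersion trend `phi = a / mean_count + b`
#'   (defaults 2 and 0.1).
#' @param fraction_dpe fraction of autosomal exons carrying a group
#'   effect, per comparison (default 0.1).
#' @param logfc_magnitude absolute log2 fold-change of planted
#'   effects (default 2).
#' @param lib_meanlog,lib_sdlog log-normal library-size parameters
#'   (defaults `log(3e7)` and 0.3).
#' @param sex_exon_fraction fraction of exons placed on X/Y
#'   (default 0.05).
#' @param seed integer RNG seed; fixed seed gives identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_exons = 5000L, n_m = 17L, n_n = 68L,
                       n_h = 63L, n_u = 11L, baseline_mean = 4,
                       baseline_sd = 2, disp_a = 2, disp_b = 0.1,
                       fraction_dpe = 0.1, logfc_magnitude = 2,
                       lib_meanlog = log(3e7), lib_sdlog = 0.3,
                       sex_exon_fraction = 0.05, seed = 1L) {
  if (n_exons < 1) stop("n_exons must be >= 1")
  if (any(c(n_m, n_n, n_h, n_u) < 0)) stop("group sizes must be >= 0")
  if (fraction_dpe < 0 || fraction_dpe > 1)
    stop("fraction_dpe must lie in [0, 1]")
  if (sex_exon_fraction < 0 || sex_exon_fraction > 1)
    stop("sex_exon_fraction must lie in [0, 1]")
  if (disp_b < 0 || disp_a < 0) stop("dispersion trend must be >= 0")
  structure(list(n_exons = as.integer(n_exons), n_m = as.integer(n_m),
                 n_n = as.integer(n_n), n_h = as.integer(n_h),
                 n_u = as.integer(n_u), baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, disp_a = disp_a,
                 disp_b = disp_b, fraction_dpe = fraction_dpe,
                 logfc_magnitude = logfc_magnitude,
                 lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog,
                 sex_exon_fraction = sex_exon_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# synthetic but valid catalog: ~3 exons per gene, sex exons on X/Y
synthetic_catalog <- function(n_exons, sex_idx) {
  chrom <- paste0("chr", rep_len(1:22, n_exons))
  if (length(sex_idx)) {
    nx <- ceiling(length(sex_idx) * 2 / 3)
    chrom[sex_idx[seq_len(nx)]] <- "chrX"
    if (length(sex_idx) > nx)
      chrom[sex_idx[(nx + 1L):length(sex_idx)]] <- "chrY"
  }
  pos <- ave(seq_len(n_exons), chrom, FUN = seq_along)
  exon_catalog(
    exon_id = sprintf("exon_%05d", seq_len(n_exons)),
    gene_id = sprintf("gene_%05d", ceiling(seq_len(n_exons) / 3)),
    chrom = chrom,
    start = pos * 1000L,
    end = pos * 1000L + 200L,
    strand = rep_len(c("+", "-"), n_exons))
}

# vectorized NB draw; phi ~ 0 entries fall back to Poisson
rnb <- function(n, mu, phi) {
  mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  out <- numeric(n)
  pois <- phi < 1e-12
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) out[!pois] <- stats::rnbinom(sum(!pois),
                                               size = 1 / phi[!pois],
                                               mu = mu[!pois])
  out
}

#' Simulate a full cohort with ground truth
#'
#' Draws counts `NB(mean = cpm/1e6 * lib, dispersion = phi_g)` with
#' group-specific mean shifts of `+/- logfc_magnitude` on designated
#' autosomal exons: one designation per comparison (M vs N shifts M;
#' C vs H shifts both M and N; M vs H shifts M). U-group samples draw
#' each exon's mean from the M or N mean with probability one half.
#' Sex exons are attenuated in one sex (X halved in males, Y nearly
#' absent in females). Truth (per-comparison differential status and
#' realized log2 fold-changes of group means) is computed from the
#' constructed means, so effects planted for one comparison that also
#' separate another are labelled truthfully.
#'
#' @param config a [sim_config].
#' @return A list: `counts` ([dpe_counts]), `catalog`
#'   ([exon_catalog]), `samples` (sheet with sample_id, group, sex),
#'   `truth` (list with per-exon `exons` data frame and the config).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_exons
  groups <- rep(c("M", "N", "H", "U"),
                c(config$n_m, config$n_n, config$n_h, config$n_u))
  n <- length(groups)
  if (n < 2L) stop("need at least two samples")
  sample_id <- sprintf("%s%03d", groups,
                       ave(seq_len(n), groups, FUN = seq_along))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  lib <- stats::rlnorm(n, config$lib_meanlog, config$lib_sdlog)

  n_sex <- round(config$sex_exon_fraction * G)
  sex_idx <- if (n_sex > 0) sample.int(G, n_sex) else integer(0)
  catalog <- synthetic_catalog(G, sex_idx)
  autosomal <- setdiff(seq_len(G), sex_idx)

  base <- truncnorm::rtruncnorm(G, a = 0, mean = config$baseline_mean,
                                sd = config$baseline_sd)
  mean_count <- 2^base / 1e6 * exp(config$lib_meanlog)
  phi <- config$disp_a / mean_count + config$disp_b

  n_dpe <- round(config$fraction_dpe * length(autosomal))
  plant <- function() {
    idx <- if (n_dpe > 0) sample(autosomal, n_dpe) else integer(0)
    delta <- numeric(G)
    delta[idx] <- sample(c(-1, 1), length(idx), replace = TRUE) *
      config$logfc_magnitude
    delta
  }
  d_mn <- plant(); d_ch <- plant(); d_mh <- plant()
  l_h <- base
  l_n <- base + d_ch
  l_m <- base + d_ch + d_mn + d_mh

  # per-sample mean CPM; U draws each exon from M or N equally
  mean_cpm <- matrix(0, G, n)
  for (s in seq_len(n)) {
    mean_cpm[, s] <- switch(groups[s],
                            M = 2^l_m, N = 2^l_n, H = 2^l_h,
                            U = ifelse(stats::runif(G) < 0.5,
                                       2^l_m, 2^l_n))
  }
  if (length(sex_idx)) {
    on_x <- which(catalog$chrom == "chrX")
    on_y <- which(catalog$chrom == "chrY")
    male <- sex == "male"
    if (length(on_x))
      mean_cpm[on_x, male] <- mean_cpm[on_x, male] * 0.5
    if (length(on_y))
      mean_cpm[on_y, !male] <- mean_cpm[on_y, !male] * 0.01
  }

  counts <- matrix(0, G, n,
                   dimnames = list(catalog$exon_id, sample_id))
  for (s in seq_len(n))
    counts[, s] <- rnb(G, mean_cpm[, s] / 1e6 * lib[s], phi)

  lfc <- function(a, b) log2(a) - log2(b)
  w_m <- config$n_m; w_n <- config$n_n
  l_c <- if (w_m + w_n > 0)
    log2((w_m * 2^l_m + w_n * 2^l_n) / (w_m + w_n)) else rep(NA_real_, G)
  truth_exons <- data.frame(
    exon_id = catalog$exon_id,
    baseline_log2cpm = base,
    dispersion = phi,
    logfc_M_vs_N = lfc(2^l_m, 2^l_n),
    logfc_C_vs_H = l_c - l_h,
    logfc_M_vs_H = lfc(2^l_m, 2^l_h),
    stringsAsFactors = FALSE)
  for (cmp in COMPARISONS)
    truth_exons[[paste0("is_dpe_", cmp)]] <-
      abs(truth_exons[[paste0("logfc_", cmp)]]) > 1e-9
  samples <- data.frame(sample_id = sample_id, group = groups,
                        sex = sex, lib_size = lib,
                        stringsAsFactors = FALSE)
  # lib_sizes are the drawn assay depths: the simulated exons are a
  # slice of the notional exome, so column sums underestimate depth
  list(counts = dpe_counts(counts, lib_sizes = lib),
       catalog = catalog,
       samples = validate_samples(samples[, c("sample_id", "group",
                                              "sex")]),
       truth = list(exons = truth_exons, samples = samples,
                    config = config))
}

#' Simulate a structureless null cohort
#'
#' Single-population NB counts with a constant dispersion: any group
#' labels assigned afterwards carry no signal. Used for type-I-error
#' and p-value-uniformity calibration.
#'
#' @param n_exons,n_samples matrix dimensions.
#' @param dispersion constant NB dispersion (`0` gives Poisson).
#' @param seed RNG seed.
#' @param baseline_mean,baseline_sd,lib_meanlog,lib_sdlog as in
#'   [sim_config].
#' @return A [dpe_counts] object.
#' @export
simulate_null <- function(n_exons, n_samples, dispersion = 0.2,
                          seed = 1L, baseline_mean = 4,
                          baseline_sd = 2, lib_meanlog = log(3e7),
                          lib_sdlog = 0.3) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  set.seed(seed)
  base <- truncnorm::rtruncnorm(n_exons, a = 0, mean = baseline_mean,
                                sd = baseline_sd)
  lib <- stats::rlnorm(n_samples, lib_meanlog, lib_sdlog)
  counts <- matrix(0L, n_exons, n_samples,
                   dimnames = list(sprintf("exon_%05d",
                                           seq_len(n_exons)),
                                   sprintf("S%03d",
                                           seq_len(n_samples))))
  for (s in seq_len(n_samples))
    counts[, s] <- rnb(n_exons, 2^base / 1e6 * lib[s], dispersion)
  dpe_counts(counts, lib_sizes = lib)
}

#' Evaluate calls against simulation truth
#'
#' Sensitivity is the fraction of truly differential exons that were
#' called; empirical FDR is the fraction of calls that are not truly
#' differential (`0` when nothing is called).
#'
#' @param calls a [call_dpe] result (or a character vector of called
#'   exon ids).
#' @param truth the `truth` element of [simulate_cohort] output.
#' @param comparison which comparison's truth column to use; defaults
#'   to the callset's own comparison.
#' @return Named list: `sensitivity`, `fdr`, `n_called`, `n_true`.
#' @export
truth_eval <- function(calls, truth, comparison = NULL) {
  called <- if (inherits(calls, "dpe_calls")) calls$exons else
    as.character(calls)
  if (is.null(comparison)) {
    if (!inherits(calls, "dpe_calls"))
      stop("comparison must be given for a plain exon id vector")
    comparison <- calls$comparison
  }
  col <- paste0("is_dpe_", comparison)
  if (!col %in% names(truth$exons))
    stop("truth has no column ", col)
  true_set <- truth$exons$exon_id[truth$exons[[col]]]
  tp <- length(intersect(called, true_set))
  list(sensitivity = if (length(true_set)) tp / length(true_set)
       else NA_real_,
       fdr = if (length(called)) (length(called) - tp) / length(called)
       else 0,
       n_called = length(called), n_true = length(true_set))
}
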