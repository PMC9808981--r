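# Random-forest classification of samples on the signature exons.
# The forest itself (bagged Gini trees with per-split feature
# subsampling) is compiled code; with mtry = "all" every split sees
# every signature exon, degrading the forest toward bagged trees -
# the study's configuration.

#' Random-forest configuration
#'
#' @param n_trees trees per forest (default 5000).
#' @param mtry features tried per split: an integer or `"all"`
#'   (default `"all"`, the study's choice of every signature exon).
#' @param train_fraction training share of the stratified split
#'   (default 0.70).
#' @param n_repeats independent split/train/evaluate repeats
#'   (default 10).
#' @param seed root RNG seed; repeat r uses `seed + r - 1`.
#' @return A validated list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 5000L, mtry = "all",
                      train_fraction = 0.70, n_repeats = 10L,
                      seed = 1L) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  if (!identical(mtry, "all") && (!is.numeric(mtry) || mtry < 1))
    stop("mtry must be a positive integer or \"all\"")
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 train_fraction = train_fraction,
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Build the classifier feature matrix from signature exons
#'
#' Restricts the normalized log2-CPM matrix to the signature exons and
#' transposes to samples-by-features. Samples with any missing value
#' are dropped and reported (mirroring the study's removal of samples
#' with NA on the signature). Unclassifiable (U) samples are returned
#' as a separate block and never enter training labels.
#'
#' @param logcpm numeric matrix, exons by samples.
#' @param signature character vector of signature exon ids.
#' @param samples sample sheet with `sample_id` and `group`.
#' @return List: `features` (labelled samples x features), `labels`
#'   (factor over M/N/H), `unknown` (U-sample features),
#'   `dropped_samples`, `missing_exons`.
#' @export
build_feature_matrix <- function(logcpm, signature, samples) {
  if (length(signature) == 0L) stop("signature is empty")
  present <- intersect(signature, rownames(logcpm))
  missing_exons <- setdiff(signature, present)
  if (length(present) == 0L)
    stop("no signature exons present in the matrix")
  idx <- match(samples$sample_id, colnames(logcpm))
  if (anyNA(idx))
    stop("samples missing from matrix: ",
         paste(samples$sample_id[is.na(idx)], collapse = ", "))
  feat <- t(logcpm[present, idx, drop = FALSE])
  rownames(feat) <- samples$sample_id
  complete <- rowSums(is.na(feat)) == 0
  dropped <- rownames(feat)[!complete]
  feat <- feat[complete, , drop = FALSE]
  grp <- as.character(samples$group)[complete]
  is_u <- grp == "U"
  if (sum(!is_u) == 0L) stop("all labelled samples were dropped")
  list(features = feat[!is_u, , drop = FALSE],
       labels = factor(grp[!is_u],
                       levels = intersect(c("M", "N", "H"),
                                          unique(grp[!is_u]))),
       unknown = feat[is_u, , drop = FALSE],
       dropped_samples = dropped,
       missing_exons = missing_exons)
}

resolve_mtry <- function(mtry, p) {
  if (identical(mtry, "all")) p else min(as.integer(mtry), p)
}

rf_train <- function(features, labels, n_trees, mtry) {
  y <- as.integer(labels) - 1L
  model <- .rf_fit_cpp(as.matrix(features), y, nlevels(labels),
                       as.integer(n_trees),
                       resolve_mtry(mtry, ncol(features)), 2L)
  model$classes <- levels(labels)
  model$feature_names <- colnames(features)
  model
}

rf_prob <- function(model, features) {
  votes <- .rf_votes_cpp(model, as.matrix(features))
  prob <- votes / rowSums(votes)
  dimnames(prob) <- list(rownames(features), model$classes)
  prob
}

oob_error_of <- function(model, labels) {
  votes <- model$oob_votes
  seen <- rowSums(votes) > 0
  pred <- max.col(votes[seen, , drop = FALSE], ties.method = "first")
  mean(pred != as.integer(labels)[seen])
}

stratified_split <- function(labels, fraction) {
  train <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n_tr <- max(1L, round(fraction * length(idx)))
    n_tr <- min(n_tr, length(idx))
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

#' Stratified 70/30 train/test evaluation of the forest
#'
#' Repeats `n_repeats` times with seeds `seed, seed+1, ...`: draw a
#' stratified split, train a forest of `n_trees` on the training
#' block, record its out-of-bag (OOB) error, and score accuracy and
#' per-class sensitivity on the held-out block. Reports means and
#' standard deviations across repeats and keeps the trained forests
#' for [classify_unknowns].
#'
#' @param features samples-by-features matrix from
#'   [build_feature_matrix].
#' @param labels class factor aligned with `features` rows.
#' @param config an [rf_config].
#' @return A list of class `rf_report`: `oob_error`, `test_accuracy`
#'   (means), `oob_sd`, `accuracy_sd`, `per_class_sensitivity`
#'   (mean, named by class), `repeats` (per-repeat data frame),
#'   `models`, `config`.
#' @export
train_eval_split <- function(features, labels, config = rf_config()) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  if (nrow(features) != length(labels))
    stop("features and labels disagree in length")
  reps <- vector("list", config$n_repeats)
  models <- vector("list", config$n_repeats)
  sens_mat <- matrix(NA_real_, config$n_repeats, nlevels(labels),
                     dimnames = list(NULL, levels(labels)))
  for (r in seq_len(config$n_repeats)) {
    set.seed(config$seed + r - 1L)
    train <- NULL
    for (attempt in seq_len(100L)) {
      cand <- stratified_split(labels, config$train_fraction)
      if (nlevels(droplevels(labels[cand])) == nlevels(labels)) {
        train <- cand; break
      }
    }
    if (is.null(train))
      stop("could not draw a split containing every class")
    test <- setdiff(seq_along(labels), train)
    model <- rf_train(features[train, , drop = FALSE], labels[train],
                      config$n_trees, config$mtry)
    oob <- oob_error_of(model, labels[train])
    prob <- rf_prob(model, features[test, , drop = FALSE])
    pred <- factor(model$classes[max.col(prob, ties.method = "first")],
                   levels = levels(labels))
    acc <- mean(pred == labels[test])
    for (cl in levels(labels)) {
      in_cl <- labels[test] == cl
      sens_mat[r, cl] <- if (any(in_cl))
        mean(pred[in_cl] == cl) else NA_real_
    }
    reps[[r]] <- data.frame(repeat_ = r, oob_error = oob,
                            test_accuracy = acc,
                            n_train = length(train),
                            n_test = length(test))
    models[[r]] <- model
  }
  reps <- do.call(rbind, reps)
  structure(list(oob_error = mean(reps$oob_error),
                 test_accuracy = mean(reps$test_accuracy),
                 oob_sd = stats::sd(reps$oob_error),
                 accuracy_sd = stats::sd(reps$test_accuracy),
                 per_class_sensitivity = colMeans(sens_mat,
                                                  na.rm = TRUE),
                 repeats = reps, models = models, config = config,
                 classes = levels(labels)),
            class = "rf_report")
}

#' @export
print.rf_report <- function(x, ...) {
  cat("random forest report (", x$config$n_repeats, " repeats, ",
      x$config$n_trees, " trees, mtry = ",
      if (identical(x$config$mtry, "all")) "all" else x$config$mtry,
      ")\n", sep = "")
  cat(sprintf("  OOB error: %.1f%% (sd %.1f)  test accuracy: %.1f%% (sd %.1f)\n",
              100 * x$oob_error, 100 * x$oob_sd,
              100 * x$test_accuracy, 100 * x$accuracy_sd))
  sens <- paste(sprintf("%s %.2f", names(x$per_class_sensitivity),
                        x$per_class_sensitivity), collapse = ", ")
  cat("  per-class sensitivity:", sens, "\n")
  invisible(x)
}

#' Classify unclassifiable samples by mean forest probability
#'
#' Averages class probabilities over the report's independently
#' trained forests and assigns each unknown sample the class with
#' the highest mean probability. A sample whose top two mean
#' probabilities differ by less than `tie_margin` keeps a near-tie
#' flag: it remains effectively unassigned between the two groups it
#' shares features with.
#'
#' @param report an [rf_report] holding trained forests.
#' @param unknown_features features of unknown samples, columns
#'   aligned to the training feature order.
#' @param tie_margin near-tie threshold on the top-two probability
#'   gap (default 0.05).
#' @return `data.frame`: `sample_id`, one probability column per
#'   class, `assigned`, `near_tie`.
#' @export
classify_unknowns <- function(report, unknown_features,
                              tie_margin = 0.05) {
  feats <- report$models[[1L]]$feature_names
  if (!identical(colnames(unknown_features), feats)) {
    missing <- setdiff(feats, colnames(unknown_features))
    if (length(missing))
      stop("unknown features missing columns: ",
           paste(utils::head(missing, 5), collapse = ", "))
    unknown_features <- unknown_features[, feats, drop = FALSE]
  }
  probs <- lapply(report$models, rf_prob,
                  features = unknown_features)
  mean_prob <- Reduce(`+`, probs) / length(probs)
  top2 <- t(apply(mean_prob, 1L, function(p)
    sort(p, decreasing = TRUE)[1:2]))
  assigned <- report$classes[max.col(mean_prob,
                                     ties.method = "first")]
  out <- data.frame(sample_id = rownames(unknown_features),
                    mean_prob,
                    assigned = assigned,
                    near_tie = (top2[, 1] - top2[, 2]) < tie_margin,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
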