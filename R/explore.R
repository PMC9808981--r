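# Unsupervised structure on normalized log2-CPM of selected exons.

#' Ward hierarchical clustering of samples
#'
#' Euclidean distances between sample columns, merged by Ward's
#' variance-minimizing criterion. The default `"ward.D2"` variant
#' operates on unsquared distances so that the merge cost equals the
#' increase in total within-cluster sum of squares.
#'
#' @param x numeric matrix, selected exons by samples (normalized
#'   log2-CPM).
#' @param variant `"ward.D2"` (default) or `"ward.D"`.
#' @return An [stats::hclust] tree with sample ids as labels.
#' @export
ward_cluster <- function(x, variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("clustering needs at least 2 samples")
  stats::hclust(stats::dist(t(x), method = "euclidean"),
                method = variant)
}

#' Principal component analysis of samples
#'
#' Samples are the observations; each exon is centered to mean zero
#' and left unscaled before singular-value decomposition. Component
#' signs follow the convention that the largest-magnitude loading of
#' each component is positive.
#'
#' @param x numeric matrix, exons by samples.
#' @param n_components number of components to keep (default
#'   `min(dim) `, capped at the matrix rank bound).
#' @return A list of class `dpe_pca`: `scores` (samples x
#'   components), `loadings` (exons x components, orthonormal),
#'   `var_explained` (fractions, non-increasing), `center` (per-exon
#'   means).
#' @export
dpe_pca <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (n < 2L) stop("PCA needs at least 2 samples")
  kmax <- min(nrow(x), n)
  if (is.null(n_components)) n_components <- kmax
  if (n_components > kmax)
    stop("n_components exceeds min(dim) = ", kmax)
  center <- rowMeans(x)
  xc <- x - center
  sv <- svd(t(xc), nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(k) {
    v <- sv$v[, k]
    sign(v[which.max(abs(v))])
  }, 0)
  flip[flip == 0] <- 1
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)],
                          n_components) %*% diag(flip, n_components)
  loadings <- sv$v %*% diag(flip, n_components)
  rownames(scores) <- colnames(x)
  rownames(loadings) <- rownames(x)
  colnames(scores) <- colnames(loadings) <-
    paste0("PC", seq_len(n_components))
  tot <- sum(xc^2)
  structure(list(scores = scores, loadings = loadings,
                 var_explained = sv$d[seq_len(n_components)]^2 /
                   tot,
                 center = center),
            class = "dpe_pca")
}

#' Project new samples into a fitted PCA
#'
#' Used for unclassifiable (U) samples: they are projected with the
#' fitted loadings rather than refit, so the component axes stay
#' anchored to the compared groups.
#'
#' @param pca a [dpe_pca] fit.
#' @param x numeric matrix, same exons (rows) as the fit, new samples
#'   as columns.
#' @return Score matrix, new samples by components.
#' @export
project_pca <- function(pca, x) {
  x <- as.matrix(x)
  if (nrow(x) != length(pca$center))
    stop("projection needs the same exons as the fitted PCA")
  t(x - pca$center) %*% pca$loadings
}

#' Leading log-fold-change MDS
#'
#' The distance between two samples is the root-mean-square of the
#' `top_k` largest absolute per-exon log2-CPM differences between
#' them (the "leading" fold changes); classical metric MDS of that
#' matrix gives 2-D coordinates.
#'
#' @param x numeric matrix, exons by samples (log2-CPM).
#' @param top_k number of leading exons per pair (default 500;
#'   clipped to the exon count with a warning).
#' @return A list: `dist` (sample distance matrix) and `coords`
#'   (samples x 2).
#' @export
mds_leading_logfc <- function(x, top_k = 500L) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (n < 3L) stop("MDS needs at least 3 samples")
  if (top_k > nrow(x)) {
    warning("top_k clipped from ", top_k, " to ", nrow(x))
    top_k <- nrow(x)
  }
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sq <- (x[, i] - x[, j])^2
      lead <- sort(sq, decreasing = TRUE)[seq_len(top_k)]
      d[i, j] <- d[j, i] <- sqrt(mean(lead))
    }
  }
  coords <- stats::cmdscale(stats::as.dist(d), k = 2)
  colnames(coords) <- c("dim1", "dim2")
  list(dist = d, coords = coords)
}
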