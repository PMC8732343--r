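## Unsupervised structure views: agglomerative clustering of profiles (the
## heatmap backbone) and a principal-component batch check. Numeric outputs
## (orders, heights, scores, separation statistics) are the interface;
## rendering is left to the caller's heatmap tool of choice.

#' Hierarchical clustering of a profile matrix
#'
#' Rows are z-scored (optional), distances are Euclidean and linkage is
#' Ward (\code{"ward.D2"}) by default; both are configurable. Constant rows
#' cannot be z-scored and are excluded with a warning. Clustering is
#' deterministic given the input order; \code{hclust} breaks ties by the
#' original observation order.
#'
#' @param mat numeric matrix (observations x variables), complete, log2
#'   scale.
#' @param row_standardize z-score rows before clustering (default TRUE).
#' @param dist_method distance passed to \code{stats::dist}.
#' @param linkage linkage passed to \code{stats::hclust}.
#' @return a list of class \code{ClusterResult}: \code{row_hclust},
#'   \code{col_hclust}, \code{row_order}, \code{col_order}, \code{matrix}
#'   (the standardized matrix rendered).
#' @export
clusterHeatmap <- function(mat, row_standardize = TRUE,
                           dist_method = "euclidean",
                           linkage = "ward.D2") {
  mat <- as.matrix(mat)
  if (anyNA(mat)) {
    stop("clustering requires a complete matrix", call. = FALSE)
  }
  if (row_standardize) {
    sds <- apply(mat, 1, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("excluding %d constant row(s) under z-scoring",
                      sum(sds == 0)))
      mat <- mat[sds > 0, , drop = FALSE]
      sds <- sds[sds > 0]
    }
    mat <- (mat - rowMeans(mat)) / sds
  }
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  }
  row_hc <- stats::hclust(stats::dist(mat, method = dist_method),
                          method = linkage)
  col_hc <- stats::hclust(stats::dist(t(mat), method = dist_method),
                          method = linkage)
  structure(list(row_hclust = row_hc, col_hclust = col_hc,
                 row_order = row_hc$order, col_order = col_hc$order,
                 matrix = mat),
            class = "ClusterResult")
}

#' Cut the row dendrogram into k clusters
#'
#' @param x a \code{ClusterResult}.
#' @param k number of clusters.
#' @return named integer cluster labels.
#' @export
cutClusters <- function(x, k) {
  stopifnot(inherits(x, "ClusterResult"))
  stats::cutree(x$row_hclust, k = k)
}

#' Principal-component batch/grouping check
#'
#' Centers the matrix, computes the leading principal components, and
#' summarizes how strongly a grouping variable (batch, compartment)
#' separates on component 1 as the between-group share of the component's
#' variance. Component signs follow a fixed convention: the
#' largest-magnitude loading of each component is positive, so scores are
#' invariant to observation order.
#'
#' @param mat numeric matrix (observations x variables), log2 scale.
#' @param grouping factor-like, one value per observation.
#' @param n_components components to return (default 2).
#' @return a list of class \code{PcaResult}: \code{scores},
#'   \code{var_explained}, \code{grouping}, \code{separation}
#'   (between-group / total variance of component-1 scores).
#' @export
pcaCheck <- function(mat, grouping, n_components = 2L) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) {
    stop("need at least 2 observations", call. = FALSE)
  }
  grouping <- factor(grouping)
  stopifnot(length(grouping) == nrow(mat))
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  s1 <- scores[, 1]
  grand <- mean(s1)
  between <- sum(tapply(s1, grouping, function(v) {
    length(v) * (mean(v) - grand)^2
  }))
  total <- sum((s1 - grand)^2)
  separation <- if (total > 0) between / total else 0
  structure(list(scores = scores, var_explained = var_explained,
                 grouping = grouping, separation = separation),
            class = "PcaResult")
}
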