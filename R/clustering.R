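# Cell clustering on the degree matrix (or the expression matrix):
# PCA to a small number of components, k-means or agglomerative clustering,
# optional t-SNE for visualization, and a driver that evaluates a grid of
# inference parameters by clustering performance.

matrix_input <- function(x) {
  if (inherits(x, "degree_matrix") || inherits(x, "expression_matrix")) {
    return(x$values)
  }
  as.matrix(x)
}

#' Principal-component embedding of cells
#'
#' Reduces a genes-by-cells matrix to `n_components` principal components,
#' treating cells as observations and genes as features. Features are
#' centred; set `standardize = TRUE` to also scale them to unit variance.
#' The sign of each component is fixed so that its largest-magnitude gene
#' loading is positive, making the embedding deterministic.
#'
#' @param x A `degree_matrix`, [expression_matrix()] or plain matrix
#'   (genes x cells).
#' @param n_components Number of components; default 20. Must not exceed
#'   `min(m, n)`.
#' @param seed Unused by the deterministic computation; accepted so all
#'   pipeline stages share one calling convention.
#' @param standardize Scale features to unit variance first; default
#'   `FALSE`.
#' @return An `n x n_components` matrix of cell coordinates (rownames =
#'   cell ids when available).
#' @export
reduce_dimensions <- function(x, n_components = 20L, seed = NULL,
                              standardize = FALSE) {
  v <- matrix_input(x)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(dim(v))) {
    stop("'n_components' must be between 1 and min(genes, cells) = ",
         min(dim(v)))
  }
  obs <- t(v)   # cells x genes
  if (standardize) {
    sds <- apply(obs, 2L, stats::sd)
    obs <- obs[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(obs, center = TRUE, scale. = standardize,
                      rank. = n_components)
  emb <- pc$x
  # fix component signs: largest |loading| positive
  for (j in seq_len(ncol(emb))) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) emb[, j] <- -emb[, j]
  }
  if (ncol(emb) < n_components) {  # centred data has rank <= n-1
    emb <- cbind(emb, matrix(0, nrow(emb), n_components - ncol(emb)))
  }
  colnames(emb) <- paste0("PC", seq_len(ncol(emb)))
  emb
}

#' Two-dimensional t-SNE embedding for visualization
#'
#' Non-linear reduction of a (typically PCA) embedding to two dimensions.
#' Intended for plotting only; no downstream statistic in this package is
#' computed from these coordinates.
#'
#' @param embedding `n x d` matrix of cell coordinates.
#' @param seed Integer seed; the embedding is reproducible given the seed.
#' @param perplexity t-SNE perplexity; requires `n > 3 * perplexity`.
#' @return `n x 2` coordinate matrix.
#' @export
embed_2d <- function(embedding, seed, perplexity = 30) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n <= 3 * perplexity) {
    stop("perplexity too large: need n > 3 * perplexity (n = ", n, ")")
  }
  set.seed(seed)
  out <- Rtsne::Rtsne(embedding, dims = 2L, perplexity = perplexity,
                      pca = FALSE, check_duplicates = FALSE, verbose = FALSE)
  coords <- out$Y
  rownames(coords) <- rownames(embedding)
  colnames(coords) <- c("tsne1", "tsne2")
  coords
}

#' Cluster cells in an embedding
#'
#' @param embedding `n x d` matrix of cell coordinates (e.g. from
#'   [reduce_dimensions()]).
#' @param k Number of clusters, at most `n`.
#' @param method `"kmeans"` (seeded initialization, 10 restarts) or
#'   `"hierarchical"` (agglomerative on Euclidean distances, cut at `k`).
#' @param seed Integer seed for the k-means initialization; ignored by the
#'   deterministic hierarchical method.
#' @param linkage Agglomeration rule for the hierarchical method:
#'   `"ward"` (Ward's D2, default), `"complete"` or `"average"`.
#' @return Integer vector of cluster labels (1..k), named by the
#'   embedding's rownames.
#' @export
cluster_cells <- function(embedding, k, method = c("kmeans", "hierarchical"),
                          seed = 0L, linkage = c("ward", "complete", "average")) {
  method <- match.arg(method)
  linkage <- match.arg(linkage)
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("'k' must be between 1 and the number of cells")
  if (k == 1L) {
    lab <- rep.int(1L, n)
  } else if (method == "kmeans") {
    set.seed(seed)
    lab <- stats::kmeans(embedding, centers = k, nstart = 10L,
                         iter.max = 100L)$cluster
  } else {
    hl <- switch(linkage, ward = "ward.D2", complete = "complete",
                 average = "average")
    hc <- stats::hclust(stats::dist(embedding), method = hl)
    lab <- stats::cutree(hc, k = k)
  }
  names(lab) <- rownames(embedding)
  lab
}

#' Evaluate a grid of inference parameters by clustering performance
#'
#' For every dataset and every (box size, z-threshold) combination, infers
#' the per-cell networks, builds the degree matrix, embeds it with PCA and
#' clusters with both k-means and hierarchical clustering (`k` = number of
#' distinct true labels); the pairwise F-measure against the true labels is
#' recorded. The resulting score array feeds [rank_parameters()].
#'
#' @param gems List of log-transformed [expression_matrix()] objects.
#' @param labels_list List of per-cell label vectors, aligned with `gems`.
#' @param box_sizes,z_thresholds Numeric vectors spanning the grid.
#' @param n_components PCA dimensionality; default 20 (capped at
#'   `min(dim) `per dataset).
#' @param seed Integer seed for the k-means initializations.
#' @return A `parameter_grid_result` (see [rank_parameters()]) with the
#'   score array attached as `attr(, "f_scores")`.
#' @export
evaluate_parameter_grid <- function(gems, labels_list,
                                    box_sizes = c(0.05, 0.1, 0.15, 0.2, 0.25),
                                    z_thresholds = c(-2, -1, 0, 1, 2),
                                    n_components = 20L, seed = 0L) {
  if (length(gems) != length(labels_list)) {
    stop("'gems' and 'labels_list' must have the same length")
  }
  grid <- expand.grid(box_size = box_sizes, z_threshold = z_thresholds,
                      KEEP.OUT.ATTRS = FALSE)
  combos <- sprintf("box%g_z%g", grid$box_size, grid$z_threshold)
  nd <- length(gems)
  f <- array(NA_real_,
             dim = c(nd, nrow(grid), 2L),
             dimnames = list(paste0("dataset", seq_len(nd)), combos,
                             c("kmeans", "hierarchical")))
  for (d in seq_len(nd)) {
    gem <- gems[[d]]
    truth <- resolve_labels(labels_list[[d]], gem$cell_ids)
    k <- length(unique(truth))
    for (ci in seq_len(nrow(grid))) {
      scns <- infer_scns(gem, box_size = grid$box_size[ci],
                         z_threshold = grid$z_threshold[ci])
      dm <- degree_matrix(scns, gem)
      emb <- reduce_dimensions(dm, min(n_components, min(dim(dm)) ))
      for (meth in c("kmeans", "hierarchical")) {
        pred <- cluster_cells(emb, k, method = meth, seed = seed)
        f[d, ci, meth] <- score_clustering(pred, truth)$FMI
      }
    }
  }
  res <- rank_parameters(f)
  res$grid <- grid
  attr(res, "f_scores") <- f
  res
}
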