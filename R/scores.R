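# External clustering validation indexes, computed from the contingency
# table of predicted vs true labels. All indexes are invariant to
# relabeling of either partition.

#' Compare a predicted clustering against reference labels
#'
#' Computes eight external validation indexes from the contingency table:
#'
#' * `ARI` - adjusted Rand index (chance-corrected pair counting; at most 1,
#'   near 0 for random labelings).
#' * `FMI` - pairwise F-measure: the harmonic mean of pairwise precision
#'   and recall over co-clustered pairs.
#' * `FMS` - Fowlkes-Mallows score: the geometric mean of the same
#'   precision and recall (distinct from `FMI`).
#' * `AMI` - adjusted mutual information (expected MI under the
#'   permutation model subtracted; arithmetic normalization; truncated at 0).
#' * `NMI` - normalized mutual information, arithmetic normalization
#'   `2 I / (H(truth) + H(pred))`.
#' * `HMG` - homogeneity: each predicted cluster contains members of a
#'   single class (`I / H(truth)`).
#' * `CPT` - completeness: all members of a class fall in one predicted
#'   cluster (`I / H(pred)`).
#' * `VMS` - V-measure: harmonic mean of homogeneity and completeness.
#'
#' Entropies use the natural logarithm. Degenerate identical single-cluster
#' partitions score 1 on all indexes.
#'
#' @param predicted,truth Vectors of equal length with cluster / class
#'   labels (any atomic type).
#' @return A `cluster_evaluation`: named list of the eight scores.
#' @export
#' @examples
#' score_clustering(c(1, 1, 2, 2), c("a", "a", "b", "b"))$ARI
score_clustering <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("'predicted' and 'truth' must have equal length")
  }
  n <- length(truth)
  if (n < 2L) stop("need at least two observations")
  tab <- table(truth, predicted)
  a <- rowSums(tab)   # class sizes (truth)
  b <- colSums(tab)   # cluster sizes (predicted)

  ch2 <- function(x) x * (x - 1) / 2
  nij2 <- sum(ch2(tab))
  A <- sum(ch2(a))
  B <- sum(ch2(b))
  Tt <- ch2(n)

  expected <- A * B / Tt
  max_idx <- (A + B) / 2
  ari <- if (max_idx == expected) 1 else (nij2 - expected) / (max_idx - expected)

  precision <- if (B > 0) nij2 / B else 1
  recall <- if (A > 0) nij2 / A else 1
  fmi <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  fms <- sqrt(precision * recall)

  p <- tab / n
  pa <- a / n
  pb <- b / n
  h_u <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  h_v <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  pij <- as.vector(p)
  pi_pj <- as.vector(outer(pa, pb))
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / pi_pj[nz]))

  hmg <- if (h_u > 0) mi / h_u else 1
  cpt <- if (h_v > 0) mi / h_v else 1
  vms <- if (hmg + cpt > 0) 2 * hmg * cpt / (hmg + cpt) else 0
  nmi <- if (h_u + h_v > 0) 2 * mi / (h_u + h_v) else 1

  emi <- expected_mutual_information(a, b, n)
  denom <- (h_u + h_v) / 2 - emi
  ami <- if (abs(denom) < .Machine$double.eps^0.5) 1 else (mi - emi) / denom
  ami <- min(1, max(0, ami))

  structure(list(ARI = ari, FMI = fmi, AMI = ami, CPT = cpt,
                 FMS = fms, HMG = hmg, NMI = nmi, VMS = vms),
            class = "cluster_evaluation")
}

#' @exportS3Method print cluster_evaluation
print.cluster_evaluation <- function(x, ...) {
  v <- unlist(x)
  cat(paste(sprintf("%s = %.4f", names(v), v), collapse = ", "), "\n")
  invisible(x)
}

# Expected mutual information of two partitions with fixed margins under
# the permutation (generalized hypergeometric) model; natural log.
expected_mutual_information <- function(a, b, n) {
  emi <- 0
  lgn <- lgamma(n + 1)
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      lw <- lgamma(ai + 1) + lgamma(bj + 1) +
        lgamma(n - ai + 1) + lgamma(n - bj + 1) -
        lgn - lgamma(nij + 1) - lgamma(ai - nij + 1) -
        lgamma(bj - nij + 1) - lgamma(n - ai - bj + nij + 1)
      emi <- emi + sum((nij / n) * log(n * nij / (ai * bj)) * exp(lw))
    }
  }
  emi
}

#' Rank box-size / z-threshold combinations across datasets
#'
#' Implements the rank-based parameter selection: within every dataset and
#' clustering method, parameter combinations are ranked 1 = best by
#' descending F-measure (ties receive their average rank). The re-ranking
#' score of a combination under one method is the mean of its ranks across
#' datasets; the final score averages the two methods' re-ranking scores.
#' The recommended combination minimizes the final score; ties are broken
#' by higher mean F-measure, then by combination order.
#'
#' @param f_scores Numeric 3-d array `[dataset, combo, method]` of
#'   F-measure scores, with dimnames on the combo axis naming the
#'   combinations. No missing values allowed.
#' @return A `parameter_grid_result`: list with `ranks` (same shape as
#'   `f_scores`), `re_rank` (combo x method), `final_score` (per combo),
#'   `mean_f` (per combo), `recommended` (combo name).
#' @export
rank_parameters <- function(f_scores) {
  if (length(dim(f_scores)) != 3L) {
    stop("'f_scores' must be a 3-d array [dataset, combo, method]")
  }
  if (anyNA(f_scores)) stop("'f_scores' contains missing values")
  nd <- dim(f_scores)[1L]
  nc <- dim(f_scores)[2L]
  nm <- dim(f_scores)[3L]
  combos <- dimnames(f_scores)[[2L]]
  if (is.null(combos)) combos <- paste0("combo", seq_len(nc))
  ranks <- f_scores
  for (d in seq_len(nd)) {
    for (meth in seq_len(nm)) {
      ranks[d, , meth] <- rank(-f_scores[d, , meth], ties.method = "average")
    }
  }
  re_rank <- apply(ranks, c(2L, 3L), mean)
  final_score <- rowMeans(re_rank)
  mean_f <- apply(f_scores, 2L, mean)
  ord <- order(final_score, -mean_f, seq_len(nc))
  structure(list(combos = combos,
                 ranks = ranks,
                 re_rank = re_rank,
                 final_score = stats::setNames(final_score, combos),
                 mean_f = stats::setNames(mean_f, combos),
                 recommended = combos[ord[1L]]),
            class = "parameter_grid_result")
}

#' @exportS3Method print parameter_grid_result
print.parameter_grid_result <- function(x, ...) {
  cat("parameter_grid_result: recommended =", x$recommended, "\n")
  df <- data.frame(combo = x$combos, final_score = unname(x$final_score),
                   mean_f = unname(x$mean_f))
  print(df[order(df$final_score), ], row.names = FALSE)
  invisible(x)
}
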