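#' Number of grid bins per expression axis
#'
#' The scatter diagram of every gene pair is partitioned into an equal-width
#' grid whose resolution grows with the square root of the number of cells:
#' `GR = floor(sqrt(n) + 1/2)`, i.e. `sqrt(n)` rounded to the nearest
#' integer.
#'
#' @param n Number of cells (positive integer).
#' @return Integer grid count, at least 1.
#' @export
#' @examples
#' compute_grid_count(100) # 10
#' compute_grid_count(124) # 11
compute_grid_count <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1) {
    stop("'n' must be a single integer >= 1")
  }
  max(1L, as.integer(floor(sqrt(n) + 0.5)))
}

#' Build the per-gene grid specification
#'
#' For each gene, the interval between its minimum and maximum expression
#' across all cells is split into `GR` equal-width bins
#' (`GR = compute_grid_count(n)`). A value lying exactly on an internal bin
#' edge belongs to the bin on its right (half-open bins, last bin closed).
#' Genes with zero expression range cannot be binned and are flagged as
#' degenerate; they never contribute edges.
#'
#' @param gem A log-transformed [expression_matrix()].
#' @return A `grid_spec` object: list with `grid_count`, `edges` (an
#'   `m x (GR+1)` matrix of bin edges), and `degenerate` (logical per gene).
#' @export
build_grid <- function(gem) {
  stopifnot_gem(gem)
  if (!gem$is_log_transformed) {
    stop("build_grid() expects a log-transformed matrix; call log_transform() first")
  }
  n <- n_cells(gem)
  gr <- compute_grid_count(n)
  rng <- t(apply(gem$values, 1L, range))
  degenerate <- rng[, 1L] == rng[, 2L]
  edges <- t(apply(rng, 1L, function(r) seq(r[1L], r[2L], length.out = gr + 1L)))
  dimnames(edges) <- list(gem$gene_ids, NULL)
  structure(list(grid_count = gr, edges = edges, degenerate = degenerate),
            class = "grid_spec")
}

# Bin index of each value under equal-width edges for one gene.
# Half-open convention: bin b covers [edges[b], edges[b+1]), last bin closed.
bin_index <- function(values, edges) {
  gr <- length(edges) - 1L
  lo <- edges[1L]
  hi <- edges[gr + 1L]
  if (hi == lo) return(rep.int(1L, length(values)))
  width <- (hi - lo) / gr
  b <- floor((values - lo) / width) + 1L
  # guard against floating-point spill at the top edge
  pmin.int(pmax.int(as.integer(b), 1L), gr)
}

#' Tentative neighborhood interval of a cell on one expression axis
#'
#' The tentative neighborhood of cell `c` for a gene covers the
#' `k = ceiling(box_size * n)` cells whose expression values are nearest to
#' the target cell's value (the target itself always included). Ties in
#' distance are resolved toward the lower value, then the lower cell index.
#' The returned closed interval spans the selected values.
#'
#' @param values Numeric vector of one gene's expression across all cells.
#' @param cell Index of the target cell.
#' @param box_size Fraction of cells in the neighborhood, in `(0, 1]`.
#' @return Numeric `c(lo, hi)`.
#' @export
tentative_neighborhood <- function(values, cell, box_size) {
  n <- length(values)
  if (box_size <= 0 || box_size > 1) stop("'box_size' must be in (0, 1]")
  k <- as.integer(ceiling(box_size * n))
  if (k < 1L) stop("box_size * n must be at least 1")
  if (cell < 1L || cell > n) stop("'cell' out of range")
  s <- sort(values)
  nearest_window(s, values[cell], k)
}

# Given sorted values s and a target value v known to occur in s, return the
# closed interval spanned by the k nearest values (ties toward lower values).
nearest_window <- function(s, v, k) {
  n <- length(s)
  iL <- findInterval(v, s, left.open = TRUE) + 1L  # first index with s >= v
  iR <- findInterval(v, s)                          # last index with s <= v
  jmin <- max(1L, iL - k + 1L)
  jmax <- min(iR, n - k + 1L)
  js <- jmin:jmax
  cost <- pmax(v - s[js], s[js + k - 1L] - v)
  j <- js[which.min(cost)]   # first minimum = lower-value preference
  c(s[j], s[j + k - 1L])
}

#' Snap a value interval to grid-bin boundaries
#'
#' Expands a tentative neighborhood interval outward to the nearest grid
#' boundaries: the final neighborhood is the inclusive range of bins the
#' interval intersects. A point on an internal edge belongs to the bin on
#' its right.
#'
#' @param interval Numeric `c(lo, hi)` within the gene's expression range.
#' @param gene_edges Bin-edge vector for the gene (length `GR + 1`).
#' @param values Optional expression vector over all cells; when supplied,
#'   per-bin cell counts for the bins in range are returned.
#' @return List with `first_bin`, `last_bin` (1-based inclusive) and, when
#'   `values` is given, `counts` (cells per bin across the range).
#' @export
snap_to_grid <- function(interval, gene_edges, values = NULL) {
  b <- bin_index(interval, gene_edges)
  out <- list(first_bin = b[1L], last_bin = b[2L])
  if (!is.null(values)) {
    gr <- length(gene_edges) - 1L
    cnt <- tabulate(bin_index(values, gene_edges), gr)
    out$counts <- cnt[b[1L]:b[2L]]
  }
  out
}
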