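# Core per-pair, per-cell local mutual information machinery.
#
# Counts are always taken over ALL n cells; what is local to the target
# cell is the grid-snapped neighborhood box. Two statistics are offered:
#
# "restricted_mi" (default): the neighborhood-restricted mutual
# information
#   I^(c) = sum_{grid cells xy in box} (n_xy/n) log( n * n_xy / (n_x n_y) )
# i.e. the frequency-weighted pointwise mutual information summed over the
# sub-regions of the intersection box G_XY^(c). Summed over the FULL grid
# this is exactly H(G_X) + H(G_Y) - H(G_X, G_Y); restricting the summation
# domain keeps the score monotone in local dependence: a cell whose
# neighborhood holds more joint mass than the product of its marginal
# masses scores positive. (This is the grid generalization of the
# box test n_xy * n > n_x * n_y used by cell-specific network methods.)
#
# "entropy_diff": the literal difference of box-restricted entropy sums
#   I^(c) = H(G_X)^(c) + H(G_Y)^(c) - H(G_X, G_Y)^(c),
#   H(G_X)^(c) = -sum_{bins x in X range} (n_x/n) log(n_x/n), etc.
# Because the three sums run over different supports while keeping the
# global denominator, this form is NOT monotone in local dependence (a
# concentrated joint RAISES the joint entropy term); it is retained as a
# documented variant and for hand-checkable worked examples.
#
# Marginal sums collapse to differences of prefix sums over bins; the joint
# sum collapses to a 2-D prefix-sum rectangle query, so one pair costs
# O(n + GR^2) for all n cells at once.

# Per-gene precomputation shared by every pair involving the gene:
# bin index per cell, bin counts, neighborhood bin range per cell, and the
# box-restricted marginal entropy per cell (used by the entropy_diff mode).
gene_axis_stats <- function(v, edges, k, log_base = exp(1),
                            neighborhood = "nearest") {
  n <- length(v)
  gr <- length(edges) - 1L
  if (edges[1L] == edges[gr + 1L]) {    # degenerate: zero expression range
    return(list(degenerate = TRUE, bins = rep.int(1L, n),
                counts = c(n, rep.int(0L, gr - 1L)),
                lo = rep.int(1L, n), hi = rep.int(1L, n),
                H = numeric(n)))
  }
  bins <- bin_index(v, edges)
  counts <- tabulate(bins, gr)
  p <- counts / n
  term <- numeric(gr)
  nz <- counts > 0L
  term[nz] <- p[nz] * (log(p[nz]) / log(log_base))
  S <- c(0, cumsum(term))

  ord <- order(v)              # ties keep lower cell index first (stable)
  s <- v[ord]
  lo <- numeric(n)
  hi <- numeric(n)
  if (neighborhood == "nearest") {
    # leftmost/rightmost sorted position of each distinct value
    firsts <- findInterval(v, s, left.open = TRUE) + 1L
    lasts <- findInterval(v, s)
    for (c_i in seq_len(n)) {
      vi <- v[c_i]
      jmin <- max(1L, firsts[c_i] - k + 1L)
      jmax <- min(lasts[c_i], n - k + 1L)
      js <- jmin:jmax
      j <- js[which.min(pmax(vi - s[js], s[js + k - 1L] - vi))]
      lo[c_i] <- s[j]          # temporarily store values
      hi[c_i] <- s[j + k - 1L]
    }
  } else if (neighborhood == "split") {
    # window centred on the cell's sorted position: floor((k-1)/2) cells
    # below, the rest above, shifted inward at the data ends
    pos <- integer(n)
    pos[ord] <- seq_len(n)
    kl <- (k - 1L) %/% 2L
    j <- pmax(1L, pmin(pos - kl, n - k + 1L))
    lo <- s[j]
    hi <- s[j + k - 1L]
  } else {
    stop("unknown neighborhood mode: ", neighborhood)
  }
  lo_bin <- bin_index(lo, edges)
  hi_bin <- bin_index(hi, edges)
  H <- -(S[hi_bin + 1L] - S[lo_bin])
  list(degenerate = FALSE, bins = bins, counts = counts,
       lo = lo_bin, hi = hi_bin, H = H)
}

# Padded 2-D prefix-sum matrix of a gr x gr term matrix.
prefix2d <- function(fm, gr) {
  P <- matrix(0, gr + 1L, gr + 1L)
  if (gr == 1L) {
    P[2L, 2L] <- fm[1L, 1L]
  } else {
    P[-1L, -1L] <- t(apply(apply(fm, 2L, cumsum), 1L, cumsum))
  }
  P
}

# Rectangle queries of a padded prefix matrix for every cell's box.
rect_query <- function(P, ax, ay) {
  hx <- ax$hi + 1L; lx <- ax$lo
  hy <- ay$hi + 1L; ly <- ay$lo
  P[cbind(hx, hy)] - P[cbind(lx, hy)] - P[cbind(hx, ly)] + P[cbind(lx, ly)]
}

# Local MI for one gene pair in every cell at once, given the two
# per-gene axis statistics. Returns the length-n vector I^(c).
pair_local_mi <- function(ax, ay, gr, n, log_base = exp(1),
                          statistic = "restricted_mi") {
  if (ax$degenerate || ay$degenerate) return(numeric(n))
  lb <- log(log_base)
  jt <- matrix(tabulate((ay$bins - 1L) * gr + ax$bins, gr * gr), gr, gr)
  if (statistic == "restricted_mi") {
    # frequency-weighted pointwise MI per grid cell
    fm <- matrix(0, gr, gr)
    nz <- jt > 0L
    denom <- outer(ax$counts, ay$counts)
    fm[nz] <- (jt[nz] / n) * ((log(jt[nz]) + log(n) - log(denom[nz])) / lb)
    return(rect_query(prefix2d(fm, gr), ax, ay))
  }
  # entropy_diff: literal H_X + H_Y - H_XY over box-restricted supports
  p <- jt / n
  fm <- matrix(0, gr, gr)
  nz <- jt > 0L
  fm[nz] <- p[nz] * (log(p[nz]) / lb)
  Hxy <- -rect_query(prefix2d(fm, gr), ax, ay)
  ax$H + ay$H - Hxy
}

pop_sd <- function(x) {
  mu <- mean(x)
  sqrt(mean((x - mu)^2))
}

resolve_gene <- function(gem, gene) {
  if (is.character(gene)) {
    idx <- match(gene, gem$gene_ids)
    if (is.na(idx)) stop("unknown gene: ", gene)
    return(idx)
  }
  idx <- as.integer(gene)
  if (is.na(idx) || idx < 1L || idx > n_genes(gem)) {
    stop("gene index out of range: ", gene)
  }
  idx
}

#' Local mutual information of a gene pair in one cell
#'
#' Computes the grid-based local mutual information score of a gene pair in
#' the neighborhood of one target cell. Neighborhoods are the
#' `ceiling(box_size * n)` nearest cells on each gene's axis, expanded
#' outward to the grid boundaries; bin frequencies are always taken over
#' all `n` cells. Two statistics are available (see `statistic`):
#'
#' * `"restricted_mi"` (default): the frequency-weighted pointwise mutual
#'   information summed over the sub-regions of the intersection box,
#'   `sum (n_xy/n) log(n n_xy / (n_x n_y))`. Over the full grid this
#'   equals `H(G_X) + H(G_Y) - H(G_X, G_Y)` exactly; restricted to the
#'   neighborhood it is positive when the box holds more joint mass than
#'   independence predicts (and can be slightly negative in locally
#'   depleted regions).
#' * `"entropy_diff"`: the literal difference
#'   `H(G_X)^(c) + H(G_Y)^(c) - H(G_X, G_Y)^(c)` with each entropy summed
#'   over its own box-restricted support and probabilities `n_x / n`.
#'   Hand-checkable, but not monotone in local dependence because the
#'   three sums run over different supports; see the methods vignette.
#'
#' A pair involving a degenerate (constant) gene scores 0.
#'
#' @param gem A log-transformed [expression_matrix()].
#' @param grid A `grid_spec` from [build_grid()]; built on the fly if `NULL`.
#' @param gene_x,gene_y Gene identifiers or row indices.
#' @param cell Cell identifier or column index.
#' @param box_size Neighborhood fraction in `(0, 1]`; default 0.2.
#' @param log_base Base of the entropy logarithm. The default is the
#'   natural logarithm; z-scores and hence edge calls are invariant to
#'   this choice.
#' @param neighborhood `"nearest"` (nearest-k window, default) or
#'   `"split"` (window split above/below the cell's own value).
#' @param statistic `"restricted_mi"` (default) or `"entropy_diff"`; see
#'   Details.
#' @return A single number (non-negative for `"entropy_diff"`).
#' @export
local_mi <- function(gem, grid = NULL, gene_x, gene_y, cell,
                     box_size = 0.2, log_base = exp(1),
                     neighborhood = c("nearest", "split"),
                     statistic = c("restricted_mi", "entropy_diff")) {
  stopifnot_gem(gem)
  neighborhood <- match.arg(neighborhood)
  statistic <- match.arg(statistic)
  if (is.null(grid)) grid <- build_grid(gem)
  gx <- resolve_gene(gem, gene_x)
  gy <- resolve_gene(gem, gene_y)
  if (is.character(cell)) {
    cell <- match(cell, gem$cell_ids)
    if (is.na(cell)) stop("unknown cell")
  }
  n <- n_cells(gem)
  k <- as.integer(ceiling(box_size * n))
  if (k < 1L) stop("box_size * n must be at least 1")
  ax <- gene_axis_stats(gem$values[gx, ], grid$edges[gx, ], k, log_base,
                        neighborhood)
  ay <- gene_axis_stats(gem$values[gy, ], grid$edges[gy, ], k, log_base,
                        neighborhood)
  pair_local_mi(ax, ay, grid$grid_count, n, log_base, statistic)[cell]
}

#' Per-cell MI profile and z-scores of one gene pair
#'
#' Evaluates the local mutual information of a gene pair in every cell and
#' standardizes it across cells:
#' `z^(c) = (I^(c) - mu) / sigma`, with `mu` and `sigma` the mean and
#' population standard deviation of the per-cell scores. When `sigma = 0`
#' (the pair's local MI never varies) all z-scores are set to 0, so the
#' pair cannot produce edges at any threshold of at least zero.
#'
#' @inheritParams local_mi
#' @return A `pair_mi_profile` object: list with `gene_x`, `gene_y`
#'   (indices), `mi_per_cell`, `mean`, `sd` and `z_per_cell`.
#' @export
pair_profile <- function(gem, grid = NULL, gene_x, gene_y,
                         box_size = 0.2, log_base = exp(1),
                         neighborhood = c("nearest", "split"),
                         statistic = c("restricted_mi", "entropy_diff")) {
  stopifnot_gem(gem)
  neighborhood <- match.arg(neighborhood)
  statistic <- match.arg(statistic)
  if (is.null(grid)) grid <- build_grid(gem)
  gx <- resolve_gene(gem, gene_x)
  gy <- resolve_gene(gem, gene_y)
  if (gx == gy) stop("gene_x and gene_y must be distinct (self-pair)")
  n <- n_cells(gem)
  k <- as.integer(ceiling(box_size * n))
  if (k < 1L) stop("box_size * n must be at least 1")
  ax <- gene_axis_stats(gem$values[gx, ], grid$edges[gx, ], k, log_base,
                        neighborhood)
  ay <- gene_axis_stats(gem$values[gy, ], grid$edges[gy, ], k, log_base,
                        neighborhood)
  mi <- pair_local_mi(ax, ay, grid$grid_count, n, log_base, statistic)
  mu <- mean(mi)
  sd_ <- pop_sd(mi)
  z <- if (sd_ > 0) (mi - mu) / sd_ else numeric(n)
  structure(list(gene_x = gx, gene_y = gy, mi_per_cell = mi,
                 mean = mu, sd = sd_, z_per_cell = z),
            class = "pair_mi_profile")
}

#' Infer one network per cell
#'
#' Runs the full inference: for every evaluated unordered gene pair the
#' per-cell local MI profile is standardized (population mean/sd across
#' cells) and an edge is stored in cell `c` whenever `z^(c)` strictly
#' exceeds `z_threshold`. Without a pair restriction all `m(m-1)/2` pairs
#' are evaluated; with one, only the listed pairs (unmatched gene symbols
#' are dropped with a message). Degenerate genes never produce edges. The
#' computation is streamed pair by pair and is fully deterministic.
#'
#' @param gem A log-transformed [expression_matrix()].
#' @param box_size Neighborhood fraction in `(0, 1]`; default 0.2.
#' @param z_threshold Edge threshold on the per-pair z-score (strict
#'   inequality); default 0.
#' @param pair_restriction Optional restriction of the evaluated pairs: a
#'   `reference_network`, or a two-column character matrix/data frame of
#'   gene symbols.
#' @param neighborhood `"nearest"` or `"split"` (see [local_mi()]).
#' @param statistic `"restricted_mi"` (default) or `"entropy_diff"` (see
#'   [local_mi()]).
#' @param log_base Entropy log base (edge calls are invariant to it).
#' @param drop_zero_edges If `TRUE`, suppress edges incident to a gene with
#'   zero expression in that cell (strict dropout handling); default
#'   `FALSE`, i.e. zeros are ordinary values in the lowest bin.
#' @param threads Accepted for interface compatibility; the implementation
#'   is single-threaded and results never depend on this value.
#' @return An `scn_set`: list with `edges` (data frame `cell`, `gene_i`,
#'   `gene_j`, `z`, with `gene_i < gene_j`), `gene_ids`, `cell_ids`,
#'   `params`, `n_pairs_evaluated` and `degenerate`.
#' @export
#' @examples
#' gem <- log_transform(synthetic_null_matrix(20, 12, seed = 1))
#' scns <- infer_scns(gem, box_size = 0.25, z_threshold = 1)
#' dm <- degree_matrix(scns)
infer_scns <- function(gem, box_size = 0.2, z_threshold = 0,
                       pair_restriction = NULL,
                       neighborhood = c("nearest", "split"),
                       statistic = c("restricted_mi", "entropy_diff"),
                       log_base = exp(1), drop_zero_edges = FALSE,
                       threads = 1L) {
  stopifnot_gem(gem)
  neighborhood <- match.arg(neighborhood)
  statistic <- match.arg(statistic)
  if (!gem$is_log_transformed) {
    stop("infer_scns() expects a log-transformed matrix; call log_transform() first")
  }
  if (box_size <= 0 || box_size > 1) stop("'box_size' must be in (0, 1]")
  m <- n_genes(gem)
  n <- n_cells(gem)
  if (m < 2L) stop("need at least two genes")
  k <- as.integer(ceiling(box_size * n))
  if (box_size * n < 1) stop("box_size * n must be at least 1")

  grid <- build_grid(gem)
  gr <- grid$grid_count

  # pairs to evaluate
  if (is.null(pair_restriction)) {
    pairs_i <- rep.int(seq_len(m - 1L), times = (m - 1L):1L)
    pairs_j <- unlist(lapply(seq_len(m - 1L), function(i) (i + 1L):m),
                      use.names = FALSE)
  } else {
    pr <- restriction_pairs(pair_restriction, gem$gene_ids)
    pairs_i <- pr$i
    pairs_j <- pr$j
    if (length(pairs_i) == 0L) {
      stop("no restriction pair maps to the expression matrix gene set")
    }
  }

  axes <- vector("list", m)
  for (g in seq_len(m)) {
    axes[[g]] <- gene_axis_stats(gem$values[g, ], grid$edges[g, ], k,
                                 log_base, neighborhood)
  }

  zero_expr <- if (drop_zero_edges) gem$values == 0 else NULL

  np <- length(pairs_i)
  cell_acc <- vector("list", np)
  z_acc <- vector("list", np)
  for (p in seq_len(np)) {
    i <- pairs_i[p]
    j <- pairs_j[p]
    ai <- axes[[i]]
    aj <- axes[[j]]
    if (ai$degenerate || aj$degenerate) next
    mi <- pair_local_mi(ai, aj, gr, n, log_base, statistic)
    sd_ <- pop_sd(mi)
    if (sd_ == 0) next
    z <- (mi - mean(mi)) / sd_
    hit <- z > z_threshold
    if (drop_zero_edges) hit <- hit & !zero_expr[i, ] & !zero_expr[j, ]
    w <- which(hit)
    if (length(w)) {
      cell_acc[[p]] <- w
      z_acc[[p]] <- z[w]
    }
  }
  counts <- lengths(cell_acc)
  edges <- data.frame(
    cell = unlist(cell_acc, use.names = FALSE),
    gene_i = rep.int(pairs_i, counts),
    gene_j = rep.int(pairs_j, counts),
    z = unlist(z_acc, use.names = FALSE)
  )
  if (nrow(edges) == 0L) {
    edges <- data.frame(cell = integer(), gene_i = integer(),
                        gene_j = integer(), z = numeric())
  }
  structure(list(edges = edges,
                 gene_ids = gem$gene_ids,
                 cell_ids = gem$cell_ids,
                 params = list(box_size = box_size,
                               z_threshold = z_threshold,
                               neighborhood = neighborhood,
                               statistic = statistic,
                               log_base = log_base,
                               drop_zero_edges = drop_zero_edges),
                 n_pairs_evaluated = np,
                 degenerate = grid$degenerate),
            class = "scn_set")
}

# Map a pair restriction (reference network or two-column table of gene
# symbols) onto gene indices; unmatched or self pairs are dropped.
restriction_pairs <- function(restriction, gene_ids) {
  if (inherits(restriction, "reference_network")) {
    a <- restriction$edges$a
    b <- restriction$edges$b
  } else {
    tab <- as.matrix(restriction)
    if (ncol(tab) < 2L) stop("pair restriction needs two columns")
    a <- as.character(tab[, 1L])
    b <- as.character(tab[, 2L])
  }
  ia <- match(a, gene_ids)
  ib <- match(b, gene_ids)
  ok <- !is.na(ia) & !is.na(ib) & ia != ib
  dropped <- sum(!ok)
  if (dropped > 0L) {
    message(dropped, " restriction pair(s) dropped (gene symbol not in matrix)")
  }
  i <- pmin.int(ia[ok], ib[ok])
  j <- pmax.int(ia[ok], ib[ok])
  key <- unique(paste(i, j))
  sp <- strsplit(key, " ", fixed = TRUE)
  list(i = as.integer(vapply(sp, `[`, "", 1L)),
       j = as.integer(vapply(sp, `[`, "", 2L)))
}

#' @exportS3Method print scn_set
print.scn_set <- function(x, ...) {
  cat(sprintf(
    "scn_set: %d cells, %d genes, %d pairs evaluated, %d edges total\n",
    length(x$cell_ids), length(x$gene_ids), x$n_pairs_evaluated,
    nrow(x$edges)))
  cat(sprintf("  box_size = %g, z_threshold = %g, neighborhood = %s\n",
              x$params$box_size, x$params$z_threshold,
              x$params$neighborhood))
  invisible(x)
}

#' Edge list of a single cell's network
#'
#' @param scns An `scn_set` from [infer_scns()].
#' @param cell Cell identifier or column index.
#' @return Data frame with `gene_a`, `gene_b` (identifiers,
#'   `gene_a < gene_b`) and `z`.
#' @export
scn_edges <- function(scns, cell) {
  stopifnot(inherits(scns, "scn_set"))
  if (is.character(cell)) {
    cell <- match(cell, scns$cell_ids)
    if (is.na(cell)) stop("unknown cell")
  }
  ed <- scns$edges[scns$edges$cell == cell, , drop = FALSE]
  ga <- scns$gene_ids[ed$gene_i]
  gb <- scns$gene_ids[ed$gene_j]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  data.frame(gene_a = ga, gene_b = gb, z = ed$z,
             stringsAsFactors = FALSE)
}

#' Degree matrix of a set of single-cell networks
#'
#' Counts, for every gene and cell, the number of edges incident to the
#' gene in that cell's network. The result has exactly the shape and
#' identifier order of the source expression matrix, so it can be fed to
#' the same dimension-reduction and clustering tools. The optional
#' `log10p1` transform applies `log10(d + 1)`.
#'
#' @param scns An `scn_set` from [infer_scns()].
#' @param gem Optional source [expression_matrix()]; when given, its cell
#'   and gene identifiers must match the networks' (alignment check).
#' @param transform `"raw"` (counts, default) or `"log10p1"`.
#' @return A `degree_matrix` object: list with `values` (m x n), `gene_ids`,
#'   `cell_ids`, `transform`.
#' @export
degree_matrix <- function(scns, gem = NULL,
                          transform = c("raw", "log10p1")) {
  stopifnot(inherits(scns, "scn_set"))
  transform <- match.arg(transform)
  if (!is.null(gem)) {
    stopifnot_gem(gem)
    if (!identical(gem$cell_ids, scns$cell_ids) ||
        !identical(gem$gene_ids, scns$gene_ids)) {
      stop("expression matrix and networks are not aligned ",
           "(gene/cell identifiers differ)")
    }
  }
  m <- length(scns$gene_ids)
  n <- length(scns$cell_ids)
  ed <- scns$edges
  idx <- c((ed$cell - 1L) * m + ed$gene_i, (ed$cell - 1L) * m + ed$gene_j)
  vals <- matrix(as.double(tabulate(idx, m * n)), m, n,
                 dimnames = list(scns$gene_ids, scns$cell_ids))
  if (transform == "log10p1") vals <- log10(vals + 1)
  structure(list(values = vals, gene_ids = scns$gene_ids,
                 cell_ids = scns$cell_ids, transform = transform),
            class = "degree_matrix")
}

#' @exportS3Method dim degree_matrix
dim.degree_matrix <- function(x) dim(x$values)

#' @exportS3Method as.matrix degree_matrix
as.matrix.degree_matrix <- function(x, ...) x$values

#' @exportS3Method print degree_matrix
print.degree_matrix <- function(x, ...) {
  cat(sprintf("degree_matrix: %d genes x %d cells (%s)\n",
              nrow(x$values), ncol(x$values), x$transform))
  invisible(x)
}

#' Per-cell presence matrix of a gene pair
#'
#' Logical vector over cells: does the (unordered) pair have an edge in
#' that cell's network?
#'
#' @param scns An `scn_set`.
#' @param gene_a,gene_b Gene identifiers or indices.
#' @return Named logical vector over cells.
#' @export
edge_presence <- function(scns, gene_a, gene_b) {
  stopifnot(inherits(scns, "scn_set"))
  ia <- if (is.character(gene_a)) match(gene_a, scns$gene_ids) else as.integer(gene_a)
  ib <- if (is.character(gene_b)) match(gene_b, scns$gene_ids) else as.integer(gene_b)
  if (is.na(ia) || is.na(ib)) stop("unknown gene")
  i <- min(ia, ib); j <- max(ia, ib)
  out <- logical(length(scns$cell_ids))
  sel <- scns$edges$gene_i == i & scns$edges$gene_j == j
  out[scns$edges$cell[sel]] <- TRUE
  names(out) <- scns$cell_ids
  out
}
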