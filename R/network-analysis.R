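# Downstream network statistics on inferred per-cell networks: reference
# network overlap, scale-free topology fitting, hub/edge enrichment for
# cell-type markers, and per-label aggregate (rewiring) networks.

#' Construct a reference network from gene symbol pairs
#'
#' @param a,b Character vectors of gene symbols (one undirected edge per
#'   position). Self-loops are dropped, duplicate unordered pairs collapsed.
#' @return A `reference_network`: list with `edges` (data frame `a`, `b`
#'   with `a < b`) and `nodes`.
#' @export
reference_network <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  keep <- a != b
  lo <- pmin(a[keep], b[keep])
  hi <- pmax(a[keep], b[keep])
  key <- paste(lo, hi, sep = "\r")
  uniq <- !duplicated(key)
  edges <- data.frame(a = lo[uniq], b = hi[uniq], stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = sort(unique(c(edges$a, edges$b)))),
            class = "reference_network")
}

#' @exportS3Method print reference_network
print.reference_network <- function(x, ...) {
  cat(sprintf("reference_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Canonical unordered-pair keys for the edge-set operations below.
canonical_edge_keys <- function(x) {
  if (inherits(x, "reference_network")) {
    return(paste(x$edges$a, x$edges$b, sep = "\r"))
  }
  if (is.data.frame(x)) {
    cols <- intersect(c("gene_a", "gene_b"), names(x))
    if (length(cols) == 2L) {
      a <- as.character(x$gene_a); b <- as.character(x$gene_b)
    } else if (ncol(x) >= 2L) {
      a <- as.character(x[[1L]]); b <- as.character(x[[2L]])
    } else stop("cannot interpret edge set: need two columns")
    keep <- a != b
    return(unique(paste(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]),
                        sep = "\r")))
  }
  if (is.character(x)) return(unique(x))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as an edge set")
}

#' Overlap coefficient of two edge sets
#'
#' `|A intersect B| / min(|A|, |B|)` on unordered gene pairs. Gene symbol
#' matching is exact and case-sensitive.
#'
#' @param a,b Edge sets: `reference_network` objects, two-column data
#'   frames (e.g. from [scn_edges()]), or canonical key vectors.
#' @return A number in `[0, 1]`.
#' @export
overlap_coefficient <- function(a, b) {
  ka <- canonical_edge_keys(a)
  kb <- canonical_edge_keys(b)
  if (length(ka) == 0L || length(kb) == 0L) {
    stop("overlap coefficient is undefined for an empty edge set")
  }
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Fit a power law to a degree distribution
#'
#' Estimates the scale-free topology fit of a network from its degree
#' sequence: the empirical degree probability `P(k)` over observed degrees
#' `k >= 1` is regressed on `k` on the log10-log10 scale by ordinary least
#' squares. The degree exponent is `gamma = -slope` and `r_squared` is the
#' coefficient of determination of the regression (linearity of
#' `log P(k)` vs `log k`).
#'
#' @param degrees Integer vector (multiset) of node degrees; zeros are
#'   ignored for the fit.
#' @param log_binning If `TRUE`, pool degrees into logarithmically spaced
#'   bins before fitting (useful for heavy tails); default `FALSE` (raw
#'   distinct-degree frequencies).
#' @return A `power_law_fit`: list with `gamma`, `r_squared`, and
#'   `fitted_points` (data frame `log_k`, `log_p`).
#' @export
scale_free_fit <- function(degrees, log_binning = FALSE) {
  degrees <- as.integer(degrees)
  if (anyNA(degrees) || any(degrees < 0L)) {
    stop("'degrees' must be non-negative integers")
  }
  pos <- degrees[degrees >= 1L]
  if (length(unique(pos)) < 3L) {
    stop("need at least 3 distinct degrees >= 1 to fit a power law")
  }
  if (log_binning) {
    nb <- max(3L, ceiling(log2(max(pos))) + 1L)
    brk <- unique(c(2^(0:nb)))
    bin <- findInterval(pos, brk)
    centres <- vapply(split(pos, bin), function(v) exp(mean(log(v))), 0)
    counts <- as.numeric(table(bin))
    widths <- vapply(split(pos, bin),
                     function(v) diff(range(v)) + 1, 0)
    p <- (counts / widths) / length(pos)
    k <- centres
  } else {
    tab <- table(pos)
    k <- as.numeric(names(tab))
    p <- as.numeric(tab) / length(pos)
  }
  lk <- log10(k)
  lp <- log10(p)
  fit <- stats::lm(lp ~ lk)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((lp - mean(lp))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(gamma = -unname(stats::coef(fit)[2L]),
                 r_squared = r2,
                 fitted_points = data.frame(log_k = lk, log_p = lp)),
            class = "power_law_fit")
}

#' @exportS3Method print power_law_fit
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power_law_fit: gamma = %.3f, R^2 = %.3f (%d degree classes)\n",
              x$gamma, x$r_squared, nrow(x$fitted_points)))
  invisible(x)
}

#' Select a size-matched subnetwork from a reference network
#'
#' Picks the `target_edge_count` reference edges with the highest
#' per-edge confidence scores, so that two networks can be compared at
#' equal edge number. Edges without a score are ranked last; score ties are
#' broken by lexicographic edge name, making the selection deterministic.
#'
#' @param target_edge_count Number of edges to select.
#' @param reference A [reference_network()].
#' @param confidence Numeric vector of per-edge scores, either named by
#'   canonical `"a\rb"` key or aligned with `reference$edges` rows.
#' @return A `reference_network` with exactly `target_edge_count` edges.
#' @export
match_network_scale <- function(target_edge_count, reference, confidence) {
  stopifnot(inherits(reference, "reference_network"))
  ne <- nrow(reference$edges)
  target_edge_count <- as.integer(target_edge_count)
  if (target_edge_count < 1L || target_edge_count > ne) {
    stop("'target_edge_count' must be between 1 and the reference edge count (",
         ne, ")")
  }
  key <- paste(reference$edges$a, reference$edges$b, sep = "\r")
  if (!is.null(names(confidence))) {
    sc <- confidence[key]
    sc[is.na(sc)] <- -Inf
  } else {
    if (length(confidence) != ne) {
      stop("unnamed 'confidence' must have one score per reference edge")
    }
    sc <- as.numeric(confidence)
    sc[is.na(sc)] <- -Inf
  }
  ord <- order(-sc, key)
  sel <- sort(ord[seq_len(target_edge_count)])
  reference_network(reference$edges$a[sel], reference$edges$b[sel])
}

#' Hub genes of one network
#'
#' A gene is a hub of a cell's network when its degree is within the top
#' `fraction` of all genes: the cutoff is the `ceiling(fraction * m)`-th
#' largest degree, and all genes tied at the cutoff are included.
#'
#' @param scn_degrees Numeric vector of gene degrees in one network.
#' @param fraction Top fraction defining hubs; default 0.25.
#' @return Integer vector of hub gene indices.
#' @export
hubs <- function(scn_degrees, fraction = 0.25) {
  m <- length(scn_degrees)
  if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
  kth <- ceiling(fraction * m)
  cutoff <- sort(scn_degrees, decreasing = TRUE)[kth]
  which(scn_degrees >= cutoff)
}

# Hub membership for every gene in every cell, from a degree matrix.
hub_matrix <- function(dm, fraction = 0.25) {
  stopifnot(inherits(dm, "degree_matrix"))
  v <- dm$values
  m <- nrow(v)
  kth <- ceiling(fraction * m)
  cutoffs <- apply(v, 2L, function(col) sort(col, decreasing = TRUE)[kth])
  sweep(v, 2L, cutoffs, ">=")
}

# One-sided (greater) Fisher exact test on a 2x2 table
#   rows: in target group / not; cols: event / no event
# a = target & event, b = target & no event, c = other & event, d = other & no event.
fisher_greater <- function(a, b, c, d) {
  tab <- matrix(c(a, c, b, d), 2L)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  structure(list(odds_ratio = or, p_value = min(1, p),
                 table = matrix(c(a, b, c, d), 2L, byrow = TRUE,
                                dimnames = list(c("target", "other"),
                                                c("event", "no_event")))),
            class = "enrichment_result")
}

#' @exportS3Method print enrichment_result
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: OR = %s, p = %.3g\n",
              format(x$odds_ratio, digits = 4), x$p_value))
  print(x$table)
  invisible(x)
}

resolve_labels <- function(labels, cell_ids) {
  if (!is.null(names(labels))) {
    idx <- match(cell_ids, names(labels))
    if (anyNA(idx)) stop("labels missing for some cells")
    labels <- labels[idx]
  }
  if (length(labels) != length(cell_ids)) {
    stop("need one label per cell")
  }
  as.character(labels)
}

#' Hub enrichment of a gene in a cell type
#'
#' Tests whether a gene is a hub of the per-cell networks more often among
#' cells of the target type than among the remaining cells: a 2x2 table of
#' (cell in target type) x (gene is hub in that cell's network), assessed
#' by a one-sided (greater) Fisher's exact test. The odds ratio is the
#' sample `ad/bc` (infinite when `bc = 0` and `ad > 0`).
#'
#' @param gene Gene identifier or index.
#' @param scns An `scn_set`, or a precomputed `degree_matrix`.
#' @param cell_labels Per-cell labels (named by cell id or in cell order).
#' @param target_label Label of the cell type of interest.
#' @param hub_fraction Top-degree fraction defining hubs; default 0.25.
#' @param alternative `"greater"` (default, directional) or `"two.sided"`.
#' @return An `enrichment_result`: list with `odds_ratio`, `p_value`,
#'   `table`.
#' @export
hub_enrichment <- function(gene, scns, cell_labels, target_label,
                           hub_fraction = 0.25,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  dm <- if (inherits(scns, "degree_matrix")) scns else degree_matrix(scns)
  labels <- resolve_labels(cell_labels, dm$cell_ids)
  if (!target_label %in% labels) {
    stop("target label '", target_label, "' not present among cell labels")
  }
  gi <- if (is.character(gene)) match(gene, dm$gene_ids) else as.integer(gene)
  if (is.na(gi)) stop("unknown gene: ", gene)
  hm <- hub_matrix(dm, hub_fraction)
  in_t <- labels == target_label
  is_hub <- hm[gi, ]
  a <- sum(in_t & is_hub); b <- sum(in_t & !is_hub)
  c_ <- sum(!in_t & is_hub); d <- sum(!in_t & !is_hub)
  res <- fisher_greater(a, b, c_, d)
  if (alternative == "two.sided") {
    res$p_value <- stats::fisher.test(matrix(c(a, c_, b, d), 2L))$p.value
  }
  res
}

#' Edge enrichment of a gene pair in a cell type
#'
#' As [hub_enrichment()], with the 2x2 table built on presence/absence of
#' the given edge in each cell's network.
#'
#' @param edge Character vector of two gene identifiers (or two indices).
#' @inheritParams hub_enrichment
#' @return An `enrichment_result`.
#' @export
edge_enrichment <- function(edge, scns, cell_labels, target_label,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(scns, "scn_set"))
  if (length(edge) != 2L) stop("'edge' must name exactly two genes")
  labels <- resolve_labels(cell_labels, scns$cell_ids)
  if (!target_label %in% labels) {
    stop("target label '", target_label, "' not present among cell labels")
  }
  present <- edge_presence(scns, edge[[1L]], edge[[2L]])
  in_t <- labels == target_label
  a <- sum(in_t & present); b <- sum(in_t & !present)
  c_ <- sum(!in_t & present); d <- sum(!in_t & !present)
  res <- fisher_greater(a, b, c_, d)
  if (alternative == "two.sided") {
    res$p_value <- stats::fisher.test(matrix(c(a, c_, b, d), 2L))$p.value
  }
  res
}

#' Screen for cell-type marker genes with network-level signal
#'
#' Finds "dark" marker genes: genes that are hubs of the target type's
#' networks significantly more often than elsewhere (one-sided Fisher test,
#' Benjamini-Hochberg adjusted across genes, adjusted p below `alpha`)
#' while showing no detectable expression difference between the target
#' type and the rest (two-sided Wilcoxon rank-sum p of at least `alpha`,
#' unadjusted, which is conservative for declaring "no difference").
#' Genes are ranked by enrichment odds ratio, descending.
#'
#' @param dm A `degree_matrix`.
#' @param gem The matching [expression_matrix()] (any scale) used for the
#'   expression-difference filter.
#' @param cell_labels Per-cell labels (named by cell id or in cell order).
#' @param target_label Label of the cell type of interest.
#' @param alpha Significance level for both sub-tests; default 0.05.
#' @param hub_fraction Top-degree fraction defining hubs; default 0.25.
#' @return Data frame with one row per screened gene: `gene`, `odds_ratio`,
#'   `p_hub` (raw), `p_hub_adj` (BH), `p_expr`, `is_marker`; marker rows
#'   first, sorted by decreasing odds ratio. The marker subset is also
#'   available as `attr(, "markers")`.
#' @export
marker_screen <- function(dm, gem, cell_labels, target_label,
                          alpha = 0.05, hub_fraction = 0.25) {
  stopifnot(inherits(dm, "degree_matrix"))
  stopifnot_gem(gem)
  if (!identical(dm$cell_ids, gem$cell_ids) ||
      !identical(dm$gene_ids, gem$gene_ids)) {
    stop("degree matrix and expression matrix are not aligned")
  }
  labels <- resolve_labels(cell_labels, dm$cell_ids)
  if (!target_label %in% labels) {
    stop("target label '", target_label, "' not present among cell labels")
  }
  in_t <- labels == target_label
  hm <- hub_matrix(dm, hub_fraction)
  m <- nrow(hm)
  ors <- numeric(m)
  p_hub <- numeric(m)
  p_expr <- numeric(m)
  for (g in seq_len(m)) {
    is_hub <- hm[g, ]
    a <- sum(in_t & is_hub); b <- sum(in_t & !is_hub)
    c_ <- sum(!in_t & is_hub); d <- sum(!in_t & !is_hub)
    fr <- fisher_greater(a, b, c_, d)
    ors[g] <- fr$odds_ratio
    p_hub[g] <- fr$p_value
    expr <- gem$values[g, ]
    p_expr[g] <- tryCatch(
      stats::wilcox.test(expr[in_t], expr[!in_t], exact = FALSE)$p.value,
      error = function(e) 1)
    if (is.na(p_expr[g])) p_expr[g] <- 1
  }
  p_adj <- stats::p.adjust(p_hub, method = "BH")
  is_marker <- p_adj < alpha & p_expr >= alpha
  out <- data.frame(gene = dm$gene_ids, odds_ratio = ors, p_hub = p_hub,
                    p_hub_adj = p_adj, p_expr = p_expr,
                    is_marker = is_marker, stringsAsFactors = FALSE)
  out <- out[order(-out$is_marker, -out$odds_ratio, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "markers") <- out$gene[out$is_marker]
  out
}

#' Aggregate network of a cell group
#'
#' Collapses the per-cell networks of all cells carrying a given label
#' (e.g. a time point) into one network: an edge is kept when it is present
#' in strictly more than `min_fraction` of that group's cells. Presence
#' frequencies are reported for every kept edge.
#'
#' @param scns An `scn_set`.
#' @param cell_labels Per-cell labels (named by cell id or in cell order).
#' @param label The group to aggregate.
#' @param min_fraction Frequency threshold (strict); default 0.7.
#' @param gene_subset Optional gene identifiers restricting the edge
#'   universe.
#' @return An `aggregate_network`: list with `label`, `n_cells` and `edges`
#'   (data frame `gene_a`, `gene_b`, `frequency`).
#' @export
aggregate_network <- function(scns, cell_labels, label, min_fraction = 0.7,
                              gene_subset = NULL) {
  stopifnot(inherits(scns, "scn_set"))
  labels <- resolve_labels(cell_labels, scns$cell_ids)
  if (!label %in% labels) stop("label '", label, "' not present")
  if (min_fraction < 0 || min_fraction >= 1) {
    stop("'min_fraction' must be in [0, 1)")
  }
  cells <- which(labels == label)
  nc <- length(cells)
  ed <- scns$edges[scns$edges$cell %in% cells, , drop = FALSE]
  if (!is.null(gene_subset)) {
    gidx <- match(gene_subset, scns$gene_ids)
    gidx <- gidx[!is.na(gidx)]
    if (length(gidx) < 2L) {
      stop("'gene_subset' maps to fewer than two genes")
    }
    ed <- ed[ed$gene_i %in% gidx & ed$gene_j %in% gidx, , drop = FALSE]
  }
  key <- paste(ed$gene_i, ed$gene_j)
  cnt <- table(key)
  freq <- as.numeric(cnt) / nc
  keep <- freq > min_fraction
  ij <- strsplit(names(cnt)[keep], " ", fixed = TRUE)
  gi <- as.integer(vapply(ij, `[`, "", 1L))
  gj <- as.integer(vapply(ij, `[`, "", 2L))
  ga <- scns$gene_ids[gi]
  gb <- scns$gene_ids[gj]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  edges <- data.frame(gene_a = ga, gene_b = gb,
                      frequency = freq[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(label = label, n_cells = nc, edges = edges),
            class = "aggregate_network")
}

#' @exportS3Method print aggregate_network
print.aggregate_network <- function(x, ...) {
  cat(sprintf("aggregate_network '%s': %d cells, %d edges\n",
              x$label, x$n_cells, nrow(x$edges)))
  invisible(x)
}

#' Mean network degree per gene per label
#'
#' Summarises a degree matrix across a label axis (e.g. time points): the
#' mean degree of every requested gene within every label, plus the label
#' where each gene's mean degree peaks (ties resolved toward the
#' lexicographically first label and flagged).
#'
#' @param dm A `degree_matrix`.
#' @param cell_labels Per-cell labels (named by cell id or in cell order).
#' @param genes Gene identifiers to summarise; default all.
#' @return List with `means` (genes x labels matrix), `argmax` (data frame
#'   `gene`, `label`, `tied`), and `per_cell` (long data frame `gene`,
#'   `label`, `cell_id`, `degree` for violin-style export).
#' @export
degree_trajectory <- function(dm, cell_labels, genes = NULL) {
  stopifnot(inherits(dm, "degree_matrix"))
  labels <- resolve_labels(cell_labels, dm$cell_ids)
  if (is.null(genes)) genes <- dm$gene_ids
  gidx <- match(genes, dm$gene_ids)
  if (anyNA(gidx)) {
    stop("unknown gene(s): ",
         paste(genes[is.na(gidx)], collapse = ", "))
  }
  labs <- sort(unique(labels))
  v <- dm$values[gidx, , drop = FALSE]
  means <- vapply(labs, function(l) rowMeans(v[, labels == l, drop = FALSE]),
                  numeric(length(gidx)))
  means <- matrix(means, nrow = length(gidx),
                  dimnames = list(genes, labs))
  top <- apply(means, 1L, function(r) {
    mx <- max(r)
    w <- labs[r == mx]
    c(label = w[1L], tied = as.character(length(w) > 1L))
  })
  argmax <- data.frame(gene = genes, label = top["label", ],
                       tied = as.logical(top["tied", ]),
                       stringsAsFactors = FALSE)
  rownames(argmax) <- NULL
  per_cell <- data.frame(
    gene = rep(genes, times = ncol(v)),
    label = rep(labels, each = length(genes)),
    cell_id = rep(dm$cell_ids, each = length(genes)),
    degree = as.vector(v), stringsAsFactors = FALSE)
  list(means = means, argmax = argmax, per_cell = per_cell)
}
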