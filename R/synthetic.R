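# Synthetic single-cell expression data with known per-cell dependency
# structure: planted cell types, gene modules coordinated only within
# their active types (Gaussian copula over negative-binomial marginals),
# independent dropout, and "dark" modules whose marginal expression is
# identical across types so only the dependency structure separates them.

#' Specify a synthetic single-cell dataset
#'
#' A module is a disjoint set of genes that is co-expressed (pairwise
#' latent correlation `rho`) in the cells of its active types and fully
#' independent elsewhere. A module with `mean_factor = 1` is "dark": its
#' genes keep identical marginal distributions in every type (only the
#' copula differs), so it is invisible to differential expression but not
#' to network degree. A `mean_factor > 1` additionally scales the module
#' genes' negative-binomial mean in active types, giving an ordinary
#' expression marker.
#'
#' @param n_cells Total number of cells.
#' @param n_genes Total number of genes.
#' @param n_types Number of cell types.
#' @param type_proportions Simplex vector of type proportions (default
#'   balanced).
#' @param modules List of modules, each a list with `genes` (integer
#'   indices), `active_types` (integer indices), `rho` in `(0, 1)`, and
#'   optional `mean_factor >= 1` (default 1). Gene sets must be disjoint.
#' @param dropout_rate Probability that any entry is independently zeroed;
#'   in `[0, 1)`. Default 0.05, chosen so that the realized count-scale
#'   correlation of a planted module stays close to its nominal `rho`
#'   (independent zeroing attenuates it; see the methods vignette).
#' @param nb_mean,nb_dispersion Negative-binomial mean and size (shape)
#'   parameters of the count marginals. Defaults 8 and 2
#'   (variance `mu + mu^2/size`, i.e. clearly overdispersed).
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_cells, n_genes, n_types = 1L,
                           type_proportions = rep(1 / n_types, n_types),
                           modules = list(), dropout_rate = 0.05,
                           nb_mean = 8, nb_dispersion = 2, seed = 1L) {
  n_cells <- as.integer(n_cells)
  n_genes <- as.integer(n_genes)
  n_types <- as.integer(n_types)
  if (n_cells < 2L || n_genes < 2L) stop("need at least 2 cells and 2 genes")
  if (n_types < 1L || n_types > n_cells) stop("invalid 'n_types'")
  if (length(type_proportions) != n_types ||
      abs(sum(type_proportions) - 1) > 1e-9 || any(type_proportions <= 0)) {
    stop("'type_proportions' must be positive and sum to 1")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("'dropout_rate' must be in [0, 1)")
  }
  if (nb_mean <= 0 || nb_dispersion <= 0) {
    stop("'nb_mean' and 'nb_dispersion' must be positive")
  }
  seen <- integer(0)
  for (mod in modules) {
    if (is.null(mod$genes) || is.null(mod$active_types) || is.null(mod$rho)) {
      stop("each module needs 'genes', 'active_types' and 'rho'")
    }
    g <- as.integer(mod$genes)
    if (any(g < 1L | g > n_genes)) stop("module gene index out of range")
    if (length(g) < 2L) stop("a module needs at least two genes")
    if (any(g %in% seen)) stop("module gene sets must be disjoint")
    seen <- c(seen, g)
    at <- as.integer(mod$active_types)
    if (any(at < 1L | at > n_types)) stop("module active type out of range")
    if (mod$rho <= 0 || mod$rho >= 1) stop("module 'rho' must be in (0, 1)")
    mf <- if (is.null(mod$mean_factor)) 1 else mod$mean_factor
    if (mf < 1) stop("'mean_factor' must be >= 1")
  }
  structure(list(n_cells = n_cells, n_genes = n_genes, n_types = n_types,
                 type_proportions = type_proportions, modules = modules,
                 dropout_rate = dropout_rate, nb_mean = nb_mean,
                 nb_dispersion = nb_dispersion, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic expression matrix with known truth
#'
#' Cells are assigned to types in blocks sized by the type proportions.
#' For each cell type, module genes active in that type are drawn from an
#' equicorrelated Gaussian copula (pairwise latent correlation `rho`),
#' every other gene from an independent standard normal; the latent values
#' are mapped through their normal CDF onto negative-binomial quantiles
#' (mean `nb_mean * mean_factor` for active module genes, `nb_mean`
#' otherwise; size `nb_dispersion`), and finally zeroed independently with
#' probability `dropout_rate`. The marginal distribution of a dark-module
#' gene (`mean_factor = 1`) is therefore identical in every type.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `gem` (raw-scale [expression_matrix()]) and `truth`
#'   (`synthetic_truth`: `cell_labels`, `dependent_pairs_per_type`,
#'   `dark_genes`, `module_genes`).
#' @export
synthetic_generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  m <- spec$n_genes

  sizes <- floor(spec$type_proportions * n)
  rem <- n - sum(sizes)
  if (rem > 0) {  # distribute the remainder over the first types
    sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  }
  type_of <- rep(seq_len(spec$n_types), times = sizes)
  cell_labels <- paste0("type", type_of)

  active <- matrix(FALSE, length(spec$modules), spec$n_types)
  for (i in seq_along(spec$modules)) {
    active[i, spec$modules[[i]]$active_types] <- TRUE
  }

  z <- matrix(stats::rnorm(m * n), m, n)
  mu <- matrix(spec$nb_mean, m, n)
  for (i in seq_along(spec$modules)) {
    mod <- spec$modules[[i]]
    g <- as.integer(mod$genes)
    mf <- if (is.null(mod$mean_factor)) 1 else mod$mean_factor
    for (ty in mod$active_types) {
      cols <- which(type_of == ty)
      shared <- stats::rnorm(length(cols))
      lam <- sqrt(mod$rho)
      z[g, cols] <- lam * matrix(shared, length(g), length(cols),
                                 byrow = TRUE) +
        sqrt(1 - mod$rho) * matrix(stats::rnorm(length(g) * length(cols)),
                                   length(g), length(cols))
      mu[g, cols] <- spec$nb_mean * mf
    }
  }
  u <- stats::pnorm(z)
  counts <- matrix(stats::qnbinom(as.vector(u), mu = as.vector(mu),
                                  size = spec$nb_dispersion), m, n)
  if (spec$dropout_rate > 0) {
    drop <- matrix(stats::runif(m * n) < spec$dropout_rate, m, n)
    counts[drop] <- 0
  }
  gene_ids <- sprintf("g%03d", seq_len(m))
  cell_ids <- sprintf("c%04d", seq_len(n))
  gem <- expression_matrix(counts, gene_ids = gene_ids, cell_ids = cell_ids)
  labels <- stats::setNames(cell_labels, cell_ids)

  dep_pairs <- vector("list", spec$n_types)
  names(dep_pairs) <- paste0("type", seq_len(spec$n_types))
  for (ty in seq_len(spec$n_types)) {
    prs <- list()
    for (i in seq_along(spec$modules)) {
      if (!active[i, ty]) next
      g <- sort(as.integer(spec$modules[[i]]$genes))
      cmb <- utils::combn(g, 2L)
      prs[[length(prs) + 1L]] <- t(cmb)
    }
    dep_pairs[[ty]] <- if (length(prs)) do.call(rbind, prs) else
      matrix(integer(), 0L, 2L)
  }
  dark <- integer(0)
  module_genes <- integer(0)
  for (mod in spec$modules) {
    mf <- if (is.null(mod$mean_factor)) 1 else mod$mean_factor
    module_genes <- c(module_genes, as.integer(mod$genes))
    if (mf == 1) dark <- c(dark, as.integer(mod$genes))
  }
  truth <- structure(list(cell_labels = labels,
                          dependent_pairs_per_type = dep_pairs,
                          dark_genes = sort(dark),
                          module_genes = sort(module_genes)),
                     class = "synthetic_truth")
  list(gem = gem, truth = truth)
}

#' Fully independent synthetic expression matrix
#'
#' Special case of [synthetic_generate()] with no modules: every gene is
#' independent of every other. Used for false-positive calibration.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param seed Integer seed.
#' @param ... Passed to [synthetic_spec()] (e.g. `dropout_rate`).
#' @return A raw-scale [expression_matrix()].
#' @export
synthetic_null_matrix <- function(n_cells, n_genes, seed = 1L, ...) {
  spec <- synthetic_spec(n_cells = n_cells, n_genes = n_genes,
                         n_types = 1L, modules = list(), seed = seed, ...)
  synthetic_generate(spec)$gem
}

#' Preset: three cell types marked by expressed co-expression modules
#'
#' Study conditions used throughout the package's validation: 3 balanced
#' cell types of 150 cells each, 60 genes, one 10-gene module per type
#' (latent correlation 0.8) whose mean is raised 3-fold in the active type,
#' dropout 0.05.
#'
#' @param seed Integer seed.
#' @param rho Module latent correlation; default 0.8.
#' @param mean_factor Mean scaling of module genes in their active type;
#'   default 3. Set to 1 for the dark (structure-only) variant.
#' @return A `synthetic_spec`.
#' @export
synthetic_modules_spec <- function(seed = 1L, rho = 0.8, mean_factor = 3) {
  synthetic_spec(
    n_cells = 450L, n_genes = 60L, n_types = 3L,
    modules = list(
      list(genes = 1:10, active_types = 1L, rho = rho,
           mean_factor = mean_factor),
      list(genes = 11:20, active_types = 2L, rho = rho,
           mean_factor = mean_factor),
      list(genes = 21:30, active_types = 3L, rho = rho,
           mean_factor = mean_factor)),
    dropout_rate = 0.05, nb_mean = 8, nb_dispersion = 2, seed = seed)
}

#' Preset: three cell types separated only by network structure
#'
#' As [synthetic_modules_spec()] but with `mean_factor = 1`: module genes
#' keep identical expression marginals in every type ("dark genes"), so
#' clustering the expression matrix carries no type signal while the
#' network degree matrix does.
#'
#' @param seed Integer seed.
#' @param rho Module latent correlation; default 0.8.
#' @return A `synthetic_spec`.
#' @export
synthetic_dark_spec <- function(seed = 1L, rho = 0.8) {
  synthetic_modules_spec(seed = seed, rho = rho, mean_factor = 1)
}

#' Preset: one dark marker module in one of two cell types
#'
#' Two balanced types of 150 cells, 40 genes, one 8-gene dark module
#' (latent correlation 0.8) active in `type1` only. The module genes are
#' hubs of `type1` networks but show no expression difference - the
#' planted truth for the marker screen.
#'
#' @param seed Integer seed.
#' @param rho Module latent correlation; default 0.8.
#' @return A `synthetic_spec`.
#' @export
synthetic_marker_spec <- function(seed = 1L, rho = 0.8) {
  synthetic_spec(
    n_cells = 300L, n_genes = 40L, n_types = 2L,
    modules = list(
      list(genes = 1:8, active_types = 1L, rho = rho, mean_factor = 1)),
    dropout_rate = 0.05, nb_mean = 8, nb_dispersion = 2, seed = seed)
}

#' Write a synthetic dataset to disk
#'
#' Writes the expression matrix (TSV), the cell labels (TSV) and the
#' planted truth (JSON) into a directory.
#'
#' @param sim Output of [synthetic_generate()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(sim$gem, file.path(dir, "gem.tsv"))
  utils::write.table(
    data.frame(cell_id = names(sim$truth$cell_labels),
               label = unname(sim$truth$cell_labels)),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  truth <- list(
    dark_genes = sim$gem$gene_ids[sim$truth$dark_genes],
    module_genes = sim$gem$gene_ids[sim$truth$module_genes],
    dependent_pairs_per_type = lapply(
      sim$truth$dependent_pairs_per_type,
      function(p) if (nrow(p)) matrix(sim$gem$gene_ids[p], ncol = 2L) else
        matrix(character(), 0L, 2L)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"))
  invisible(dir)
}
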