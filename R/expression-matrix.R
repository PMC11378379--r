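#' Construct an expression matrix object
#'
#' The gene expression matrix (GEM) is the central input container: an
#' `m` genes by `n` cells non-negative matrix with unique gene and cell
#' identifiers and a flag recording whether values are on the
#' log2(x + 1) scale.
#'
#' @param values Numeric matrix, genes as rows, cells as columns. Must be
#'   non-negative with no missing values. Raw counts and continuous
#'   abundance units (TPM/FPKM) are both accepted.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#'   Defaults to `rownames(values)`.
#' @param cell_ids Character vector of unique cell identifiers, one per
#'   column. Defaults to `colnames(values)`.
#' @param is_log_transformed Logical; `TRUE` once [log_transform()] has been
#'   applied.
#'
#' @return An object of class `"expression_matrix"`: a list with elements
#'   `values`, `gene_ids`, `cell_ids` and `is_log_transformed`.
#' @seealso [load_expression_matrix()], [filter_low_genes()],
#'   [log_transform()]
#' @export
#' @examples
#' m <- matrix(rpois(12, 5), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' gem <- expression_matrix(m)
#' dim(gem)
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              is_log_transformed = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) {
    gene_ids <- paste0("gene", seq_len(nrow(values)))
  }
  if (is.null(cell_ids)) {
    cell_ids <- paste0("cell", seq_len(ncol(values)))
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("length of 'gene_ids' (", length(gene_ids),
         ") does not match the number of rows (", nrow(values), ")")
  }
  if (length(cell_ids) != ncol(values)) {
    stop("length of 'cell_ids' (", length(cell_ids),
         ") does not match the number of columns (", ncol(values), ")")
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicated gene identifiers: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (anyDuplicated(cell_ids)) {
    dup <- unique(cell_ids[duplicated(cell_ids)])
    stop("duplicated cell identifiers: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (any(values < 0)) stop("expression matrix contains negative values")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values,
                 gene_ids = gene_ids,
                 cell_ids = cell_ids,
                 is_log_transformed = isTRUE(is_log_transformed)),
            class = "expression_matrix")
}

#' @exportS3Method dim expression_matrix
dim.expression_matrix <- function(x) dim(x$values)

#' @exportS3Method print expression_matrix
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_log_transformed) "log2(x+1) scale" else "raw scale"))
  invisible(x)
}

#' @exportS3Method as.matrix expression_matrix
as.matrix.expression_matrix <- function(x, ...) x$values

n_genes <- function(gem) nrow(gem$values)
n_cells <- function(gem) ncol(gem$values)

stopifnot_gem <- function(gem) {
  if (!inherits(gem, "expression_matrix")) {
    stop("expected an 'expression_matrix' object; got ",
         paste(class(gem), collapse = "/"))
  }
  invisible(gem)
}

#' Filter genes detected in too few cells
#'
#' Removes genes with nonzero (detected) expression in fewer than
#' `min_cells` cells, the standard dropout-driven gene filter for
#' single-cell data. Zero values are treated as dropouts, i.e. "not
#' expressed". The filter operates on the raw (pre-log) matrix.
#'
#' @param gem An [expression_matrix()] with `is_log_transformed = FALSE`.
#' @param min_cells Minimum number of cells in which a gene must be
#'   detected (value strictly greater than zero) to be retained.
#'   Default 10.
#'
#' @return An `expression_matrix` containing the retained genes in their
#'   original order; the cell axis is unchanged.
#' @export
filter_low_genes <- function(gem, min_cells = 10L) {
  stopifnot_gem(gem)
  if (gem$is_log_transformed) {
    stop("filter_low_genes() must run on the raw matrix, before log_transform()")
  }
  min_cells <- as.integer(min_cells)
  if (length(min_cells) != 1L || is.na(min_cells) || min_cells < 0L) {
    stop("'min_cells' must be a single non-negative integer")
  }
  detected <- rowSums(gem$values > 0)
  keep <- detected >= min_cells
  if (!any(keep)) {
    stop("no gene is detected in at least ", min_cells,
         " cells; nothing survives the filter")
  }
  expression_matrix(gem$values[keep, , drop = FALSE],
                    gene_ids = gem$gene_ids[keep],
                    cell_ids = gem$cell_ids,
                    is_log_transformed = FALSE)
}

#' Log-transform an expression matrix
#'
#' Applies `log2(v + 1)` entrywise (pseudocount of one). Transforming an
#' already-transformed matrix is an error: the flag on the object guards
#' against accidental double transformation.
#'
#' @param gem An [expression_matrix()] on the raw scale.
#' @return The transformed `expression_matrix` with
#'   `is_log_transformed = TRUE`.
#' @export
log_transform <- function(gem) {
  stopifnot_gem(gem)
  if (gem$is_log_transformed) {
    stop("matrix is already log-transformed")
  }
  expression_matrix(log2(gem$values + 1),
                    gene_ids = gem$gene_ids,
                    cell_ids = gem$cell_ids,
                    is_log_transformed = TRUE)
}

#' Select the most variable genes
#'
#' Keeps the `k` genes with the highest variance across cells, a generic
#' stand-in for model-based feature selection when the pair-wise network
#' inference would otherwise be too expensive on the full gene set.
#' Original gene order is preserved; variance ties at the cutoff are
#' broken by lexicographic gene identifier so the selection is
#' deterministic.
#'
#' @param gem An [expression_matrix()].
#' @param k Number of genes to retain; must not exceed the number of genes.
#' @return An `expression_matrix` with `k` genes.
#' @export
select_top_variable_genes <- function(gem, k) {
  stopifnot_gem(gem)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) {
    stop("'k' must be a single positive integer")
  }
  m <- n_genes(gem)
  if (k > m) stop("'k' (", k, ") exceeds the number of genes (", m, ")")
  v <- apply(gem$values, 1L, stats::var)
  ord <- order(-v, gem$gene_ids)   # variance desc, then gene id asc
  keep_idx <- sort(ord[seq_len(k)])  # preserve original order
  expression_matrix(gem$values[keep_idx, , drop = FALSE],
                    gene_ids = gem$gene_ids[keep_idx],
                    cell_ids = gem$cell_ids,
                    is_log_transformed = gem$is_log_transformed)
}
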