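#' Load an expression matrix from disk
#'
#' Reads a gene expression matrix in one of three plain-text layouts:
#'
#' * `"tsv"` / `"csv"`: genes as rows, cells as columns; the first column
#'   holds gene identifiers and the header row holds cell identifiers (the
#'   first header field is ignored).
#' * `"mtx"`: MatrixMarket coordinate format with 1-based indices, read
#'   with [Matrix::readMM()]; requires sibling files `genes.txt` and
#'   `cells.txt` (one identifier per line) in the same directory.
#'
#' @param path Path to the matrix file.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`. Default guesses from the
#'   file extension.
#' @return An [expression_matrix()] on the raw scale
#'   (`is_log_transformed = FALSE`).
#' @export
load_expression_matrix <- function(path,
                                   format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     stop("cannot guess format from extension '.", ext,
                          "'; pass 'format' explicitly"))
  }
  if (format == "mtx") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("failed to parse MatrixMarket file '",
                                           path, "': ", conditionMessage(e)))
    dirn <- dirname(path)
    gene_file <- file.path(dirn, "genes.txt")
    cell_file <- file.path(dirn, "cells.txt")
    if (!file.exists(gene_file) || !file.exists(cell_file)) {
      stop("MTX input requires sibling 'genes.txt' and 'cells.txt' in ", dirn)
    }
    gene_ids <- readLines(gene_file)
    cell_ids <- readLines(cell_file)
    gene_ids <- gene_ids[nzchar(gene_ids)]
    cell_ids <- cell_ids[nzchar(cell_ids)]
    if (length(gene_ids) != nrow(m)) {
      stop("genes.txt lists ", length(gene_ids), " ids but matrix has ",
           nrow(m), " rows")
    }
    if (length(cell_ids) != ncol(m)) {
      stop("cells.txt lists ", length(cell_ids), " ids but matrix has ",
           ncol(m), " columns")
    }
    return(expression_matrix(as.matrix(m), gene_ids = gene_ids,
                             cell_ids = cell_ids))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                      colClasses = NA, comment.char = "",
                      stringsAsFactors = FALSE, quote = "\""),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e)))
  if (ncol(df) < 2L) {
    stop("matrix file '", path,
         "' has fewer than two columns; wrong separator?")
  }
  gene_ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1L)))[1L]
    stop("non-numeric expression values in column ", bad + 1L,
         " of '", path, "'")
  }
  expression_matrix(vals, gene_ids = gene_ids, cell_ids = colnames(vals))
}

#' Read a two-column cell label file
#'
#' @param path TSV with two columns: cell identifier and label (cell type
#'   or time point). A header line is detected and skipped when its first
#'   field is `cell_id`.
#' @return Named character vector of labels, names are cell identifiers.
#' @export
load_cell_labels <- function(path) {
  if (!file.exists(path)) stop("label file does not exist: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (ncol(df) < 2L) stop("label file must have two tab-separated columns")
  if (identical(tolower(df[1L, 1L]), "cell_id")) df <- df[-1L, , drop = FALSE]
  labels <- as.character(df[[2L]])
  names(labels) <- as.character(df[[1L]])
  if (anyDuplicated(names(labels))) stop("duplicated cell ids in label file")
  labels
}

#' Read a reference network edge list
#'
#' Two-column TSV of gene symbols (one undirected edge per line), `#`
#' comments allowed. Self-loops are dropped; duplicate unordered pairs are
#' collapsed.
#'
#' @param path Path to the edge-list file.
#' @param upper_case Harmonize symbols to upper case before matching
#'   (human gene symbol convention). Default `FALSE`: matching elsewhere in
#'   the package is exact and case-sensitive.
#' @return A `reference_network` object (see [reference_network()]).
#' @export
load_reference_network <- function(path, upper_case = FALSE) {
  if (!file.exists(path)) stop("edge-list file does not exist: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (ncol(df) < 2L) stop("edge list must have two tab-separated columns")
  a <- as.character(df[[1L]])
  b <- as.character(df[[2L]])
  if (upper_case) {
    a <- toupper(a)
    b <- toupper(b)
  }
  reference_network(a, b)
}

#' Write per-cell network edges as a TSV table
#'
#' One row per (cell, edge): columns `cell_id`, `gene_a`, `gene_b`, `z`,
#' with `gene_a < gene_b` lexicographically.
#'
#' @param scns An `scn_set` from [infer_scns()].
#' @param path Output file; `.gz` suffix triggers gzip compression.
#' @return Invisibly, the path.
#' @export
write_scn_table <- function(scns, path) {
  stopifnot(inherits(scns, "scn_set"))
  ed <- scns$edges
  ga <- scns$gene_ids[ed$gene_i]
  gb <- scns$gene_ids[ed$gene_j]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  out <- data.frame(cell_id = scns$cell_ids[ed$cell],
                    gene_a = ga, gene_b = gb, z = ed$z,
                    stringsAsFactors = FALSE)
  out <- out[order(out$cell_id, out$gene_a, out$gene_b), , drop = FALSE]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a degree matrix as TSV
#'
#' Genes as rows, cells as columns, identifiers in the same order as the
#' source expression matrix; first column `gene_id`.
#'
#' @param dm A `degree_matrix` object.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_degree_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "degree_matrix"))
  df <- data.frame(gene_id = dm$gene_ids, dm$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", dm$cell_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' @param gem An [expression_matrix()].
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_expression_matrix <- function(gem, path) {
  stopifnot_gem(gem)
  df <- data.frame(gene_id = gem$gene_ids, gem$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", gem$cell_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
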