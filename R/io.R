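#' Construct a raw count matrix container
#'
#' The single source input of the pipeline: a cells-in-rows matrix of
#' non-negative integer counts with unique cell and gene identifiers and an
#' optional per-cell label vector.
#'
#' @param counts numeric matrix, cells x genes, non-negative integers.
#' @param cell_ids character vector of unique cell identifiers (rows).
#' @param gene_ids character vector of unique gene identifiers (columns).
#' @param labels optional per-cell class labels (character or factor).
#' @return An object of class `RawCountMatrix`.
#' @export
raw_count_matrix <- function(counts, cell_ids, gene_ids, labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != length(cell_ids))
    stop("counts has ", nrow(counts), " rows but ", length(cell_ids),
         " cell ids")
  if (ncol(counts) != length(gene_ids))
    stop("counts has ", ncol(counts), " columns but ", length(gene_ids),
         " gene ids")
  if (anyDuplicated(cell_ids)) stop("duplicated cell ids")
  if (anyDuplicated(gene_ids)) stop("duplicated gene ids")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("non-integer counts are not allowed")
  if (!is.null(labels) && length(labels) != nrow(counts))
    stop("labels length must equal the number of cells")
  dimnames(counts) <- list(as.character(cell_ids), as.character(gene_ids))
  structure(list(counts = counts,
                 cell_ids = as.character(cell_ids),
                 gene_ids = as.character(gene_ids),
                 labels = if (is.null(labels)) NULL else as.character(labels)),
            class = "RawCountMatrix")
}

#' @export
print.RawCountMatrix <- function(x, ...) {
  cat("RawCountMatrix:", nrow(x$counts), "cells x", ncol(x$counts), "genes;",
      sprintf("%.1f%% non-zero", 100 * sparsity(x)),
      if (!is.null(x$labels)) paste0("; ", length(unique(x$labels)), " labels"),
      "\n")
  invisible(x)
}

#' Read a count matrix from disk
#'
#' Supports Matrix Market triplet files (with companion plain-text gene and
#' cell identifier files, one id per line) and dense CSV with gene ids in the
#' header and cell ids in the first column. MTX files stored genes x cells
#' are auto-transposed when the identifier file lengths disambiguate the
#' orientation.
#'
#' @param path path to the `.mtx` or `.csv` file.
#' @param format `"mtx"` or `"csv"`; guessed from the extension by default.
#' @param gene_file,cell_file identifier files for the MTX dialect; default
#'   `<stem>.genes.txt` and `<stem>.cells.txt` next to `path`.
#' @return A [raw_count_matrix()].
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv"),
                        gene_file = NULL, cell_file = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("parse error: empty file ", path)
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    gene_file <- gene_file %||% paste0(stem, ".genes.txt")
    cell_file <- cell_file %||% paste0(stem, ".cells.txt")
    m <- tryCatch(as.matrix(Matrix::readMM(path)),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e)))
    genes <- readLines(gene_file)
    cells <- readLines(cell_file)
    if (nrow(m) == length(genes) && ncol(m) == length(cells) &&
        !(nrow(m) == length(cells) && ncol(m) == length(genes))) {
      m <- t(m)  # stored genes x cells
    }
    if (nrow(m) != length(cells) || ncol(m) != length(genes))
      stop("MTX dimensions ", nrow(m), "x", ncol(m),
           " do not match identifier files (", length(cells), " cells, ",
           length(genes), " genes)")
    raw_count_matrix(m, cells, genes)
  } else {
    df <- tryCatch(utils::read.csv(path, check.names = FALSE,
                                   stringsAsFactors = FALSE),
                   error = function(e) stop("parse error in ", path, ": ",
                                            conditionMessage(e)))
    if (ncol(df) < 2) stop("parse error: CSV needs cell-id column plus genes")
    cells <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    raw_count_matrix(m, cells, colnames(df)[-1])
  }
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()] for both dialects.
#'
#' @param raw a `RawCountMatrix`.
#' @param path output file path (`.mtx` or `.csv`).
#' @param format `"mtx"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(raw, path, format = c("auto", "mtx", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "csv"
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(raw$counts, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(raw$gene_ids, paste0(stem, ".genes.txt"))
    writeLines(raw$cell_ids, paste0(stem, ".cells.txt"))
  } else {
    df <- data.frame(cell_id = raw$cell_ids, raw$counts,
                     check.names = FALSE)
    colnames(df) <- c("cell_id", raw$gene_ids)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Log-transform a count matrix
#'
#' Applies `log1p` so the zero pattern of the counts is preserved exactly.
#' Optional per-cell depth scaling first rescales each cell's counts so its
#' total equals the median cell total.
#'
#' @param raw a `RawCountMatrix`.
#' @param scale_per_cell scale cells to the median total before the log
#'   (default `FALSE`).
#' @return An object of class `NormalizedMatrix` with fields `values`,
#'   `cell_ids`, `gene_ids`, `labels`.
#' @export
log_normalize <- function(raw, scale_per_cell = FALSE) {
  stopifnot(inherits(raw, "RawCountMatrix"))
  m <- raw$counts
  if (scale_per_cell) {
    tot <- rowSums(m)
    med <- stats::median(tot[tot > 0])
    if (any(tot == 0)) {
      warning(sum(tot == 0), " cell(s) with zero total left all-zero")
    }
    sf <- ifelse(tot > 0, med / tot, 0)
    m <- m * sf
  }
  structure(list(values = log1p(m),
                 cell_ids = raw$cell_ids,
                 gene_ids = raw$gene_ids,
                 labels = raw$labels),
            class = "NormalizedMatrix")
}

#' Discretize log expression into bin tokens
#'
#' Token 0 is reserved for zeros; the non-zero values are split into
#' `n_bins - 1` equal-width bins spanning the smallest positive value to the
#' matrix maximum, so tokens are monotone in the underlying value and the
#' maximum maps to the highest token.
#'
#' @param norm a `NormalizedMatrix`.
#' @param n_bins total number of tokens including the zero token (>= 2).
#' @return An object of class `BinnedMatrix` with integer `tokens` in
#'   `[0, n_bins - 1]`, `n_bins` and the `bin_edges` used.
#' @export
bin_expression <- function(norm, n_bins = 5) {
  stopifnot(inherits(norm, "NormalizedMatrix"), n_bins >= 2)
  v <- norm$values
  pos <- v[v > 0]
  tok <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  if (length(pos) == 0) {
    warning("all-zero matrix: every token is 0")
    edges <- c(0, 1)
  } else {
    lo <- min(pos)
    hi <- max(pos)
    if (hi <= lo) hi <- lo + 1e-8  # single distinct positive value
    width <- (hi - lo) / (n_bins - 1)
    nz <- v > 0
    t_nz <- 1L + as.integer(floor((v[nz] - lo) / width))
    t_nz[t_nz > n_bins - 1L] <- n_bins - 1L
    t_nz[t_nz < 1L] <- 1L
    tok[nz] <- t_nz
    edges <- seq(lo, hi, length.out = n_bins)
  }
  structure(list(tokens = tok, n_bins = as.integer(n_bins), bin_edges = edges,
                 cell_ids = norm$cell_ids, gene_ids = norm$gene_ids,
                 labels = norm$labels),
            class = "BinnedMatrix")
}

#' Fraction of non-zero entries
#'
#' Reports the non-zero occupancy of a count matrix (real droplet data sits
#' around 10 percent).
#'
#' @param raw a `RawCountMatrix` (or plain matrix).
#' @return Fraction of entries different from zero, in `[0, 1]`.
#' @export
sparsity <- function(raw) {
  m <- if (inherits(raw, "RawCountMatrix")) raw$counts else as.matrix(raw)
  sum(m != 0) / length(m)
}

#' Select the most variable genes of a normalized matrix
#'
#' @param norm a `NormalizedMatrix`.
#' @param n number of genes to keep.
#' @return Character vector of gene ids ordered by decreasing variance.
#' @export
top_variable_genes <- function(norm, n) {
  v <- apply(norm$values, 2L, stats::var)
  norm$gene_ids[order(v, decreasing = TRUE)][seq_len(min(n, length(v)))]
}
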