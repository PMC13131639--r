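#' Single-cell table
#'
#' Cells x genes counts with per-cell type labels, a log-normalized layer
#' (counts scaled to 10,000 per cell, then log1p) and a PCA embedding of
#' the normalized layer used for KNN smoothing.
#'
#' @param counts cells x genes matrix of non-negative integers with cell
#'   ids as rownames and gene ids as colnames.
#' @param cell_type character/factor label per cell.
#' @param embedding optional cells x d coordinate matrix; computed by PCA
#'   of the normalized layer when `NULL`.
#' @param embedding_dims embedding dimensionality when computed (default 20,
#'   capped by the data's rank).
#' @return An object of class `CellTable`: list with `counts`, `normalized`,
#'   `cell_type`, `cell_ids`, `gene_ids`, `embedding`.
#' @export
cell_table <- function(counts, cell_type, embedding = NULL, embedding_dims = 20L) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("cell%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("gene%05d", seq_len(ncol(counts)))
  if (length(cell_type) != nrow(counts)) stop("one cell type label per cell required")
  cell_type <- as.character(cell_type)
  lib <- rowSums(counts)
  lib[lib == 0] <- 1 # empty cells normalize to all-zero rather than NaN
  normalized <- log1p(counts / lib * 1e4)
  if (is.null(embedding)) {
    d <- min(embedding_dims, nrow(counts) - 1L, ncol(counts))
    centered <- sweep(normalized, 2L, colMeans(normalized))
    sv <- svd(centered, nu = d, nv = 0)
    embedding <- sv$u %*% diag(sv$d[seq_len(d)], d, d)
    rownames(embedding) <- rownames(counts)
  } else {
    embedding <- as.matrix(embedding)
    if (nrow(embedding) != nrow(counts)) stop("embedding rows must align with cells")
  }
  structure(list(counts = counts, normalized = normalized,
                 cell_type = cell_type, cell_ids = rownames(counts),
                 gene_ids = colnames(counts), embedding = embedding),
            class = "CellTable")
}

#' @export
print.CellTable <- function(x, ...) {
  cat(sprintf("CellTable: %d cells x %d genes, %d types, %d-d embedding\n",
              length(x$cell_ids), length(x$gene_ids),
              length(unique(x$cell_type)), ncol(x$embedding)))
  invisible(x)
}
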