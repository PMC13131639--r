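#' Expression matrix container
#'
#' A genes x samples numeric matrix with a layer tag distinguishing raw
#' counts from logCPM. Gene and sample identifiers must be unique; raw
#' counts must be non-negative integers and logCPM values finite.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are taken as gene/sample identifiers unless `gene_ids` /
#'   `sample_ids` are supplied.
#' @param layer `"raw_counts"` or `"logcpm"`.
#' @param gene_ids,sample_ids optional identifier vectors overriding dimnames.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `layer`.
#' @export
expression_matrix <- function(values, layer = c("raw_counts", "logcpm"),
                              gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required (dimnames or arguments)")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifier: ", gene_ids[duplicated(gene_ids)][1L])
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifier: ", sample_ids[duplicated(sample_ids)][1L])
  }
  storage.mode(values) <- "double"
  if (layer == "raw_counts") {
    if (any(values < 0) || any(values != round(values))) {
      stop("raw_counts layer requires non-negative integer entries")
    }
  } else if (any(!is.finite(values))) {
    stop("logcpm layer requires finite entries")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, layer = layer),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              length(x$gene_ids), length(x$sample_ids), x$layer))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

stop_parse <- function(line, fmt, ...) {
  stop(sprintf("line %d: %s", line, sprintf(fmt, ...)), call. = FALSE)
}

#' Read an expression matrix
#'
#' Reads a dense delimited matrix (genes in rows, first column gene id,
#' header row of sample ids) or a Matrix Market triplet with companion
#' gene/sample identifier files (one identifier per line).
#'
#' @param path file path; for `mtx_triplet` the `.mtx` file.
#' @param format `"dense_csv"` or `"mtx_triplet"`.
#' @param layer layer tag for the returned matrix (default `"raw_counts"`).
#' @param sep field separator for dense input; inferred from the extension
#'   (`.tsv`/`.txt` -> tab, otherwise comma) when `NULL`.
#' @param transpose if `TRUE`, dense input is samples-in-rows and is
#'   transposed after reading.
#' @param genes_path,samples_path identifier files for `mtx_triplet`;
#'   default `<path>.genes.txt` and `<path>.samples.txt`.
#' @return An [expression_matrix()] preserving input gene/sample order.
#' @export
read_expression <- function(path, format = c("dense_csv", "mtx_triplet"),
                            layer = "raw_counts", sep = NULL, transpose = FALSE,
                            genes_path = NULL, samples_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense_csv") {
    if (is.null(sep)) {
      sep <- if (grepl("\\.(tsv|txt)(\\.gz)?$", path)) "\t" else ","
    }
    lines <- readLines(path)
    if (length(lines) < 2L) stop_parse(1L, "expected a header and at least one data row")
    header <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
    if (length(header) < 2L) stop_parse(1L, "malformed header: fewer than two fields")
    ids_col <- character(length(lines) - 1L)
    vals <- matrix(NA_real_, nrow = length(lines) - 1L, ncol = length(header) - 1L)
    for (i in seq_along(ids_col)) {
      fields <- strsplit(lines[i + 1L], sep, fixed = TRUE)[[1L]]
      if (length(fields) != length(header)) {
        stop_parse(i + 1L, "expected %d fields, found %d", length(header), length(fields))
      }
      ids_col[i] <- fields[1L]
      v <- suppressWarnings(as.numeric(fields[-1L]))
      if (anyNA(v)) {
        bad <- fields[-1L][which(is.na(v))[1L]]
        stop_parse(i + 1L, "non-numeric cell '%s'", bad)
      }
      vals[i, ] <- v
    }
    if (anyDuplicated(ids_col)) {
      stop_parse(which(duplicated(ids_col))[1L] + 1L, "duplicate identifier '%s'",
                 ids_col[duplicated(ids_col)][1L])
    }
    col_ids <- header[-1L]
    if (anyDuplicated(col_ids)) {
      stop_parse(1L, "duplicate identifier '%s'", col_ids[duplicated(col_ids)][1L])
    }
    dimnames(vals) <- list(ids_col, col_ids)
    if (transpose) vals <- t(vals)
    expression_matrix(vals, layer = layer)
  } else {
    if (is.null(genes_path)) genes_path <- paste0(path, ".genes.txt")
    if (is.null(samples_path)) samples_path <- paste0(path, ".samples.txt")
    for (p in c(genes_path, samples_path)) {
      if (!file.exists(p)) stop("companion identifier file not found: ", p)
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_path)
    samples <- readLines(samples_path)
    if (nrow(m) != length(genes) || ncol(m) != length(samples)) {
      stop(sprintf("dimension mismatch: matrix is %d x %d but %d gene and %d sample ids supplied",
                   nrow(m), ncol(m), length(genes), length(samples)))
    }
    dimnames(m) <- list(genes, samples)
    expression_matrix(m, layer = layer)
  }
}

#' Write an expression matrix as dense CSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces doubles bit-identically.
#'
#' @param x an [expression_matrix()].
#' @param path output path.
#' @param sep field separator (default comma).
#' @export
write_expression <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  header <- paste(c("gene_id", x$sample_ids), collapse = sep)
  body <- vapply(seq_along(x$gene_ids), function(i) {
    paste(c(x$gene_ids[i], formatC(x$values[i, ], format = "g", digits = 17)),
          collapse = sep)
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' logCPM normalization
#'
#' Computes `log2(1e6 * count / library_size + pseudocount)` per entry,
#' where the library size is the column sum of raw counts. With the default
#' pseudocount of 1, zero counts map to exactly 0.
#'
#' @param x an [expression_matrix()] with layer `raw_counts`.
#' @param pseudocount positive number added inside the log (default 1).
#' @return An [expression_matrix()] with layer `logcpm`.
#' @export
log_cpm <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$layer != "raw_counts") stop("log_cpm expects the raw_counts layer")
  if (!is.numeric(pseudocount) || pseudocount < 0) stop("pseudocount must be non-negative")
  lib <- colSums(x$values)
  if (any(lib == 0)) {
    stop("zero library size for sample(s): ",
         paste(x$sample_ids[lib == 0], collapse = ", "))
  }
  v <- log2(sweep(x$values, 2L, lib / 1e6, "/") + pseudocount)
  expression_matrix(v, layer = "logcpm")
}

#' Read a sample metadata table
#'
#' Tab-separated with a header row; one row per sample. Requires a
#' `sample_id` column; recognises `d_oarsi`, `control_oarsi`, `kl_grade`
#' and `cluster` when present, and carries any further columns as clinical
#' covariates. Empty cells become `NA`; numeric parsing uses dot decimals.
#'
#' @param path TSV file path.
#' @return A `data.frame` with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata requires a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1L])
  }
  for (col in c("d_oarsi", "control_oarsi")) {
    if (col %in% names(df)) {
      if (any(df[[col]] < 0, na.rm = TRUE)) stop(col, " must be non-negative")
    }
  }
  df
}

#' Write a sample metadata table (TSV, empty cell for NA)
#' @param metadata data.frame with a `sample_id` column.
#' @param path output path.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
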