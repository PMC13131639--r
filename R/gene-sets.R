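#' Gene set collection
#'
#' @param sets named list of character vectors (gene symbols). Names must be
#'   unique; genes are deduplicated preserving first occurrence; empty sets
#'   are rejected.
#' @param source free-text provenance tag (e.g. "hallmark", "panglao").
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, source = "unknown") {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("all gene sets must be named")
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate set name: ", names(sets)[duplicated(names(sets))][1L])
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set: ", names(sets)[lengths(sets) == 0L][1L])
  }
  structure(list(sets = sets, source = source), class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection [%s]: %d sets, median size %g\n",
              x$source, length(x$sets), stats::median(lengths(x$sets))))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Tab-separated: set name, description (discarded), then gene symbols.
#' Duplicate genes within a set are collapsed; a line with fewer than three
#' fields is a parse error naming the line.
#'
#' @param path GMT file path.
#' @param source provenance tag stored on the collection.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop_parse(i, "GMT line has %d fields; expected name, description, >=1 gene",
                 length(fields))
    }
    nm <- fields[1L]
    if (nm %in% names(sets)) stop_parse(i, "duplicate set name '%s'", nm)
    sets[[nm]] <- unique(fields[-(1:2)])
  }
  gene_set_collection(sets, source = source)
}

#' Write gene sets in GMT format
#' @param x a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "GeneSetCollection"))
  lines <- vapply(names(x$sets), function(nm) {
    paste(c(nm, x$source, x$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
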