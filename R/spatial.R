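# Spatial cell-table composition summaries, per-type gene detection
# statistics, and zoom-region enrichment testing.

#' Spatial cell table
#'
#' Positioned, typed cells with per-gene transcript counts and region
#' membership. The region scheme assigns exactly one label per cell;
#' `"whole"` always refers to every cell.
#'
#' @param cells data.frame with columns `cell_id`, `x`, `y`, `cell_type`,
#'   `region`.
#' @param counts cells x genes matrix of non-negative integer transcript
#'   counts, rows aligned with `cells`.
#' @return An object of class `SpatialCellTable`.
#' @export
spatial_cell_table <- function(cells, counts) {
  req <- c("cell_id", "x", "y", "cell_type", "region")
  if (!all(req %in% names(cells))) {
    stop("cells must have columns: ", paste(req, collapse = ", "))
  }
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(cells)) stop("counts rows must align with cells")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(!is.finite(cells$x)) || any(!is.finite(cells$y))) {
    stop("coordinates must be finite")
  }
  if (anyNA(cells$region)) stop("every cell needs exactly one region label")
  structure(list(cells = cells, counts = counts, genes = colnames(counts)),
            class = "SpatialCellTable")
}

#' @export
print.SpatialCellTable <- function(x, ...) {
  cat(sprintf("SpatialCellTable: %d cells, %d panel genes, regions: %s\n",
              nrow(x$cells), length(x$genes),
              paste(sort(unique(x$cells$region)), collapse = ", ")))
  invisible(x)
}

#' Label a rectangular region over cell centroids
#'
#' @param table a [spatial_cell_table()].
#' @param rect c(xmin, ymin, xmax, ymax).
#' @param name label for cells inside the rectangle (default "zoom").
#' @param other label for the remaining cells (default "rest").
#' @return The table with its `region` column replaced.
#' @export
label_rect_region <- function(table, rect, name = "zoom", other = "rest") {
  stopifnot(inherits(table, "SpatialCellTable"), length(rect) == 4L)
  inside <- table$cells$x >= rect[1] & table$cells$x <= rect[3] &
    table$cells$y >= rect[2] & table$cells$y <= rect[4]
  table$cells$region <- ifelse(inside, name, other)
  table
}

scope_index <- function(table, scope) {
  if (identical(scope, "whole")) rep(TRUE, nrow(table$cells))
  else table$cells$region == scope
}

#' Cell-type composition of a region
#'
#' @param table a [spatial_cell_table()].
#' @param scope `"whole"` or a region label.
#' @return `data.frame`: cell_type, count, fraction, percent (one
#'   decimal). Fractions sum to 1 over the scope; every type present on
#'   the whole slide is listed (zero counts allowed).
#' @export
composition <- function(table, scope = "whole") {
  stopifnot(inherits(table, "SpatialCellTable"))
  keep <- scope_index(table, scope)
  if (!any(keep)) stop("empty scope: ", scope)
  types <- sort(unique(table$cells$cell_type))
  counts <- table(factor(table$cells$cell_type[keep], levels = types))
  out <- data.frame(cell_type = types, count = as.integer(counts),
                    fraction = as.numeric(counts) / sum(counts),
                    stringsAsFactors = FALSE)
  out$percent <- round(100 * out$fraction, 1)
  rownames(out) <- NULL
  out[order(-out$count), ]
}

#' Fold enrichment of a cell type in a region
#'
#' `fold = fraction(type | region) / fraction(type | reference)`. The
#' whole-slide reference includes the region's own cells; the remainder
#' reference excludes them.
#'
#' @param table a [spatial_cell_table()].
#' @param region region label.
#' @param cell_type type of interest.
#' @param reference `"whole_slide"` or `"remainder"`.
#' @return List with `fold`, `region_fraction`, `reference_fraction`,
#'   `region_count`, `region_n`, `reference_count`, `reference_n`.
#' @export
region_fold_enrichment <- function(table, region, cell_type,
                                   reference = c("whole_slide", "remainder")) {
  reference <- match.arg(reference)
  stopifnot(inherits(table, "SpatialCellTable"))
  in_region <- scope_index(table, region)
  if (!any(in_region)) stop("empty region: ", region)
  ref_idx <- if (reference == "whole_slide") rep(TRUE, nrow(table$cells)) else !in_region
  if (!any(ref_idx)) stop("empty reference scope")
  is_type <- table$cells$cell_type == cell_type
  ref_count <- sum(is_type & ref_idx)
  if (ref_count == 0L) stop("cell type '", cell_type, "' absent from reference; fold undefined")
  region_frac <- sum(is_type & in_region) / sum(in_region)
  ref_frac <- ref_count / sum(ref_idx)
  list(fold = region_frac / ref_frac,
       region_fraction = region_frac, reference_fraction = ref_frac,
       region_count = sum(is_type & in_region), region_n = sum(in_region),
       reference_count = ref_count, reference_n = sum(ref_idx))
}

#' Per-type gene detection statistics
#'
#' For every (gene, type) within the scope: the fraction of cells with a
#' positive count and the mean count over all cells of the type (zeros
#' included) — the statistics behind a detection-frequency dot plot.
#'
#' @param table a [spatial_cell_table()].
#' @param genes panel genes to report; all must be in the panel.
#' @param scope `"whole"` or a region label.
#' @param positive_min minimum count to call a cell gene-positive (default 1).
#' @return `data.frame`: gene, cell_type, n_cells, fraction_positive,
#'   mean_count.
#' @export
detection_stats <- function(table, genes = table$genes, scope = "whole",
                            positive_min = 1L) {
  stopifnot(inherits(table, "SpatialCellTable"))
  missing <- setdiff(genes, table$genes)
  if (length(missing)) stop("gene(s) not in panel: ", paste(missing, collapse = ", "))
  keep <- scope_index(table, scope)
  if (!any(keep)) stop("empty scope: ", scope)
  types <- sort(unique(table$cells$cell_type[keep]))
  rows <- list()
  for (g in genes) {
    cnt <- table$counts[keep, g]
    ty <- table$cells$cell_type[keep]
    for (t0 in types) {
      v <- cnt[ty == t0]
      rows[[paste(g, t0)]] <- data.frame(
        gene = g, cell_type = t0, n_cells = length(v),
        fraction_positive = mean(v >= positive_min),
        mean_count = mean(v), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Zoom-region gene enrichment
#'
#' Per gene, the fraction of gene-positive cells inside the region is
#' compared with the remainder of the tissue via a 2x2 Fisher's exact
#' test (two-sided), with BH correction across the gene list.
#' `fold` is the ratio of positive fractions (region / remainder).
#'
#' @param table a [spatial_cell_table()].
#' @param region region label.
#' @param genes panel genes to test (default: all).
#' @param positive_min minimum count to call a cell positive (default 1).
#' @return `data.frame`: gene, positives_region, n_region,
#'   positives_remainder, n_remainder, fold, odds_ratio, p_value,
#'   q_value. A gene with zero positives everywhere gets `fold = NA`,
#'   `p_value = 1`.
#' @export
zoom_gene_enrichment <- function(table, region, genes = table$genes,
                                 positive_min = 1L) {
  stopifnot(inherits(table, "SpatialCellTable"))
  missing <- setdiff(genes, table$genes)
  if (length(missing)) stop("gene(s) not in panel: ", paste(missing, collapse = ", "))
  in_region <- scope_index(table, region)
  if (!any(in_region) || all(in_region)) stop("region and remainder must both be non-empty")
  n_in <- sum(in_region); n_out <- sum(!in_region)
  rows <- lapply(genes, function(g) {
    pos <- table$counts[, g] >= positive_min
    a <- sum(pos & in_region); b <- n_in - a
    c0 <- sum(pos & !in_region); d0 <- n_out - c0
    if (a + c0 == 0L) {
      return(data.frame(gene = g, positives_region = 0L, n_region = n_in,
                        positives_remainder = 0L, n_remainder = n_out,
                        fold = NA_real_, odds_ratio = NA_real_,
                        p_value = 1, stringsAsFactors = FALSE))
    }
    ft <- fisher_exact_2x2(matrix(c(a, c0, b, d0), 2L))
    fold <- if (c0 == 0L) Inf else (a / n_in) / (c0 / n_out)
    data.frame(gene = g, positives_region = a, n_region = n_in,
               positives_remainder = c0, n_remainder = n_out,
               fold = fold, odds_ratio = ft$odds_ratio,
               p_value = ft$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out[order(out$p_value, out$gene), ]
}
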