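# Cell-type marker derivation under conjunctive enrichment and
# prevalence thresholds, marker enrichment in bulk PC loadings, and
# many-to-one comparison of marker-set expression across bulk clusters.

#' Derive cell-type markers from labelled single cells
#'
#' One-vs-all rank-sum test per gene on the log-normalized layer.
#' log2FC is computed on de-logged normalized means,
#' `log2((mean_in + eps) / (mean_out + eps))`; `frac_in` / `frac_out` are
#' detection fractions (raw count > 0). A gene is a marker for a type
#' when `log2FC >= lfc_min` AND `frac_in >= frac_min` AND
#' `frac_in - frac_out >= gap_min`. BH correction is applied within type
#' across all tested genes; markers are sorted by descending log2FC.
#'
#' @param cells a [cell_table()] with at least 2 types of >= 3 cells.
#' @param lfc_min minimum log2 fold change (default 0.5).
#' @param frac_min minimum in-type detection fraction (default 0.40).
#' @param gap_min minimum detection-gap over other cells (default 0.10).
#' @param eps pseudo-mean in the fold-change ratio (default 1e-9).
#' @return Named list (per type) of data.frames with columns gene,
#'   log2_fold_change, frac_in, frac_out, p_value, q_value.
#' @export
sc_markers <- function(cells, lfc_min = 0.5, frac_min = 0.40, gap_min = 0.10,
                       eps = 1e-9) {
  stopifnot(inherits(cells, "CellTable"))
  types <- sort(unique(cells$cell_type))
  if (length(types) < 2L) stop("need at least 2 cell types")
  sizes <- table(cells$cell_type)
  if (any(sizes < 3L)) stop("every cell type needs at least 3 cells")
  detected <- cells$counts > 0
  delog <- expm1(cells$normalized)
  out <- list()
  for (ty in types) {
    in_ty <- cells$cell_type == ty
    frac_in <- colMeans(detected[in_ty, , drop = FALSE])
    frac_out <- colMeans(detected[!in_ty, , drop = FALSE])
    mean_in <- colMeans(delog[in_ty, , drop = FALSE])
    mean_out <- colMeans(delog[!in_ty, , drop = FALSE])
    lfc <- log2((mean_in + eps) / (mean_out + eps))
    p <- vapply(seq_along(cells$gene_ids), function(g) {
      wilcoxon_rank_sum(cells$normalized[in_ty, g], cells$normalized[!in_ty, g],
                        mode = "normal_tie_corrected")$p_value
    }, numeric(1))
    q <- bh_adjust(p)
    keep <- lfc >= lfc_min & frac_in >= frac_min & (frac_in - frac_out) >= gap_min
    df <- data.frame(gene = cells$gene_ids[keep],
                     log2_fold_change = lfc[keep],
                     frac_in = frac_in[keep], frac_out = frac_out[keep],
                     p_value = p[keep], q_value = q[keep],
                     stringsAsFactors = FALSE)
    out[[ty]] <- df[order(-df$log2_fold_change, df$gene), ]
    rownames(out[[ty]]) <- NULL
  }
  structure(out, class = "MarkerSet",
            thresholds = c(lfc_min = lfc_min, frac_min = frac_min, gap_min = gap_min))
}

#' Marker-loading enrichment on a bulk principal component
#'
#' For each cell type, collects the chosen component's loadings of that
#' type's marker genes present in the bulk PCA and tests their median
#' displacement from zero with a two-sided one-sample signed-rank test.
#'
#' @param pca a `PcaResult` from [pca_embed()].
#' @param markers a `MarkerSet` from [sc_markers()], or a named list of
#'   gene-id vectors.
#' @param component which component (default 1).
#' @return `data.frame` per type: n_genes, median_loading, p_value;
#'   types with no marker in the PCA universe get `NA` entries.
#' @export
loading_enrichment <- function(pca, markers, component = 1L) {
  stopifnot(inherits(pca, "PcaResult"))
  if (component > ncol(pca$loadings)) stop("component out of range")
  gene_lists <- marker_gene_lists(markers)
  load <- pca$loadings[, component]
  res <- lapply(names(gene_lists), function(ty) {
    g <- intersect(gene_lists[[ty]], rownames(pca$loadings))
    if (length(g) == 0L) {
      return(data.frame(cell_type = ty, n_genes = 0L, median_loading = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    v <- load[g]
    sr <- signed_rank_test(v)
    data.frame(cell_type = ty, n_genes = length(g),
               median_loading = stats::median(v), p_value = sr$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

marker_gene_lists <- function(markers) {
  if (inherits(markers, "MarkerSet")) {
    lapply(markers, function(df) df$gene)
  } else if (is.list(markers)) {
    markers
  } else stop("markers must be a MarkerSet or a named list of gene vectors")
}

# Many-to-one adjusted p-values for contrasts of every group against a
# reference, by simulation of the max-|t| null (shared reference and
# pooled-variance chi-square induce the classical correlation structure).
dunnett_max_t <- function(values, labels, reference, n_boot = 10000L, seed = 1L) {
  labels <- as.character(labels)
  groups <- split(values, labels)
  if (!reference %in% names(groups)) stop("reference cluster not present")
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("every cluster needs at least 2 samples")
  k <- length(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  df <- N - k
  s2 <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / df
  others <- setdiff(names(groups), reference)
  se <- sqrt(s2 * (1 / ns[others] + 1 / ns[reference]))
  tstat <- (means[others] - means[reference]) / se
  maxt <- with_seed(seed, {
    e <- matrix(stats::rnorm(n_boot * k), n_boot, k) /
      rep(sqrt(ns), each = n_boot)
    colnames(e) <- names(groups)
    s2b <- stats::rchisq(n_boot, df) / df
    tb <- (e[, others, drop = FALSE] - e[, reference]) /
      (sqrt(s2b) * rep(sqrt(1 / ns[others] + 1 / ns[reference]), each = n_boot))
    apply(abs(tb), 1L, max)
  })
  p_adj <- vapply(abs(tstat), function(t0) mean(maxt >= t0), numeric(1))
  data.frame(cluster = others, estimate = means[others] - means[reference],
             t_statistic = as.numeric(tstat), p_adjusted = p_adj,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Marker-set expression by bulk cluster with many-to-one comparison
#'
#' Per sample, each type's score is the mean logCPM over that type's top
#' markers present in the bulk matrix. Scores are compared across
#' clusters by one-way ANOVA, followed by many-to-one contrasts of every
#' cluster against the reference with family-wise adjustment over the
#' K - 1 comparisons (simulated max-|t| null, Dunnett-style).
#'
#' @param bulk logCPM [expression_matrix()].
#' @param markers a `MarkerSet` or named list of gene vectors (assumed
#'   pre-sorted, best first).
#' @param labels cluster label per bulk sample.
#' @param reference reference cluster label.
#' @param top_n markers per type used for scoring (default 20).
#' @param n_boot max-|t| null draws (default 10000).
#' @param seed RNG seed for the null draws.
#' @return List per type: `scores` (per sample), `cluster_means`,
#'   `anova_p`, `contrasts` (data.frame vs reference). Types with no
#'   marker in the bulk universe are skipped with a warning.
#' @export
marker_score_by_cluster <- function(bulk, markers, labels, reference,
                                    top_n = 20L, n_boot = 10000L, seed = 1L) {
  stopifnot(inherits(bulk, "ExpressionMatrix"))
  labels <- as.character(labels)
  if (length(labels) != length(bulk$sample_ids)) stop("one label per sample required")
  if (!reference %in% labels) stop("reference cluster not present in labels")
  gene_lists <- marker_gene_lists(markers)
  out <- list()
  for (ty in names(gene_lists)) {
    g <- intersect(utils::head(gene_lists[[ty]], top_n), bulk$gene_ids)
    if (length(g) == 0L) {
      warning("no markers of type '", ty, "' found in bulk matrix; skipped")
      next
    }
    sc <- colMeans(bulk$values[g, , drop = FALSE])
    fit <- stats::oneway.test(sc ~ factor(labels), var.equal = TRUE)
    contrasts <- dunnett_max_t(sc, labels, reference, n_boot = n_boot, seed = seed)
    out[[ty]] <- list(scores = sc,
                      cluster_means = vapply(split(sc, labels), mean, numeric(1)),
                      anova_p = fit$p.value, contrasts = contrasts,
                      n_markers = length(g))
  }
  out
}
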