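# Resampling-based consensus clustering with CDF / delta-AUC model
# selection. The consensus matrix entry for a sample pair is the fraction
# of resampling iterations in which the pair clustered together, among
# iterations that sampled both.

#' Select the most variable genes by MAD
#'
#' Genes are ranked by descending median absolute deviation (raw MAD,
#' no consistency constant) across samples, ties broken by gene id.
#'
#' @param x a logCPM [expression_matrix()].
#' @param n number of genes to return (positive, at most the gene count).
#' @param criterion only `"mad"` is implemented.
#' @return Character vector of `n` gene ids, most variable first.
#' @export
select_variable_genes <- function(x, n, criterion = c("mad")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (n <= 0) stop("n must be positive")
  if (n > length(x$gene_ids)) stop("n exceeds the number of genes")
  mads <- apply(x$values, 1L, stats::mad, constant = 1)
  ord <- order(-mads, x$gene_ids)
  x$gene_ids[ord][seq_len(n)]
}

#' Resampling consensus clustering
#'
#' Per iteration, `ceiling(subsample_fraction * n)` samples are drawn
#' without replacement and clustered at every K in `k_range` with the
#' base clusterer; co-cluster and co-sample counts accumulate across
#' iterations. Final assignments at each K come from average-linkage
#' hierarchical clustering of `1 - consensus`. A master seed spawns one
#' child seed per iteration, so results are independent of execution
#' order.
#'
#' @param x a logCPM [expression_matrix()].
#' @param genes gene ids to cluster on (e.g. from [select_variable_genes()]).
#' @param k_range integer vector of K values (default 2:10).
#' @param n_iterations resampling iterations (default 2000).
#' @param subsample_fraction fraction of samples per iteration (default 0.8).
#' @param base_clusterer `"hclust_pearson"` (agglomerative, 1 - Pearson
#'   correlation distance, average linkage) or `"kmeans"`.
#' @param seed integer master seed.
#' @return A `ConsensusResult`: list with `k_range`, `params`, and per-K
#'   entries `consensus` (n x n, NA where never co-sampled), `cosampled`
#'   (integer counts) and `assignments`; [consensus_cdf_auc()] adds CDF,
#'   AUC and delta-AUC diagnostics.
#' @export
run_consensus <- function(x, genes, k_range = 2:10, n_iterations = 2000L,
                          subsample_fraction = 0.8,
                          base_clusterer = c("hclust_pearson", "kmeans"),
                          seed = 1L) {
  base_clusterer <- match.arg(base_clusterer)
  stopifnot(inherits(x, "ExpressionMatrix"))
  missing <- setdiff(genes, x$gene_ids)
  if (length(missing)) stop("genes absent from matrix: ", paste(utils::head(missing, 3), collapse = ", "))
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  if (subsample_fraction <= 0 || subsample_fraction > 1) stop("subsample_fraction must lie in (0, 1]")
  n <- length(x$sample_ids)
  m <- as.integer(ceiling(subsample_fraction * n))
  if (max(k_range) > m) stop("K larger than the subsample size")
  vals <- x$values[genes, , drop = FALSE]
  iter_seeds <- derive_seeds(seed, n_iterations)
  cosampled <- matrix(0L, n, n)
  coclustered <- lapply(k_range, function(k) matrix(0L, n, n))
  names(coclustered) <- as.character(k_range)
  for (it in seq_len(n_iterations)) {
    idx <- with_seed(iter_seeds[it], sort(sample.int(n, m)))
    sub <- vals[, idx, drop = FALSE]
    labs <- base_cluster_labels(sub, k_range, base_clusterer, iter_seeds[it])
    cosampled[idx, idx] <- cosampled[idx, idx] + 1L
    for (kk in seq_along(k_range)) {
      same <- outer(labs[[kk]], labs[[kk]], "==")
      coclustered[[kk]][idx, idx] <- coclustered[[kk]][idx, idx] + same
    }
  }
  per_k <- lapply(seq_along(k_range), function(kk) {
    cons <- coclustered[[kk]] / cosampled
    cons[cosampled == 0L] <- NA_real_
    diag(cons) <- 1
    dimnames(cons) <- list(x$sample_ids, x$sample_ids)
    assignments <- consensus_call(cons, k_range[kk])
    list(consensus = cons, cosampled = cosampled, assignments = assignments)
  })
  names(per_k) <- as.character(k_range)
  res <- structure(list(
    k_range = k_range, per_k = per_k, sample_ids = x$sample_ids,
    params = list(n_genes_selected = length(genes), n_iterations = n_iterations,
                  subsample_fraction = subsample_fraction,
                  base_clusterer = base_clusterer, seed = seed)),
    class = "ConsensusResult")
  consensus_cdf_auc(res)
}

# Cluster one subsampled matrix (genes x samples) at every K.
base_cluster_labels <- function(sub, k_range, base_clusterer, seed) {
  if (base_clusterer == "hclust_pearson") {
    cc <- suppressWarnings(stats::cor(sub))
    cc[!is.finite(cc)] <- 0 # constant columns: treat as uncorrelated
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    lapply(k_range, function(k) stats::cutree(hc, k = k))
  } else {
    with_seed(seed, lapply(k_range, function(k) {
      stats::kmeans(t(sub), centers = k, nstart = 5)$cluster
    }))
  }
}

# Final assignments: hierarchical clustering of (1 - consensus), average
# linkage; never-co-sampled pairs are imputed at the neutral value 0.5.
consensus_call <- function(consensus, k) {
  d <- 1 - consensus
  d[is.na(d)] <- 0.5
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  stats::cutree(hc, k = k)
}

#' Consensus CDF, AUC and delta-AUC diagnostics
#'
#' The empirical CDF of defined lower-triangle consensus values is
#' evaluated on the grid 0, 0.01, ..., 1; AUC by the trapezoid rule.
#' delta-AUC at the first K equals that K's AUC; thereafter
#' `(AUC(K) - AUC(K-1)) / AUC(K-1)`.
#'
#' @param result a `ConsensusResult` from [run_consensus()].
#' @return The result with `cdf_grid`, per-K `cdf`, `auc`, `delta_auc`.
#' @export
consensus_cdf_auc <- function(result) {
  stopifnot(inherits(result, "ConsensusResult"))
  grid <- seq(0, 1, by = 0.01)
  aucs <- numeric(length(result$k_range))
  cdfs <- vector("list", length(result$k_range))
  for (kk in seq_along(result$k_range)) {
    cons <- result$per_k[[kk]]$consensus
    vals <- cons[lower.tri(cons)]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) stop("no defined sample pairs in consensus matrix")
    cdf <- vapply(grid, function(t) mean(vals <= t), numeric(1))
    aucs[kk] <- sum(diff(grid) * (utils::head(cdf, -1) + utils::tail(cdf, -1)) / 2)
    cdfs[[kk]] <- cdf
  }
  delta <- numeric(length(aucs))
  delta[1L] <- aucs[1L]
  if (length(aucs) > 1L) {
    delta[-1L] <- diff(aucs) / utils::head(aucs, -1)
  }
  result$cdf_grid <- grid
  for (kk in seq_along(result$k_range)) {
    result$per_k[[kk]]$cdf <- cdfs[[kk]]
    result$per_k[[kk]]$auc <- aucs[kk]
    result$per_k[[kk]]$delta_auc <- delta[kk]
  }
  result$auc <- stats::setNames(aucs, result$k_range)
  result$delta_auc <- stats::setNames(delta, result$k_range)
  result
}

#' Suggest K by the diminishing-delta-AUC rule
#'
#' Among K values whose relative AUC gain is still non-negligible
#' (`delta_auc >= min_delta`), returns the K at which the gain curve
#' flattens most sharply, i.e. maximizing `delta_auc(K) / delta_auc(K+1)`.
#' The rule is advisory: the full curve stays in the result and K remains
#' a confirmable parameter.
#'
#' @param result a `ConsensusResult` with diagnostics.
#' @param min_delta smallest relative AUC gain still counted as a real
#'   improvement (default 0.02).
#' @return Integer K, or `NA` if no K qualifies.
#' @export
select_k <- function(result, min_delta = 0.02) {
  d <- result$delta_auc
  ks <- result$k_range
  if (length(ks) < 2L) return(NA_integer_)
  head_d <- d[-length(d)]
  ratio <- head_d / pmax(d[-1L], 1e-12)
  ratio[!is.finite(head_d) | head_d < min_delta] <- -Inf
  if (all(ratio == -Inf)) return(NA_integer_)
  ks[which.max(ratio)]
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf("ConsensusResult: %d samples, K = %s (%d iterations, %.0f%% subsampling)\n",
              length(x$sample_ids), paste(range(x$k_range), collapse = "-"),
              x$params$n_iterations, 100 * x$params$subsample_fraction))
  if (!is.null(x$delta_auc)) {
    cat("delta-AUC:", paste(sprintf("K%s=%.4f", names(x$delta_auc), x$delta_auc),
                            collapse = " "), "\n")
  }
  invisible(x)
}

#' PCA of a gene subset
#'
#' Gene-centered SVD of the samples x genes matrix. Loadings columns are
#' unit-norm; each component's sign is fixed so its largest-magnitude
#' loading is positive.
#'
#' @param x a logCPM [expression_matrix()].
#' @param genes gene ids to embed (default: all).
#' @param n_components number of components (default: full rank).
#' @return A `PcaResult`: list with `scores` (samples x components),
#'   `loadings` (genes x components), `variance_explained`.
#' @export
pca_embed <- function(x, genes = NULL, n_components = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.null(genes)) genes <- x$gene_ids
  missing <- setdiff(genes, x$gene_ids)
  if (length(missing)) stop("genes absent from matrix: ", paste(utils::head(missing, 3), collapse = ", "))
  if (length(x$sample_ids) < 2L) stop("PCA requires at least 2 samples")
  mat <- t(x$values[genes, , drop = FALSE]) # samples x genes
  centered <- sweep(mat, 2L, colMeans(mat))
  r <- min(dim(centered)) - 0L
  sv <- svd(centered)
  d <- sv$d
  total_var <- sum(d^2)
  if (is.null(n_components)) n_components <- sum(d > max(d) * 1e-12)
  n_components <- min(n_components, length(d))
  idx <- seq_len(n_components)
  scores <- sv$u[, idx, drop = FALSE] %*% diag(d[idx], n_components, n_components)
  loadings <- sv$v[, idx, drop = FALSE]
  for (j in idx) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- x$sample_ids
  rownames(loadings) <- genes
  colnames(scores) <- colnames(loadings) <- paste0("PC", idx)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = if (total_var > 0) d[idx]^2 / total_var else rep(0, n_components)),
            class = "PcaResult")
}
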