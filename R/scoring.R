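# Per-cell signed module scores with KNN smoothing, single-sample and
# preranked gene-set enrichment, and rank correlations against clinical
# severity.

#' Per-cell signed degeneration score
#'
#' `raw(cell) = mean(normalized expression over pos genes) -
#'  mean(normalized expression over neg genes)`, using the genes of each
#' list present in the cell universe.
#'
#' @param cells a [cell_table()].
#' @param pos_genes,neg_genes gene-id vectors; each must intersect the
#'   cell gene universe.
#' @return A `ScoreVector`: list with `cell_ids`, `raw`, `smoothed`
#'   (NULL until [knn_smooth()]), `pos_set`, `neg_set`, `k`.
#' @export
degeneration_score <- function(cells, pos_genes, neg_genes) {
  stopifnot(inherits(cells, "CellTable"))
  pos <- intersect(pos_genes, cells$gene_ids)
  neg <- intersect(neg_genes, cells$gene_ids)
  if (length(pos) == 0L) stop("no positive-set gene found in the cell universe")
  if (length(neg) == 0L) stop("no negative-set gene found in the cell universe")
  raw <- rowMeans(cells$normalized[, pos, drop = FALSE]) -
    rowMeans(cells$normalized[, neg, drop = FALSE])
  structure(list(cell_ids = cells$cell_ids, raw = unname(raw), smoothed = NULL,
                 pos_set = deparse(substitute(pos_genes)),
                 neg_set = deparse(substitute(neg_genes)), k = NA_integer_),
            class = "ScoreVector")
}

#' KNN smoothing of per-cell scores
#'
#' Each cell's smoothed score is the mean raw score over the cell itself
#' and its k Euclidean nearest neighbors in the embedding; distance ties
#' are broken by cell index. `k = 0` is the identity. The operator is a
#' convex combination, so smoothed scores stay within the raw range.
#'
#' @param scores a `ScoreVector` from [degeneration_score()].
#' @param embedding cells x d coordinate matrix aligned with the scores.
#' @param k number of neighbors, `0 <= k < n_cells` (default 15).
#' @return The `ScoreVector` with `smoothed` filled and `k` recorded.
#' @export
knn_smooth <- function(scores, embedding, k = 15L) {
  stopifnot(inherits(scores, "ScoreVector"))
  embedding <- as.matrix(embedding)
  n <- length(scores$raw)
  if (nrow(embedding) != n) stop("embedding rows must align with cells")
  if (k < 0 || k >= n) stop("k must satisfy 0 <= k < number of cells")
  if (k == 0L) {
    scores$smoothed <- scores$raw
    scores$k <- 0L
    return(scores)
  }
  d2 <- as.matrix(stats::dist(embedding))^2
  smoothed <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ], seq_len(n)) # stable: ties broken by cell index
    nn <- setdiff(ord, i)[seq_len(k)]
    smoothed[i] <- mean(scores$raw[c(i, nn)])
  }
  scores$smoothed <- smoothed
  scores$k <- as.integer(k)
  scores
}

#' Per-type score summaries
#'
#' Median, 25th/75th percentiles (linear interpolation) and n of the
#' smoothed (or raw, if unsmoothed) score per cell type.
#'
#' @param scores a `ScoreVector`.
#' @param cells the [cell_table()] the scores were computed from.
#' @return `data.frame`: cell_type, n, median, q25, q75; types with no
#'   cells are omitted.
#' @export
summarize_scores <- function(scores, cells) {
  stopifnot(inherits(scores, "ScoreVector"), inherits(cells, "CellTable"))
  if (!identical(scores$cell_ids, cells$cell_ids)) stop("score/cell alignment mismatch")
  v <- if (is.null(scores$smoothed)) scores$raw else scores$smoothed
  per <- split(v, cells$cell_type)
  out <- data.frame(
    cell_type = names(per),
    n = lengths(per),
    median = vapply(per, stats::median, numeric(1)),
    q25 = vapply(per, function(z) stats::quantile(z, 0.25, names = FALSE), numeric(1)),
    q75 = vapply(per, function(z) stats::quantile(z, 0.75, names = FALSE), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(-out$median), ]
}

# ssGSEA-style statistic for one sample: genes ranked by expression
# descending; running difference between the weighted in-set ECDF
# (weights = rank statistic ^ alpha) and the uniform out-of-set ECDF.
ssgsea_one <- function(expr_ranked_desc, in_set, alpha) {
  N <- length(in_set)
  m <- sum(in_set)
  rnk <- N:1 # rank statistic: top gene has rank N
  w <- ifelse(in_set, rnk^alpha, 0)
  sw <- sum(w)
  if (sw == 0) return(0)
  ecdf_in <- cumsum(w) / sw
  ecdf_out <- if (m == N) rep(0, N) else cumsum(!in_set) / (N - m)
  sum(ecdf_in - ecdf_out)
}

#' Single-sample gene-set scores (ssGSEA-style)
#'
#' For each sample, genes are ranked by expression descending (ties broken
#' by gene id for determinism); the set score is the summed difference
#' between the weighted in-set ECDF (weights `rank^alpha`) and the uniform
#' out-of-set ECDF. Scores are rescaled per set across samples to zero
#' mean, unit variance (left at 0 when constant).
#'
#' @param x logCPM [expression_matrix()].
#' @param sets a [gene_set_collection()].
#' @param alpha rank-weight exponent (default 0.25).
#' @param rescale standardize per set across samples (default TRUE).
#' @return sets x samples numeric matrix; sets with fewer than 2 genes in
#'   the universe are skipped with a warning.
#' @export
ssgsea_sample_scores <- function(x, sets, alpha = 0.25, rescale = TRUE) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(sets, "GeneSetCollection"))
  usable <- names(sets$sets)[vapply(sets$sets, function(g) {
    length(intersect(g, x$gene_ids)) >= 2L
  }, logical(1))]
  dropped <- setdiff(names(sets$sets), usable)
  if (length(dropped)) {
    warning("set(s) with < 2 genes in universe skipped: ",
            paste(dropped, collapse = ", "))
  }
  if (length(usable) == 0L) stop("no usable gene set")
  n_s <- length(x$sample_ids)
  scores <- matrix(NA_real_, length(usable), n_s,
                   dimnames = list(usable, x$sample_ids))
  for (s in seq_len(n_s)) {
    v <- x$values[, s]
    ord <- order(-v, x$gene_ids)
    genes_ranked <- x$gene_ids[ord]
    for (st in usable) {
      in_set <- genes_ranked %in% sets$sets[[st]]
      scores[st, s] <- ssgsea_one(v[ord], in_set, alpha)
    }
  }
  if (rescale) {
    for (st in usable) {
      sdv <- stats::sd(scores[st, ])
      scores[st, ] <- if (is.na(sdv) || sdv == 0) 0 else
        (scores[st, ] - mean(scores[st, ])) / sdv
    }
  }
  scores
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score. Genes must be
# pre-ranked descending. Weight = |statistic| over set members; when the
# set's total weight is zero the walk is unweighted.
gsea_es <- function(stats_ranked, in_set) {
  N <- length(in_set)
  m <- sum(in_set)
  if (m == 0L || m == N) stop("set must be a proper subset of the ranked universe")
  w <- ifelse(in_set, abs(stats_ranked), 0)
  if (sum(w) == 0) w <- as.numeric(in_set)
  p_hit <- cumsum(w) / sum(w)
  p_miss <- cumsum(!in_set) / (N - m)
  dev <- p_hit - p_miss
  dev[which.max(abs(dev))]
}

#' Preranked gene-set enrichment
#'
#' Classical weighted running-sum enrichment score with weight
#' `|statistic|`; the null distribution comes from random same-size gene
#' sets (gene-label permutation). NES = ES / mean(|null ES| of matching
#' sign); the p-value is the matching-sign tail frequency with a +1
#' pseudocount. Apply [bh_adjust()] across sets at the caller.
#'
#' @param ranked_stats named numeric vector (gene -> statistic); ranked
#'   descending internally, ties broken by gene id.
#' @param set gene-id vector; must intersect the universe.
#' @param n_perm null permutations (>= 100; default 1000).
#' @param seed RNG seed.
#' @return List with `es`, `nes`, `p_value`, `n_genes`, `direction`.
#' @export
preranked_gsea <- function(ranked_stats, set, n_perm = 1000L, seed = 1L) {
  if (is.null(names(ranked_stats))) stop("ranked_stats must be a named vector")
  if (n_perm < 100L) stop("n_perm must be >= 100")
  ord <- order(-ranked_stats, names(ranked_stats))
  s <- ranked_stats[ord]
  genes <- names(s)
  in_set <- genes %in% set
  m <- sum(in_set)
  if (m == 0L) stop("set does not intersect the ranked universe")
  if (m == length(genes)) stop("set covers the whole universe")
  es <- gsea_es(s, in_set)
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(genes), m)
    flag <- logical(length(genes)); flag[idx] <- TRUE
    gsea_es(s, flag)
  }, numeric(1)))
  same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  nes <- if (length(same_sign) > 0 && mean(abs(same_sign)) > 0) {
    es / mean(abs(same_sign))
  } else sign(es) * Inf
  p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
  list(es = es, nes = nes, p_value = min(1, p), n_genes = m,
       direction = if (es >= 0) "up" else "down")
}

#' Preranked enrichment over a collection
#'
#' Runs [preranked_gsea()] for every set and applies BH across sets.
#'
#' @inheritParams preranked_gsea
#' @param sets a [gene_set_collection()].
#' @return `data.frame`: set_name, es, nes, p_value, q_value, direction,
#'   n_genes.
#' @export
preranked_gsea_collection <- function(ranked_stats, sets, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(sets, "GeneSetCollection"))
  seeds <- derive_seeds(seed, length(sets$sets))
  rows <- lapply(seq_along(sets$sets), function(i) {
    r <- preranked_gsea(ranked_stats, sets$sets[[i]], n_perm = n_perm, seed = seeds[i])
    data.frame(set_name = names(sets$sets)[i], es = r$es, nes = r$nes,
               p_value = r$p_value, direction = r$direction,
               n_genes = r$n_genes, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out[order(out$p_value), c("set_name", "es", "nes", "p_value", "q_value",
                            "direction", "n_genes")]
}
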