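# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: enumeration over combinations / sign patterns /
# permutations, direct hypergeometric sums, and naive running sums.

# Two-sided rank-sum p by enumeration of all C(N, n) group assignments.
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(n)])
  combos <- utils::combn(length(pooled), n)
  W_null <- apply(combos, 2L, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(W_null <= W_obs), mean(W_null >= W_obs)))
}

# Two-sided signed-rank p by enumeration of all 2^n sign patterns.
oracle_signedrank_p <- function(x) {
  d <- x[x != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  V_null <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L])
  }, numeric(1))
  min(1, 2 * min(mean(V_null <= V_obs + 1e-9), mean(V_null >= V_obs - 1e-9)))
}

# Two-sided Fisher p for a 2x2 table as an explicit hypergeometric sum.
oracle_fisher_p <- function(a, b, c, d) {
  k <- a + c
  support <- max(0, k - (c + d)):min(k, a + b)
  pr <- vapply(support, function(x) {
    choose(a + b, x) * choose(c + d, k - x) / choose(a + b + c + d, k)
  }, numeric(1))
  p_obs <- pr[support == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# BH step-up by the literal definition: q_i = min over {j: p_j >= p_i}
# of m p_j / rank_j, clipped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  rk <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i] - 1e-15)
    min(1, min(m * p[js] / rk[js]))
  }, numeric(1))
}

# GSEA enrichment score by a naive elementwise running sum.
oracle_gsea_es <- function(stats_ranked, in_set) {
  N <- length(in_set)
  w <- abs(stats_ranked) * in_set
  if (sum(w) == 0) w <- as.numeric(in_set)
  run <- 0; best <- 0
  hit_total <- sum(w); miss_total <- N - sum(in_set)
  for (i in seq_len(N)) {
    run <- run + if (in_set[i]) w[i] / hit_total else -1 / miss_total
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Tiny deterministic ExpressionMatrix fixture.
tiny_logcpm <- function(values, genes = NULL, samples = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) {
    genes <- if (!is.null(rownames(values))) rownames(values)
             else paste0("g", seq_len(nrow(values)))
  }
  if (is.null(samples)) {
    samples <- if (!is.null(colnames(values))) colnames(values)
               else paste0("s", seq_len(ncol(values)))
  }
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, layer = "logcpm")
}

# Two-group bulk matrix with duplicated columns inside each group, for
# perfect-separation consensus checks.
duplicated_group_matrix <- function(n_per_group = 5L, n_genes = 40L, seed = 11L) {
  set.seed(seed)
  a <- rnorm(n_genes); b <- rnorm(n_genes) + 3 * rep(c(1, -1), length.out = n_genes)
  vals <- cbind(matrix(rep(a, n_per_group), ncol = n_per_group),
                matrix(rep(b, n_per_group), ncol = n_per_group))
  vals <- vals + matrix(rnorm(length(vals), sd = 1e-3), nrow = n_genes)
  tiny_logcpm(vals)
}

# Small labelled CellTable with planted perfect/partial markers.
tiny_cell_table <- function(n_per_type = 100L, n_markers = 5L, n_genes = 60L,
                            fold = 6, seed = 5L) {
  set.seed(seed)
  types <- rep(c("alpha", "beta"), each = n_per_type)
  lam <- matrix(0.3, nrow = 2L * n_per_type, ncol = n_genes)
  lam[types == "alpha", seq_len(n_markers)] <- 0.3 * fold
  lam[types == "beta", n_markers + seq_len(n_markers)] <- 0.3 * fold
  counts <- matrix(rpois(length(lam), lam), nrow = nrow(lam),
                   dimnames = list(sprintf("c%03d", seq_len(nrow(lam))),
                                   sprintf("g%03d", seq_len(n_genes))))
  ct <- cell_table(counts, types, embedding_dims = 10L)
  attr(ct, "truth") <- list(alpha = colnames(counts)[seq_len(n_markers)],
                            beta = colnames(counts)[n_markers + seq_len(n_markers)])
  ct
}

# Spatial table rebuilt from explicit per-type region counts (used to
# replay printed worked examples exactly).
spatial_from_counts <- function(region_counts, rest_counts) {
  types <- union(names(region_counts), names(rest_counts))
  region_counts <- region_counts[types]; region_counts[is.na(region_counts)] <- 0
  rest_counts <- rest_counts[types]; rest_counts[is.na(rest_counts)] <- 0
  n <- sum(region_counts) + sum(rest_counts)
  cells <- data.frame(
    cell_id = sprintf("c%05d", seq_len(n)),
    x = seq_len(n), y = 0,
    cell_type = c(rep(types, region_counts), rep(types, rest_counts)),
    region = rep(c("zoom", "rest"), c(sum(region_counts), sum(rest_counts))),
    stringsAsFactors = FALSE
  )
  spatial_cell_table(cells, matrix(0L, n, 1, dimnames = list(cells$cell_id, "dummy")))
}
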