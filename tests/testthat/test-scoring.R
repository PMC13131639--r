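test_that("degeneration_score arithmetic and antisymmetry", {
  counts <- matrix(c(9, 1), 1, 2, dimnames = list("c1", c("pos1", "neg1")))
  ct <- cell_table(counts, "A", embedding = matrix(0, 1, 1))
  # normalized values are fixed by construction; check raw = pos - neg
  sv <- degeneration_score(ct, "pos1", "neg1")
  expect_equal(sv$raw, ct$normalized[1, "pos1"] - ct$normalized[1, "neg1"],
               ignore_attr = TRUE)
  # identical sets cancel exactly
  expect_equal(degeneration_score(ct, c("pos1", "neg1"), c("pos1", "neg1"))$raw, 0)
  # antisymmetry under set swap
  ct2 <- tiny_cell_table(n_per_type = 30, seed = 2)
  truth <- attr(ct2, "truth")
  a <- degeneration_score(ct2, truth$alpha, truth$beta)$raw
  b <- degeneration_score(ct2, truth$beta, truth$alpha)$raw
  expect_equal(a, -b, tolerance = 1e-12)
  expect_error(degeneration_score(ct2, "not_a_gene", truth$beta), "positive-set")
})

test_that("knn_smooth: identity, fixed point, tie rule, boundedness", {
  emb <- matrix(c(0, 1, 2), 3, 1)
  sv <- structure(list(cell_ids = paste0("c", 1:3), raw = c(0, 3, 6),
                       smoothed = NULL, pos_set = "p", neg_set = "n",
                       k = NA_integer_), class = "ScoreVector")
  expect_equal(knn_smooth(sv, emb, k = 0)$smoothed, c(0, 3, 6))
  # k = 1 with the middle cell's distance tie broken toward the lower index
  expect_equal(knn_smooth(sv, emb, k = 1)$smoothed, c(1.5, 1.5, 4.5))
  # constants are a fixed point
  svc <- sv; svc$raw <- rep(2.5, 3)
  expect_equal(knn_smooth(svc, emb, k = 2)$smoothed, rep(2.5, 3))
  # convex combination: bounded by raw extremes, at any k
  set.seed(6)
  n <- 80
  emb2 <- matrix(rnorm(2 * n), n, 2)
  sv2 <- structure(list(cell_ids = paste0("c", 1:n), raw = rnorm(n),
                        smoothed = NULL, pos_set = "p", neg_set = "n",
                        k = NA_integer_), class = "ScoreVector")
  for (k in c(1, 5, 20)) {
    sm <- knn_smooth(sv2, emb2, k = k)$smoothed
    expect_gte(min(sm), min(sv2$raw))
    expect_lte(max(sm), max(sv2$raw))
  }
  expect_error(knn_smooth(sv2, emb2[1:10, ], k = 1), "align")
  expect_error(knn_smooth(sv2, emb2, k = n), "k must satisfy")
})

test_that("summarize_scores uses linear-interpolation percentiles", {
  counts <- matrix(0L, 3, 2, dimnames = list(paste0("c", 1:3), c("g1", "g2")))
  ct <- cell_table(counts, rep("A", 3), embedding = matrix(0, 3, 1))
  sv <- structure(list(cell_ids = ct$cell_ids, raw = c(1, 2, 3), smoothed = NULL,
                       pos_set = "p", neg_set = "n", k = NA_integer_),
                  class = "ScoreVector")
  s <- summarize_scores(sv, ct)
  expect_equal(s$median, 2)
  expect_equal(s$q25, 1.5)
  expect_equal(s$q75, 2.5)
  expect_equal(s$n, 3L)
  sv$raw <- rep(4, 3)
  s2 <- summarize_scores(sv, ct)
  expect_equal(s2$q75 - s2$q25, 0)
})

test_that("lining-high module scores rank cell types as planted", {
  sc <- simulate_sc(sc_sim_params(n_cells = 1500, n_genes = 300,
                                  markers_per_type = 8, seed = 23))
  truth <- attr(sc, "truth")
  sv <- degeneration_score(sc, truth$lining_fibroblast, truth$sublining_fibroblast)
  sv <- knn_smooth(sv, sc$embedding, k = 15)
  s <- summarize_scores(sv, sc)
  expect_identical(s$cell_type[1], "lining_fibroblast")
  expect_identical(s$cell_type[nrow(s)], "sublining_fibroblast")
  # smoothing reduces within-type dispersion
  sv0 <- degeneration_score(sc, truth$lining_fibroblast, truth$sublining_fibroblast)
  lin <- sc$cell_type == "lining_fibroblast"
  expect_lt(stats::sd(sv$smoothed[lin]), stats::sd(sv0$raw[lin]))
})

test_that("ssgsea: top-set maximality against the exhaustive subset oracle", {
  vals <- matrix(c(10:1), 10, 1,
                 dimnames = list(paste0("g", 1:10), "s1"))
  em <- expression_matrix(vals, layer = "logcpm")
  subsets <- utils::combn(10, 3)
  scores <- apply(subsets, 2, function(ix) {
    sets <- gene_set_collection(list(S = paste0("g", ix)))
    ssgsea_sample_scores(em, sets, rescale = FALSE)[1, 1]
  })
  top <- which(apply(subsets, 2, function(ix) all(ix %in% 1:3)))
  expect_equal(which.max(scores), top)
})

test_that("ssgsea degenerate and determinism properties", {
  set.seed(9)
  vals <- matrix(rnorm(40, 5), 10, 4,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  vals[, 4] <- vals[, 3] # duplicated sample
  em <- expression_matrix(vals, layer = "logcpm")
  whole <- gene_set_collection(list(ALL = paste0("g", 1:10)))
  sc_all <- ssgsea_sample_scores(em, whole)
  expect_equal(unname(sc_all[1, ]), rep(0, 4)) # constant set rescales to 0
  part <- gene_set_collection(list(S = paste0("g", 1:4)))
  raw <- ssgsea_sample_scores(em, part, rescale = FALSE)
  expect_identical(raw[1, 3], raw[1, 4])
  expect_warning(
    ssgsea_sample_scores(em, gene_set_collection(list(S = paste0("g", 1:3),
                                                      TINY = c("g1", "zz")))),
    "skipped")
  # invariance under monotone relabeling of gene ids (same ranks)
  em2 <- em; rownames(em2$values) <- paste0("h", sprintf("%02d", 1:10))
  em2 <- expression_matrix(em2$values, layer = "logcpm")
  part2 <- gene_set_collection(list(S = paste0("h", sprintf("%02d", 1:4))))
  expect_equal(unname(ssgsea_sample_scores(em2, part2, rescale = FALSE)),
               unname(raw), tolerance = 1e-12)
})

test_that("preranked ES: closed form, enumeration oracle, and bounds", {
  # set occupying the top |set| ranks with equal statistics -> ES = +1
  s <- setNames(c(rep(2, 4), rep(1, 8)), paste0("g", sprintf("%02d", 1:12)))
  r <- preranked_gsea(s, paste0("g", sprintf("%02d", 1:4)), n_perm = 100, seed = 1)
  expect_equal(r$es, 1)
  expect_identical(r$direction, "up")
  # all-zero statistics: unweighted walk vs naive enumeration on 12 genes
  s0 <- setNames(rep(0, 12), paste0("g", sprintf("%02d", 1:12)))
  set.seed(4)
  for (i in 1:10) {
    members <- sample(names(s0), sample(2:6, 1))
    ord <- order(-s0, names(s0))
    in_set <- names(s0)[ord] %in% members
    expect_equal(preranked_gsea(s0, members, n_perm = 100, seed = i)$es,
                 oracle_gsea_es(s0[ord], in_set), tolerance = 1e-12)
  }
  # weighted case against the oracle too
  set.seed(5)
  sw <- setNames(rnorm(12), paste0("g", sprintf("%02d", 1:12)))
  members <- sample(names(sw), 5)
  ord <- order(-sw, names(sw))
  rw <- preranked_gsea(sw, members, n_perm = 200, seed = 3)
  expect_equal(rw$es, oracle_gsea_es(sw[ord], names(sw)[ord] %in% members),
               tolerance = 1e-12)
  expect_true(abs(rw$es) <= 1)
  expect_equal(sign(rw$nes), sign(rw$es))
  expect_error(preranked_gsea(sw, "absent", n_perm = 100), "intersect")
  expect_error(preranked_gsea(sw, names(sw), n_perm = 100), "whole universe")
})

test_that("uniformly scattered sets are not called enriched", {
  set.seed(31)
  genes <- paste0("g", sprintf("%03d", 1:200))
  hits <- replicate(60, {
    s <- setNames(rnorm(200), genes)
    members <- sample(genes, 20)
    preranked_gsea(s, members, n_perm = 200, seed = sample.int(1e6, 1))$p_value
  })
  expect_gte(mean(hits > 0.05), 0.9)
})

test_that("preranked collection applies BH across sets", {
  set.seed(40)
  s <- setNames(c(sort(rnorm(50), decreasing = TRUE)), paste0("g", 1:50))
  sets <- gene_set_collection(list(TOP = paste0("g", 1:8),
                                   RAND = paste0("g", c(5, 17, 23, 31, 44)),
                                   LOW = paste0("g", 43:50)))
  res <- preranked_gsea_collection(s, sets, n_perm = 500, seed = 2)
  expect_identical(res$set_name[1], "TOP")
  expect_identical(res$direction[res$set_name == "LOW"], "down")
  expect_equal(res$q_value, bh_adjust(res$p_value), tolerance = 1e-12)
})

test_that("spearman power for planted negative correlation at cohort size", {
  # reduced replicate count; the 500-replicate version runs in acceptance
  set.seed(77)
  r <- 2 * sin(-0.3 * pi / 6) # Pearson r giving Spearman rho ~ -0.3
  hits <- replicate(100, {
    x <- rnorm(135)
    y <- r * x + sqrt(1 - r^2) * rnorm(135)
    res <- spearman_assoc(x, y)
    res$rho < 0 && res$p_value < 0.05
  })
  expect_gte(mean(hits), 0.9)
})
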