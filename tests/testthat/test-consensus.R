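test_that("select_variable_genes ranks by MAD with lexicographic ties", {
  em <- tiny_logcpm(rbind(A = c(1, 2, 3, 4, 100), B = c(5, 5, 5, 5, 5)),
                    genes = c("A", "B"))
  expect_identical(select_variable_genes(em, 1), "A") # MAD_A = 1, MAD_B = 0
  const <- tiny_logcpm(matrix(2, 3, 4), genes = c("gb", "ga", "gc"))
  expect_identical(select_variable_genes(const, 2), c("ga", "gb"))
  em2 <- tiny_logcpm(rbind(A = c(0, 1, 10), B = c(0, 5, 50)))
  expect_identical(select_variable_genes(em2, 2), c("B", "A"))
  expect_error(select_variable_genes(em, 0), "positive")
  expect_error(select_variable_genes(em, 3), "exceeds")
})

test_that("perfect two-group data yields a 0/1 consensus matrix", {
  em <- duplicated_group_matrix(n_per_group = 5)
  cr <- run_consensus(em, em$gene_ids, k_range = 2, n_iterations = 50,
                      subsample_fraction = 0.8, seed = 2)
  cons <- cr$per_k[["2"]]$consensus
  grp <- rep(c(1, 2), each = 5)
  same <- outer(grp, grp, "==")
  defined <- !is.na(cons)
  expect_true(all(abs(cons[defined & same] - 1) < 1e-12))
  expect_true(all(abs(cons[defined & !same]) < 1e-12))
  expect_equal(adjusted_rand_index(cr$per_k[["2"]]$assignments, grp), 1)
})

test_that("single full-sample iteration gives the 0/1 co-membership matrix", {
  em <- duplicated_group_matrix(n_per_group = 4)
  cr <- run_consensus(em, em$gene_ids, k_range = 2, n_iterations = 1,
                      subsample_fraction = 1, seed = 5)
  cons <- cr$per_k[["2"]]$consensus
  expect_true(all(cons %in% c(0, 1)))
  labs <- cr$per_k[["2"]]$assignments
  expect_identical(unname(cons), unname(outer(labs, labs, "==") * 1))
})

test_that("consensus entries are invariant under sample reordering", {
  em <- duplicated_group_matrix(n_per_group = 4)
  perm <- c(3, 7, 1, 8, 5, 2, 6, 4)
  vals <- em$values[, perm]
  colnames(vals) <- paste0("r", seq_len(8)) # fresh ids, permuted data
  em2 <- expression_matrix(vals, layer = "logcpm")
  c1 <- run_consensus(em, em$gene_ids, 2, n_iterations = 80, seed = 3)
  c2 <- run_consensus(em2, em2$gene_ids, 2, n_iterations = 80, seed = 3)
  m1 <- c1$per_k[["2"]]$consensus
  m2 <- c2$per_k[["2"]]$consensus
  # compare after undoing the permutation; entries defined in both runs
  m2u <- m2[order(perm), order(perm)]
  both <- !is.na(m1) & !is.na(m2u)
  expect_true(all(abs(m1[both] - m2u[both]) < 1e-12))
})

test_that("CDF/AUC diagnostics match a closed-form step integral", {
  # synthetic ConsensusResult with all-0/1 consensus values
  n <- 6
  cons <- matrix(0, n, n); cons[1:3, 1:3] <- 1; cons[4:6, 4:6] <- 1
  diag(cons) <- 1
  fake <- structure(list(k_range = 2L,
                         per_k = list(`2` = list(consensus = cons)),
                         sample_ids = paste0("s", 1:n)),
                    class = "ConsensusResult")
  fake <- consensus_cdf_auc(fake)
  vals <- cons[lower.tri(cons)]
  f0 <- mean(vals == 0)
  # step CDF: f0 on [0, 1); trapezoid grid gives f0 * 0.99 + (f0+1)/2 * 0.01
  expect_equal(fake$auc[["2"]], f0 * 0.99 + (f0 + 1) / 2 * 0.01, tolerance = 1e-12)
  expect_true(all(diff(fake$per_k[["2"]]$cdf) >= 0))
  expect_equal(fake$per_k[["2"]]$cdf[101], 1)
})

test_that("delta-AUC arithmetic follows the relative-change definition", {
  cons1 <- diag(4) * 0 + 0.2; diag(cons1) <- 1
  cons2 <- cons1
  fake <- structure(list(k_range = c(2L, 3L),
                         per_k = list(`2` = list(consensus = cons1),
                                      `3` = list(consensus = cons2)),
                         sample_ids = paste0("s", 1:4)),
                    class = "ConsensusResult")
  fake <- consensus_cdf_auc(fake)
  expect_equal(fake$delta_auc[[1]], fake$auc[[1]])
  expect_equal(fake$delta_auc[[2]], 0) # identical AUC at successive K
  # (0.5, 0.6) -> delta 0.2, checked on the formula directly
  expect_equal((0.6 - 0.5) / 0.5, 0.2)
})

test_that("assignments are seed-invariant for perfectly separated data", {
  em <- duplicated_group_matrix(n_per_group = 5)
  grp <- rep(c(1, 2), each = 5)
  aris <- vapply(1:10, function(s) {
    cr <- run_consensus(em, em$gene_ids, 2, n_iterations = 30, seed = s)
    adjusted_rand_index(cr$per_k[["2"]]$assignments, grp)
  }, numeric(1))
  expect_true(all(aris == 1))
})

test_that("run_consensus validates inputs", {
  em <- duplicated_group_matrix()
  expect_error(run_consensus(em, c(em$gene_ids, "nope"), 2, 10), "absent")
  expect_error(run_consensus(em, em$gene_ids, k_range = 9, n_iterations = 10,
                             subsample_fraction = 0.8), "subsample size")
})

test_that("pca_embed: rank-1 data, eigen oracle, duplicated samples", {
  # samples on a line in gene space
  base <- c(1, 2, 3)
  vals <- outer(base, c(0, 1, 2, 3)) + 5
  em <- tiny_logcpm(vals)
  p <- pca_embed(em)
  expect_equal(p$variance_explained[1], 1, tolerance = 1e-12)

  set.seed(20)
  vals2 <- matrix(rnorm(8 * 12), 8, 12)
  em2 <- tiny_logcpm(vals2)
  p2 <- pca_embed(em2)
  cov_s <- stats::cov(t(em2$values)) * (12 - 1) # scatter matrix of samples
  ev <- eigen(cov_s, symmetric = TRUE)
  for (j in 1:3) {
    expect_lt(min(sum((p2$loadings[, j] - ev$vectors[, j])^2),
                  sum((p2$loadings[, j] + ev$vectors[, j])^2)), 1e-16)
  }
  expect_equal(p2$variance_explained[1:3],
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-10)
  # unit-norm loadings, non-increasing variance, positive max-loading sign
  expect_equal(colSums(p2$loadings^2), rep(1, ncol(p2$loadings)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(diff(p2$variance_explained) <= 1e-12))
  expect_true(all(apply(p2$loadings, 2, function(v) v[which.max(abs(v))] > 0)))

  # duplicated samples get identical scores
  vals3 <- cbind(vals2, vals2[, 1])
  colnames(vals3) <- paste0("s", 1:13)
  p3 <- pca_embed(tiny_logcpm(vals3))
  expect_equal(p3$scores[1, ], p3$scores[13, ], tolerance = 1e-10)
  expect_error(pca_embed(tiny_logcpm(matrix(1:3, 3, 1))), "at least 2")
})

test_that("AUC polarizes toward 1 as K reaches the true block count", {
  set.seed(14)
  blocks <- rep(1:3, each = 5)
  vals <- matrix(rnorm(60 * 15, sd = 0.05), 60, 15) +
    outer(rnorm(60), as.numeric(blocks == 1) * 3) +
    outer(rnorm(60), as.numeric(blocks == 2) * 3)
  em <- tiny_logcpm(vals)
  cr <- run_consensus(em, em$gene_ids, k_range = 2:3, n_iterations = 60, seed = 1)
  expect_gt(cr$auc[["3"]], cr$auc[["2"]])
  cons3 <- cr$per_k[["3"]]$consensus
  vals3 <- cons3[lower.tri(cons3)]
  expect_gt(mean(vals3 < 0.05 | vals3 > 0.95, na.rm = TRUE), 0.9)
})
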