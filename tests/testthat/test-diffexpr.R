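# DE recovery tests run on reduced cohorts (hundreds of genes) to keep
# the suite fast; power is set by the planted effect, not the gene count.

make_de_cohort <- function(n_per = c(30, 90), n_genes = 400, n_de = 40,
                           effect = 4, seed = 17) {
  p <- bulk_sim_params(n_samples = sum(n_per),
                       cluster_proportions = n_per / sum(n_per),
                       n_genes = n_genes, markers_per_cluster = n_de,
                       log2_effect = effect, oarsi_shift = c(0, 0),
                       trauma_rate = c(0.1, 0.1), seed = seed)
  sim <- simulate_bulk(p)
  list(lc = log_cpm(sim$expression), sim = sim)
}

test_that("planted cluster markers are recovered up at q < 0.05", {
  co <- make_de_cohort()
  labels <- co$sim$metadata$cluster
  de <- de_cluster_vs_rest(co$lc, labels, "C1")
  planted <- co$sim$truth$C1
  hits <- de$gene[de$q_value < 0.05 & de$direction == "up"]
  expect_gte(mean(planted %in% hits), 0.9) # power >= 0.9 at n = 30 vs 90
})

test_that("constant genes and degenerate designs are handled", {
  vals <- rbind(flat = rep(3, 10), varying = c(rnorm(5, 1), rnorm(5, 4)))
  em <- tiny_logcpm(vals, genes = c("flat", "varying"))
  de <- de_cluster_vs_rest(em, rep(c("a", "b"), each = 5), "a",
                           expressed_min_frac = 0)
  expect_equal(de$p_value[de$gene == "flat"], 1)
  expect_equal(de$log2_fold_change[de$gene == "flat"], 0)
  expect_error(de_cluster_vs_rest(em, c("a", rep("b", 9)), "a",
                                  expressed_min_frac = 0), "at least 2")
})

test_that("degeneration DE is antisymmetric under strata swap", {
  co <- make_de_cohort(n_per = c(20, 20), n_genes = 100, seed = 3)
  md <- co$sim$metadata
  md$d_oarsi <- rep(c(10L, 25L), 20)
  de_hi <- de_degeneration(co$lc, md, threshold = 20)
  # swapping strata: recode so previous high becomes low
  md2 <- md
  md2$d_oarsi <- ifelse(md$d_oarsi >= 20, 10L, 25L)
  de_lo <- de_degeneration(co$lc, md2, threshold = 20)
  m <- match(de_hi$gene, de_lo$gene)
  expect_equal(de_hi$log2_fold_change, -de_lo$log2_fold_change[m], tolerance = 1e-12)
  expect_equal(de_hi$p_value, de_lo$p_value[m], tolerance = 1e-12)
  md$d_oarsi <- rep(5L, nrow(md))
  expect_error(de_degeneration(co$lc, md, threshold = 20), "one stratum")
})

test_that("genes shifted in high-OARSI samples come out positive", {
  set.seed(8)
  n <- 60; n_genes <- 150
  vals <- matrix(rnorm(n_genes * n, 5), n_genes, n,
                 dimnames = list(sprintf("g%03d", 1:n_genes), sprintf("s%03d", 1:n)))
  high <- rep(c(FALSE, TRUE), each = n / 2)
  shifted <- 1:15
  vals[shifted, high] <- vals[shifted, high] + 2
  em <- expression_matrix(vals, layer = "logcpm")
  md <- data.frame(sample_id = colnames(vals),
                   d_oarsi = ifelse(high, 22L, 12L))
  de <- de_degeneration(em, md, threshold = 20, expressed_min_frac = 0)
  hits <- de$gene[de$q_value < 0.05 & de$direction == "up"]
  expect_true(all(rownames(vals)[shifted] %in% hits))
})

test_that("label permutation yields near-zero discoveries", {
  co <- make_de_cohort(n_per = c(30, 30), n_genes = 300, n_de = 0,
                       effect = 0, seed = 5)
  labels <- co$sim$metadata$cluster
  set.seed(33)
  fdp <- replicate(10, {
    de <- de_cluster_vs_rest(co$lc, sample(labels), "C1")
    mean(de$q_value < 0.05)
  })
  expect_lte(mean(fdp), 0.05)
})

test_that("associate_metadata dispatches tests by type and normality", {
  set.seed(44)
  n <- 90
  labels <- rep(c("C1", "C2", "C3"), each = 30)
  md <- data.frame(
    sample_id = sprintf("s%02d", 1:n),
    gaussian = rnorm(n, 50, 5),
    skewed = rexp(n) + ifelse(labels == "C2", 2, 0),
    binary = ifelse(runif(n) < ifelse(labels == "C3", 0.6, 0.1), "yes", "no"),
    stringsAsFactors = FALSE
  )
  res <- associate_metadata(md, labels, seed = 7)
  expect_identical(res$test_used[res$variable == "gaussian"], "welch_anova")
  expect_identical(res$test_used[res$variable == "skewed"], "kruskal_wallis")
  expect_identical(res$test_used[res$variable == "binary"], "fisher_exact")
  expect_lt(res$p_value[res$variable == "binary"], 0.05)
  expect_lt(res$p_value[res$variable == "skewed"], 0.05)
  # summaries cover every cluster
  expect_true(all(lengths(res$group_summary) == 3L))
  md$all_missing <- NA_real_
  expect_warning(associate_metadata(md, labels, seed = 7), "skipped")
})

test_that("2x2 categorical association matches the hypergeometric oracle", {
  labels <- rep(c("C1", "C2"), c(10, 10))
  md <- data.frame(sample_id = sprintf("s%02d", 1:20),
                   flag = rep(c("y", "n", "y", "n"), c(3, 7, 8, 2)),
                   stringsAsFactors = FALSE)
  res <- associate_metadata(md, labels)
  expect_equal(res$p_value, oracle_fisher_p(3, 8, 7, 2), tolerance = 1e-12)
})

test_that("Kruskal-Wallis p-values are calibrated under the null", {
  set.seed(55)
  labels <- rep(c("C1", "C2", "C3"), each = 20)
  pvals <- replicate(200, {
    md <- data.frame(sample_id = sprintf("s%02d", 1:60), v = rexp(60))
    stats::kruskal.test(md$v, factor(labels))$p.value
  })
  mine <- replicate(40, {
    md <- data.frame(sample_id = sprintf("s%02d", 1:60), v = rexp(60),
                     stringsAsFactors = FALSE)
    associate_metadata(md, labels)$p_value
  })
  # the dispatch's KW p-values sit inside the same null distribution
  expect_gt(stats::ks.test(mine, pvals)$p.value, 0.01)
})

test_that("a cluster-specific trauma covariate is detected at cohort sizes", {
  # 38% vs 4-14% rates with paper-like group sizes (39/51/36/9)
  set.seed(66)
  sizes <- c(39, 51, 36, 9)
  labels <- rep(paste0("C", 1:4), sizes)
  rates <- c(0.10, 0.04, 0.14, 0.38)
  hits <- replicate(40, {
    flag <- ifelse(runif(sum(sizes)) < rates[match(labels, paste0("C", 1:4))],
                   "yes", "no")
    md <- data.frame(sample_id = seq_along(labels), flag = flag,
                     stringsAsFactors = FALSE)
    associate_metadata(md, labels, seed = 5, n_sim = 2000)$p_value < 0.05
  })
  # moderate power: the C4 cell is tiny, so require detection well above alpha
  expect_gt(mean(hits), 0.3)
})
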