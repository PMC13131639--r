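# Hypothesis-testing primitives used across the pipeline. The rank-based
# tests carry their own exact small-sample paths so that downstream
# modules do not depend on any particular engine's conventions.

# Exact null distribution of the rank-sum W of a group of size n among
# N = n + m untied observations, by dynamic programming over subset sums.
ranksum_null <- function(n, m) {
  N <- n + m
  wmax <- sum((N - n + 1):N)
  # f[k+1, w+1] = number of k-subsets of {1..N} with rank sum w
  f <- matrix(0, nrow = n + 1L, ncol = wmax + 1L)
  f[1L, 1L] <- 1
  for (r in seq_len(N)) {
    kmax <- min(r, n)
    for (k in kmax:1) {
      idx <- (r + 1L):(wmax + 1L)
      f[k + 1L, idx] <- f[k + 1L, idx] + f[k, idx - r]
    }
  }
  counts <- f[n + 1L, ]
  list(w = 0:wmax, prob = counts / choose(N, n))
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided. In `auto` mode an exact enumeration of the rank-sum null is
#' used when the smaller group has at most 12 observations and there are
#' no ties; otherwise a normal approximation with tie and continuity
#' correction is used.
#'
#' @param x,y non-empty numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"normal_tie_corrected"`.
#' @return List with `statistic` (rank sum of `x`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal_tie_corrected")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) stop("both input vectors must be non-empty")
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n)])
  ties <- anyDuplicated(pooled) > 0L
  if (mode == "exact" || (mode == "auto" && min(n, m) <= 12L && !ties)) {
    if (ties) stop("exact mode is undefined in the presence of ties")
    null <- ranksum_null(n, m)
    lo <- sum(null$prob[null$w <= W])
    hi <- sum(null$prob[null$w >= W])
    p <- min(1, 2 * min(lo, hi))
  } else {
    mu <- n * (N + 1) / 2
    tie_tab <- table(pooled)
    sigma2 <- n * m / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(statistic = W, p_value = 1))
    z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- min(1, 2 * stats::pnorm(-z))
  }
  list(statistic = W, p_value = p)
}

#' One-sample Wilcoxon signed-rank test
#'
#' Two-sided test of symmetry about `mu`. Zeros (values equal to `mu`) are
#' dropped. Exact enumeration over all sign assignments is used for up to
#' 12 non-zero values (valid under ties in the absolute ranks); otherwise
#' a tie-corrected normal approximation with continuity correction.
#'
#' @param x numeric vector.
#' @param mu hypothesised centre (default 0).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return List with `statistic` (positive-rank sum V), `p_value`, `n_used`.
#' @export
signed_rank_test <- function(x, mu = 0, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(statistic = 0, p_value = 1, n_used = 0L))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (mode == "exact" || (mode == "auto" && n <= 12L)) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_null <- as.numeric(signs %*% r)
    lo <- mean(v_null <= V + 1e-9)
    hi <- mean(v_null >= V - 1e-9)
    p <- min(1, 2 * min(lo, hi))
  } else {
    mu_v <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) return(list(statistic = V, p_value = 1, n_used = n))
    z <- max(0, abs(V - mu_v) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-z))
  }
  list(statistic = V, p_value = p, n_used = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control: `q_i = min over {j : p_j >= p_i} of m * p_j / rank_j`,
#' clipped at 1. Order-preserving; `NA`s propagate.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return Vector of q-values in the input order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(q)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  q
}

# Exact two-sided Fisher p for a 2x2 table by summation of hypergeometric
# probabilities no larger than that of the observed table.
fisher_exact_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m1 <- a + b; m2 <- c + d; k <- a + c
  support <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(p_value = min(1, p), odds_ratio = or)
}

# log probability of an r x c table under fixed margins
log_table_prob <- function(tab) {
  sum(lfactorial(rowSums(tab))) + sum(lfactorial(colSums(tab))) -
    lfactorial(sum(tab)) - sum(lfactorial(tab))
}

#' Fisher's exact test for contingency tables
#'
#' Exact (conditional hypergeometric) for 2x2 tables; Monte Carlo over
#' margin-fixed tables for larger tables, with a +1 pseudocount and a
#' fixed seed for determinism.
#'
#' @param tab integer matrix of counts.
#' @param n_sim Monte Carlo draws for tables larger than 2x2.
#' @param seed RNG seed for the Monte Carlo path.
#' @return List with `p_value`, `method`, and `odds_ratio` (2x2 only).
#' @export
fisher_exact <- function(tab, n_sim = 1e5, seed = 1L) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (nrow(tab) == 2L && ncol(tab) == 2L) {
    res <- fisher_exact_2x2(tab)
    return(list(p_value = res$p_value, method = "exact", odds_ratio = res$odds_ratio))
  }
  keep_r <- rowSums(tab) > 0; keep_c <- colSums(tab) > 0
  tab <- tab[keep_r, keep_c, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(list(p_value = 1, method = "degenerate", odds_ratio = NA_real_))
  }
  lp_obs <- log_table_prob(tab)
  p <- with_seed(seed, {
    sims <- stats::r2dtable(n_sim, rowSums(tab), colSums(tab))
    lp <- vapply(sims, log_table_prob, numeric(1))
    (1 + sum(lp <= lp_obs + 1e-7)) / (n_sim + 1)
  })
  list(p_value = p, method = "monte_carlo", odds_ratio = NA_real_)
}

#' Spearman correlation with tie correction
#'
#' rho is the Pearson correlation of mid-ranks. The p-value uses full
#' permutation enumeration for n <= 9 and the t approximation otherwise.
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @return List with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_assoc <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rho is undefined for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    perms <- permutations_of(n)
    cx <- rx - mean(rx)
    denom <- sqrt(sum(cx^2)) * sqrt(sum((ry - mean(ry))^2))
    rho_null <- as.numeric((matrix(ry[perms], nrow = nrow(perms)) %*% cx) -
                             0) / denom
    # centre term vanishes because sum(cx) = 0
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
    method <- "t_approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

# All permutations of 1..n as an n! x n matrix (n <= 9).
permutations_of <- function(n) {
  if (n > 9L) stop("permutation enumeration capped at n = 9")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    remap <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(remap[sub], nrow(sub), n - 1L)
  }
  out
}
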