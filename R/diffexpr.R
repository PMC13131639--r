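# Differential expression and metadata association. The DE engine is a
# rank-sum test on logCPM with Benjamini-Hochberg control: distribution
# free and reproducible; the result contract keeps the engine pluggable.

# Core engine: two-group rank-sum DE on a logCPM matrix.
de_two_group <- function(x, in_group, expressed_min_frac = 0.1) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$layer != "logcpm") stop("DE expects the logcpm layer")
  n_in <- sum(in_group); n_out <- sum(!in_group)
  if (n_in < 2L || n_out < 2L) stop("each group needs at least 2 samples")
  expressed <- rowMeans(x$values > 0) >= expressed_min_frac
  genes <- x$gene_ids[expressed]
  vals <- x$values[expressed, , drop = FALSE]
  stat <- p <- lfc <- numeric(length(genes))
  for (i in seq_along(genes)) {
    v <- vals[i, ]
    a <- v[in_group]; b <- v[!in_group]
    lfc[i] <- mean(a) - mean(b)
    wt <- wilcoxon_rank_sum(a, b, mode = "normal_tie_corrected")
    stat[i] <- wt$statistic
    p[i] <- wt$p_value
  }
  q <- bh_adjust(p)
  out <- data.frame(gene = genes, log2_fold_change = lfc, statistic = stat,
                    p_value = p, q_value = q,
                    direction = ifelse(lfc >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out[order(out$p_value, out$gene), ]
}

#' Cluster-versus-rest differential expression
#'
#' Rank-sum test of each expressed gene in the target cluster versus all
#' remaining samples; log2FC is the mean logCPM difference; BH correction
#' across tested genes. Genes are "expressed" when non-zero in at least
#' `expressed_min_frac` of samples.
#'
#' @param x logCPM [expression_matrix()].
#' @param labels cluster label per sample (aligned with `x$sample_ids`).
#' @param target cluster label to contrast against the rest.
#' @param expressed_min_frac expressed-gene filter (default 0.1).
#' @return `data.frame` with gene, log2_fold_change, statistic, p_value,
#'   q_value, direction; ordered by p.
#' @export
de_cluster_vs_rest <- function(x, labels, target, expressed_min_frac = 0.1) {
  if (length(labels) != length(x$sample_ids)) stop("one label per sample required")
  if (!target %in% labels) stop("target cluster not present in labels")
  de_two_group(x, labels == target, expressed_min_frac)
}

#' Degeneration-dichotomy differential expression
#'
#' Samples are stratified at `d_oarsi >= threshold` (high degeneration)
#' and contrasted with the same engine as [de_cluster_vs_rest()];
#' positive log2FC means higher expression with high degeneration.
#'
#' @param x logCPM [expression_matrix()].
#' @param metadata data.frame with `sample_id` and `d_oarsi` covering all
#'   samples of `x`.
#' @param threshold D-OARSI dichotomy point (default 20).
#' @param expressed_min_frac expressed-gene filter (default 0.1).
#' @return As [de_cluster_vs_rest()].
#' @export
de_degeneration <- function(x, metadata, threshold = 20L, expressed_min_frac = 0.1) {
  idx <- match(x$sample_ids, metadata$sample_id)
  if (anyNA(idx)) stop("metadata missing for sample(s): ",
                       paste(utils::head(x$sample_ids[is.na(idx)], 3), collapse = ", "))
  high <- metadata$d_oarsi[idx] >= threshold
  if (all(high) || !any(high)) {
    stop("degeneration threshold ", threshold, " puts all samples in one stratum")
  }
  de_two_group(x, high, expressed_min_frac)
}

#' Cluster-association tests for clinical metadata
#'
#' Continuous variables: Shapiro-Wilk in every cluster; if all p > 0.05
#' the variable is summarised as mean (SD) and tested by Welch's one-way
#' ANOVA, otherwise as median (p25, p75) with a Kruskal-Wallis test.
#' Categorical variables use Fisher's exact test (exact for 2x2,
#' Monte Carlo otherwise) and n (%) summaries.
#'
#' @param metadata data.frame, one row per sample.
#' @param labels cluster label per row of `metadata`.
#' @param variables columns to test; default: all columns except
#'   `sample_id` and `cluster`. Numeric columns are treated as continuous,
#'   everything else as categorical.
#' @param normality_alpha Shapiro-Wilk dispatch threshold (default 0.05).
#' @param seed seed for Monte Carlo Fisher tests.
#' @param n_sim Monte Carlo draws for Fisher tests beyond 2x2.
#' @return `data.frame` with variable, type, test_used, p_value and a
#'   `group_summary` list-column of per-cluster summaries.
#' @export
associate_metadata <- function(metadata, labels, variables = NULL,
                               normality_alpha = 0.05, seed = 1L, n_sim = 1e5) {
  labels <- as.character(labels)
  if (length(labels) != nrow(metadata)) stop("one label per metadata row required")
  groups <- split(seq_len(nrow(metadata)), labels)
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    stop("need at least 2 clusters with at least 2 samples each")
  }
  if (is.null(variables)) {
    variables <- setdiff(names(metadata), c("sample_id", "cluster"))
  }
  rows <- list()
  for (v in variables) {
    vals <- metadata[[v]]
    if (all(is.na(vals))) {
      warning("variable '", v, "' missing for all samples; skipped")
      next
    }
    if (is.numeric(vals)) {
      sw_p <- vapply(groups, function(ix) {
        g <- vals[ix][!is.na(vals[ix])]
        if (length(unique(g)) < 3L || length(g) < 3L) return(0) # cannot assess: non-normal path
        stats::shapiro.test(g)$p.value
      }, numeric(1))
      if (all(sw_p > normality_alpha)) {
        fit <- stats::oneway.test(vals ~ factor(labels), var.equal = FALSE)
        test_used <- "welch_anova"
        pval <- fit$p.value
        summ <- vapply(groups, function(ix) {
          g <- vals[ix]
          sprintf("%.1f (%.1f)", mean(g, na.rm = TRUE), stats::sd(g, na.rm = TRUE))
        }, character(1))
      } else {
        fit <- stats::kruskal.test(vals, factor(labels))
        test_used <- "kruskal_wallis"
        pval <- fit$p.value
        summ <- vapply(groups, function(ix) {
          q <- stats::quantile(vals[ix], c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
          sprintf("%.1f (%.1f, %.1f)", q[2], q[1], q[3])
        }, character(1))
      }
      type <- "continuous"
    } else {
      tab <- table(factor(vals), factor(labels))
      ft <- fisher_exact(unclass(tab), n_sim = n_sim, seed = seed)
      test_used <- "fisher_exact"
      pval <- ft$p_value
      summ <- vapply(groups, function(ix) {
        tt <- table(factor(vals[ix], levels = rownames(tab)))
        paste(sprintf("%s: %d (%.0f%%)", names(tt), tt, 100 * tt / sum(tt)),
              collapse = "; ")
      }, character(1))
      type <- "categorical"
    }
    rows[[v]] <- list(variable = v, type = type, test_used = test_used,
                      p_value = pval, group_summary = summ)
  }
  out <- data.frame(
    variable = vapply(rows, `[[`, character(1), "variable"),
    type = vapply(rows, `[[`, character(1), "type"),
    test_used = vapply(rows, `[[`, character(1), "test_used"),
    p_value = vapply(rows, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  out$group_summary <- lapply(rows, `[[`, "group_summary")
  rownames(out) <- NULL
  out
}
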