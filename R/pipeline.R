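# End-to-end orchestration on synthetic cohorts: simulate -> normalize ->
# cluster -> DE -> markers -> score -> gsea -> spatial -> report, with a
# JSON run manifest recording parameters, per-stage seeds and output
# checksums so any stage can be re-executed in isolation.

default_pipeline_config <- function() {
  list(
    stages = c("simulate", "normalize", "cluster", "de", "markers",
               "score", "gsea", "spatial", "report"),
    master_seed = 1L,
    outdir = "synoclust_run",
    bulk = list(n_samples = 60L, n_genes = 2000L, markers_per_cluster = 100L,
                log2_effect = 2),
    sc = list(n_cells = 1000L, n_genes = 400L, markers_per_type = 5L),
    spatial = list(n_cells = 5000L),
    cluster = list(n_genes = 500L, k_range = 2:6, n_iterations = 100L,
                   subsample_fraction = 0.8),
    de = list(oarsi_threshold = 20L, expressed_min_frac = 0.1),
    markers = list(top_n = 20L),
    score = list(k = 15L),
    gsea = list(n_perm = 200L, gmt = NULL)
  )
}

read_pipeline_config <- function(config) {
  base <- default_pipeline_config()
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  out <- utils::modifyList(base, config)
  if (!is.null(out$gsea$gmt) && !file.exists(out$gsea$gmt)) {
    stop("config validation failed: GMT file not found: ", out$gsea$gmt)
  }
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the synthetic end-to-end pipeline
#'
#' Validates the configuration, runs the stages in dependency order and
#' writes per-stage TSV/CSV outputs plus a `manifest.json` with
#' parameters, derived per-stage seeds and MD5 checksums of every output.
#' Re-running with the same config reproduces identical checksums.
#'
#' @param config a list of overrides of the default config, or a path to
#'   a JSON file of such overrides. Keys: `master_seed`, `outdir`,
#'   `stages`, and per-stage parameter maps (`bulk`, `sc`, `spatial`,
#'   `cluster`, `de`, `markers`, `score`, `gsea`).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stage_names <- c("simulate", "cluster", "de", "markers", "score", "gsea", "spatial")
  seeds <- stats::setNames(as.list(derive_seeds(cfg$master_seed, length(stage_names))),
                           stage_names)
  manifest <- list(config = cfg, seeds = seeds, outputs = list())
  emit <- function(name, path) manifest$outputs[[name]] <<- path
  failed_marker <- file.path(cfg$outdir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fn) {
    if (!name %in% cfg$stages) return(invisible())
    ok <- tryCatch({ fn(); TRUE }, error = function(e) {
      writeLines(paste0("stage '", name, "' failed: ", conditionMessage(e)),
                 failed_marker)
      stop("pipeline aborted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    invisible(ok)
  }

  run_stage("simulate", function() {
    bp <- do.call(bulk_sim_params, c(cfg$bulk, list(seed = seeds$simulate)))
    state$bulk <- simulate_bulk(bp)
    scp <- do.call(sc_sim_params, c(cfg$sc, list(seed = seeds$simulate)))
    state$sc <- simulate_sc(scp)
    spp <- do.call(spatial_sim_params, c(cfg$spatial, list(seed = seeds$simulate)))
    state$spatial <- simulate_spatial(spp)
    emit("bulk_counts", write_expression(state$bulk$expression,
                                         file.path(cfg$outdir, "bulk_counts.csv")))
    emit("bulk_metadata", write_sample_metadata(state$bulk$metadata,
                                                file.path(cfg$outdir, "bulk_metadata.tsv")))
    truth <- data.frame(cluster = rep(names(state$bulk$truth), lengths(state$bulk$truth)),
                        gene = unlist(state$bulk$truth, use.names = FALSE))
    emit("bulk_truth", write_tsv(truth, file.path(cfg$outdir, "bulk_truth.tsv")))
  })

  run_stage("normalize", function() {
    state$logcpm <- log_cpm(state$bulk$expression)
    emit("bulk_logcpm", write_expression(state$logcpm,
                                         file.path(cfg$outdir, "bulk_logcpm.csv")))
  })

  run_stage("cluster", function() {
    genes <- select_variable_genes(state$logcpm, cfg$cluster$n_genes)
    state$consensus <- run_consensus(
      state$logcpm, genes, k_range = cfg$cluster$k_range,
      n_iterations = cfg$cluster$n_iterations,
      subsample_fraction = cfg$cluster$subsample_fraction,
      seed = seeds$cluster)
    k_hat <- select_k(state$consensus)
    k_use <- if (is.na(k_hat)) 4L else k_hat
    state$assignments <- paste0("C", state$consensus$per_k[[as.character(k_use)]]$assignments)
    emit("assignments", write_tsv(
      data.frame(sample_id = state$logcpm$sample_ids, cluster = state$assignments,
                 stringsAsFactors = FALSE),
      file.path(cfg$outdir, "cluster_assignments.tsv")))
    emit("delta_auc", write_tsv(
      data.frame(k = state$consensus$k_range, auc = unname(state$consensus$auc),
                 delta_auc = unname(state$consensus$delta_auc)),
      file.path(cfg$outdir, "consensus_delta_auc.tsv")))
    state$pca <- pca_embed(state$logcpm, genes, n_components = 10L)
    emit("pca_scores", write_tsv(
      data.frame(sample_id = rownames(state$pca$scores), state$pca$scores),
      file.path(cfg$outdir, "pca_scores.tsv")))
  })

  run_stage("de", function() {
    state$de <- de_degeneration(state$logcpm, state$bulk$metadata,
                                threshold = cfg$de$oarsi_threshold,
                                expressed_min_frac = cfg$de$expressed_min_frac)
    emit("de_degeneration", write_tsv(state$de,
                                      file.path(cfg$outdir, "de_degeneration.tsv")))
    assoc <- associate_metadata(state$bulk$metadata, state$bulk$metadata$cluster,
                                variables = c("d_oarsi", "kl_grade", "major_trauma"),
                                seed = seeds$de)
    assoc$group_summary <- vapply(assoc$group_summary, paste, character(1), collapse = " | ")
    emit("associations", write_tsv(assoc, file.path(cfg$outdir, "metadata_associations.tsv")))
  })

  run_stage("markers", function() {
    state$markers <- sc_markers(state$sc)
    flat <- do.call(rbind, lapply(names(state$markers), function(ty) {
      df <- state$markers[[ty]]
      if (nrow(df) == 0L) return(NULL)
      cbind(cell_type = ty, df)
    }))
    emit("markers", write_tsv(flat, file.path(cfg$outdir, "sc_markers.tsv")))
  })

  run_stage("score", function() {
    up <- state$de$gene[state$de$q_value < 0.25 & state$de$direction == "up"]
    dn <- state$de$gene[state$de$q_value < 0.25 & state$de$direction == "down"]
    # scoring needs genes shared with the single-cell universe; the
    # synthetic bulk and sc universes are disjoint, so fall back to the
    # top planted sc markers as a stand-in module when empty
    pos <- intersect(up, state$sc$gene_ids)
    neg <- intersect(dn, state$sc$gene_ids)
    if (length(pos) == 0L || length(neg) == 0L) {
      truth <- attr(state$sc, "truth")
      pos <- truth[["lining_fibroblast"]]
      neg <- truth[["sublining_fibroblast"]]
    }
    sv <- degeneration_score(state$sc, pos, neg)
    sv <- knn_smooth(sv, state$sc$embedding, k = min(cfg$score$k,
                                                     length(sv$raw) - 1L))
    state$scores <- sv
    emit("cell_scores", write_tsv(
      data.frame(cell_id = sv$cell_ids, raw = sv$raw, smoothed = sv$smoothed),
      file.path(cfg$outdir, "cell_scores.tsv")))
    emit("score_summary", write_tsv(summarize_scores(sv, state$sc),
                                    file.path(cfg$outdir, "score_summary.tsv")))
  })

  run_stage("gsea", function() {
    sets <- if (!is.null(cfg$gsea$gmt)) read_gmt(cfg$gsea$gmt) else {
      truth <- state$bulk$truth
      gene_set_collection(stats::setNames(truth, paste0("cluster_markers_", names(truth))),
                          source = "planted")
    }
    stats_vec <- stats::setNames(state$de$log2_fold_change, state$de$gene)
    state$gsea <- preranked_gsea_collection(stats_vec, sets,
                                            n_perm = cfg$gsea$n_perm,
                                            seed = seeds$gsea)
    emit("gsea", write_tsv(state$gsea, file.path(cfg$outdir, "gsea.tsv")))
  })

  run_stage("spatial", function() {
    tab <- state$spatial
    comp_whole <- composition(tab, "whole")
    comp_zoom <- composition(tab, "zoom")
    emit("composition_whole", write_tsv(comp_whole,
                                        file.path(cfg$outdir, "composition_whole.tsv")))
    emit("composition_zoom", write_tsv(comp_zoom,
                                       file.path(cfg$outdir, "composition_zoom.tsv")))
    emit("detection_stats", write_tsv(detection_stats(tab),
                                      file.path(cfg$outdir, "detection_stats.tsv")))
    emit("zoom_enrichment", write_tsv(zoom_gene_enrichment(tab, "zoom"),
                                      file.path(cfg$outdir, "zoom_gene_enrichment.tsv")))
  })

  run_stage("report", function() {
    manifest$checksums <<- as.list(tools::md5sum(unlist(manifest$outputs)))
  })

  manifest_path <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}
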