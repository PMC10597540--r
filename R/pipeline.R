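#' Pipeline configuration
#'
#' Validated bundle of paths, thresholds and counts driving [run_pipeline()].
#'
#' @param matrix_paths named character vector of expression matrix TSVs,
#'   names among the four modalities.
#' @param metadata_path path to the metadata TSV.
#' @param network_path optional regulator-target network TSV; regulator
#'   scoring is skipped when `NULL`.
#' @param out_dir output directory.
#' @param cluster_fdr exploratory FDR threshold for subtype calls (default 0.2).
#' @param de_fdr DE significance threshold (default 0.05).
#' @param overlap_alpha significance level for cluster overlaps (default 0.05).
#' @param metrics,linkages clustering grid (defaults: all five x all three).
#' @param max_k maximum clusters per dendrogram.
#' @param n_boot bootstrap resamples.
#' @param n_perm GSEA permutations.
#' @param freq_cut,unique_cut near-zero-variance filter parameters.
#' @param seed global seed; per-stage seeds are derived by a counter.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_paths, metadata_path, network_path = NULL,
                            out_dir = "episubtype_results",
                            cluster_fdr = 0.2, de_fdr = 0.05,
                            overlap_alpha = 0.05,
                            metrics = DISTANCE_METRICS,
                            linkages = LINKAGE_METHODS,
                            max_k = 10, n_boot = 1000, n_perm = 1000,
                            freq_cut = 19, unique_cut = 10, seed = 1L) {
  bad <- setdiff(names(matrix_paths), MODALITIES)
  if (length(bad)) stop("unknown modality in matrix_paths: ", paste(bad, collapse = ", "))
  for (thr in c(cluster_fdr = cluster_fdr, de_fdr = de_fdr,
                overlap_alpha = overlap_alpha)) {
    if (thr <= 0 || thr > 1) stop("thresholds must lie in (0, 1]")
  }
  for (p in c(unlist(matrix_paths), metadata_path, network_path))
    if (!file.exists(p)) stop("no such file: ", p)
  structure(list(matrix_paths = matrix_paths, metadata_path = metadata_path,
                 network_path = network_path, out_dir = out_dir,
                 cluster_fdr = cluster_fdr, de_fdr = de_fdr,
                 overlap_alpha = overlap_alpha, metrics = metrics,
                 linkages = linkages, max_k = max_k, n_boot = n_boot,
                 n_perm = n_perm, freq_cut = freq_cut,
                 unique_cut = unique_cut, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full subtype-discovery pipeline
#'
#' Per modality: preprocessing and subtype discovery; then bootstrap CIs and
#' bootstrap difference tests for every flagged cluster, pairwise
#' cross-modality cluster overlaps on shared-sample universes, cluster-vs-rest
#' differential expression, custom gene sets from the blood signatures with
#' cross-modality preranked GSEA against the matching brain ranking, and
#' (when a network is supplied) regulator activation scoring with concordance
#' against the blood miRNA DE. Every artifact is written under
#' `config$out_dir` and indexed in `manifest.json` together with the
#' per-stage seeds.
#'
#' @param config a [pipeline_config()].
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("'config' must be a pipeline_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed_counter <- local({ i <- 0L; function() {
    i <<- i + 1L; (config$seed + i) %% 2147483647L } })
  manifest <- list(package_version = as.character(utils::packageVersion("episubtype")),
                   r_version = as.character(getRversion()),
                   global_seed = config$seed, seeds = list(), artifacts = list())
  log_msg <- function(...) message("[episubtype] ", ...)

  metadata <- stage("read_metadata", read_metadata(config$metadata_path))
  calls <- list()
  de_tables <- list()
  for (mod in names(config$matrix_paths)) {
    unit <- if (grepl("mirna", mod)) "cpm" else "tpm"
    mat <- stage(paste0("read_matrix:", mod),
                 read_matrix(config$matrix_paths[[mod]], modality = mod, unit = unit))
    log_msg("preprocess ", mod, ": ", nrow(mat$values), " features x ",
            ncol(mat$values), " samples")
    pp <- stage(paste0("preprocess:", mod),
                preprocess_pipeline(mat, metadata, freq_cut = config$freq_cut,
                                    unique_cut = config$unique_cut))
    log_msg("subtype discovery ", mod, " (", nrow(pp$values),
            " features after filtering)")
    call <- stage(paste0("subtype:", mod),
                  discover_subtypes(pp, metadata, metrics = config$metrics,
                                    linkages = config$linkages,
                                    max_k = config$max_k,
                                    fdr_threshold = config$cluster_fdr))
    if (is.null(call)) { log_msg("no subtype called for ", mod); next }
    calls[[mod]] <- call
    assoc_path <- file.path(config$out_dir, paste0("subtype_", mod, ".json"))
    jsonlite::write_json(
      list(config = list(metric = call$distance$metric,
                         linkage = call$linkage$method),
           k = call$optimal_k,
           clusters = call$associations,
           best_cluster = call$best_cluster, best_fdr = call$best_fdr,
           direction = call$direction,
           assignments = as.list(call$assignments)),
      assoc_path, auto_unbox = TRUE, digits = NA)
    manifest$artifacts[[paste0("subtype_", mod)]] <- assoc_path

    s <- seed_counter()
    manifest$seeds[[paste0("bootstrap_", mod)]] <- s
    md <- metadata[match(names(call$assignments), metadata$sample_id), ]
    inb <- call$assignments == call$best_cluster
    ci <- stage(paste0("bootstrap_ci:", mod),
                bootstrap_proportion_ci(md$outcome[inb], n_boot = config$n_boot,
                                        seed = s))
    dt <- stage(paste0("bootstrap_test:", mod),
                bootstrap_difference_test(md$outcome[inb], md$outcome[!inb],
                                          n_boot = config$n_boot,
                                          seed = seed_counter()))
    ci_path <- file.path(config$out_dir, paste0("bootstrap_", mod, ".json"))
    jsonlite::write_json(list(point = ci$point, lower = ci$lower,
                              upper = ci$upper, n_boot = ci$n_boot,
                              difference_p = dt$p_value),
                         ci_path, auto_unbox = TRUE, digits = NA)
    manifest$artifacts[[paste0("bootstrap_", mod)]] <- ci_path

    de <- stage(paste0("de:", mod),
                differential_expression(pp, call$assignments, call$best_cluster))
    de_tables[[mod]] <- de
    de_path <- file.path(config$out_dir, paste0("de_", mod, ".tsv"))
    write_de_table(de, de_path)
    manifest$artifacts[[paste0("de_", mod)]] <- de_path
  }

  if (length(calls) >= 2L) {
    pairs <- utils::combn(names(calls), 2L, simplify = FALSE)
    ov <- lapply(pairs, function(pr) {
      a <- calls[[pr[1L]]]; b <- calls[[pr[2L]]]
      shared <- intersect(names(a$assignments), names(b$assignments))
      if (length(shared) < 2L) return(NULL)
      res <- overlap_test(
        intersect(names(a$assignments)[a$assignments == a$best_cluster], shared),
        intersect(names(b$assignments)[b$assignments == b$best_cluster], shared),
        shared)
      data.frame(modality_a = pr[1L], modality_b = pr[2L],
                 same_direction = a$direction == b$direction,
                 n_universe = res$n_universe, n_a = res$n_a, n_b = res$n_b,
                 n_intersection = res$n_intersection, p_over = res$p_over,
                 overlap_percent = res$overlap_percent,
                 significant = res$p_over < config$overlap_alpha &
                   a$direction == b$direction,
                 stringsAsFactors = FALSE)
    })
    ov <- do.call(rbind, ov)
    if (!is.null(ov)) {
      ov_path <- file.path(config$out_dir, "cluster_overlaps.tsv")
      utils::write.table(ov, ov_path, sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$artifacts$cluster_overlaps <- ov_path
    }
  }

  # cross-modality GSEA: blood signatures against the matching brain ranking
  for (kind in c("mirna", "mrna")) {
    blood <- paste0("blood_", kind); brain <- paste0("brain_", kind)
    if (is.null(de_tables[[blood]]) || is.null(de_tables[[brain]])) next
    sets <- withCallingHandlers(
      build_custom_sets(de_tables[[blood]], fdr_cut = config$de_fdr,
                        name_prefix = paste0(blood, "_sig")),
      warning = function(w) { log_msg(conditionMessage(w)); invokeRestart("muffleWarning") })
    if (!length(sets)) next
    ranks <- stats::setNames(de_tables[[brain]]$log2_fc, de_tables[[brain]]$feature)
    sets <- Filter(function(s) any(s$members %in% names(ranks)), sets)
    if (!length(sets)) next
    s <- seed_counter()
    manifest$seeds[[paste0("gsea_", kind)]] <- s
    gsea <- stage(paste0("gsea:", kind),
                  preranked_gsea(ranks, sets, n_perm = max(100, config$n_perm),
                                 seed = s))
    gsea_path <- file.path(config$out_dir, paste0("gsea_", kind, ".tsv"))
    flat <- gsea
    flat$leading_edge <- vapply(gsea$leading_edge, paste, character(1L),
                                collapse = ",")
    utils::write.table(flat, gsea_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$artifacts[[paste0("gsea_", kind)]] <- gsea_path
    gmt_path <- file.path(config$out_dir, paste0("sets_", kind, ".gmt"))
    write_gmt(sets, gmt_path)
    manifest$artifacts[[paste0("sets_", kind)]] <- gmt_path
  }

  if (!is.null(config$network_path) && !is.null(de_tables$blood_mrna)) {
    network <- stage("read_network", read_network(config$network_path))
    scores <- stage("regulator_scores",
                    regulator_scores(network, de_tables$blood_mrna,
                                     fdr_cut = config$de_fdr))
    if (!is.null(de_tables$blood_mirna)) {
      conc <- stage("concordance",
                    concordance_table(scores, de_tables$blood_mirna))
      scores <- merge(scores, conc$table[, c("regulator", "observed_log2_fc",
                                             "observed_fdr", "concordant")],
                      by = "regulator", all.x = TRUE)
      manifest$concordance_counts <- as.list(conc$counts)
    }
    reg_path <- file.path(config$out_dir, "regulators.tsv")
    utils::write.table(scores, reg_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$artifacts$regulators <- reg_path
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  log_msg("done; manifest at ", manifest_path)
  invisible(manifest)
}
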