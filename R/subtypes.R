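DISTANCE_METRICS <- c("manhattan", "canberra", "binary", "minkowski", "euclidean")
LINKAGE_METHODS <- c("ward_d", "ward_d2", "complete")

grid_index <- function(metric, linkage) {
  (match(metric, DISTANCE_METRICS) - 1L) * length(LINKAGE_METHODS) +
    match(linkage, LINKAGE_METHODS)
}

#' Find the optimal number of clusters in one dendrogram
#'
#' Two-phase stepwise split. Phase 1: the dendrogram is cut at k = 2, each
#' cluster is tested against the rest ([split_and_test()]) and k is increased
#' until some cluster reaches `fdr_p < fdr_threshold`; if none does by
#' `max_k`, the search reports no subtype. Phase 2: while k < `max_k` and the
#' minimum nominal p-value among the k+1 cluster associations is smaller than
#' the minimum at k, the split advances; the final k is optimal.
#'
#' @param dendro an `hclust` object.
#' @param metadata cohort metadata.
#' @param max_k largest number of clusters examined.
#' @param fdr_threshold exploratory significance threshold on the
#'   BH-adjusted cluster association p-values (default 0.2).
#' @return a `subtype_call` object, or `NULL` when no cluster is significant
#'   at any examined k.
#' @export
find_optimal_clusters <- function(dendro, metadata, max_k = 10, fdr_threshold = 0.2) {
  if (max_k < 2L) stop("'max_k' must be at least 2")
  n <- length(dendro$order)
  kmax <- min(max_k, n)
  results <- list()
  k_sig <- NA_integer_
  for (k in 2L:kmax) {
    results[[k]] <- split_and_test(dendro, metadata, k)
    if (any(results[[k]]$fdr_p < fdr_threshold)) { k_sig <- k; break }
  }
  if (is.na(k_sig)) return(NULL)
  k <- k_sig
  while (k < kmax) {
    if (length(results) < k + 1L || is.null(results[[k + 1L]]))
      results[[k + 1L]] <- split_and_test(dendro, metadata, k + 1L)
    if (min(results[[k + 1L]]$wald_p) < min(results[[k]]$wald_p)) k <- k + 1L else break
  }
  build_subtype_call(dendro, metadata, k, results[[k]])
}

build_subtype_call <- function(dendro, metadata, k, assoc) {
  assignment <- cut_dendrogram(dendro, k)
  best <- order(assoc$fdr_p, assoc$wald_p, assoc$cluster)[1L]
  md <- metadata[match(names(assignment), metadata$sample_id), ]
  inb <- assignment == assoc$cluster[best]
  p_in <- mean(md$outcome[inb])
  p_out <- mean(md$outcome[!inb])
  structure(list(
    distance = attr(dendro, "distance_spec"),
    linkage = attr(dendro, "linkage_spec"),
    optimal_k = k,
    assignments = assignment,
    associations = assoc,
    best_cluster = assoc$cluster[best],
    best_fdr = assoc$fdr_p[best],
    direction = if (p_in > p_out) "risk" else "protective",
    recurrence_in = p_in,
    recurrence_out = p_out,
    dendrogram = dendro
  ), class = "subtype_call")
}

#' Select the best clustering configuration
#'
#' Picks the call whose flagged cluster has the lowest BH-adjusted p-value;
#' ties are broken by smaller optimal k, then by grid order (manhattan <
#' canberra < binary < minkowski < euclidean, crossed with ward_d < ward_d2 <
#' complete).
#'
#' @param calls list of `subtype_call` objects.
#' @return the winning `subtype_call`.
#' @export
select_best_approach <- function(calls) {
  calls <- Filter(Negate(is.null), calls)
  if (!length(calls)) stop("no subtype calls to select from")
  fdr <- vapply(calls, function(x) x$best_fdr, numeric(1L))
  k <- vapply(calls, function(x) x$optimal_k, numeric(1L))
  gi <- vapply(calls, function(x) {
    if (is.null(x$distance)) Inf
    else grid_index(x$distance$metric, x$linkage$method)
  }, numeric(1L))
  calls[[order(fdr, k, gi)[1L]]]
}

#' Discover outcome-associated molecular subtypes
#'
#' The core estimator: hierarchical clustering of samples over a distance x
#' linkage grid, stepwise dendrogram splitting with covariate-adjusted
#' logistic association against seizure recurrence and FDR-governed stopping
#' ([find_optimal_clusters()]), then selection of the configuration yielding
#' the cluster with the lowest adjusted p-value ([select_best_approach()]).
#'
#' @param matrix an [expr_matrix()] with unit `"scaled"` (see
#'   [preprocess_pipeline()]).
#' @param metadata cohort metadata covering the matrix samples.
#' @param metrics distance metrics to scan (default: all five).
#' @param linkages linkage methods to scan (default: all three).
#' @param minkowski_power,canberra_denominator passed to [compute_distance()].
#' @param max_k,fdr_threshold passed to [find_optimal_clusters()].
#' @return a `subtype_call` with the winning configuration, assignments,
#'   per-cluster association table and a `grid` summary of every
#'   configuration scanned; `NULL` when no configuration yields a significant
#'   cluster.
#' @export
discover_subtypes <- function(matrix, metadata,
                              metrics = DISTANCE_METRICS,
                              linkages = LINKAGE_METHODS,
                              minkowski_power = 2,
                              canberra_denominator = "abs",
                              max_k = 10, fdr_threshold = 0.2) {
  metrics <- match.arg(metrics, DISTANCE_METRICS, several.ok = TRUE)
  linkages <- match.arg(linkages, LINKAGE_METHODS, several.ok = TRUE)
  calls <- list()
  grid <- list()
  for (metric in metrics) {
    d <- compute_distance(matrix, metric, minkowski_power = minkowski_power,
                          canberra_denominator = canberra_denominator)
    for (linkage in linkages) {
      dendro <- agglomerate(d, linkage)
      attr(dendro, "distance_spec") <- list(metric = metric,
                                            minkowski_power = minkowski_power)
      attr(dendro, "linkage_spec") <- list(method = linkage)
      call <- find_optimal_clusters(dendro, metadata, max_k = max_k,
                                    fdr_threshold = fdr_threshold)
      id <- paste(metric, linkage, sep = "/")
      calls[[id]] <- call
      grid[[id]] <- data.frame(
        metric = metric, linkage = linkage,
        optimal_k = if (is.null(call)) NA_integer_ else call$optimal_k,
        best_cluster = if (is.null(call)) NA_integer_ else call$best_cluster,
        best_fdr = if (is.null(call)) NA_real_ else call$best_fdr,
        stringsAsFactors = FALSE)
    }
  }
  grid <- do.call(rbind, grid)
  rownames(grid) <- NULL
  if (all(vapply(calls, is.null, logical(1L)))) {
    message("no cluster reached FDR < ", fdr_threshold,
            " in any configuration; no subtype called")
    return(invisible(NULL))
  }
  best <- select_best_approach(calls)
  best$grid <- grid
  best
}

#' @export
print.subtype_call <- function(x, ...) {
  cfg <- if (is.null(x$distance)) "custom dendrogram"
  else paste0(x$distance$metric, " distance, ", x$linkage$method, " linkage")
  cat("Outcome-associated subtype call\n")
  cat(sprintf("  configuration: %s\n", cfg))
  cat(sprintf("  optimal k: %d clusters over %d samples\n",
              x$optimal_k, length(x$assignments)))
  cat(sprintf("  flagged cluster: %d (%s), n = %d, recurrence %d/%d = %.0f%% vs %.0f%% outside\n",
              x$best_cluster, x$direction,
              sum(x$assignments == x$best_cluster),
              x$associations$n_recurrence_in[x$associations$cluster == x$best_cluster],
              x$associations$n_in[x$associations$cluster == x$best_cluster],
              100 * x$recurrence_in, 100 * x$recurrence_out))
  cat(sprintf("  best FDR-adjusted p: %.3g\n", x$best_fdr))
  invisible(x)
}

#' @export
summary.subtype_call <- function(object, ...) {
  print(object)
  cat("\nPer-cluster associations at optimal k:\n")
  print(object$associations, row.names = FALSE, digits = 3)
  if (!is.null(object$grid)) {
    cat("\nConfiguration grid:\n")
    print(object$grid, row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Plot the dendrogram of a subtype call
#'
#' Draws the winning dendrogram with the optimal-k clusters boxed and the
#' flagged cluster highlighted.
#'
#' @param x a `subtype_call`.
#' @param ... passed to `plot.hclust`.
#' @export
plot.subtype_call <- function(x, ...) {
  h <- x$dendrogram
  plot(h, hang = -1, xlab = "", sub = "",
       main = sprintf("%s / %s: k = %d, flagged cluster %d (%s)",
                      x$distance$metric, x$linkage$method,
                      x$optimal_k, x$best_cluster, x$direction), ...)
  border <- ifelse(sort(unique(x$assignments)) == x$best_cluster, "red", "grey40")
  stats::rect.hclust(h, k = x$optimal_k, border = border)
  invisible(x)
}
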