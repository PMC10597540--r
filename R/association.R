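#' Covariate-adjusted association of cluster membership with outcome
#'
#' Maximum-likelihood logistic regression of seizure recurrence on an
#' indicator of membership in one cluster, adjusted for sex, pathology
#' (reference level: hippocampal sclerosis), surgical side and epilepsy
#' duration. Returns the two-sided Wald p-value for the indicator. Quasi- or
#' complete separation (fitted probabilities within 1e-8 of 0/1, or
#' coefficients beyond +/-15) is reported via `separation_flag` with
#' `converged = FALSE` rather than silently trusted.
#'
#' @param assignment named integer vector of cluster labels (from
#'   [cut_dendrogram()]).
#' @param metadata cohort metadata (see [read_metadata()]).
#' @param cluster_label the cluster whose membership indicator is tested.
#' @return one-row `data.frame`: cluster, n_in, n_recurrence_in, coefficient,
#'   wald_p, converged, separation_flag.
#' @export
cluster_outcome_association <- function(assignment, metadata, cluster_label) {
  idx <- match(names(assignment), metadata$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(names(assignment)[is.na(idx)], collapse = ", "))
  md <- metadata[idx, , drop = FALSE]
  in_cluster <- assignment == cluster_label
  if (!any(in_cluster) || all(in_cluster))
    stop("cluster ", cluster_label, " must have samples both inside and outside")
  if (length(unique(md$outcome)) < 2L)
    stop("degenerate model: outcome is constant across the cohort")
  dat <- data.frame(outcome = md$outcome,
                    in_cluster = in_cluster,
                    sex = md$sex,
                    pathology = droplevels(factor(md$pathology, levels = PATHOLOGY_LEVELS)),
                    surgical_side = md$surgical_side,
                    epilepsy_duration = md$epilepsy_duration)
  fit <- suppressWarnings(
    stats::glm(outcome ~ in_cluster + sex + pathology + surgical_side +
                 epilepsy_duration, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  co <- summary(fit)$coefficients
  row <- grep("^in_cluster", rownames(co))
  eps <- 1e-8
  sep <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps) ||
    any(abs(stats::coef(fit)) > 15, na.rm = TRUE)
  data.frame(cluster = cluster_label,
             n_in = sum(in_cluster),
             n_recurrence_in = sum(md$outcome[in_cluster]),
             coefficient = unname(co[row, "Estimate"]),
             wald_p = unname(co[row, "Pr(>|z|)"]),
             converged = fit$converged && !sep,
             separation_flag = sep,
             stringsAsFactors = FALSE)
}

#' Test every cluster of one dendrogram cut against the rest
#'
#' Cuts the dendrogram at `k`, fits one cluster-versus-rest logistic model
#' per cluster and applies Benjamini-Hochberg adjustment across the k nominal
#' Wald p-values of the cut.
#'
#' @param dendro an `hclust` object.
#' @param metadata cohort metadata.
#' @param k number of clusters.
#' @return `data.frame` with one row per cluster, including `fdr_p`.
#' @export
split_and_test <- function(dendro, metadata, k) {
  assignment <- cut_dendrogram(dendro, k)
  res <- do.call(rbind, lapply(seq_len(k), function(lbl)
    cluster_outcome_association(assignment, metadata, lbl)))
  res$fdr_p <- stats::p.adjust(res$wald_p, method = "BH")
  res
}
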