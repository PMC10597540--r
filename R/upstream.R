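#' Activation z-score for one upstream regulator
#'
#' Over the regulator's differentially expressed targets (`fdr_p < fdr_cut`
#' in `de`), a target is consistent with regulator activation when its
#' observed direction matches the expected edge sign under an active
#' regulator (a repression edge expects the target down). The unweighted
#' activation score is z = (n_consistent - n_inconsistent) /
#' sqrt(n_consistent + n_inconsistent); z <= -2 predicts a deactivated
#' regulator, z >= +2 an activated one. `overlap_p` is the hypergeometric
#' upper-tail probability of seeing that many DE targets among the
#' regulator's measured targets, against the measured universe.
#'
#' @param network edge data.frame (regulator, target, sign; see
#'   [read_network()]).
#' @param de a `de_table` of the target modality (e.g. cluster-vs-rest mRNA).
#' @param regulator regulator id.
#' @param fdr_cut DE significance cutoff (default 0.05).
#' @param z_threshold |z| cutoff for a directional prediction (default 2).
#' @return one-row `data.frame`: regulator, n_targets_measured, n_targets_de,
#'   n_consistent, n_inconsistent, overlap_p, z, predicted_state; or `NULL`
#'   (with a message) when the regulator has no DE target.
#' @export
activation_zscore <- function(network, de, regulator, fdr_cut = 0.05,
                              z_threshold = 2) {
  edges <- network[network$regulator == regulator, , drop = FALSE]
  if (!nrow(edges)) stop("regulator '", regulator, "' absent from the network")
  measured <- edges[edges$target %in% de$feature, , drop = FALSE]
  de_sub <- de[match(measured$target, de$feature), , drop = FALSE]
  is_de <- de_sub$fdr_p < fdr_cut
  if (!any(is_de)) {
    message("regulator '", regulator, "' has no differentially expressed target; score omitted")
    return(NULL)
  }
  expected_dir <- ifelse(measured$sign[is_de] == "repression", "down", "up")
  consistent <- de_sub$direction[is_de] == expected_dir
  n_c <- sum(consistent); n_i <- sum(!consistent)
  z <- (n_c - n_i) / sqrt(n_c + n_i)
  n_de_universe <- sum(de$fdr_p < fdr_cut)
  overlap_p <- stats::phyper(sum(is_de) - 1L, n_de_universe,
                             nrow(de) - n_de_universe, nrow(measured),
                             lower.tail = FALSE)
  state <- if (z >= z_threshold) "activated"
           else if (z <= -z_threshold) "deactivated" else "indeterminate"
  data.frame(regulator = regulator,
             n_targets_measured = nrow(measured),
             n_targets_de = sum(is_de),
             n_consistent = n_c, n_inconsistent = n_i,
             overlap_p = overlap_p, z = z, predicted_state = state,
             stringsAsFactors = FALSE)
}

#' Score every regulator of a network
#'
#' @inheritParams activation_zscore
#' @return `data.frame` of [activation_zscore()] rows for the regulators with
#'   at least one differentially expressed target.
#' @export
regulator_scores <- function(network, de, fdr_cut = 0.05, z_threshold = 2) {
  regs <- unique(network$regulator)
  rows <- suppressMessages(lapply(regs, function(r)
    activation_zscore(network, de, r, fdr_cut = fdr_cut,
                      z_threshold = z_threshold)))
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no regulator has a differentially expressed target at FDR < ", fdr_cut)
  out
}

#' Concordance of predicted regulator activity with observed miRNA expression
#'
#' Joins predicted activation states (from target mRNA shifts) with the
#' regulators' own differential expression in the miRNA modality. A
#' prediction is concordant when a deactivated call meets observed
#' downregulation or an activated call meets upregulation; regulators without
#' a directional prediction or absent from the miRNA table are untestable.
#'
#' @param scores output of [regulator_scores()].
#' @param mirna_de a `de_table` of the miRNA modality.
#' @return list with `table` (per-regulator data.frame: predicted_state,
#'   observed_log2_fc, observed_fdr, concordant) and `counts`
#'   (concordant / discordant / untestable).
#' @export
concordance_table <- function(scores, mirna_de) {
  idx <- match(scores$regulator, mirna_de$feature)
  if (all(is.na(idx))) stop("no scored regulator appears in the miRNA DE table")
  tab <- data.frame(regulator = scores$regulator,
                    predicted_state = scores$predicted_state,
                    z = scores$z,
                    observed_log2_fc = mirna_de$log2_fc[idx],
                    observed_fdr = mirna_de$fdr_p[idx],
                    stringsAsFactors = FALSE)
  tab$concordant <- ifelse(
    is.na(tab$observed_log2_fc) | tab$predicted_state == "indeterminate", NA,
    (tab$predicted_state == "deactivated" & tab$observed_log2_fc < 0) |
    (tab$predicted_state == "activated" & tab$observed_log2_fc > 0))
  counts <- c(concordant = sum(tab$concordant %in% TRUE),
              discordant = sum(tab$concordant %in% FALSE),
              untestable = sum(is.na(tab$concordant)))
  list(table = tab, counts = counts)
}
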