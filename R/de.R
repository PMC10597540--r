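#' Two-sample t-test for one feature
#'
#' Pooled-variance Student's t by default, Welch by `variant = "welch"`. Both
#' return the two-sided p-value. A zero-variance comparison returns t = 0,
#' p = 1 with `flagged = TRUE`.
#'
#' @param values_in,values_out numeric vectors (>= 2 each).
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @return list with `t`, `df`, `p`, `flagged`.
#' @export
two_sample_ttest <- function(values_in, values_out,
                             variant = c("student", "welch")) {
  variant <- match.arg(variant)
  n1 <- length(values_in); n2 <- length(values_out)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  m1 <- mean(values_in); m2 <- mean(values_out)
  v1 <- stats::var(values_in); v2 <- stats::var(values_out)
  if (variant == "student") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    if (sp2 == 0) return(list(t = 0, df = n1 + n2 - 2, p = 1, flagged = TRUE))
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) return(list(t = 0, df = n1 + n2 - 2, p = 1, flagged = TRUE))
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), flagged = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Shifted log2 fold change for centred data
#'
#' Standardised expression is signed, so the ratio of group means is
#' undefined; each feature is first shifted so that its minimum over all of
#' its values becomes `epsilon`, then the log2 ratio of the shifted group
#' means is taken.
#'
#' @param values_in,values_out the feature's values in the two groups.
#' @param epsilon positive floor after the shift (default 0.001).
#' @return the shifted log2 fold change (in over out).
#' @export
shifted_fold_change <- function(values_in, values_out, epsilon = 0.001) {
  shift <- -min(c(values_in, values_out)) + epsilon
  log2(mean(values_in + shift) / mean(values_out + shift))
}

#' Cluster-versus-rest differential expression
#'
#' Per-feature two-sample t-test of the flagged cluster against the rest of
#' the cohort, Benjamini-Hochberg adjustment across all retained features,
#' and the shifted log2 fold change. Vectorised across features.
#'
#' @param matrix an [expr_matrix()] (typically unit `"scaled"`).
#' @param assignment named cluster labels (a `subtype_call$assignments`
#'   vector); samples absent from the matrix are ignored.
#' @param cluster_label the cluster of interest.
#' @param variant t-test variant, `"student"` or `"welch"`.
#' @param epsilon fold-change shift floor.
#' @return a `de_table` data.frame sorted by `fdr_p`: feature, t_statistic,
#'   nominal_p, fdr_p, log2_fc, mean_in, mean_out, direction.
#' @export
differential_expression <- function(matrix, assignment, cluster_label,
                                    variant = c("student", "welch"),
                                    epsilon = 0.001) {
  stopifnot_expr_matrix(matrix)
  variant <- match.arg(variant)
  ids <- intersect(sample_ids(matrix), names(assignment))
  grp_in <- ids[assignment[ids] == cluster_label]
  grp_out <- setdiff(ids, grp_in)
  if (length(grp_in) < 2L || length(grp_out) < 2L)
    stop("cluster and remainder each need >= 2 samples with expression data")
  xi <- matrix$values[, grp_in, drop = FALSE]
  xo <- matrix$values[, grp_out, drop = FALSE]
  n1 <- ncol(xi); n2 <- ncol(xo)
  m1 <- rowMeans(xi); m2 <- rowMeans(xo)
  v1 <- rowSums((xi - m1)^2) / (n1 - 1)
  v2 <- rowSums((xo - m2)^2) / (n2 - 1)
  if (variant == "student") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se2 <- v1 / n1 + v2 / n2
    se <- sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  zero <- se == 0
  t[zero] <- 0; p[zero] <- 1
  shift <- -pmin(apply(xi, 1L, min), apply(xo, 1L, min)) + epsilon
  lfc <- log2((m1 + shift) / (m2 + shift))
  out <- data.frame(feature = feature_ids(matrix),
                    t_statistic = t, nominal_p = p,
                    fdr_p = bh_adjust(p), log2_fc = lfc,
                    mean_in = m1, mean_out = m2,
                    direction = ifelse(lfc >= 0, "up", "down"),
                    flagged = zero,
                    stringsAsFactors = FALSE)
  out <- out[order(out$fdr_p, out$nominal_p, out$feature), ]
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

#' Write a differential-expression table to TSV
#' @param de a `de_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
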