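#' Bootstrap percentile confidence interval for a recurrence proportion
#'
#' Resamples the binary outcomes of one cluster with replacement `n_boot`
#' times and takes the empirical 2.5/97.5 percentiles (linear-interpolation
#' quantiles) of the resampled proportions.
#'
#' @param outcomes binary (0/1) outcome vector of the cluster members.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed for reproducibility.
#' @return object of class `bootstrap_ci`: point estimate, lower/upper
#'   bounds, the resampled proportions, n_boot and seed.
#' @export
bootstrap_proportion_ci <- function(outcomes, n_boot = 1000, level = 0.95,
                                    seed = NULL) {
  if (!length(outcomes)) stop("'outcomes' must be nonempty")
  if (!all(outcomes %in% c(0, 1))) stop("'outcomes' must be binary 0/1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(outcomes)
  props <- vapply(seq_len(n_boot), function(i)
    mean(sample(outcomes, n, replace = TRUE)), numeric(1L))
  alpha <- (1 - level) / 2
  q <- stats::quantile(props, c(alpha, 1 - alpha), names = FALSE)
  structure(list(point = mean(outcomes), lower = q[1L], upper = q[2L],
                 props = props, n = n, n_boot = n_boot, level = level,
                 seed = seed),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("recurrence %d/%d = %.0f%%, %.0f%% CI (%.0f-%.0f%%), %d bootstrap resamples\n",
              round(x$point * x$n), x$n, 100 * x$point, 100 * x$level,
              round(100 * x$lower), round(100 * x$upper), x$n_boot))
  invisible(x)
}

#' t-test between two bootstrap proportion distributions
#'
#' Builds the two bootstrap distributions of the recurrence proportion
#' independently and compares them with a two-sample Student's t-test. The
#' p-value scales with the number of resamples rather than the number of
#' subjects and is anti-conservative; it is implemented as described and
#' should be read as a descriptive separation measure.
#'
#' @param outcomes_in,outcomes_out binary outcome vectors for the cluster and
#'   the remainder of the cohort.
#' @param n_boot resamples per group.
#' @param seed optional integer seed.
#' @return list with `p_value`, the two bootstrap means, and `defined`
#'   (FALSE when both bootstrap distributions are degenerate).
#' @export
bootstrap_difference_test <- function(outcomes_in, outcomes_out, n_boot = 1000,
                                      seed = NULL) {
  if (!length(outcomes_in) || !length(outcomes_out))
    stop("both outcome vectors must be nonempty")
  if (!is.null(seed)) set.seed(seed)
  bi <- bootstrap_proportion_ci(outcomes_in, n_boot = n_boot)
  bo <- bootstrap_proportion_ci(outcomes_out, n_boot = n_boot)
  if (stats::var(bi$props) == 0 && stats::var(bo$props) == 0) {
    return(list(p_value = NA_real_, mean_in = mean(bi$props),
                mean_out = mean(bo$props), defined = FALSE))
  }
  tt <- stats::t.test(bi$props, bo$props)
  list(p_value = tt$p.value, mean_in = mean(bi$props),
       mean_out = mean(bo$props), defined = TRUE)
}

#' Hypergeometric over-representation test of two sample sets
#'
#' Upper-tail probability of observing at least the given intersection
#' between two fixed-size subsets of a finite universe, equivalent to a
#' one-sided Fisher's exact test for over-representation. The overlap
#' percentage is Jaccard: 100 |A n B| / |A u B|.
#'
#' @param set_a,set_b character vectors of sample ids.
#' @param universe character vector containing both sets (e.g. the samples
#'   with both modalities measured).
#' @return object of class `overlap_result`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("both sets must be subsets of the universe")
  x <- length(intersect(set_a, set_b))
  na <- length(set_a); nb <- length(set_b); nu <- length(universe)
  p <- stats::phyper(x - 1L, na, nu - na, nb, lower.tail = FALSE)
  uni <- length(union(set_a, set_b))
  structure(list(n_universe = nu, n_a = na, n_b = nb, n_intersection = x,
                 p_over = p,
                 overlap_percent = if (uni) 100 * x / uni else 0),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("|A|=%d, |B|=%d, |A n B|=%d of universe %d: %.0f%% overlap, P = %.2g\n",
              x$n_a, x$n_b, x$n_intersection, x$n_universe,
              round(x$overlap_percent), x$p_over))
  invisible(x)
}

#' Cross-modality membership of flagged clusters
#'
#' Restricts to the samples present in every call and tabulates membership in
#' each call's flagged cluster, with counts of samples belonging to all,
#' exactly two, exactly one, or none of the flagged clusters.
#'
#' @param calls named list of `subtype_call` objects (one per modality).
#' @return list with `membership` (logical sample x call matrix) and `counts`
#'   (named vector; counts sum to the shared universe size).
#' @export
multiway_membership_table <- function(calls) {
  if (length(calls) < 2L) stop("need at least two subtype calls")
  ids <- Reduce(intersect, lapply(calls, function(x) names(x$assignments)))
  if (!length(ids)) stop("the calls share no samples")
  memb <- vapply(calls, function(x)
    x$assignments[ids] == x$best_cluster, logical(length(ids)))
  if (length(ids) == 1L)
    memb <- matrix(memb, nrow = 1L, dimnames = list(ids, names(calls)))
  else rownames(memb) <- ids
  hits <- rowSums(memb)
  counts <- vapply(seq(length(calls), 0L), function(k) sum(hits == k), integer(1L))
  names(counts) <- paste0("in_", seq(length(calls), 0L))
  list(membership = memb, counts = counts)
}
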