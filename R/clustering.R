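#' Sample-by-sample distance matrix
#'
#' Computes distances between samples (columns) of a standardised expression
#' matrix. Metrics: manhattan sum|x-y|; euclidean sqrt(sum (x-y)^2); minkowski
#' (sum|x-y|^p)^(1/p); canberra sum |x-y|/(|x|+|y|) with 0/0 terms omitted
#' (the `"sum"` denominator variant |x+y| is available by flag); binary =
#' share of positions where exactly one of the pair is nonzero among
#' positions where at least one is.
#'
#' @param matrix an [expr_matrix()] with unit `"scaled"` and >= 3 samples.
#' @param metric one of `"manhattan"`, `"canberra"`, `"binary"`,
#'   `"minkowski"`, `"euclidean"`.
#' @param minkowski_power p for the minkowski metric (default 2).
#' @param canberra_denominator `"abs"` for the classic |x|+|y| form (default),
#'   `"sum"` for the |x+y| variant.
#' @return a `dist` object over samples.
#' @export
compute_distance <- function(matrix, metric = c("manhattan", "canberra", "binary",
                                                "minkowski", "euclidean"),
                             minkowski_power = 2,
                             canberra_denominator = c("abs", "sum")) {
  stopifnot_expr_matrix(matrix)
  metric <- match.arg(metric)
  canberra_denominator <- match.arg(canberra_denominator)
  if (matrix$unit != "scaled")
    stop("distances are computed on standardised data; run scale_center() first")
  if (ncol(matrix$values) < 3L) stop("need at least 3 samples")
  if (!all(is.finite(matrix$values))) {
    bad <- feature_ids(matrix)[!apply(is.finite(matrix$values), 1L, all)]
    stop("non-finite values in feature(s): ", paste(bad, collapse = ", "))
  }
  if (!is.finite(minkowski_power) || minkowski_power <= 0)
    stop("'minkowski_power' must be a finite positive number")
  x <- t(matrix$values)
  if (metric == "canberra" && canberra_denominator == "sum") {
    n <- nrow(x)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      num <- abs(x[i, ] - x[j, ])
      den <- abs(x[i, ] + x[j, ])
      keep <- den > 0
      d[i, j] <- d[j, i] <- sum(num[keep] / den[keep])
    }
    return(stats::as.dist(d))
  }
  stats::dist(x, method = metric, p = minkowski_power)
}

#' Agglomerative hierarchical clustering
#'
#' Lance-Williams agglomeration of a distance matrix: `complete` (new distance
#' = max of the merged pair's), `ward_d` (Ward coefficients applied to the
#' input distances as-is) and `ward_d2` (Ward on squared distances with
#' square-root heights) - the two Ward variants of the R clustering stack.
#'
#' @param dist a `dist` object (or symmetric matrix with zero diagonal).
#' @param linkage one of `"ward_d"`, `"ward_d2"`, `"complete"`.
#' @return an `hclust` dendrogram.
#' @export
agglomerate <- function(dist, linkage = c("ward_d", "ward_d2", "complete")) {
  linkage <- match.arg(linkage)
  if (is.matrix(dist)) {
    if (!isSymmetric(unname(dist))) stop("distance matrix must be symmetric")
    dist <- stats::as.dist(dist)
  }
  method <- c(ward_d = "ward.D", ward_d2 = "ward.D2", complete = "complete")[linkage]
  stats::hclust(dist, method = method)
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last k-1 merges. Cluster labels 1..k are assigned by first
#' appearance in the dendrogram's leaf order, so label 1 is always the
#' leftmost cluster of the plotted tree.
#'
#' @param dendro an `hclust` object.
#' @param k number of clusters, between 2 and the number of leaves.
#' @return named integer vector mapping sample id to cluster label.
#' @export
cut_dendrogram <- function(dendro, k) {
  n <- length(dendro$order)
  if (k < 2L || k > n) stop("'k' must be between 2 and the number of leaves (", n, ")")
  raw <- stats::cutree(dendro, k = k)
  first_seen <- unique(raw[dendro$order])
  out <- match(raw, first_seen)
  names(out) <- names(raw)
  if (is.null(names(out))) names(out) <- dendro$labels
  out
}
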