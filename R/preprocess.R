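#' Scale and centre features, optionally within processing batches
#'
#' Per feature (and per batch stratum when `by_batch = TRUE`): subtract the
#' mean and divide by the sample standard deviation (n-1 denominator).
#' Features with zero variance within a stratum map to 0 in that stratum; a
#' stratum holding a single sample is set to 0 with a warning (its SD is
#' undefined).
#'
#' @param matrix an [expr_matrix()].
#' @param metadata cohort metadata supplying the `batch` column, matched to
#'   the matrix by `sample_id`; required when `by_batch = TRUE`.
#' @param by_batch standardise within each batch stratum rather than globally.
#' @return an [expr_matrix()] with unit `"scaled"`.
#' @export
scale_center <- function(matrix, metadata = NULL, by_batch = FALSE) {
  stopifnot_expr_matrix(matrix)
  vals <- matrix$values
  if (by_batch) {
    if (is.null(metadata)) stop("'metadata' with a batch column is required when by_batch = TRUE")
    idx <- match(sample_ids(matrix), metadata$sample_id)
    if (anyNA(idx))
      stop("samples missing from metadata: ",
           paste(sample_ids(matrix)[is.na(idx)], collapse = ", "))
    batch <- as.character(metadata$batch[idx])
    if (anyNA(batch)) stop("every sample needs a batch label when by_batch = TRUE")
    strata <- split(seq_len(ncol(vals)), batch)
  } else {
    strata <- list(all = seq_len(ncol(vals)))
  }
  out <- vals
  for (cols in strata) {
    if (length(cols) == 1L) {
      warning("batch stratum with a single sample set to 0 (SD undefined)")
      out[, cols] <- 0
      next
    }
    x <- vals[, cols, drop = FALSE]
    mu <- rowMeans(x)
    sdv <- sqrt(rowSums((x - mu)^2) / (length(cols) - 1L))
    z <- (x - mu) / sdv
    z[sdv == 0, ] <- 0
    out[, cols] <- z
  }
  expr_matrix(out, modality = matrix$modality, unit = "scaled")
}

# distinct values after rounding to 8 significant digits, so floating noise
# does not defeat the frequency-ratio rule
nzv_metrics <- function(v) {
  tab <- sort(table(signif(v, 8L)), decreasing = TRUE)
  ratio <- if (length(tab) == 1L) Inf else as.numeric(tab[1L]) / as.numeric(tab[2L])
  c(freq_ratio = ratio, pct_unique = 100 * length(tab) / length(v))
}

#' Near-zero-variance feature filter
#'
#' Removes a feature iff the count of its most frequent value divided by the
#' count of its second most frequent value is at least `freq_cut` AND its
#' number of distinct values as a percentage of the sample count is at most
#' `unique_cut`. A feature with a single distinct value is always removed.
#' Remaining features keep their original order.
#'
#' @param matrix an [expr_matrix()].
#' @param freq_cut most-common to second-most-common frequency ratio cutoff.
#' @param unique_cut percent-distinct cutoff.
#' @return list with `matrix` (filtered [expr_matrix()]) and `removed`
#'   (character vector of dropped feature ids).
#' @export
near_zero_variance_filter <- function(matrix, freq_cut = 19, unique_cut = 10) {
  stopifnot_expr_matrix(matrix)
  if (nrow(matrix$values) == 0L || ncol(matrix$values) == 0L)
    stop("empty expression matrix")
  met <- t(apply(matrix$values, 1L, nzv_metrics))
  drop <- met[, "freq_ratio"] >= freq_cut & met[, "pct_unique"] <= unique_cut
  list(matrix = expr_matrix(matrix$values[!drop, , drop = FALSE],
                            modality = matrix$modality, unit = matrix$unit),
       removed = feature_ids(matrix)[drop])
}

#' Standardise, filter and re-standardise an expression matrix
#'
#' The quality-control composition applied before clustering: scale and
#' centre within batches, remove near-zero-variance features, then scale and
#' centre the final matrix globally.
#'
#' @inheritParams scale_center
#' @inheritParams near_zero_variance_filter
#' @return an [expr_matrix()] with unit `"scaled"`; the removed feature ids
#'   are attached as attribute `"removed"`.
#' @export
preprocess_pipeline <- function(matrix, metadata, by_batch = TRUE,
                                freq_cut = 19, unique_cut = 10) {
  scaled <- scale_center(matrix, metadata, by_batch = by_batch)
  filt <- near_zero_variance_filter(scaled, freq_cut = freq_cut,
                                    unique_cut = unique_cut)
  out <- scale_center(filt$matrix, metadata, by_batch = FALSE)
  attr(out, "removed") <- filt$removed
  out
}
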