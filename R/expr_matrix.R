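#' Expression matrix container
#'
#' A light S3 wrapper around a numeric feature-by-sample matrix carrying the
#' modality label and the measurement unit. Rows are features (miRNAs or
#' genes), columns are samples. Values are counts-per-million (miRNA),
#' transcripts-per-million (mRNA), or standardised z-scores after
#' [scale_center()].
#'
#' @param values numeric matrix, features in rows, samples in columns; must
#'   carry unique, non-empty rownames (feature ids) and colnames (sample ids).
#' @param modality one of `"blood_mirna"`, `"blood_mrna"`, `"brain_mirna"`,
#'   `"brain_mrna"`.
#' @param unit one of `"cpm"`, `"tpm"`, `"scaled"`.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, modality, unit) {
  modality <- match.arg(modality, MODALITIES)
  unit <- match.arg(unit, c("cpm", "tpm", "scaled"))
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  structure(list(values = values, modality = modality, unit = unit),
            class = "expr_matrix")
}

MODALITIES <- c("blood_mirna", "blood_mrna", "brain_mirna", "brain_mrna")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples [%s, unit=%s]\n",
              nrow(x$values), ncol(x$values), x$modality, x$unit))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

stopifnot_expr_matrix <- function(x) {
  if (!inherits(x, "expr_matrix")) stop("expected an 'expr_matrix' object")
  invisible(x)
}
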