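#' Read an expression matrix from TSV
#'
#' The dialect is a header row of sample ids with the first column holding
#' feature ids, tab-separated. Duplicate feature or sample ids and
#' non-numeric cells are rejected with the offending row/column named.
#'
#' @param path path to a tab-separated file.
#' @param modality,unit labels attached to the returned [expr_matrix()].
#' @return an [expr_matrix()].
#' @export
read_matrix <- function(path, modality, unit) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || nrow(df) < 1L) stop("empty or malformed matrix file: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sam <- colnames(df)[-1L]
  if (anyDuplicated(sam))
    stop("duplicate sample id in ", path, ": ",
         paste(unique(sam[duplicated(sam)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1L)))
    stop("non-numeric cells in ", path, ", column(s): ",
         paste(sam[bad], collapse = ", "))
  }
  rownames(vals) <- ids
  expr_matrix(vals, modality = modality, unit = unit)
}

#' Write an expression matrix to TSV
#'
#' @param matrix an [expr_matrix()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot_expr_matrix(matrix)
  df <- data.frame(feature = feature_ids(matrix), matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

PATHOLOGY_LEVELS <- c("hippocampal sclerosis", "malformations of cortical development",
                      "no lesion", "other")

#' Read cohort metadata from TSV
#'
#' Required columns: `sample_id`, `outcome` (1 = seizure recurrence, 0 =
#' seizure free, i.e. Engel Ia/Ib at >= 1 year), `sex`, `pathology` (one of
#' hippocampal sclerosis, malformations of cortical development, no lesion,
#' other), `surgical_side` (dominant/nondominant), `epilepsy_duration`
#' (years, >= 0), `batch`. Optional logical availability columns
#' `has_<modality>`.
#'
#' @param path path to a tab-separated metadata file.
#' @return a `data.frame` with `pathology` as a factor whose reference level
#'   is hippocampal sclerosis.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(df)
}

validate_metadata <- function(df) {
  need <- c("sample_id", "outcome", "sex", "pathology", "surgical_side",
            "epilepsy_duration", "batch")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!all(df$outcome %in% c(0L, 1L)))
    stop("outcome must be 0 (seizure free) or 1 (seizure recurrence)")
  bad <- setdiff(unique(df$pathology), PATHOLOGY_LEVELS)
  if (length(bad))
    stop("unknown pathology value(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(PATHOLOGY_LEVELS, collapse = ", "))
  if (any(df$epilepsy_duration < 0)) stop("epilepsy_duration must be >= 0 years")
  df$pathology <- factor(df$pathology, levels = PATHOLOGY_LEVELS)
  df$batch <- factor(df$batch)
  df
}

#' Write cohort metadata to TSV
#' @param metadata a metadata `data.frame` (see [read_metadata()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a regulator-target network from TSV
#'
#' Columns: `regulator`, `target`, `sign` (repression/activation). Duplicate
#' edges are rejected.
#'
#' @param path path to a tab-separated edge list.
#' @return a `data.frame` of edges.
#' @export
read_network <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_network(df)
}

validate_network <- function(df) {
  need <- c("regulator", "target", "sign")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("network missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$sign %in% c("repression", "activation")))
    stop("network sign must be 'repression' or 'activation'")
  key <- paste(df$regulator, df$target)
  if (anyDuplicated(key))
    stop("duplicate network edge(s): ", paste(unique(key[duplicated(key)]), collapse = "; "))
  df
}

#' Write a regulator-target network to TSV
#' @param network edge `data.frame` (regulator, target, sign).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_network <- function(network, path) {
  utils::write.table(network, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param path path to a GMT file (name, description, tab-separated members).
#' @return a named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors (or of [gene_set()] objects).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    members <- if (inherits(s, "gene_set")) s$members else s
    nm <- if (inherits(s, "gene_set")) s$name else names(sets)[i]
    paste(c(nm, "na", members), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
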