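# Small in-code fixtures shared across test files.

# metadata table with valid covariates; outcome supplied or drawn
make_metadata <- function(n, outcome = NULL, n_batches = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(outcome)) outcome <- rbinom(n, 1, 0.5)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    outcome = outcome,
    sex = rbinom(n, 1, 0.5),
    pathology = sample(c("hippocampal sclerosis", "malformations of cortical development",
                         "no lesion", "other"), n, replace = TRUE,
                       prob = c(0.55, 0.1, 0.2, 0.15)),
    surgical_side = sample(c("dominant", "nondominant"), n, replace = TRUE),
    epilepsy_duration = round(runif(n, 1, 40), 1),
    batch = paste0("b", rep_len(seq_len(n_batches), n)),
    stringsAsFactors = FALSE)
}

# expression matrix wrapper with generated ids
make_expr <- function(values, modality = "blood_mirna", unit = "scaled") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  expr_matrix(values, modality = modality, unit = unit)
}

# small simulation settings used where full-size cohorts are not needed
small_params <- function(seed = 1, ...) {
  sim_params(n_features = c(blood_mirna = 60, blood_mrna = 200,
                            brain_mirna = 60, brain_mrna = 200),
             n_signal_features = c(blood_mirna = 15, blood_mrna = 50,
                                   brain_mirna = 15, brain_mrna = 50),
             seed = seed, ...)
}
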