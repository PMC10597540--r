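#' Simulation parameters for a synthetic multimodal epilepsy-surgery cohort
#'
#' Bundles and validates the knobs of the synthetic cohort generator. The
#' defaults emulate the structure the subtype analysis assumes: 40 subjects
#' with nested modality availability (40 blood miRNA / 35 blood mRNA / 32
#' brain / 30 with all four), two processing batches, a planted subtype
#' covering 40% of subjects whose members carry coordinated expression shifts
#' (miRNA signal down, mRNA targets up) and an enriched seizure-recurrence
#' rate (0.8 vs 0.4 background, overall ~0.56).
#'
#' @param n_subjects number of subjects.
#' @param n_features named counts of features per modality.
#' @param n_batches number of processing batches.
#' @param subtype_fraction proportion of subjects in the planted subtype;
#'   `subtype_fraction * n_subjects` must be at least 2.
#' @param recurrence_rate_subtype,recurrence_rate_background Bernoulli
#'   recurrence probabilities inside/outside the planted subtype.
#' @param n_signal_features named counts of shifted features per modality.
#' @param effect_size shift applied to signal features of subtype members, in
#'   units of the within-batch sample noise SD (miRNA down, mRNA up).
#' @param coupling_fraction proportion of the brain mRNA signal genes drawn
#'   from the blood mRNA signal genes (the blood-brain coordinated signal).
#' @param network_density expected number of planted targets per signal miRNA
#'   (zero-truncated Poisson).
#' @param decoy_density expected number of decoy targets per non-signal miRNA
#'   (Poisson; 0 disables decoy edges).
#' @param modality_missingness named counts of subjects lacking each modality.
#' @param seed integer seed; identical seeds give byte-identical cohorts.
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(n_subjects = 40L,
                       n_features = c(blood_mirna = 400L, blood_mrna = 2000L,
                                      brain_mirna = 400L, brain_mrna = 2000L),
                       n_batches = 2L,
                       subtype_fraction = 0.4,
                       recurrence_rate_subtype = 0.8,
                       recurrence_rate_background = 0.4,
                       n_signal_features = c(blood_mirna = 100L, blood_mrna = 500L,
                                             brain_mirna = 100L, brain_mrna = 500L),
                       effect_size = 2,
                       coupling_fraction = 0.5,
                       network_density = 5,
                       decoy_density = network_density,
                       modality_missingness = c(blood_mirna = 0L, blood_mrna = 5L,
                                                brain_mirna = 8L, brain_mrna = 8L),
                       seed = 1L) {
  p <- list(n_subjects = as.integer(n_subjects),
            n_features = n_features[MODALITIES],
            n_batches = as.integer(n_batches),
            subtype_fraction = subtype_fraction,
            recurrence_rate_subtype = recurrence_rate_subtype,
            recurrence_rate_background = recurrence_rate_background,
            n_signal_features = n_signal_features[MODALITIES],
            effect_size = effect_size,
            coupling_fraction = coupling_fraction,
            network_density = network_density,
            decoy_density = decoy_density,
            modality_missingness = modality_missingness[MODALITIES],
            seed = as.integer(seed))
  for (f in c("subtype_fraction", "recurrence_rate_subtype",
              "recurrence_rate_background", "coupling_fraction")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("parameter '", f, "' must be a probability in [0, 1]")
  }
  if (p$n_subjects < 4L) stop("parameter 'n_subjects' must be at least 4")
  if (round(p$subtype_fraction * p$n_subjects) < 2)
    stop("parameter 'subtype_fraction' too small: subtype must hold >= 2 subjects")
  if (any(is.na(p$n_features)) || any(p$n_features < 1))
    stop("parameter 'n_features' must name all four modalities with counts >= 1")
  if (any(is.na(p$n_signal_features)) || any(p$n_signal_features < 0) ||
      any(p$n_signal_features > p$n_features))
    stop("parameter 'n_signal_features' must be in [0, n_features] per modality")
  if (p$n_batches < 1L) stop("parameter 'n_batches' must be >= 1")
  if (p$network_density < 0) stop("parameter 'network_density' must be >= 0")
  if (p$decoy_density < 0) stop("parameter 'decoy_density' must be >= 0")
  if (any(is.na(p$modality_missingness)) || any(p$modality_missingness < 0) ||
      any(p$modality_missingness >= p$n_subjects))
    stop("parameter 'modality_missingness' must be in [0, n_subjects) per modality")
  class(p) <- "sim_params"
  p
}

# Seed-determined design shared by simulate_cohort() and
# simulate_regulator_network(): subtype members and signal feature sets.
draw_design <- function(params) {
  set.seed(params$seed)
  n <- params$n_subjects
  sample_id <- sprintf("S%02d", seq_len(n))
  m <- max(2L, as.integer(round(params$subtype_fraction * n)))
  members <- sort(sample(sample_id, m))

  feats <- list()
  n_mir <- max(params$n_features[c("blood_mirna", "brain_mirna")])
  n_gene <- max(params$n_features[c("blood_mrna", "brain_mrna")])
  mir_univ <- sprintf("mir%04d", seq_len(n_mir))
  gene_univ <- sprintf("gene%05d", seq_len(n_gene))
  universe <- list(blood_mirna = mir_univ[seq_len(params$n_features["blood_mirna"])],
                   brain_mirna = mir_univ[seq_len(params$n_features["brain_mirna"])],
                   blood_mrna = gene_univ[seq_len(params$n_features["blood_mrna"])],
                   brain_mrna = gene_univ[seq_len(params$n_features["brain_mrna"])])

  signal <- list()
  signal$blood_mirna <- sort(sample(universe$blood_mirna,
                                    params$n_signal_features["blood_mirna"]))
  signal$blood_mrna <- sort(sample(universe$blood_mrna,
                                   params$n_signal_features["blood_mrna"]))
  # Brain mRNA signal shares coupling_fraction of the blood signal genes.
  k_brain <- params$n_signal_features["brain_mrna"]
  k_shared <- min(as.integer(round(params$coupling_fraction * k_brain)),
                  sum(signal$blood_mrna %in% universe$brain_mrna))
  shared <- sample(intersect(signal$blood_mrna, universe$brain_mrna), k_shared)
  rest_pool <- setdiff(universe$brain_mrna, signal$blood_mrna)
  signal$brain_mrna <- sort(c(shared, sample(rest_pool, k_brain - k_shared)))
  signal$brain_mirna <- sort(sample(universe$brain_mirna,
                                    params$n_signal_features["brain_mirna"]))

  list(sample_id = sample_id, members = members,
       universe = universe[MODALITIES], signal = signal[MODALITIES])
}

# Nested availability emulating the study's 40/35/32/30 structure: all
# subjects have blood miRNA; blood mRNA drops the last few; the brain subset
# overlaps blood mRNA except for (up to) two donors, so an all-four core
# smaller than any single modality exists.
draw_availability <- function(params) {
  n <- params$n_subjects
  miss <- params$modality_missingness
  avail <- list()
  avail$blood_mirna <- seq_len(n - miss["blood_mirna"])
  avail$blood_mrna <- seq_len(n - miss["blood_mrna"])
  n_brain <- n - max(miss["brain_mirna"], miss["brain_mrna"])
  n_mrna <- length(avail$blood_mrna)
  outside <- min(2L, max(0L, n - n_mrna), n_brain)
  brain <- c(seq_len(n_brain - outside),
             if (outside > 0L) (n_mrna + 1L):(n_mrna + outside))
  avail$brain_mirna <- sort(brain[seq_len(min(length(brain), n - miss["brain_mirna"]))])
  avail$brain_mrna <- sort(brain[seq_len(min(length(brain), n - miss["brain_mrna"]))])
  lapply(avail[MODALITIES], function(i) sort(unique(pmin(i, n))))
}

#' Simulate a multimodal cohort with a planted outcome-associated subtype
#'
#' Draws feature-by-sample matrices for the four modalities, per-sample
#' clinical covariates and a binary seizure-recurrence outcome. Values are a
#' per-feature log-normal baseline plus an additive per-batch offset plus
#' unit-variance sample noise; signal features of subtype members are shifted
#' by `effect_size` noise-SD units, downward for miRNAs and upward for their
#' mRNA targets (the coordinated repression signal).
#'
#' @param params a [sim_params()] object.
#' @return a list with `matrices` (named list of [expr_matrix()]), `metadata`
#'   (cohort data.frame with availability flags) and `truth`
#'   (subtype members, per-modality signal feature sets, generator params).
#' @export
simulate_cohort <- function(params = sim_params()) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  design <- draw_design(params)
  n <- params$n_subjects
  ids <- design$sample_id
  in_subtype <- ids %in% design$members

  # covariate frequencies approximate the study cohort table
  sex <- stats::rbinom(n, 1L, 0.475)
  pathology <- sample(PATHOLOGY_LEVELS, n, replace = TRUE,
                      prob = c(0.55, 0.10, 0.20, 0.15))
  side <- ifelse(stats::rbinom(n, 1L, 0.525) == 1L, "dominant", "nondominant")
  duration <- round(pmax(1, stats::rnorm(n, 21.3, 13.5)), 1)
  batch <- paste0("b", rep_len(seq_len(params$n_batches), n)[sample.int(n)])
  outcome <- stats::rbinom(n, 1L, ifelse(in_subtype,
                                         params$recurrence_rate_subtype,
                                         params$recurrence_rate_background))

  avail <- draw_availability(params)
  metadata <- data.frame(sample_id = ids, outcome = outcome, sex = sex,
                         pathology = pathology, surgical_side = side,
                         epilepsy_duration = duration, batch = batch,
                         stringsAsFactors = FALSE)
  for (mod in MODALITIES)
    metadata[[paste0("has_", mod)]] <- seq_len(n) %in% avail[[mod]]
  metadata <- validate_metadata(metadata)

  matrices <- list()
  for (mod in MODALITIES) {
    feats <- design$universe[[mod]]
    nf <- length(feats)
    cols <- avail[[mod]]
    ns <- length(cols)
    baseline <- stats::rlnorm(nf, meanlog = 4, sdlog = 1)
    offs <- matrix(stats::rnorm(nf * params$n_batches, 0, 0.5), nf)
    bidx <- match(batch[cols], paste0("b", seq_len(params$n_batches)))
    vals <- baseline + offs[, bidx, drop = FALSE] +
      matrix(stats::rnorm(nf * ns), nf, ns)
    sig <- feats %in% design$signal[[mod]]
    mem <- in_subtype[cols]
    if (any(sig) && any(mem) && params$effect_size != 0) {
      dir <- if (grepl("mirna", mod)) -1 else 1
      vals[sig, mem] <- vals[sig, mem] + dir * params$effect_size
    }
    dimnames(vals) <- list(feats, ids[cols])
    unit <- if (grepl("mirna", mod)) "cpm" else "tpm"
    matrices[[mod]] <- expr_matrix(vals, modality = mod, unit = unit)
  }

  truth <- list(subtype_members = design$members,
                signal_features = design$signal,
                outcome = stats::setNames(outcome, ids),
                params = unclass(params))
  list(matrices = matrices, metadata = metadata, truth = truth)
}

#' Simulate a regulator-target network with planted repression edges
#'
#' Every planted signal miRNA receives a zero-truncated
#' Poisson(`network_density`) number of targets drawn from the planted blood
#' mRNA signal genes, all with expected sign `"repression"` (an active miRNA
#' pushes its targets down). Non-signal miRNAs receive
#' Poisson(`decoy_density`) decoy targets among non-signal genes with random
#' signs.
#'
#' @param params a [sim_params()] object (same seed as the cohort gives the
#'   matching planted signal sets).
#' @return edge `data.frame` with columns regulator, target, sign.
#' @export
simulate_regulator_network <- function(params = sim_params()) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  if (params$network_density <= 0)
    stop("parameter 'network_density' must be > 0 to plant a network")
  design <- draw_design(params)
  set.seed((params$seed %% 2147483000L) + 7L)
  mirs <- design$signal$blood_mirna
  genes <- design$signal$blood_mrna
  edges <- list()
  for (r in mirs) {
    k <- 0L
    while (k == 0L) k <- stats::rpois(1L, params$network_density)
    k <- min(k, length(genes))
    edges[[r]] <- data.frame(regulator = r,
                             target = sort(sample(genes, k)),
                             sign = "repression", stringsAsFactors = FALSE)
  }
  if (params$decoy_density > 0) {
    decoy_mirs <- setdiff(design$universe$blood_mirna, mirs)
    decoy_genes <- setdiff(design$universe$blood_mrna, genes)
    if (length(decoy_genes)) {
      for (r in decoy_mirs) {
        k <- min(stats::rpois(1L, params$decoy_density), length(decoy_genes))
        if (k > 0L)
          edges[[r]] <- data.frame(regulator = r,
                                   target = sort(sample(decoy_genes, k)),
                                   sign = sample(c("repression", "activation"),
                                                 k, replace = TRUE),
                                   stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  validate_network(out)
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Writes the four expression matrices (TSV), the metadata table (TSV), the
#' regulator network (TSV) and the ground truth (JSON) produced by
#' [simulate_cohort()] and [simulate_regulator_network()]; files round-trip
#' through [read_matrix()], [read_metadata()] and [read_network()].
#'
#' @param params a [sim_params()] object.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture_bundle <- function(params = sim_params(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(params)
  network <- simulate_regulator_network(params)
  paths <- c()
  for (mod in MODALITIES) {
    p <- file.path(dir, paste0(mod, ".tsv"))
    write_matrix(cohort$matrices[[mod]], p)
    paths[mod] <- p
  }
  paths["metadata"] <- write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  paths["network"] <- write_network(network, file.path(dir, "network.tsv"))
  paths["truth"] <- file.path(dir, "truth.json")
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
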