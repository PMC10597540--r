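#' Build custom gene sets from a differential-expression table
#'
#' One set per fold-change direction, holding the features significant at
#' `fdr_p < fdr_cut`; the naming mirrors the custom-signature convention
#' (e.g. `B4_mRNA_UP` / `B4_mRNA_DOWN`). Directions with no significant
#' feature are omitted with a warning.
#'
#' @param de a `de_table` from [differential_expression()].
#' @param fdr_cut significance cutoff on `fdr_p` (default 0.05).
#' @param name_prefix prefix for the set names.
#' @return named list of `gene_set` objects.
#' @export
build_custom_sets <- function(de, fdr_cut = 0.05, name_prefix = "set") {
  if (!nrow(de)) stop("'de' is empty")
  sets <- list()
  for (dir in c("up", "down")) {
    members <- de$feature[de$fdr_p < fdr_cut & de$direction == dir]
    nm <- paste0(name_prefix, "_", toupper(dir))
    if (!length(members)) {
      warning("no significant '", dir, "' features at FDR < ", fdr_cut,
              "; set ", nm, " omitted")
      next
    }
    sets[[nm]] <- structure(
      list(name = nm, members = unique(members),
           provenance = list(direction = dir, fdr_cut = fdr_cut,
                             n_tested = nrow(de))),
      class = "gene_set")
  }
  sets
}

set_members <- function(set) if (inherits(set, "gene_set")) set$members else set

# Ranks stats descending with ties broken by feature id, for determinism.
rank_stats <- function(ranked_stats) {
  if (is.null(names(ranked_stats))) stop("'ranked_stats' must be named")
  ranked_stats[order(-ranked_stats, names(ranked_stats))]
}

#' Weighted running-sum enrichment score
#'
#' Walks the list of features sorted by the ranking statistic (descending),
#' adding |stat|^w normalised over the set at member positions and
#' subtracting 1/(N - m) at non-members; the score is the running sum's
#' maximum deviation from zero, sign retained.
#'
#' @param ranked_stats named numeric vector (feature -> ranking statistic,
#'   e.g. shifted log2 fold change).
#' @param set a `gene_set` or character vector; its intersection with the
#'   ranked universe must be nonempty and strictly smaller than the universe.
#' @param weight_exponent w in |stat|^w (default 1).
#' @return list with `es`, the `running` profile over the sorted list, and
#'   the sorted feature order.
#' @export
enrichment_score <- function(ranked_stats, set, weight_exponent = 1) {
  s <- rank_stats(ranked_stats)
  members <- names(s) %in% set_members(set)
  m <- sum(members)
  if (m == 0L) stop("set does not intersect the ranked universe")
  if (m == length(s)) stop("set must be strictly smaller than the ranked universe")
  w <- abs(s)^weight_exponent
  denom <- sum(w[members])
  if (denom == 0) stop("undefined weights: all member statistics are zero")
  step <- ifelse(members, w / denom, -1 / (length(s) - m))
  running <- cumsum(step)
  hi <- max(running); lo <- min(running)
  # extremum of larger magnitude; magnitude ties (within floating tolerance)
  # resolve to the positive peak
  es <- if (hi >= -lo - 1e-12) hi else lo
  list(es = es, running = running, order = names(s))
}

# ES extremum only, for permutation nulls: O(m log m) given the positions of
# a random set in the sorted list.
es_at_positions <- function(w, pos, n) {
  pos <- sort(pos)
  m <- length(pos)
  wm <- w[pos]
  denom <- sum(wm)
  if (denom == 0) return(0)
  cum <- cumsum(wm / denom) - (pos - seq_len(m)) / (n - m)
  pre <- c(-(pos[1L] - 1L) / (n - m),
           if (m > 1L) cum[-m] - (diff(pos) - 1L) / (n - m))
  hi <- max(cum)
  lo <- min(pre)
  if (hi >= -lo - 1e-12) hi else lo
}

#' Preranked gene-set enrichment with a gene-label permutation null
#'
#' For each set, the observed running-sum score ([enrichment_score()]) is
#' compared against scores of `n_perm` random sets of equal size drawn from
#' the ranked universe. The nominal p-value is the fraction of null scores of
#' the same sign at least as extreme (with the +1 continuity bound); NES is
#' the score divided by the mean |null score| of matching sign; FDR is
#' Benjamini-Hochberg across the supplied sets. The leading edge holds the
#' member features at or before (after, for negative scores) the running-sum
#' extremum.
#'
#' @param ranked_stats named numeric vector of ranking statistics.
#' @param sets named list of `gene_set` objects or character vectors.
#' @param n_perm number of permutations (>= 100).
#' @param seed optional integer seed.
#' @param weight_exponent passed to [enrichment_score()].
#' @return data.frame with one row per set: set, size, es, nes, nominal_p,
#'   fdr_p, leading_edge (list column), n_perm.
#' @export
preranked_gsea <- function(ranked_stats, sets, n_perm = 10000, seed = NULL,
                           weight_exponent = 1) {
  if (n_perm < 100) stop("'n_perm' must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  s <- rank_stats(ranked_stats)
  n <- length(s)
  w <- abs(s)^weight_exponent
  rows <- lapply(names(sets), function(nm) {
    obs <- enrichment_score(ranked_stats, sets[[nm]], weight_exponent)
    members <- which(obs$order %in% set_members(sets[[nm]]))
    m <- length(members)
    null_es <- vapply(seq_len(n_perm), function(i)
      es_at_positions(w, sample.int(n, m), n), numeric(1L))
    if (obs$es >= 0) {
      same <- null_es[null_es >= 0]
      p <- (1 + sum(same >= obs$es)) / (1 + length(same))
    } else {
      same <- null_es[null_es < 0]
      p <- (1 + sum(same <= obs$es)) / (1 + length(same))
    }
    nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
    peak <- if (obs$es >= 0) which.max(obs$running) else which.min(obs$running)
    lead <- if (obs$es >= 0) obs$order[intersect(members, seq_len(peak))]
            else obs$order[members[members >= peak]]
    data.frame(set = nm, size = m, es = obs$es, nes = nes, nominal_p = p,
               leading_edge = I(list(lead)), n_perm = n_perm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_p <- bh_adjust(out$nominal_p)
  out[, c("set", "size", "es", "nes", "nominal_p", "fdr_p",
          "leading_edge", "n_perm")]
}

#' Hypergeometric over-representation of a query set in annotations
#'
#' Upper-tail hypergeometric p per annotation set (one-sided Fisher), with a
#' Benjamini-Hochberg column across annotations.
#'
#' @param query character vector of feature ids.
#' @param annotations named list of annotation sets.
#' @param universe character vector containing query and annotations.
#' @return data.frame: annotation, n_annotation, n_overlap, p, fdr_p.
#' @export
over_representation <- function(query, annotations, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  rows <- lapply(names(annotations), function(nm) {
    ann <- unique(set_members(annotations[[nm]]))
    if (!all(ann %in% universe))
      stop("annotation '", nm, "' is not a subset of the universe")
    x <- length(intersect(query, ann))
    data.frame(annotation = nm, n_annotation = length(ann), n_overlap = x,
               p = stats::phyper(x - 1L, length(ann),
                                 length(universe) - length(ann),
                                 length(query), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_p <- bh_adjust(out$p)
  out
}
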