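test_that("exchangeable cluster and outcome give a null association", {
  # cluster and remainder are exact covariate/outcome mirrors, so the
  # membership indicator carries no information
  half <- make_metadata(100, seed = 21)
  md <- rbind(half, half)
  md$sample_id <- sprintf("S%03d", 1:200)
  assignment <- setNames(rep(c(1L, 2L), each = 100), md$sample_id)
  res <- cluster_outcome_association(assignment, md, 1L)
  expect_lt(abs(res$coefficient), 1e-6)
  expect_gt(res$wald_p, 0.99)
  expect_false(res$separation_flag)
})

test_that("membership identical to outcome raises the separation flag", {
  set.seed(22)
  md <- make_metadata(30)
  assignment <- setNames(ifelse(md$outcome == 1, 1L, 2L), md$sample_id)
  res <- cluster_outcome_association(assignment, md, 1L)
  expect_true(res$separation_flag)
  expect_false(res$converged)
})

test_that("degenerate outcomes and empty clusters are rejected", {
  md <- make_metadata(20, outcome = rep(1, 20), seed = 1)
  assignment <- setNames(rep(c(1L, 2L), 10), md$sample_id)
  expect_error(cluster_outcome_association(assignment, md, 1L), "constant")
  md2 <- make_metadata(20, seed = 2)
  expect_error(cluster_outcome_association(
    setNames(rep(1L, 20), md2$sample_id), md2, 1L), "inside and outside")
})

test_that("coefficient and Wald p match an independent IRLS oracle", {
  set.seed(23)
  n <- 500
  md <- make_metadata(n)
  member <- rbinom(n, 1, 0.4)
  # planted log-odds 1.5 for membership, no covariate effects
  md$outcome <- rbinom(n, 1, plogis(-0.75 + 1.5 * member))
  assignment <- setNames(ifelse(member == 1, 1L, 2L), md$sample_id)
  res <- cluster_outcome_association(assignment, md, 1L)
  expect_lt(abs(res$coefficient - 1.5), 0.3)

  X <- model.matrix(~ member + sex + pathology + surgical_side + epilepsy_duration,
                    data = transform(md, pathology = factor(pathology,
                      levels = c("hippocampal sclerosis",
                                 "malformations of cortical development",
                                 "no lesion", "other"))))
  oracle <- irls_logistic(X, md$outcome)
  expect_lt(abs(res$coefficient - oracle$beta[2]), 1e-6)
  expect_lt(abs(res$wald_p - oracle$p[2]), 1e-6)
})

test_that("cluster-vs-rest tests at one cut mirror for k=2 and BH-adjust within the cut", {
  set.seed(24)
  co <- simulate_cohort(small_params(seed = 24))
  pp <- preprocess_pipeline(co$matrices$blood_mirna, co$metadata)
  h <- agglomerate(compute_distance(pp, "euclidean"), "complete")
  res2 <- split_and_test(h, co$metadata, 2)
  expect_equal(res2$wald_p[1], res2$wald_p[2], tolerance = 1e-9)
  for (k in 2:5) {
    res <- split_and_test(h, co$metadata, k)
    expect_equal(res$fdr_p, bh_by_hand(res$wald_p), tolerance = 1e-12)
    expect_true(all(res$fdr_p >= res$wald_p - 1e-12))
    expect_equal(sum(res$n_in), 40)
    expect_true(all(res$n_recurrence_in <= res$n_in))
  }
})

test_that("the two-phase optimal-k rule follows the stated p-value trace", {
  set.seed(25)
  co <- simulate_cohort(small_params(seed = 25))
  pp <- preprocess_pipeline(co$matrices$blood_mirna, co$metadata)
  h <- agglomerate(compute_distance(pp, "euclidean"), "complete")
  fake <- function(minp) {
    traces <- list()
    traces[[2]] <- c(0.30, 0.30)
    traces[[3]] <- c(minp[1], 0.50, 0.70)
    traces[[4]] <- c(minp[2], 0.40, 0.60, 0.80)
    traces[[5]] <- c(minp[3], 0.45, 0.55, 0.65, 0.85)
    function(dendro, metadata, k) {
      p <- traces[[k]]
      data.frame(cluster = seq_len(k), n_in = 1, n_recurrence_in = 1,
                 coefficient = 1, wald_p = p, converged = TRUE,
                 separation_flag = FALSE, fdr_p = p.adjust(p, "BH"))
    }
  }
  # significance first at k=3; k=4 min p worse than k=3 -> optimal 3
  testthat::with_mocked_bindings(
    split_and_test = fake(c(0.02, 0.04, 0.01)),
    {
      call <- find_optimal_clusters(h, co$metadata)
      expect_equal(call$optimal_k, 3L)
      expect_equal(call$best_fdr, 0.06)
    },
    .package = "episubtype")
  # k=4 improves on k=3, k=5 does not -> optimal 4
  testthat::with_mocked_bindings(
    split_and_test = fake(c(0.02, 0.005, 0.01)),
    {
      call <- find_optimal_clusters(h, co$metadata)
      expect_equal(call$optimal_k, 4L)
    },
    .package = "episubtype")
  # nothing ever significant -> no call
  testthat::with_mocked_bindings(
    split_and_test = function(dendro, metadata, k)
      data.frame(cluster = seq_len(k), n_in = 1, n_recurrence_in = 1,
                 coefficient = 0, wald_p = rep(0.9, k), converged = TRUE,
                 separation_flag = FALSE, fdr_p = rep(0.9, k)),
    expect_null(find_optimal_clusters(h, co$metadata)),
    .package = "episubtype")
})

test_that("the best configuration wins on FDR with k and grid-order tie-breaks", {
  stub_call <- function(fdr, k, metric, linkage) {
    structure(list(best_fdr = fdr, optimal_k = k,
                   distance = list(metric = metric, minkowski_power = 2),
                   linkage = list(method = linkage)),
              class = "subtype_call")
  }
  a <- stub_call(0.12, 3, "manhattan", "ward_d")
  b <- stub_call(0.03, 4, "euclidean", "complete")
  expect_identical(select_best_approach(list(a, b)), b)
  expect_identical(select_best_approach(list(a)), a)
  # FDR tie broken by smaller k
  c1 <- stub_call(0.05, 4, "manhattan", "ward_d")
  c2 <- stub_call(0.05, 3, "euclidean", "complete")
  expect_identical(select_best_approach(list(c1, c2)), c2)
  # full tie broken by grid order (canberra before minkowski)
  d1 <- stub_call(0.05, 3, "minkowski", "ward_d")
  d2 <- stub_call(0.05, 3, "canberra", "complete")
  expect_identical(select_best_approach(list(d1, d2)), d2)
  expect_error(select_best_approach(list(NULL)), "no subtype calls")
})

test_that("association p-values are invariant to sample permutation", {
  co <- simulate_cohort(small_params(seed = 26))
  pp <- preprocess_pipeline(co$matrices$blood_mirna, co$metadata)
  set.seed(1)
  perm <- sample(ncol(pp$values))
  pp2 <- expr_matrix(pp$values[, perm], pp$modality, pp$unit)
  call1 <- discover_subtypes(pp, co$metadata, metrics = "euclidean",
                             linkages = "ward_d2")
  call2 <- discover_subtypes(pp2, co$metadata, metrics = "euclidean",
                             linkages = "ward_d2")
  expect_equal(call1$best_fdr, call2$best_fdr, tolerance = 1e-9)
  expect_equal(call1$optimal_k, call2$optimal_k)
  expect_equal(sort(names(call1$assignments)[call1$assignments == call1$best_cluster]),
               sort(names(call2$assignments)[call2$assignments == call2$best_cluster]))
})

test_that("under the global null the minimum cluster p at k=3 is not anti-conservative", {
  hits <- 0L
  for (s in 1:200) {
    set.seed(s + 3000)
    md <- make_metadata(24)
    m <- make_expr(matrix(rnorm(30 * 24), 30), unit = "scaled")
    colnames(m$values) <- md$sample_id
    h <- agglomerate(compute_distance(m, "euclidean"), "ward_d2")
    res <- split_and_test(h, md, 3)
    if (min(res$wald_p) < 0.01) hits <- hits + 1L
  }
  expect_lte(hits / 200, 0.05)
})
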