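test_that("parameter validation names the offending field", {
  expect_error(sim_params(subtype_fraction = 1.4), "subtype_fraction")
  expect_error(sim_params(recurrence_rate_subtype = -0.1), "recurrence_rate_subtype")
  expect_error(sim_params(n_subjects = 100, subtype_fraction = 0.001), "subtype_fraction")
  expect_error(sim_params(n_batches = 0), "n_batches")
  expect_error(sim_params(network_density = -1), "network_density")
  expect_error(sim_params(n_signal_features = c(blood_mirna = 1000, blood_mrna = 1,
                                                brain_mirna = 1, brain_mrna = 1)),
               "n_signal_features")
})

test_that("identical seeds give byte-identical cohorts and fixture bundles", {
  a <- simulate_cohort(small_params(seed = 7))
  b <- simulate_cohort(small_params(seed = 7))
  expect_identical(a, b)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture_bundle(small_params(seed = 7), d1)
  write_fixture_bundle(small_params(seed = 7), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("modality availability is nested with an all-four core", {
  co <- simulate_cohort(sim_params(seed = 3))
  md <- co$metadata
  counts <- vapply(paste0("has_", c("blood_mirna", "blood_mrna", "brain_mirna",
                                    "brain_mrna")), function(cl) sum(md[[cl]]),
                   integer(1L))
  expect_equal(unname(counts), c(40L, 35L, 32L, 32L))
  all4 <- rowSums(md[paste0("has_", c("blood_mirna", "blood_mrna",
                                      "brain_mirna", "brain_mrna"))]) == 4
  expect_equal(sum(all4), 30L)
  for (mod in names(co$matrices))
    expect_setequal(colnames(co$matrices[[mod]]$values),
                    md$sample_id[md[[paste0("has_", mod)]]])
})

test_that("null effect size leaves subtype and background means equal", {
  co <- simulate_cohort(small_params(seed = 11, effect_size = 0))
  mat <- co$matrices$blood_mirna$values
  mem <- colnames(mat) %in% co$truth$subtype_members
  sig <- co$truth$signal_features$blood_mirna
  diff <- mean(rowMeans(mat[sig, mem, drop = FALSE]) -
               rowMeans(mat[sig, !mem, drop = FALSE]))
  expect_lt(abs(diff), 0.2)
  # and a nonzero effect shifts miRNA signal down in members
  co2 <- simulate_cohort(small_params(seed = 11, effect_size = 2))
  mat2 <- co2$matrices$blood_mirna$values
  mem2 <- colnames(mat2) %in% co2$truth$subtype_members
  sig2 <- co2$truth$signal_features$blood_mirna
  diff2 <- mean(rowMeans(mat2[sig2, mem2, drop = FALSE]) -
                rowMeans(mat2[sig2, !mem2, drop = FALSE]))
  expect_lt(diff2, -1.5)
})

test_that("equal recurrence rates produce binomial outcome counts across seeds", {
  counts <- vapply(1:100, function(s) {
    co <- simulate_cohort(sim_params(
      n_subjects = 40, recurrence_rate_subtype = 0.5,
      recurrence_rate_background = 0.5, seed = s,
      n_features = c(blood_mirna = 5, blood_mrna = 5, brain_mirna = 5, brain_mrna = 5),
      n_signal_features = c(blood_mirna = 2, blood_mrna = 2, brain_mirna = 2,
                            brain_mrna = 2)))
    sum(co$truth$outcome)
  }, numeric(1L))
  bounds <- qbinom(c(0.005, 0.995), 40, 0.5)
  expect_lte(mean(counts < bounds[1] | counts > bounds[2]), 0.05)
  # pooled count over all seeds well inside its own 99.9% band
  pooled <- qbinom(c(0.0005, 0.9995), 40 * 100, 0.5)
  expect_true(sum(counts) >= pooled[1] && sum(counts) <= pooled[2])
})

test_that("planted network edges repress signal genes; decoys are controllable", {
  p <- small_params(seed = 5)
  design_truth <- simulate_cohort(p)$truth$signal_features
  net0 <- simulate_regulator_network(small_params(seed = 5, decoy_density = 0))
  expect_true(all(net0$sign == "repression"))
  expect_true(all(net0$regulator %in% design_truth$blood_mirna))
  expect_true(all(net0$target %in% design_truth$blood_mrna))
  net <- simulate_regulator_network(p)
  decoys <- net[!net$regulator %in% design_truth$blood_mirna, ]
  expect_true(all(!decoys$target %in% design_truth$blood_mrna))
  planted <- net[net$regulator %in% design_truth$blood_mirna, ]
  expect_true(all(planted$sign == "repression"))
})

test_that("planted edge counts match the zero-truncated Poisson expectation", {
  counts <- vapply(1:20, function(s) {
    p <- sim_params(n_features = c(blood_mirna = 50, blood_mrna = 200,
                                   brain_mirna = 50, brain_mrna = 200),
                    n_signal_features = c(blood_mirna = 10, blood_mrna = 100,
                                          brain_mirna = 10, brain_mrna = 100),
                    network_density = 5, decoy_density = 0, seed = s)
    nrow(simulate_regulator_network(p))
  }, numeric(1L))
  # 10 regulators x E[truncated Pois(5)] ~ 50.3; pooled mean within 3 SD
  expect_gt(mean(counts), 50 - 3 * sqrt(50) / sqrt(20))
  expect_lt(mean(counts), 50.7 + 3 * sqrt(50) / sqrt(20))
})

test_that("fixture bundles round-trip losslessly through the readers", {
  dir <- withr::local_tempdir()
  p <- small_params(seed = 9)
  paths <- write_fixture_bundle(p, dir)
  co <- simulate_cohort(p)
  for (mod in c("blood_mirna", "blood_mrna", "brain_mirna", "brain_mrna")) {
    back <- read_matrix(paths[[mod]], modality = mod,
                        unit = co$matrices[[mod]]$unit)
    expect_equal(back$values, co$matrices[[mod]]$values, tolerance = 1e-8)
  }
  md <- read_metadata(paths[["metadata"]])
  expect_equal(md$outcome, co$metadata$outcome)
  expect_equal(as.character(md$pathology), as.character(co$metadata$pathology))
  net <- read_network(paths[["network"]])
  expect_identical(net, simulate_regulator_network(p))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(length(truth$subtype_members),
               round(p$subtype_fraction * p$n_subjects))
  expect_setequal(truth$subtype_members, co$truth$subtype_members)
})
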