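fake_de <- function(features, fdr, lfc) {
  structure(data.frame(feature = features, t_statistic = lfc, nominal_p = fdr,
                       fdr_p = fdr, log2_fc = lfc,
                       mean_in = 0, mean_out = 0,
                       direction = ifelse(lfc >= 0, "up", "down"),
                       flagged = FALSE, stringsAsFactors = FALSE),
            class = c("de_table", "data.frame"))
}

test_that("custom sets split significant features by direction", {
  de <- fake_de(sprintf("g%02d", 1:20),
                fdr = c(rep(0.01, 15), rep(0.5, 5)),
                lfc = c(rep(1, 10), rep(-1, 5), rep(1, 5)))
  sets <- build_custom_sets(de, name_prefix = "B4_mRNA")
  expect_named(sets, c("B4_mRNA_UP", "B4_mRNA_DOWN"))
  expect_length(sets$B4_mRNA_UP$members, 10)
  expect_length(sets$B4_mRNA_DOWN$members, 5)
  expect_length(intersect(sets$B4_mRNA_UP$members, sets$B4_mRNA_DOWN$members), 0)
  null_de <- fake_de(c("a", "b"), fdr = c(0.9, 0.8), lfc = c(1, -1))
  expect_warning(expect_warning(empty <- build_custom_sets(null_de), "up"), "down")
  expect_length(empty, 0)
})

test_that("enrichment score walks the stated running sum", {
  stats <- c(g1 = 3, g2 = 2, g3 = 1)
  top <- enrichment_score(stats, "g1")
  expect_equal(top$es, 1)
  bottom <- enrichment_score(stats, "g3")
  expect_equal(bottom$running, c(-0.5, -1, 0))
  expect_equal(bottom$es, -1)
  expect_error(enrichment_score(stats, c("g1", "g2", "g3")), "strictly smaller")
  expect_error(enrichment_score(stats, "absent"), "intersect")
  expect_error(enrichment_score(c(g1 = 0, g2 = 1, g3 = 2), "g1"),
               "all member statistics are zero")
})

test_that("enrichment score equals a step-by-step oracle and negates under sign flip", {
  set.seed(41)
  for (i in 1:500) {
    n <- sample(10:60, 1)
    stats <- setNames(round(rnorm(n), 6), sprintf("f%03d", seq_len(n)))
    m <- sample(1:(n - 1), 1)
    members <- sample(names(stats), m)
    es <- enrichment_score(stats, members)$es
    expect_equal(es, naive_es(stats, members), tolerance = 1e-12)
    # fast extremum used for permutation nulls agrees with the full walk
    s_sorted <- stats[order(-stats, names(stats))]
    pos <- which(names(s_sorted) %in% members)
    expect_equal(episubtype:::es_at_positions(abs(s_sorted), pos, n), es,
                 tolerance = 1e-12)
  }
  set.seed(42)
  stats <- setNames(rnorm(40), sprintf("u%02d", 1:40))
  members <- sample(names(stats), 8)
  expect_equal(enrichment_score(-stats, members)$es,
               -enrichment_score(stats, members)$es, tolerance = 1e-12)
})

test_that("preranked GSEA flags a planted top-of-list set and is null-calibrated", {
  set.seed(43)
  stats <- setNames(sort(rnorm(200, sd = 2), decreasing = TRUE),
                    sprintf("g%03d", 1:200))
  res <- preranked_gsea(stats, list(top = names(stats)[1:15]), n_perm = 500,
                        seed = 1)
  expect_gt(res$es, 0.8)
  expect_lt(res$nominal_p, 0.02)
  expect_true(all(unlist(res$leading_edge) %in% names(stats)[1:15]))
  expect_error(preranked_gsea(stats, list(top = names(stats)[1:15]), n_perm = 50),
               "at least 100")
  # es does not depend on the permutation count
  res2 <- preranked_gsea(stats, list(top = names(stats)[1:15]), n_perm = 1000,
                         seed = 1)
  expect_equal(res2$es, res$es)

  # null: random sets on shuffled stats give uniform-ish p-values
  set.seed(44)
  ps <- vapply(1:50, function(i) {
    st <- setNames(rnorm(100), sprintf("n%03d", 1:100))
    preranked_gsea(st, list(s = sample(names(st), 10)), n_perm = 200)$nominal_p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("enrichment score matches fgsea's statistic on random instances", {
  set.seed(45)
  for (i in 1:25) {
    n <- sample(20:80, 1)
    stats <- setNames(rnorm(n), sprintf("f%03d", seq_len(n)))
    members <- sample(names(stats), sample(2:10, 1))
    s_sorted <- stats[order(-stats, names(stats))]
    ref <- fgsea::calcGseaStat(unname(s_sorted),
                               which(names(s_sorted) %in% members),
                               gseaParam = 1, scoreType = "std")
    expect_equal(enrichment_score(stats, members)$es, ref, tolerance = 1e-10)
  }
})

test_that("over-representation p-values reduce to the hypergeometric oracle", {
  u <- sprintf("x%02d", 1:10)
  res <- over_representation(u[1:4], list(hit = u[1:5], miss = u[5:10],
                                          all = u), u)
  expect_equal(res$p[res$annotation == "hit"],
               enum_hyper_upper(10, 5, 4, 4), tolerance = 1e-12)
  expect_equal(res$p[res$annotation == "all"], 1)
  dis <- over_representation(u[1:3], list(d = u[4:6]), u)
  expect_equal(dis$p, 1)
  expect_error(over_representation(u[1:2], list(a = "zz"), u), "subset")
  expect_error(over_representation(u, list(a = u[1]), character(0)), "empty universe")
  # identical annotation is the most enriched among equal-sized ones
  q <- u[1:4]
  r2 <- over_representation(q, list(same = q, other = u[7:10]), u)
  expect_lt(r2$p[r2$annotation == "same"], r2$p[r2$annotation == "other"])
})

test_that("GMT files round-trip through the reader", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9", "g2"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back, sets)
})
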