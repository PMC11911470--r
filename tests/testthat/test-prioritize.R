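test_that("read_relationships parses, trims, dedups and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SET_ID\tMEMBER_ID",
               "herb1\tnpA", "herb1\tnpB",
               "herb2\tnpA ", "herb2\tnpC",
               "herb2\tnpC"), f)          # duplicate + padded field
  sc <- suppressMessages(read_relationships(f, "herb_to_np"))
  expect_s3_class(sc, "set_collection")
  expect_equal(sc$layer, "herb_to_np")
  expect_equal(lengths(sc$members), c(herb1 = 2L, herb2 = 2L))
  expect_true("npA" %in% sc$members$herb2)  # whitespace trimmed

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SET_ID\tMEMBER_ID", "herb1\tnpA", "herb1\t"), f2)
  expect_warning(sc2 <- read_relationships(f2, "np_to_gene"), "malformed")
  expect_equal(lengths(sc2$members), c(herb1 = 1L))

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("SET_ID\tMEMBER_ID", f3)
  expect_error(read_relationships(f3, "np_to_gene"), "empty")

  # GMT dialect for signature sets
  f4 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SIG1\tdesc\tg1\tg2\tg3", "SIG2\tdesc\tg2\tg4"), f4)
  sc4 <- read_relationships(f4, "np_to_gene")
  expect_equal(lengths(sc4$members), c(SIG1 = 3L, SIG2 = 2L))
})

test_that("stouffer_combine matches normal quantile/CDF closed forms", {
  s <- stouffer_combine(c(0.5, 0.5))
  expect_equal(s$z_sum, 0, tolerance = 1e-10)
  expect_equal(s$meta_p, 0.5, tolerance = 1e-10)

  # singleton is the identity
  for (p in c(0.9, 0.3, 0.01, 1e-8))
    expect_equal(stouffer_combine(p)$meta_p, p, tolerance = 1e-10)

  s2 <- stouffer_combine(c(0.025, 0.025))
  expect_equal(s2$z_sum, 2 * qnorm(0.975) / sqrt(2), tolerance = 1e-10)
  expect_equal(s2$meta_p, pnorm(2 * qnorm(0.975) / sqrt(2), lower.tail = FALSE),
               tolerance = 1e-10)

  # sqrt(k) scaling: k identical p gives Z = sqrt(k) * z_single
  for (k in c(2, 6, 12))
    expect_equal(stouffer_combine(rep(0.025, k))$z_sum,
                 sqrt(k) * qnorm(0.975), tolerance = 1e-10)

  # boundary values are clamped, not fatal
  expect_message(sb <- stouffer_combine(c(0, 0.5)), "clamped")
  expect_true(sb$meta_p > 0 && sb$meta_p < 1)
  expect_error(stouffer_combine(numeric(0)), "no p-values")
})

test_that("stouffer_combine is order-invariant and decreasing in k", {
  set.seed(21)
  ps <- runif(8, 0.01, 0.99)
  expect_equal(stouffer_combine(ps)$meta_p,
               stouffer_combine(rev(ps))$meta_p, tolerance = 1e-14)
  metas <- vapply(1:8, function(k) stouffer_combine(rep(0.2, k))$meta_p, 0)
  expect_true(all(diff(metas) < 0))
})

test_that("consensus_np_ranking pools available analyses per NP", {
  mk <- function(ids, ps) data.table::data.table(
    set_id = ids, es = 0.5, nes = 1, p = ps,
    effective_size = 5L, n_perm_used = 100L, at_floor = FALSE)
  # single analysis: ranking identical to that analysis's -log10 p order
  one <- list(a1 = mk(c("np1", "np2", "np3"), c(0.2, 0.01, 0.6)))
  rl <- consensus_np_ranking(one)
  expect_equal(rl$items, c("np2", "np1", "np3"))
  expect_equal(attr(rl, "table")[np_id == "np2"]$meta_p, 0.01,
               tolerance = 1e-12)

  # null-centre propagation: p 0.5 everywhere -> rank_stat -log10(0.5)
  flat <- lapply(1:12, function(i) mk("npX", 0.5))
  names(flat) <- paste0("a", 1:12)
  rl2 <- consensus_np_ranking(flat)
  expect_equal(rl2$stats, -log10(0.5), tolerance = 1e-10)

  # NP present in 6 of 12 analyses combines only the available k
  six <- c(lapply(1:6, function(i) mk(c("npA", "npB"), c(0.025, 0.5))),
           lapply(7:12, function(i) mk("npB", 0.5)))
  names(six) <- paste0("a", 1:12)
  tab <- attr(consensus_np_ranking(six), "table")
  expect_equal(tab[np_id == "npA"]$k, 6L)
  expect_equal(tab[np_id == "npA"]$z_sum, 6 * qnorm(0.975) / sqrt(6),
               tolerance = 1e-10)
})

test_that("adjust_pvalues matches brute-force BH and Bonferroni", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)  # m = 1
  expect_equal(adjust_pvalues(c(0.01, rep(0.5, 4)), "bonferroni")[1], 0.05)
  expect_equal(adjust_pvalues(c(0.3, rep(0.5, 4)), "bonferroni")[1], 1.0)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_identical(adjust_pvalues(numeric(0), "bh"), numeric(0))

  set.seed(31)
  for (i in 1:200) {
    m <- sample(1:40, 1)
    p <- runif(m)
    bh <- adjust_pvalues(p, "bh")
    bf <- adjust_pvalues(p, "bonferroni")
    expect_equal(bh, brute_bh(p), tolerance = 1e-14)
    expect_equal(bf, brute_bonferroni(p), tolerance = 1e-14)
    expect_true(all(p <= bh + 1e-14) && all(bh <= bf + 1e-14))
  }
})

test_that("prioritize_herbs reports adjusted p-values and strict selection", {
  set.seed(41)
  N <- 60
  np_rank <- ranked_list(sprintf("np%02d", 1:N),
                         sort(rexp(N, 0.5), decreasing = TRUE))
  herb_sets <- list(
    topherb = np_rank$items[1:6],                  # exactly the top NPs
    h2 = sample(np_rank$items, 6), h3 = sample(np_rank$items, 6),
    h4 = sample(np_rank$items, 6), h5 = sample(np_rank$items, 6))
  res <- prioritize_herbs(np_rank, herb_sets,
                          gsea_params(n_perm = 999, n_perm_max = 99999,
                                      seed = 8))
  expect_equal(res$herb_id[1], "topherb")
  top <- res[res$herb_id == "topherb", ]
  expect_lte(top$p, 1 / 1000)
  expect_true(top$selected)
  expect_equal(top$n_np_targets, 6L)
  # invariants p <= fdr <= 1, p <= bonferroni <= 1, strict selection rule
  expect_true(all(res$p <= res$p_fdr + 1e-14 & res$p_fdr <= 1))
  expect_true(all(res$p <= res$p_bonferroni + 1e-14 & res$p_bonferroni <= 1))
  expect_identical(res$selected, res$p_bonferroni < 0.05)
  # Bonferroni m is the number of herbs actually tested
  expect_equal(res$p_bonferroni, pmin(1, res$p * nrow(res)))
})

test_that("a herb at the Bonferroni boundary is not selected", {
  # nominal p = 0.01 with m = 5 -> adjusted exactly 0.05, strict < fails
  p <- c(0.01, 0.2, 0.4, 0.6, 0.8)
  adj <- adjust_pvalues(p, "bonferroni")
  expect_equal(adj[1], 0.05)
  expect_false(adj[1] < 0.05)
})

test_that("compare_scores_by_label: exact enumeration and degenerate cases", {
  # all C(6,3) = 20 rank splits: most extreme two-sided arrangement -> p = 0.1
  r <- compare_scores_by_label(c(1, 2, 3, 4, 5, 6),
                               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$p_two_sided, 2 / 20)

  r2 <- compare_scores_by_label(c(1, 2, 3, 1, 2, 3),
                                c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r2$p_two_sided, 1.0)

  expect_error(compare_scores_by_label(1:3, c(TRUE, TRUE, TRUE)), "non-empty")
})

test_that("compare_scores_by_label p is uniform under label permutation", {
  set.seed(51)
  scores <- rnorm(40)
  ps <- replicate(1000, {
    lab <- sample(rep(c(TRUE, FALSE), each = 20))
    compare_scores_by_label(scores, lab)$p_two_sided
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.025)
})
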