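test_that("read_sumstats parses, remaps schema and drops invalid rows", {
  f <- write_tsv(tiny_sumstats(), withr::local_tempfile(fileext = ".tsv"))
  dt <- read_sumstats(f)
  expect_equal(nrow(dt), 3L)
  expect_equal(dt$snp, c("rs1", "rs2", "rs3"))
  expect_equal(attr(dt, "n_dropped"), 0L)

  # alternate header mapped via schema gives the same records
  alt <- tiny_sumstats()
  data.table::setnames(alt, c("EA", "OA", "BETA"), c("A1", "A2", "B"))
  f2 <- write_tsv(alt, withr::local_tempfile(fileext = ".tsv"))
  dt2 <- read_sumstats(f2, schema = c(EA = "A1", OA = "A2", BETA = "B"))
  expect_equal(dt2, dt)

  # invariant-violating rows are dropped and counted
  bad <- tiny_sumstats()
  bad$SE[2] <- 0
  bad$P[3] <- 0
  f3 <- write_tsv(bad, withr::local_tempfile(fileext = ".tsv"))
  expect_message(dt3 <- read_sumstats(f3), "dropped 2")
  expect_equal(nrow(dt3), 1L)
  expect_equal(attr(dt3, "n_dropped"), 2L)

  # missing required column is a configuration error, empty file an input error
  f4 <- write_tsv(tiny_sumstats()[, !"SE"], withr::local_tempfile(fileext = ".tsv"))
  expect_error(read_sumstats(f4), "missing required column")
  f5 <- write_tsv(tiny_sumstats()[0], withr::local_tempfile(fileext = ".tsv"))
  expect_error(read_sumstats(f5), "empty")
})

test_that("select_instruments filters by FDR, applying BH only when absent", {
  qtl <- data.table::data.table(
    snp = paste0("rs", 1:4), chr = "1", pos = 1:4 * 100L,
    ea = "A", oa = "G", beta = 0.1, se = 0.01,
    p = c(0.01, 0.02, 0.03, 0.04),
    gene = c("G1", "G1", "G2", "G2"))
  # no fdr column: BH across the full table -> all adjusted to 0.04, all pass
  inst <- select_instruments(qtl, 0.05)
  expect_named(inst, c("G1", "G2"))
  expect_equal(sum(vapply(inst, nrow, 0L)), 4L)

  # fdr present: used as-is, never recomputed (independent of p column)
  qtl2 <- data.table::copy(qtl)[, fdr := c(0.01, 0.2, 0.01, 0.2)]
  inst2 <- select_instruments(qtl2, 0.05)
  expect_equal(vapply(inst2, nrow, 0L), c(G1 = 1L, G2 = 1L))
  qtl3 <- data.table::copy(qtl2)[, p := rev(p)]
  inst3 <- select_instruments(qtl3, 0.05)
  expect_equal(lapply(inst3, `[[`, "snp"), lapply(inst2, `[[`, "snp"))

  # all above threshold -> empty result
  qtl4 <- data.table::copy(qtl)[, fdr := 0.5]
  expect_length(select_instruments(qtl4, 0.05), 0L)

  expect_error(select_instruments(qtl, 1.5), "fdr_threshold")
})

test_that("ld_clump applies the greedy rule and respects the window", {
  v <- data.table::data.table(
    snp = c("s1", "s2", "s3"), chr = "1", pos = c(1e6, 1.1e6, 1.2e6),
    ea = "A", oa = "G", beta = 0.1, se = 0.01, p = c(1e-8, 1e-6, 1e-4))
  ld <- data.table::data.table(
    snp_a = c("s1", "s1", "s2"), snp_b = c("s2", "s3", "s3"),
    r2 = c(0.5, 0.01, 0.01))
  kept <- ld_clump(v, ld, r2_threshold = 0.1, window_kb = 10000)
  expect_setequal(kept$snp, c("s1", "s3"))

  # no LD records: everything retained
  expect_equal(nrow(ld_clump(v, NULL, 0.1, 10000)), 3L)

  # perfect LD: only the best-p SNP survives
  ld_all <- data.table::data.table(
    snp_a = c("s1", "s1", "s2"), snp_b = c("s2", "s3", "s3"), r2 = 1)
  expect_equal(ld_clump(v, ld_all, 0.1, 10000)$snp, "s1")

  # pairs beyond the window count as r2 = 0
  v_far <- data.table::copy(v)[, pos := c(1e6, 1e6 + 2e7, 1e6 + 4e7)]
  expect_equal(nrow(ld_clump(v_far, ld_all, 0.1, window_kb = 10000)), 3L)

  expect_error(ld_clump(v, ld, r2_threshold = 0), "r2_threshold")
})

test_that("ld_clump output is mutually sub-threshold and keeps the min-p SNP", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    v <- data.table::data.table(
      snp = sprintf("s%02d", 1:n), chr = "1",
      pos = sort(sample.int(5e6, n)), ea = "A", oa = "G",
      beta = 0.1, se = 0.01, p = runif(n, 1e-10, 1e-2))
    pairs <- t(combn(n, 2))
    ld <- data.table::data.table(snp_a = v$snp[pairs[, 1]],
                                 snp_b = v$snp[pairs[, 2]],
                                 r2 = runif(nrow(pairs)))
    thr <- runif(1, 0.05, 0.6)
    kept <- ld_clump(v, ld, thr, window_kb = 10000)
    expect_true(v$snp[which.min(v$p)] %in% kept$snp)
    if (nrow(kept) > 1) {
      for (i in 1:(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
        r2ij <- ld[(snp_a == kept$snp[i] & snp_b == kept$snp[j]) |
                     (snp_a == kept$snp[j] & snp_b == kept$snp[i])]$r2
        within <- abs(kept$pos[i] - kept$pos[j]) <= 1e7
        if (within && length(r2ij)) expect_lt(max(r2ij), thr)
      }
    }
  }
})

test_that("harmonize handles swaps, complements, palindromes and mismatches", {
  ex <- list(snp = "rs1", ea = "A", oa = "G", eaf = 0.2, beta = 0.2,
             se = 0.05, p = 1e-5)
  # swapped outcome alleles: swap back, negate beta
  out <- list(snp = "rs1", ea = "G", oa = "A", eaf = 0.8, beta = 0.1,
              se = 0.04, p = 0.01)
  h <- harmonize(ex, out)
  expect_equal(h$action, "swap_flip")
  expect_false(h$dropped)
  expect_equal(h$outcome$ea, "A")
  expect_equal(h$outcome$beta, -0.1)
  expect_equal(h$outcome$eaf, 0.2)

  # identical orientation: untouched
  out2 <- list(snp = "rs1", ea = "A", oa = "G", eaf = 0.2, beta = 0.1,
               se = 0.04, p = 0.01)
  h2 <- harmonize(ex, out2)
  expect_equal(h2$action, "none")
  expect_equal(h2$outcome$beta, 0.1)

  # strand complement (T/C is the complement of A/G)
  out3 <- list(snp = "rs1", ea = "T", oa = "C", eaf = 0.2, beta = 0.1,
               se = 0.04, p = 0.01)
  h3 <- harmonize(ex, out3)
  expect_equal(h3$action, "strand_complement")
  expect_equal(h3$outcome$beta, 0.1)
  expect_equal(h3$outcome$ea, "A")

  # palindromic with ambiguous outcome EAF is dropped
  exp_pal <- list(snp = "rs2", ea = "A", oa = "T", eaf = 0.2, beta = 0.2,
                  se = 0.05, p = 1e-5)
  out_pal <- list(snp = "rs2", ea = "A", oa = "T", eaf = 0.50, beta = 0.1,
                  se = 0.04, p = 0.01)
  h4 <- harmonize(exp_pal, out_pal, palindrome_eaf_window = 0.08)
  expect_equal(h4$action, "dropped_palindrome")
  expect_true(h4$dropped)

  # palindromic with discordant unambiguous EAFs gets flipped
  out_pal2 <- list(snp = "rs2", ea = "A", oa = "T", eaf = 0.8, beta = 0.1,
                   se = 0.04, p = 0.01)
  h5 <- harmonize(exp_pal, out_pal2)
  expect_equal(h5$action, "swap_flip")
  expect_equal(h5$outcome$beta, -0.1)

  # irreconcilable alleles
  out4 <- list(snp = "rs1", ea = "A", oa = "C", eaf = 0.2, beta = 0.1,
               se = 0.04, p = 0.01)
  expect_equal(harmonize(ex, out4)$action, "dropped_mismatch")

  expect_error(harmonize(ex, list(snp = "rs9", ea = "A", oa = "G",
                                  beta = 0, se = 1, p = 1)),
               "contract violation")
})

test_that("harmonize is idempotent and invariant to allele re-encoding", {
  set.seed(7)
  n_checked <- 0
  for (i in 1:2000) {
    pal <- runif(1) < 0.3
    ex <- random_variant("rsX", palindromic = pal)
    out <- random_variant("rsX", palindromic = pal)
    if (!pal && runif(1) < 0.5) { out$ea <- ex$ea; out$oa <- ex$oa }
    h <- harmonize(ex, out)
    if (h$dropped) next
    n_checked <- n_checked + 1
    # idempotence: re-harmonizing the aligned outcome is a no-op
    h2 <- harmonize(ex, h$outcome)
    expect_equal(h2$action, "none")
    expect_equal(h2$outcome$beta, h$outcome$beta)
    # re-encoding the outcome on the opposite allele labelling changes nothing
    h3 <- harmonize(ex, flip_variant(out))
    expect_false(h3$dropped)
    expect_equal(h3$outcome$beta, h$outcome$beta, tolerance = 1e-12)
    expect_equal(h3$outcome$ea, h$outcome$ea)
  }
  expect_gt(n_checked, 200)
})

test_that("find_proxy picks the best-r2 candidate above threshold", {
  outcome <- data.table::data.table(
    snp = c("rsA", "rsB"), chr = "1", pos = c(100L, 200L),
    ea = c("G", "T"), oa = c("T", "C"), eaf = c(0.3, 0.4),
    beta = c(0.15, -0.1), se = c(0.02, 0.02), p = c(1e-4, 1e-3))
  ld <- data.table::data.table(
    snp_a = c("rsQ", "rsQ"), snp_b = c("rsA", "rsB"), r2 = c(0.9, 0.85),
    phased_alleles = c("A/C=G/T", ""))
  hit <- find_proxy("rsQ", outcome, ld, min_r2 = 0.8)
  expect_equal(hit$snp, "rsQ")
  expect_equal(hit$proxy_of, "rsA")
  expect_equal(hit$ea, "A")   # re-phased to the query's alleles
  expect_equal(hit$oa, "C")
  expect_equal(hit$beta, 0.15)

  # below threshold -> none
  ld_low <- data.table::copy(ld)[, r2 := c(0.7, 0.6)]
  expect_null(find_proxy("rsQ", outcome, ld_low, min_r2 = 0.8))

  # r2 tie -> lexicographically smaller partner id
  ld_tie <- data.table::copy(ld)[, r2 := 0.9]
  expect_equal(find_proxy("rsQ", outcome, ld_tie, 0.8)$proxy_of, "rsA")
})
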