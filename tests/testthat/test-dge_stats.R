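test_that("compute_rpkm matches units and the exact-rational worked example", {
  expect_equal(compute_rpkm(1000, 1000, 1e9), 1)          # units cancel
  expect_equal(compute_rpkm(0, 500, 1e6), 0)
  # 18 reads on a 688 bp gene in a 25,603,968-read library; frozen value
  # from exact rational arithmetic
  expect_equal(compute_rpkm(18, 688, 25603968), 1.0218256286554654,
               tolerance = 1e-14)
  expect_error(compute_rpkm(1, 0, 10), class = "dgepair_domain_error")
  expect_error(compute_rpkm(-1, 10, 10), class = "dgepair_domain_error")
  expect_error(compute_rpkm(1, 10, 0), class = "dgepair_domain_error")
})

test_that("log2_fold_change applies the zero substitution rule", {
  expect_equal(log2_fold_change(1, 2), 1)
  expect_equal(log2_fold_change(3.7, 3.7), 0)
  # substitution forces 5.12/0.01 = 512 = 2^9
  expect_equal(log2_fold_change(0, 5.12, 0.01), 9)
  expect_equal(log2_fold_change(5.12, 0, 0.01), -9)
  expect_true(is.finite(log2_fold_change(0, 0)))
  expect_error(log2_fold_change(-1, 2), class = "dgepair_domain_error")
})

test_that("audic_pmf closed-form cases and swap identity hold", {
  expect_equal(audic_pmf(0, 0, 7e6, 7e6), 0.5)
  expect_equal(audic_pmf(0, 3, 7e6, 7e6), 0.0625)   # (1/2)^(y+1)
  # frozen exact-rational value at r = 3
  expect_equal(audic_pmf(5, 12, 1e6, 3e6), 0.04785480134887621,
               tolerance = 1e-12)
  # construction identity: pmf(x | y; N2, N1) = (N2/N1) * pmf(y | x; N1, N2)
  set.seed(42)
  for (i in 1:20) {
    x <- sample(0:40, 1); y <- sample(0:40, 1)
    N1 <- sample(1e5:1e6, 1); N2 <- sample(1e5:1e6, 1)
    expect_equal(audic_pmf(y, x, N2, N1), (N2 / N1) * audic_pmf(x, y, N1, N2),
                 tolerance = 1e-12)
  }
  expect_error(audic_pmf(-1, 0, 10, 10), class = "dgepair_domain_error")
  expect_error(audic_pmf(0, 0.5, 10, 10), class = "dgepair_domain_error")
})

test_that("audic_pvalue matches its defining cases", {
  # equal counts at equal depth: lower tail is exactly 1/2 + pmf/2 >= 1/2,
  # doubling and capping gives 1
  for (x in c(0L, 1L, 7L, 20L))
    expect_equal(audic_pvalue(x, x, 5e6, 5e6), 1)
  expect_equal(audic_pvalue(0, 0, 1e6, 2e6), 2 / 3, tolerance = 1e-12)
  # frozen exact-rational tail sum
  expect_equal(audic_pvalue(3, 30, 1e6, 1e6), 1.4011748135089874e-06,
               tolerance = 1e-10)
})

test_that("pmf and p-value agree with the frozen exact-rational table", {
  tab <- load_exact_audic()
  pmf <- audic_pmf(tab$x, tab$y, 1e6, 1e6 * tab$a / tab$b)
  expect_lt(max(rel_err(pmf, tab$pmf)), 1e-10)
  pv <- audic_pvalue(tab$x, tab$y, 1e6, 1e6 * tab$a / tab$b)
  expect_lt(max(rel_err(pv, tab$p_two)), 1e-10)
})

test_that("pmf normalizes over y at representative x and depth ratios", {
  for (r in c(0.1, 1, 10)) {
    for (x in c(0L, 13L, 60L, 100L)) {
      # K chosen so the true remainder is < 1e-12 (negative-binomial tail)
      K <- stats::qnbinom(1e-13, size = x + 1, prob = 1 / (1 + r),
                          lower.tail = FALSE) + 50
      expect_equal(sum(audic_pmf(x, 0:K, 1e6, r * 1e6)), 1, tolerance = 1e-9)
    }
  }
})

test_that("bh_fdr is the textbook step-up", {
  expect_equal(bh_fdr(0.2), 0.2)                       # single test
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "dgepair_domain_error")

  set.seed(7)
  for (i in 1:50) {
    p <- round(runif(sample(1:40, 1)), 3)  # rounding forces ties
    got <- bh_fdr(p)
    expect_equal(got, brute_bh(p), tolerance = 1e-14)
    expect_equal(got, stats::p.adjust(p, method = "BH"), tolerance = 1e-14)
    expect_true(all(got >= p))                          # never decreases
    expect_equal(order(got[order(p)]), seq_along(p))    # monotone in p
  }
})

test_that("log2 ratios are invariant to joint count/depth scaling", {
  counts <- toy_counts()
  libs1 <- library_pair("L", "S", 1e5, 2e5)
  libs2 <- library_pair("L", "S", 1e6, 2e6)
  scaled <- counts
  scaled[c("reads_L", "reads_S")] <- counts[c("reads_L", "reads_S")] * 10L
  r1 <- call_degs(counts, libs1)
  r2 <- call_degs(scaled, libs2)
  expect_equal(r2$log2_ratio, r1$log2_ratio, tolerance = 1e-12)
})

test_that("call_degs applies inclusive thresholds and drops untestable genes", {
  libs <- library_pair("L", "S", 1e6, 1e6)
  res <- call_degs(toy_counts(), libs)
  # g4 has zero reads in both libraries: untestable, dropped
  expect_identical(attr(res, "untestable"), "g4")
  expect_identical(res$gene_id, c("g1", "g2", "g3"))
  expect_identical(res$direction,
                   ifelse(res$log2_ratio > 0, "up",
                          ifelse(res$log2_ratio < 0, "down", "none")))
  expect_identical(res$is_deg,
                   res$fdr <= 0.001 & abs(res$log2_ratio) >= 1)
  expect_true(all(res$fdr >= res$p_value))
  s <- attr(res, "summary")
  expect_lte(s[["degs_up"]] + s[["degs_down"]], s[["genes_tested"]])

  # boundary: fdr at exactly the threshold and log2 exactly -1 is a DEG.
  # length doubling halves S RPKM: counts (40, 80) at depths (1e4, 4e4)
  # give log2(80/4e4 * 1e4/40) = -1 exactly
  cfg <- test_config(fdr_threshold = 1, min_abs_log2 = 1)
  one <- call_degs(data.frame(gene_id = "b", length_bp = 100L,
                              reads_L = 40L, reads_S = 80L),
                   library_pair("L", "S", 1e4, 4e4), cfg)
  expect_equal(one$log2_ratio, -1)
  expect_true(one$is_deg)      # fdr <= 1 (inclusive) and |log2| >= 1 (inclusive)
  expect_identical(one$direction, "down")

  expect_error(call_degs(toy_counts()[0, ], libs),
               class = "dgepair_domain_error")
})

test_that("null simulation keeps the raw test conservative (small replicate)", {
  spec <- synthetic_spec(n_genes = 2000, total_reads_L = 1e6,
                         total_reads_S = 1e6, de_fraction = 0,
                         min_mean_count = 50, seed = 11)
  g <- generate_counts(spec)
  res <- call_degs(g$counts, g$libs)
  expect_lte(mean(res$p_value <= 0.001), 0.004)
  expect_equal(sum(res$is_deg), 0)
})
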