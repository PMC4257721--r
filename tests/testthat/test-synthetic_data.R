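test_that("generate_counts honours the spec contract", {
  spec <- synthetic_spec(n_genes = 1000, total_reads_L = 1e5,
                         total_reads_S = 1e5, de_fraction = 0.1, seed = 2)
  g <- generate_counts(spec)
  expect_equal(sum(g$truth$is_de), 100L)             # exactly 10% flagged
  expect_equal(sum(g$truth$effect_log2 > 0), 50L)    # even up/down split
  expect_true(all(g$counts$length_bp >= 200 & g$counts$length_bp <= 3000))

  # odd remainder goes up
  g3 <- generate_counts(synthetic_spec(n_genes = 30, total_reads_L = 1e4,
                                       total_reads_S = 1e4,
                                       term_size_range = c(2L, 5L),
                                       de_fraction = 0.1, seed = 2))
  expect_equal(sum(g3$truth$effect_log2 > 0), 2L)
  expect_equal(sum(g3$truth$effect_log2 < 0), 1L)

  # determinism: same spec and seed give bit-identical tables
  g2 <- generate_counts(spec)
  expect_identical(g$counts, g2$counts)
  expect_identical(g$truth, g2$truth)
  # a different seed does not
  galt <- generate_counts(synthetic_spec(n_genes = 1000, total_reads_L = 1e5,
                                         total_reads_S = 1e5,
                                         de_fraction = 0.1, seed = 3))
  expect_false(identical(g$counts$reads_L, galt$counts$reads_L))
})

test_that("null generation matches its stated expectations", {
  spec <- synthetic_spec(n_genes = 2000, total_reads_L = 1e6,
                         total_reads_S = 1e6, de_fraction = 0, seed = 9)
  g <- generate_counts(spec)
  expect_true(all(g$truth$effect_log2 == 0))
  # sum of library-L counts has expectation total_reads_L; Poisson sum
  # concentrates within a few thousand of 1e6
  expect_lt(abs(sum(g$counts$reads_L) - 1e6), 5 * sqrt(1e6))
})

test_that("min_mean_count floors per-gene expected counts", {
  spec <- synthetic_spec(n_genes = 500, total_reads_L = 1e5,
                         total_reads_S = 2e5, min_mean_count = 50, seed = 4)
  g <- generate_counts(spec)
  expect_gte(min(g$truth$baseline_prop) * 1e5, 50 - 1e-9)
  expect_equal(sum(g$truth$baseline_prop), 1, tolerance = 1e-12)
})

test_that("generate_annotations plants (or does not plant) an enriched term", {
  spec0 <- synthetic_spec(n_genes = 300, total_reads_L = 1e4,
                          total_reads_S = 1e4, n_terms = 0, seed = 5)
  genes <- sprintf("g%03d", 1:300)
  # zero terms -> empty map
  a0 <- generate_annotations(genes, spec0)
  expect_length(a0$annotations$map, 0L)

  # planted odds ratio 1 -> nothing enriched in truth
  spec1 <- synthetic_spec(n_genes = 300, total_reads_L = 1e4,
                          total_reads_S = 1e4, n_terms = 10,
                          term_size_range = c(5L, 20L),
                          planted_term_size = 30, planted_or = 1, seed = 5)
  truth <- data.frame(gene_id = genes, is_de = rep(c(TRUE, FALSE), c(30, 270)))
  a1 <- generate_annotations(genes, spec1, truth)
  expect_false(any(a1$truth$enriched))

  # strongly planted term is mostly drawn from true-DE genes
  spec8 <- synthetic_spec(n_genes = 300, total_reads_L = 1e4,
                          total_reads_S = 1e4, n_terms = 10,
                          term_size_range = c(5L, 20L),
                          planted_term_size = 30, planted_or = 50, seed = 5)
  a8 <- generate_annotations(genes, spec8, truth)
  expect_true(a8$truth$enriched[a8$truth$term_id == "TERM_PLANTED"])
  planted_members <- names(Filter(function(t) "TERM_PLANTED" %in% t,
                                  a8$annotations$map))
  expect_gt(mean(planted_members %in% genes[1:30]), 0.5)

  expect_error(generate_annotations(character(0), spec1),
               class = "dgepair_domain_error")
})

test_that("generate_hits_and_catalog produces screenable fixtures", {
  spec <- synthetic_spec(n_genes = 200, total_reads_L = 1e4,
                         total_reads_S = 1e4, hit_fraction = 0.5,
                         n_catalog = 6, seed = 6)
  genes <- sprintf("g%03d", 1:200)
  hc <- generate_hits_and_catalog(genes, spec)
  expect_equal(nrow(hc$hits), 100L)
  expect_named(hc$hits, dgepair:::HITS_COLUMNS)
  # e-values straddle the conventional 1e-5 threshold
  expect_gt(sum(hc$hits$e_value <= 1e-5), 0)
  expect_gt(sum(hc$hits$e_value > 1e-5), 0)
  # one catalogue entry per category -> report carries all six groups
  expect_equal(nrow(hc$catalog), 6L)
  expect_setequal(hc$catalog$category, flowering_categories())

  # a hit at exactly 1e-5 passes the inclusive downstream screen
  degs <- data.frame(gene_id = "g001", is_deg = TRUE, log2_ratio = 2,
                     fdr = 1e-5, direction = "up", p_value = 1e-7)
  hit <- toy_hits("g001", 1e-5)
  expect_equal(nrow(screen_flowering_related(degs, hit)), 1L)

  # 0 hits requested -> empty, correctly typed table
  hc0 <- generate_hits_and_catalog(genes,
           synthetic_spec(n_genes = 200, total_reads_L = 1e4,
                          total_reads_S = 1e4, hit_fraction = 0, seed = 6))
  expect_equal(nrow(hc0$hits), 0L)
})

test_that("degenerate generator specs are rejected", {
  expect_error(synthetic_spec(n_genes = 0), class = "dgepair_domain_error")
  expect_error(synthetic_spec(n_genes = 100, de_fraction = 1),
               class = "dgepair_domain_error")
  expect_error(synthetic_spec(n_genes = 10, term_size_range = c(5L, 50L)),
               class = "dgepair_domain_error")
  expect_error(synthetic_spec(n_genes = 100, total_reads_L = 1e3,
                              total_reads_S = 1e3, min_mean_count = 100),
               class = "dgepair_domain_error")
})
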