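test_that("site matrix applies the per-group presence rule", {
  tabs <- two_group_tables(rep(0.5, 3), rep(0.5, 3), n_per_group = 2, seed = 2)
  # knock out one site in one required sample
  tabs$level[tabs$sample_id == "A_1" & tabs$pos == 100] <- NA
  sm <- build_site_matrix(tabs, c("A_1", "A_2"), c("B_1", "B_2"))
  expect_equal(nrow(sm$sites), 2L)
  expect_false(100 %in% sm$sites$pos)
  # relaxed presence keeps it
  sm2 <- build_site_matrix(tabs, c("A_1", "A_2"), c("B_1", "B_2"),
                           min_present = 1)
  expect_equal(nrow(sm2$sites), 3L)
  expect_error(build_site_matrix(tabs, c("A_1"), c("B_1", "B_2")),
               "2 samples")
})

test_that("per-site differences match hand arithmetic on a 3-site fixture", {
  tabs <- dplyr::bind_rows(
    cpg_tab("A_1", "chr1", c(10, 20, 30), c(2, 0, 10), c(8, 10, 0)),
    cpg_tab("A_2", "chr1", c(10, 20, 30), c(4, 5, 8), c(6, 5, 2)),
    cpg_tab("B_1", "chr1", c(10, 20, 30), c(8, 5, 1), c(2, 5, 9)),
    cpg_tab("B_2", "chr1", c(10, 20, 30), c(6, 10, 3), c(4, 0, 7)))
  sm <- build_site_matrix(tabs, c("A_1", "A_2"), c("B_1", "B_2"))
  # site 10: A mean (0.2+0.4)/2=0.3, B mean (0.8+0.6)/2=0.7 -> diff 0.4
  expect_equal(sm$diff, c(0.4, 0.5, -0.7), tolerance = 1e-12)
})

test_that("segmentation finds the planted block and respects the gap rule", {
  # 12 equally spaced CpGs, diff 0.4 at sites 4-9, 0 elsewhere:
  # exhaustive search over contiguous blocks of length >= 6 picks sites 4-9
  d <- c(0, 0, 0, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4, 0, 0, 0)
  expect_equal(oracle_best_block(d, 6), c(4, 9))
  mk_sm <- function(pos, diff) {
    structure(list(
      sites = tibble::tibble(chrom = "chr1", pos = as.integer(pos)),
      a = matrix(0.5, length(pos), 2), b = matrix(0.5 + diff, length(pos), 2),
      diff = diff), class = "site_matrix")
  }
  sm <- mk_sm(seq(0, by = 100, length.out = 12), d)
  cand <- segment_candidates(sm, dmr_params(min_cpgs = 6))
  expect_equal(nrow(cand), 1L)
  expect_equal(c(cand$idx_from, cand$idx_to), c(4L, 9L))
  # two CpG clusters 1,000 bp apart are never merged at a 300 bp gap cap
  pos2 <- c(seq(0, by = 50, length.out = 10), seq(1500, by = 50, length.out = 10))
  sm2 <- mk_sm(pos2, rep(0.4, 20))
  cand2 <- segment_candidates(sm2, dmr_params(min_cpgs = 6))
  expect_equal(nrow(cand2), 2L)
  expect_true(all(cand2$n_cpgs == 10L))
  # zero signal still yields candidates; downstream tests neutralize them
  sm3 <- mk_sm(seq(0, by = 100, length.out = 12), rep(0, 12))
  cand3 <- segment_candidates(sm3, dmr_params(min_cpgs = 6))
  expect_gte(nrow(cand3), 1L)
})

test_that("region tests behave at the degenerate extremes", {
  same <- matrix(c(0.1, 0.4, 0.7), 3, 2)
  r <- test_region(same, same)
  expect_equal(r$d_ks, 0)
  expect_equal(r$p_ks, 1)
  expect_equal(r$mean_diff, 0)
  lo <- matrix(0, 3, 2)
  hi <- matrix(1, 3, 2)
  r2 <- test_region(lo, hi)
  expect_equal(r2$d_ks, 1)
  expect_equal(r2$mean_diff, 1)
  expect_lt(r2$p_ks, 0.01)
  expect_error(test_region(matrix(0, 3, 1), hi), "2 samples")
})

test_that("exact region p-values match exhaustive enumeration", {
  for (seed in c(101, 202, 303)) {
    withr::with_seed(seed, {
      a <- matrix(runif(8 * 4), 8, 4)
      b <- matrix(runif(8 * 4, 0.2, 1), 8, 4)
    })
    got <- test_region(a, b, method = "exact")
    want <- oracle_exact_p(a, b)
    expect_equal(got$p_ks, want$p_ks, tolerance = 1e-12)
    expect_equal(got$p_mwu, want$p_mwu, tolerance = 1e-12)
    # permutation p-values can never be below 1 / C(8,4)
    expect_gte(got$p_ks, 1 / choose(8, 4))
  }
})

test_that("calling applies the published effect-size filter", {
  # planted difference of 0.15 fails a 0.20 threshold regardless of p
  tabs <- two_group_tables(rep(0.4, 15), rep(0.55, 15), n_per_group = 6,
                           coverage = 200, seed = 7)
  p <- dmr_params(min_cpgs = 10, p_threshold = 0.5, diff_threshold = 0.20)
  got <- call_dmrs(tabs, paste0("A_", 1:6), paste0("B_", 1:6), p)
  expect_equal(nrow(got), 0L)
  expect_gt(attr(got, "n_candidates"), 0L)
  # the same data passes a 0.10 threshold
  p2 <- dmr_params(min_cpgs = 10, p_threshold = 0.5, diff_threshold = 0.10)
  got2 <- call_dmrs(tabs, paste0("A_", 1:6), paste0("B_", 1:6), p2)
  expect_equal(nrow(got2), 1L)
  expect_equal(got2$direction, "hyper")
  expect_lt(abs(got2$mean_diff - 0.15), 0.03)
})

test_that("raising the difference threshold never increases the call count", {
  d <- sim_design(seed = 6, groups = c("youngWT", "oldWT"),
                  chrom_lengths = c(chr1 = 4e5))
  e <- sim_effects(n_age_hyper = 10, n_age_hypo = 5)
  g <- simulate_genome(d, e)
  tabs <- filter_by_coverage(simulate_methylomes(g, d, e), 5)
  thresholds <- c(0.05, 0.10, 0.20, 0.30)
  counts <- vapply(thresholds, function(th) {
    nrow(call_dmrs(tabs, paste0("youngWT_", 1:4), paste0("oldWT_", 1:4),
                   dmr_params(p_threshold = 0.05, diff_threshold = th)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # called DMRs are disjoint and satisfy the CpG minimum
  dmrs <- call_dmrs(tabs, paste0("youngWT_", 1:4), paste0("oldWT_", 1:4))
  expect_true(all(dmrs$n_cpgs >= 10))
  if (nrow(dmrs) > 1) {
    ord <- order(dmrs$chrom, dmrs$start)
    same <- dmrs$chrom[ord][-1] == dmrs$chrom[ord][-nrow(dmrs)]
    expect_true(all(dmrs$start[ord][-1][same] >=
                      dmrs$end[ord][-nrow(dmrs)][same]))
  }
  expect_true(all(dmrs$direction == ifelse(dmrs$mean_diff > 0,
                                           "hyper", "hypo")))
})

test_that("nearest-gene annotation uses gaps, overlaps and tie-breaks", {
  genes <- tibble::tibble(
    gene_id = c("far", "near", "tie_b", "tie_a"), chrom = "chr1",
    start = c(5000L, 2000L, 8000L, 10000L), end = c(6000L, 3000L, 9000L, 11000L),
    strand = "+", tss = c(5000L, 2000L, 8000L, 10000L))
  dmrs <- tibble::tibble(chrom = "chr1",
                         start = c(1000L, 2500L, 9500L),
                         end = c(1100L, 2600L, 9500L + 0L) + c(0L, 0L, 0L),
                         name = c("d1", "d2", "d3"), n_cpgs = 10L,
                         mean_diff = 0.3, p_ks = 1e-3, p_mwu = 1e-3,
                         q_value = 1e-3, direction = "hyper")
  dmrs$end[3] <- 9500L + 500L  # equidistant: gap 0 to tie_b end... adjust
  dmrs$start[3] <- 9200L; dmrs$end[3] <- 9800L
  got <- annotate_nearest_gene(dmrs, genes)
  expect_equal(got$gene_id[1], "near")
  expect_equal(got$distance[1], 900L)
  expect_equal(got$gene_id[2], "near")   # inside the gene body
  expect_equal(got$distance[2], 0L)
  # d3 spans [9200, 9800): gap 200 to both tie_b and tie_a -> smaller start
  expect_equal(got$gene_id[3], "tie_b")
  expect_equal(got$distance[3], 200L)
  expect_error(annotate_nearest_gene(dmrs, genes[0, ]), "empty")
})
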