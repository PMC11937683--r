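test_that("genome simulation matches spacing expectation and is deterministic", {
  d <- sim_design(seed = 5, chrom_lengths = c(chr1 = 1e6),
                  cpg_spacing_mean = 100)
  e0 <- sim_effects(n_age_hyper = 0, n_age_hypo = 0)
  g <- simulate_genome(d, e0)
  # exponential spacing with mean 100 over 1 Mb: ~10,000 CpGs within 5%
  expect_gt(nrow(g$cpgs), 9500)
  expect_lt(nrow(g$cpgs), 10500)
  expect_equal(nrow(g$regions), 0L)
  # determinism: same seed gives identical output
  g2 <- simulate_genome(d, e0)
  expect_identical(g, g2)
  # positions strictly increasing within chromosome
  expect_true(all(diff(g$cpgs$pos) > 0))
})

test_that("planted regions are disjoint, autosomal and span the set CpG count", {
  d <- sim_design(seed = 2, chrom_lengths = c(chr1 = 5e5, chrX = 5e5))
  e <- sim_effects(n_age_hyper = 6, n_age_hypo = 4, region_n_cpgs = 15)
  g <- simulate_genome(d, e)
  expect_equal(nrow(g$regions), 10L)
  expect_true(all(g$regions$chrom == "chr1"))
  expect_equal(sum(g$regions$class == "age_hyper"), 6L)
  ord <- order(g$regions$start)
  expect_true(all(g$regions$start[ord][-1] >= g$regions$end[ord][-10]))
  # each region spans exactly region_n_cpgs consecutive CpGs
  for (i in seq_len(nrow(g$regions))) {
    inside <- g$cpgs$pos >= g$regions$start[i] & g$cpgs$pos < g$regions$end[i] &
      g$cpgs$chrom == g$regions$chrom[i]
    expect_equal(sum(inside), 15L)
  }
  # a chromosome too short to host the request errors
  expect_error(
    simulate_genome(sim_design(seed = 2, chrom_lengths = c(chr1 = 10000)),
                    sim_effects(n_age_hyper = 50)),
    "too short")
})

test_that("null methylomes center at the baseline mean", {
  d <- sim_design(seed = 9, n_per_group = 2, groups = "youngWT",
                  chrom_lengths = c(chr1 = 1e6), coverage_mean = 20)
  e <- sim_effects(baseline_beta = c(2, 2), n_age_hyper = 0, n_age_hypo = 0,
                   age_effect = 0, tg_effect_background = 0,
                   overdispersion = 0)
  g <- simulate_genome(d, e)
  tabs <- simulate_methylomes(g, d, e)
  lv <- tabs$level[!is.na(tabs$level)]
  # Beta(2,2) baseline: pooled mean 0.5; allow 3 x SE of the site-level mean
  se <- sd(lv) / sqrt(length(lv))
  expect_lt(abs(mean(lv) - 0.5), 3 * se + 1e-3)
  # counts respect invariants
  expect_true(all(tabs$meth_count >= 0 & tabs$unmeth_count >= 0))
  expect_true(all(tabs$level >= 0 & tabs$level <= 1, na.rm = TRUE))
})

test_that("planted age effect is recovered inside hyper regions", {
  d <- sim_design(seed = 4, groups = c("youngWT", "oldWT"))
  e <- sim_effects(age_effect = 0.3, n_age_hyper = 30, n_age_hypo = 0,
                   tg_effect_in_hyper = 0, tg_effect_background = 0)
  g <- simulate_genome(d, e)
  tabs <- simulate_methylomes(g, d, e)
  mat <- aggregate_regions(tabs, g$regions)
  young <- rowMeans(mat[, paste0("youngWT_", 1:4)])
  old <- rowMeans(mat[, paste0("oldWT_", 1:4)])
  # clipping at 1 trims the realized shift slightly below the nominal 0.3
  expect_lt(abs(mean(old - young) - 0.3), 0.04)
})

test_that("zero overdispersion reduces to binomial sampling", {
  # fixed mu and coverage; chi-square GOF of per-site counts vs binomial
  d <- sim_design(seed = 12, n_per_group = 2, groups = "youngWT",
                  chrom_lengths = c(chr1 = 2e5), coverage_mean = 30)
  e <- sim_effects(baseline_beta = c(2000, 2000), n_age_hyper = 0,
                   n_age_hypo = 0, tg_effect_background = 0,
                   overdispersion = 0)
  g <- simulate_genome(d, e)
  tabs <- simulate_methylomes(g, d, e)
  tabs <- tabs[tabs$meth_count + tabs$unmeth_count > 0, ]
  # variance of levels at given total n is p(1-p)/n under the binomial;
  # baseline Beta(2000,2000) is nearly degenerate at p = 0.5
  tot <- tabs$meth_count + tabs$unmeth_count
  z2 <- (tabs$meth_count - tot * 0.5)^2 / (tot * 0.25)
  # z^2 ~ chi-square(1) on average: mean close to 1
  expect_lt(abs(mean(z2) - 1), 3 * sqrt(2 / length(z2)) + 0.02)
})

test_that("adding samples or groups does not perturb existing draws", {
  e <- sim_effects()
  d2 <- sim_design(seed = 8, n_per_group = 2)
  d4 <- sim_design(seed = 8, n_per_group = 4)
  g <- simulate_genome(d2, e)
  t2 <- simulate_methylomes(g, d2, e)
  t4 <- simulate_methylomes(g, d4, e)
  s1_2 <- t2[t2$sample_id == "youngWT_1", ]
  s1_4 <- t4[t4$sample_id == "youngWT_1", ]
  expect_identical(as.data.frame(s1_2), as.data.frame(s1_4))
})

test_that("feeding simulation honors the elasticity parameter", {
  base <- list(tissues = "muscle", fed_mean = c(muscle = 120),
               fasted_mean = c(muscle = 90), cv = 0.05, n_per_state = 30)
  mean_state <- function(rho, st, seed = 21) {
    p <- do.call(feeding_params,
                 c(base, list(elasticity_rho = c(WT = rho), seed = seed)))
    tab <- simulate_feeding(p)
    mean(tab$value[tab$state == st])
  }
  # rho = 1: refed mean back at the fed mean (within 3 SE of lognormal noise)
  se <- 120 * 0.05 / sqrt(30)
  expect_lt(abs(mean_state(1, "refed") - mean_state(1, "fed")), 3 * sqrt(2) * se)
  # rho = 0: refed mean stays at the fasted mean
  expect_lt(abs(mean_state(0, "refed") - mean_state(0, "fasted")),
            3 * sqrt(2) * se)
  # cv -> 0 degenerates to the state means exactly
  p0 <- do.call(feeding_params,
                c(base[names(base) != "cv"],
                  list(cv = 1e-12, elasticity_rho = c(WT = 0.5), seed = 1)))
  tab0 <- simulate_feeding(p0)
  expect_equal(tab0$value[tab0$state == "fed"], rep(120, 30),
               tolerance = 1e-8)
  expect_equal(tab0$value[tab0$state == "refed"], rep(105, 30),
               tolerance = 1e-8)
})

test_that("MIAMI simulation plants classes as configured", {
  # no planted fractions: all probes unchanged in truth
  t0 <- simulate_miami(500, frac_hyper = 0, frac_hypo = 0, seed = 2)
  expect_true(all(t0$true_class == "unchanged"))
  # noiseless effect log(2): hyper probes have HpaII/MspI ratio exactly 2
  t1 <- simulate_miami(2000, frac_hyper = 0.2, frac_hypo = 0.2,
                       effect_logfc = log(2), noise_sd = 0, seed = 3)
  hyper <- t1$true_class == "hypermethylated"
  expect_equal(t1$hpaii_ratio[hyper] / t1$mspi_ratio[hyper],
               rep(2, sum(hyper)), tolerance = 1e-12)
  # planted fractions recovered within 3 binomial SE at n = 10,000
  t2 <- simulate_miami(10000, frac_hyper = 0.1, frac_hypo = 0.1, seed = 4)
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(mean(t2$true_class == "hypermethylated") - 0.1), 3 * se)
  expect_lt(abs(mean(t2$true_class == "hypomethylated") - 0.1), 3 * se)
})
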