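test_that("coverage filter keeps the inclusive boundary", {
  tab <- cpg_tab("s1", "chr1", c(10, 20, 30), c(4, 5, 0), c(5, 5, 0))
  expect_equal(filter_by_coverage(tab, 10)$pos, 20L)   # 9 reads removed
  expect_equal(filter_by_coverage(tab, 1)$pos, c(10L, 20L)) # zero-cov removed
  # order preserved
  tab2 <- cpg_tab("s1", "chr1", c(30, 10), c(6, 6), c(6, 6))
  expect_equal(filter_by_coverage(tab2, 5)$pos, c(30L, 10L))
})

test_that("window tiling handles partial windows, overlap and sex exclusion", {
  layout <- tibble::tibble(chrom = c("chr1", "chrX"),
                           length = c(250000L, 250000L),
                           is_sex_chromosome = c(FALSE, TRUE))
  w <- make_windows(layout, 100000)
  expect_equal(nrow(w), 3L)
  expect_equal(w$start[3], 200000L)
  expect_equal(w$end[3], 250000L)
  expect_false(any(w$chrom == "chrX"))
  # half-size step: enumerated by hand
  w2 <- make_windows(layout, 100000, step = 50000)
  expect_equal(nrow(w2), 5L)
  expect_equal(w2$start, c(0L, 50000L, 100000L, 150000L, 200000L))
  expect_equal(w2$end, c(100000L, 150000L, 200000L, 250000L, 250000L))
  # keeping sex chromosomes doubles the count here
  expect_equal(nrow(make_windows(layout, 100000, exclude_sex = FALSE)), 6L)
  expect_error(make_windows(layout, 100, step = 200), "step")
})

test_that("feature regions follow strand and clip at boundaries", {
  genes <- tibble::tibble(
    gene_id = c("plus", "minus", "edge"), chrom = "chr1",
    start = c(2000L, 2000L, 200L), end = c(3000L, 3000L, 900L),
    strand = c("+", "-", "+"))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  fr <- make_feature_regions(genes, promoter_bp = 2000, tss_flank_bp = 2000)
  prom <- fr$promoters
  expect_equal(c(prom$start[1], prom$end[1]), c(0L, 2000L))
  expect_equal(c(prom$start[2], prom$end[2]), c(3000L, 5000L))
  tssp <- fr$TSS_proximal
  # tss at 200 clips at chromosome start
  expect_equal(c(tssp$start[3], tssp$end[3]), c(0L, 2200L))
  expect_equal(fr$gene_bodies$start, genes$start)
})

test_that("region aggregation equals the brute-force per-site scan", {
  tab <- cpg_tab("s1", "chr1", c(100, 200), c(2, 4), c(8, 6))
  reg <- tibble::tibble(chrom = "chr1", start = 0L, end = 300L, label = "w1")
  m <- aggregate_regions(tab, reg)
  expect_equal(m$s1, 0.3)  # mean of 0.2 and 0.4
  # fewer than min_sites eligible CpGs gives a missing cell
  m2 <- aggregate_regions(tab, tibble::tibble(chrom = "chr1", start = 500L,
                                              end = 900L, label = "w2"))
  expect_true(is.na(m2$s1))
  # randomized regions vs oracle
  tabs <- dplyr::bind_rows(random_cpg_table(200, "s1", seed = 31),
                           random_cpg_table(200, "s2", seed = 32))
  regions <- withr::with_seed(33, {
    start <- sample.int(90000, 50)
    tibble::tibble(chrom = "chr1", start = start,
                   end = start + sample(500:5000, 50),
                   label = sprintf("r%02d", 1:50))
  })
  got <- aggregate_regions(tabs, regions, min_sites = 2)
  want <- oracle_aggregate(tabs, regions, min_sites = 2)
  expect_equal(unname(as.matrix(got[, c("s1", "s2")])), unname(want),
               tolerance = 1e-12)
  expect_error(aggregate_regions(tabs, regions[0, ]), "empty region")
})

test_that("global summaries match sort-based statistics", {
  mat <- tibble::tibble(region_id = paste0("r", 1:3), chrom = "chr1",
                        start = 0:2, end = 1:3,
                        s1 = c(0.1, 0.2, 0.3), s2 = c(0.5, 0.5, 0.5))
  s <- summarize_global(mat)
  expect_equal(s$median[s$sample_id == "s1"], 0.2)
  expect_equal(s$median[s$sample_id == "s2"], 0.5)
  # sorting oracle on many random values
  v <- withr::with_seed(11, runif(1001))
  mat2 <- tibble::tibble(region_id = paste0("r", seq_along(v)), chrom = "chr1",
                         start = seq_along(v), end = seq_along(v) + 1,
                         s1 = v)
  med <- summarize_global(mat2)$median
  expect_equal(med, sort(v)[501])
  # all-missing sample errors by name
  mat$s2 <- NA_real_
  expect_error(summarize_global(mat), "s2")
})

test_that("sample PCA has spectral properties and handles duplicates", {
  mat <- withr::with_seed(5, tibble::tibble(
    region_id = paste0("r", 1:40), chrom = "chr1",
    start = 1:40, end = 2:41,
    a = runif(40), b = runif(40), c = runif(40)))
  mat$d <- mat$a  # duplicated sample
  p <- pca_samples(mat)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-12)
  sc <- p$scores
  expect_equal(unlist(sc[sc$sample_id == "a", -1]),
               unlist(sc[sc$sample_id == "d", -1]), tolerance = 1e-10)
  # 2-sample case: PC1 separation equals the Euclidean distance up to sign
  m2 <- mat[, c("region_id", "chrom", "start", "end", "a", "b")]
  p2 <- pca_samples(m2)
  d_ab <- sqrt(sum((mat$a - mat$b)^2))
  expect_equal(abs(diff(p2$scores$PC1)), d_ab, tolerance = 1e-10)
  expect_error(pca_samples(mat[1, ]), "2 complete regions")
})

test_that("hierarchical clustering is deterministic and oracle-consistent", {
  mat <- tibble::tibble(region_id = paste0("r", 1:10), chrom = "chr1",
                        start = 1:10, end = 2:11,
                        A = seq(0.1, 1, 0.1), B = seq(0.1, 1, 0.1),
                        C = rev(seq(0.1, 1, 0.1)))
  tree <- hcluster(mat, "euclidean")
  # identical samples A and B merge first
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))
  # correlation distance is scale-invariant
  mat2 <- mat
  mat2$A <- mat$A * 2
  t1 <- hcluster(mat, "correlation")
  t2 <- hcluster(mat2, "correlation")
  expect_equal(t1$height, t2$height, tolerance = 1e-12)
  expect_equal(t1$merge, t2$merge)
  # complete-linkage heights match the O(n^3) oracle on 6 samples
  m6 <- withr::with_seed(9, {
    d <- tibble::tibble(region_id = paste0("r", 1:15), chrom = "chr1",
                        start = 1:15, end = 2:16)
    for (s in letters[1:6]) d[[s]] <- runif(15)
    d
  })
  tree6 <- hcluster(m6, "euclidean")
  x6 <- t(as.matrix(m6[, letters[1:6]]))
  expect_equal(tree6$height, oracle_complete_linkage_heights(x6),
               tolerance = 1e-12)
  # zero-variance row under correlation errors with its name
  mat$C <- 0.4
  expect_error(hcluster(mat, "correlation"), "C")
})

test_that("row z-scoring normalizes and flags degenerate rows", {
  mat <- tibble::tibble(region_id = c("r1", "r2"), chrom = "chr1",
                        start = 1:2, end = 2:3,
                        s1 = c(1, 5), s2 = c(2, 5), s3 = c(3, 5))
  expect_error(zscore_rows(mat), "r2")
  expect_warning(z <- zscore_rows(mat, on_zero_spread = "drop"), "dropped")
  expect_equal(nrow(z), 1L)
  expect_equal(unlist(z[1, c("s1", "s2", "s3")]), c(s1 = -1, s2 = 0, s3 = 1))
  # recomputed row means/sds of a random matrix are 0/1 to 1e-12
  big <- withr::with_seed(13, {
    d <- tibble::tibble(region_id = paste0("r", 1:30), chrom = "chr1",
                        start = 1:30, end = 2:31)
    for (s in paste0("s", 1:8)) d[[s]] <- runif(30)
    d
  })
  zb <- as.matrix(zscore_rows(big)[, paste0("s", 1:8)])
  expect_lt(max(abs(rowMeans(zb))), 1e-12)
  expect_lt(max(abs(apply(zb, 1, sd) - 1)), 1e-12)
})
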