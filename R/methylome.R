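#' Filter CpG sites by read coverage
#'
#' Retains sites covered by at least `min_reads` reads
#' (methylated + unmethylated), the per-tissue coverage rule of the
#' underlying sequencing design (10 reads for tibialis anterior, 5 for
#' gastrocnemius). The boundary is inclusive and row order is preserved.
#'
#' @param table CpG site table (any number of samples).
#' @param min_reads Minimum total read count (>= 1).
#' @return Filtered tibble.
#' @export
filter_by_coverage <- function(table, min_reads) {
  check_cpg_table(table)
  stopifnot(min_reads >= 1)
  table[table$meth_count + table$unmeth_count >= min_reads, , drop = FALSE]
}

#' Tile chromosomes into (sliding) windows
#'
#' Windows start at 0 and advance by `step`; the default `step = size` gives
#' disjoint tiling. A trailing partial window is kept. Sex chromosomes are
#' dropped when `exclude_sex` is `TRUE`, matching the convention of excluding
#' them from whole-genome bisulfite analyses.
#'
#' @param layout Genome layout tibble (`chrom`, `length`,
#'   `is_sex_chromosome`).
#' @param size Window width in bp.
#' @param step Step between window starts; must not exceed `size`.
#' @param exclude_sex Drop chromosomes flagged as sex chromosomes.
#' @return Region tibble (`chrom`, `start`, `end`, `label`), 0-based
#'   half-open.
#' @export
make_windows <- function(layout, size, step = size, exclude_sex = TRUE) {
  if (step > size) abort("`step` must not exceed `size`")
  stopifnot(step >= 1)
  keep <- layout
  if (exclude_sex) keep <- keep[!keep$is_sex_chromosome, , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(keep)), function(i) {
    len <- keep$length[i]
    starts <- seq(0L, max(0L, len - 1L), by = step)
    ends <- pmin(starts + size, len)
    ok <- starts < ends
    tibble(chrom = keep$chrom[i], start = as.integer(starts[ok]),
           end = as.integer(ends[ok]),
           label = sprintf("%s:%d-%d", keep$chrom[i], starts[ok], ends[ok]))
  })
}

#' Build promoter, gene-body, CGI and TSS-proximal region sets
#'
#' Promoters span `promoter_bp` upstream of the TSS (`[tss - promoter_bp,
#' tss)` on `+` strand genes, mirrored for `-`); gene bodies are the
#' annotated intervals; CGIs pass through unchanged; TSS-proximal regions are
#' symmetric `tss_flank_bp` flanks. All regions are clipped at 0 and, when a
#' layout is supplied, at chromosome ends.
#'
#' @param genes Gene annotation tibble (see [read_gene_bed()]).
#' @param cgis Optional CpG-island region tibble (`chrom`, `start`, `end`).
#' @param promoter_bp Promoter width upstream of the TSS (default 2 kb).
#' @param tss_flank_bp TSS-proximal flank (default 2 kb each side).
#' @param layout Optional genome layout for upper clipping.
#' @return Named list of region tibbles: `promoters`, `gene_bodies`, `CGIs`,
#'   `TSS_proximal`.
#' @export
make_feature_regions <- function(genes, cgis = NULL, promoter_bp = 2000,
                                 tss_flank_bp = 2000, layout = NULL) {
  stopifnot(promoter_bp > 0, tss_flank_bp > 0)
  clip <- function(tab) {
    tab$start <- pmax(tab$start, 0L)
    if (!is.null(layout)) {
      len <- layout$length[match(tab$chrom, layout$chrom)]
      tab$end <- as.integer(pmin(tab$end, len))
    }
    tab[tab$start < tab$end, , drop = FALSE]
  }
  prom <- tibble(
    chrom = genes$chrom,
    start = as.integer(ifelse(genes$strand == "+",
                              genes$tss - promoter_bp, genes$tss + 1L)),
    end = as.integer(ifelse(genes$strand == "+",
                            genes$tss, genes$tss + 1L + promoter_bp)),
    label = genes$gene_id
  )
  bodies <- tibble(chrom = genes$chrom, start = genes$start, end = genes$end,
                   label = genes$gene_id)
  tssp <- tibble(chrom = genes$chrom,
                 start = as.integer(genes$tss - tss_flank_bp),
                 end = as.integer(genes$tss + tss_flank_bp),
                 label = genes$gene_id)
  cgi <- if (is.null(cgis) || nrow(cgis) == 0) {
    tibble(chrom = character(), start = integer(), end = integer(),
           label = character())
  } else {
    tibble(chrom = cgis$chrom, start = cgis$start, end = cgis$end,
           label = tbl_col(cgis, "label") %||%
             sprintf("CGI_%d", seq_len(nrow(cgis))))
  }
  list(promoters = clip(prom), gene_bodies = clip(bodies), CGIs = clip(cgi),
       TSS_proximal = clip(tssp))
}

#' Aggregate per-CpG methylation levels over regions
#'
#' The value of a (region, sample) cell is the unweighted mean of the
#' sample's per-site methylation levels at retained CpGs inside the region;
#' it is missing when fewer than `min_sites` covered CpGs fall in the region.
#' Tables should already be coverage-filtered.
#'
#' @param tables Long CpG site table (all samples).
#' @param regions Region tibble (`chrom`, `start`, `end`, optionally
#'   `label`).
#' @param min_sites Minimum eligible CpGs for a defined cell (default 1).
#' @return Wide methylation-matrix tibble: `region_id`, `chrom`, `start`,
#'   `end`, then one column per sample; values in `[0, 1]` or `NA`.
#' @export
aggregate_regions <- function(tables, regions, min_sites = 1) {
  check_cpg_table(tables)
  if (is.null(regions) || nrow(regions) == 0) abort("empty region list")
  regions <- as_tibble(regions)
  if (!"label" %in% names(regions)) {
    regions$label <- sprintf("region_%d", seq_len(nrow(regions)))
  }
  sites <- tables |> filter(!is.na(.data$level))
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(sites$chrom,
                           IRanges::IRanges(sites$pos + 1L, sites$pos + 1L)),
    GenomicRanges::GRanges(regions$chrom,
                           IRanges::IRanges(regions$start + 1L, regions$end))
  )
  cells <- tibble(
    region_id = regions$label[S4Vectors::subjectHits(hits)],
    sample_id = sites$sample_id[S4Vectors::queryHits(hits)],
    level = sites$level[S4Vectors::queryHits(hits)]
  ) |>
    group_by(.data$region_id, .data$sample_id) |>
    summarise(value = if (n() >= min_sites) mean(.data$level) else NA_real_,
              .groups = "drop")
  samples <- sort(unique(tables$sample_id))
  wide <- tidyr::pivot_wider(cells, names_from = "sample_id",
                             values_from = "value")
  for (s in setdiff(samples, names(wide))) wide[[s]] <- NA_real_
  out <- regions |>
    select(region_id = "label", "chrom", "start", "end") |>
    left_join(wide, by = "region_id")
  out[, c("region_id", "chrom", "start", "end", samples)]
}

matrix_sample_cols <- function(matrix) {
  setdiff(names(matrix), c("region_id", "chrom", "start", "end"))
}

matrix_values <- function(matrix) {
  m <- as.matrix(matrix[, matrix_sample_cols(matrix), drop = FALSE])
  rownames(m) <- matrix$region_id
  m
}

#' Per-sample global methylation summaries
#'
#' Mean, median and quartiles of the non-missing region values of each
#' sample, the summary behind boxplots of mean window methylation.
#'
#' @param matrix Wide methylation matrix from [aggregate_regions()].
#' @return Tibble with one row per sample: `sample_id`, `n_regions`, `mean`,
#'   `median`, `q25`, `q75`.
#' @export
summarize_global <- function(matrix) {
  vals <- matrix_values(matrix)
  if (nrow(vals) == 0 || ncol(vals) == 0) abort("empty methylation matrix")
  purrr::map_dfr(colnames(vals), function(s) {
    v <- vals[, s]
    v <- v[!is.na(v)]
    if (length(v) == 0) abort(sprintf("sample %s has no defined values", s))
    tibble(sample_id = s, n_regions = length(v), mean = mean(v),
           median = stats::median(v),
           q25 = unname(stats::quantile(v, 0.25)),
           q75 = unname(stats::quantile(v, 0.75)))
  })
}

#' Principal-component analysis of samples
#'
#' Regions with any missing value are dropped (complete-case), samples are
#' the observations, and the decomposition is on centered, unscaled values.
#'
#' @param matrix Wide methylation matrix.
#' @return A `methyl_pca` object: `scores` (tibble of per-sample
#'   coordinates), `var_explained` (fractions, non-increasing), and the
#'   underlying `prcomp` fit.
#' @export
pca_samples <- function(matrix) {
  vals <- matrix_values(matrix)
  complete <- vals[stats::complete.cases(vals), , drop = FALSE]
  if (ncol(complete) < 2) abort("need at least 2 samples")
  if (nrow(complete) < 2) abort("fewer than 2 complete regions after filtering")
  fit <- stats::prcomp(t(complete), center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- as_tibble(fit$x, rownames = "sample_id")
  structure(list(scores = scores, var_explained = ve, fit = fit,
                 n_regions = nrow(complete)),
            class = "methyl_pca")
}

#' @export
print.methyl_pca <- function(x, ...) {
  cat(sprintf("PCA of %d samples on %d complete regions\n",
              nrow(x$scores), x$n_regions))
  cat(sprintf("PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$var_explained[1],
              100 * (x$var_explained[2] %||% 0)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.methyl_pca <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.methyl_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores), n_regions = x$n_regions,
         pve_pc1 = x$var_explained[1],
         pve_pc2 = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_)
}

#' Hierarchical clustering of samples or regions
#'
#' Complete-linkage agglomeration on Euclidean or correlation
#' (`1 - Pearson r`) distance, the two conventions used for methylome sample
#' trees and DMR z-score heatmaps respectively. Complete-case rows are used;
#' ties in merge order follow `stats::hclust`'s deterministic input-order
#' behavior.
#'
#' @param matrix Wide methylation matrix.
#' @param distance `"euclidean"` or `"correlation"`.
#' @param linkage Agglomeration method (complete).
#' @param on Cluster `"samples"` (columns) or `"regions"` (rows).
#' @return An `hclust` object with an added `$leaf_order` character vector.
#' @export
hcluster <- function(matrix, distance = c("euclidean", "correlation"),
                     linkage = "complete", on = c("samples", "regions")) {
  distance <- match.arg(distance)
  on <- match.arg(on)
  vals <- matrix_values(matrix)
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  obs <- if (on == "samples") t(vals) else vals
  if (nrow(obs) < 2) abort("need at least 2 observations to cluster")
  if (distance == "euclidean") {
    d <- stats::dist(obs)
  } else {
    sds <- apply(obs, 1, stats::sd)
    if (any(sds == 0)) {
      abort(sprintf("zero-variance row under correlation distance: %s",
                    rownames(obs)[sds == 0][1]))
    }
    d <- stats::as.dist(1 - stats::cor(t(obs)))
  }
  tree <- stats::hclust(d, method = linkage)
  tree$leaf_order <- rownames(obs)[tree$order]
  tree
}

#' Row-wise z-scoring of a methylation matrix
#'
#' Transforms each region row to mean 0 and sample (n-1) standard deviation
#' 1 over its non-missing entries, the transformation used for DMR heatmaps.
#'
#' @param matrix Wide methylation matrix.
#' @param on_zero_spread `"error"` (default) or `"drop"` rows with fewer than
#'   2 values or zero spread (dropping warns).
#' @return Matrix tibble of the same shape with z-scored values.
#' @export
zscore_rows <- function(matrix, on_zero_spread = c("error", "drop")) {
  on_zero_spread <- match.arg(on_zero_spread)
  vals <- matrix_values(matrix)
  ok <- rep(TRUE, nrow(vals))
  for (i in seq_len(nrow(vals))) {
    v <- vals[i, ]
    m <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    if (sum(!is.na(v)) < 2 || is.na(s) || s == 0) {
      if (on_zero_spread == "error") {
        abort(sprintf("zero-spread row: %s", matrix$region_id[i]))
      }
      ok[i] <- FALSE
      next
    }
    vals[i, ] <- (v - m) / s
  }
  if (!all(ok)) {
    warn(sprintf("dropped %d zero-spread rows", sum(!ok)))
  }
  out <- matrix[ok, , drop = FALSE]
  out[, matrix_sample_cols(matrix)] <- as_tibble(vals[ok, , drop = FALSE])
  out
}
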