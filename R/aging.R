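#' Split an age-contrast DMR list into hyper- and hypo-methylated sets
#'
#' DMRs from the old-WT versus young-WT contrast partition by the sign of
#' their mean difference: regions gaining methylation with age
#' (age-associated hyperDMRs) and regions losing it (age-associated
#' hypoDMRs).
#'
#' @param dmrs DMR tibble from [call_dmrs()] (A = young WT, B = old WT).
#' @return An `age_dmr_sets` list with elements `hyper` and `hypo`.
#' @export
classify_age_dmrs <- function(dmrs) {
  structure(list(hyper = dmrs[dmrs$mean_diff > 0, , drop = FALSE],
                 hypo = dmrs[dmrs$mean_diff < 0, , drop = FALSE]),
            class = "age_dmr_sets")
}

#' @export
print.age_dmr_sets <- function(x, ...) {
  cat(sprintf("age-associated DMRs: %d hyper, %d hypo\n",
              nrow(x$hyper), nrow(x$hypo)))
  invisible(x)
}

#' Region-by-sample methylation matrix with per-group means and z-scores
#'
#' Aggregates the given regions over all samples, appends per-group mean
#' columns, and returns a row-z-scored copy for heatmap display.
#'
#' @param regions Region tibble (e.g. called DMRs; needs `chrom`, `start`,
#'   `end`, and a `label`/`name` column).
#' @param tables Long CpG site table with a `group` column (or supply
#'   `groups`).
#' @param groups Optional named character vector mapping sample_id to group.
#' @param min_sites Minimum eligible CpGs per cell.
#' @return List with `matrix` (wide values), `group_means` (region by group),
#'   and `zscores` (row-z-scored copy; zero-spread rows dropped).
#' @export
region_group_matrix <- function(regions, tables, groups = NULL,
                                min_sites = 1) {
  regions <- as_tibble(regions)
  if (!"label" %in% names(regions) && "name" %in% names(regions)) {
    regions$label <- regions$name
  }
  if (is.null(groups)) {
    if (!"group" %in% names(tables)) {
      abort("supply `groups` or a `group` column in `tables`")
    }
    groups <- tables |> distinct(.data$sample_id, .data$group) |>
      (\(d) stats::setNames(d$group, d$sample_id))()
  }
  mat <- aggregate_regions(tables, regions, min_sites = min_sites)
  samples <- matrix_sample_cols(mat)
  gm <- tibble(region_id = mat$region_id)
  for (g in unique(groups)) {
    cols <- samples[groups[samples] == g]
    gm[[g]] <- rowMeans(mat[, cols, drop = FALSE], na.rm = TRUE)
  }
  z <- suppressWarnings(zscore_rows(mat, on_zero_spread = "drop"))
  list(matrix = mat, group_means = gm, zscores = z)
}

#' Dnmt3a sensitivity of age-associated DMR sets
#'
#' Quantifies, on the methylation-proportion scale, how strongly Dnmt3a
#' overexpression shifts methylation inside age-hyper versus age-hypo DMRs
#' in young animals: per region, delta = mean(young Tg) - mean(young WT);
#' the two per-region delta distributions are compared by a Wilcoxon rank
#' test. The published observation corresponds to delta_hyper > delta_hypo
#' ("age-associated hyperDMRs are more sensitive to Dnmt3a"). Old-Tg samples
#' are deliberately not part of this statistic.
#'
#' @param age_sets An `age_dmr_sets` object from [classify_age_dmrs()].
#' @param tables Long CpG site table containing young WT and young Tg
#'   samples.
#' @param young_wt,young_tg Sample-id vectors.
#' @param min_sites Minimum CpGs per region cell.
#' @return A `dnmt3a_sensitivity` object: per-region deltas, set means,
#'   rank-test p-value, and the ordering conclusion.
#' @export
dnmt3a_sensitivity <- function(age_sets, tables, young_wt, young_tg,
                               min_sites = 1) {
  stopifnot(inherits(age_sets, "age_dmr_sets"))
  if (nrow(age_sets$hyper) == 0) abort("empty region set: hyper")
  if (nrow(age_sets$hypo) == 0) abort("empty region set: hypo")
  deltas_for <- function(regions, cls) {
    regions <- as_tibble(regions)
    regions$label <- tbl_col(regions, "name") %||%
      sprintf("%s_%d", cls, seq_len(nrow(regions)))
    mat <- aggregate_regions(
      tables |> filter(.data$sample_id %in% c(young_wt, young_tg)),
      regions, min_sites = min_sites)
    wt <- rowMeans(mat[, intersect(young_wt, names(mat)), drop = FALSE],
                   na.rm = TRUE)
    tg <- rowMeans(mat[, intersect(young_tg, names(mat)), drop = FALSE],
                   na.rm = TRUE)
    tibble(region_id = mat$region_id, class = cls, delta = tg - wt)
  }
  per_region <- bind_rows(deltas_for(age_sets$hyper, "hyper"),
                          deltas_for(age_sets$hypo, "hypo")) |>
    filter(is.finite(.data$delta))
  dh <- per_region$delta[per_region$class == "hyper"]
  dl <- per_region$delta[per_region$class == "hypo"]
  p <- suppressWarnings(stats::wilcox.test(dh, dl, exact = FALSE)$p.value)
  structure(list(
    per_region = per_region,
    delta_hyper = mean(dh), delta_hypo = mean(dl),
    p_value = p,
    conclusion = sprintf(
      "delta_hyper (%.3f) %s delta_hypo (%.3f), rank-test p = %.3g",
      mean(dh), if (mean(dh) > mean(dl)) ">" else "<=", mean(dl), p)
  ), class = "dnmt3a_sensitivity")
}

#' @export
print.dnmt3a_sensitivity <- function(x, ...) {
  cat("Dnmt3a sensitivity of age-associated DMRs (young animals)\n")
  cat(" ", x$conclusion, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dnmt3a_sensitivity <- function(x, ...) x$per_region

#' @exportS3Method generics::glance
glance.dnmt3a_sensitivity <- function(x, ...) {
  tibble(delta_hyper = x$delta_hyper, delta_hypo = x$delta_hypo,
         p_value = x$p_value,
         n_hyper = sum(x$per_region$class == "hyper"),
         n_hypo = sum(x$per_region$class == "hypo"))
}

#' Venn-style overlap of two gene sets
#'
#' @param a,b Character vectors of gene ids (duplicates ignored).
#' @return List with `counts` (a_only, shared, b_only) and `membership`
#'   tibble (`gene_id`, `set`).
#' @export
overlap_sets <- function(a, b) {
  a <- unique(a); b <- unique(b)
  shared <- intersect(a, b)
  membership <- bind_rows(
    tibble(gene_id = setdiff(a, b), set = "a_only"),
    tibble(gene_id = shared, set = "shared"),
    tibble(gene_id = setdiff(b, a), set = "b_only")
  )
  list(counts = c(a_only = length(setdiff(a, b)), shared = length(shared),
                  b_only = length(setdiff(b, a))),
       membership = membership)
}

#' Overlap of DMR-associated genes with differentially expressed genes
#'
#' Gene-level join of a DMRG list against a DEG table, split by DMR
#' direction (hyper/hypo) and DEG direction (up/down by sign of log2
#' fold-change). Duplicate gene ids on either side are collapsed with a
#' warning.
#'
#' @param dmrg DMRG tibble from [annotate_nearest_gene()] (needs `gene_id`
#'   and `direction`).
#' @param degs DEG tibble (`gene_id`, `log2fc`, `fdr`), see
#'   [read_deg_table()].
#' @return List with `n_overlap`, a `by_direction` count tibble, and the
#'   joined `genes` tibble.
#' @export
overlap_with_degs <- function(dmrg, degs) {
  d1 <- dmrg |> filter(!is.na(.data$gene_id)) |>
    select("gene_id", dmr_direction = "direction")
  if (anyDuplicated(d1$gene_id)) {
    warn("duplicate gene ids in DMRG list collapsed (first direction kept)")
    d1 <- d1[!duplicated(d1$gene_id), , drop = FALSE]
  }
  d2 <- degs |> mutate(deg_direction = ifelse(.data$log2fc > 0, "up", "down"))
  if (anyDuplicated(d2$gene_id)) {
    warn("duplicate gene ids in DEG table collapsed (first entry kept)")
    d2 <- d2[!duplicated(d2$gene_id), , drop = FALSE]
  }
  joined <- inner_join(d1, d2, by = "gene_id")
  by_dir <- joined |>
    dplyr::count(.data$dmr_direction, .data$deg_direction, name = "n")
  list(n_overlap = nrow(joined), by_direction = by_dir, genes = joined)
}
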