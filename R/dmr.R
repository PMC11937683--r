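#' DMR calling parameters
#'
#' Defaults follow metilene's own defaults (minimum 10 CpGs per region,
#' 300 bp maximum gap
#' between neighboring CpGs) and the tibialis-anterior filter set
#' (p < 0.01, |difference| > 20%). `diff_threshold` is on the proportion
#' scale: 20% is 0.20. `tissue_mode = "gastrocnemius"` switches to the
#' second published filter set (p < 0.05, |difference| > 10%).
#'
#' @param min_cpgs Minimum CpGs per candidate region.
#' @param max_cpg_gap_bp Maximum gap between adjacent CpGs within a region.
#' @param p_threshold KS p-value cutoff for calling.
#' @param diff_threshold Minimum absolute mean methylation difference.
#' @param adjust `"BH"` to report Benjamini-Hochberg q-values alongside (the
#'   published filter uses the raw KS p; q-values are informational).
#' @param min_present Samples per group in which a site must have a defined
#'   level to enter the matrix; `NULL` means all samples of the group.
#' @param p_method `"asymptotic"` (analytic KS/MWU p-values, the calling
#'   default) or `"exact"` (full enumeration of sample-label assignments;
#'   only feasible for small groups).
#' @param tissue_mode Optional `"TA"` or `"gastrocnemius"` preset overriding
#'   `p_threshold`/`diff_threshold`.
#' @return A `dmr_params` list.
#' @export
dmr_params <- function(min_cpgs = 10, max_cpg_gap_bp = 300,
                       p_threshold = 0.01, diff_threshold = 0.20,
                       adjust = c("BH", "none"), min_present = NULL,
                       p_method = c("asymptotic", "exact"),
                       tissue_mode = NULL) {
  adjust <- match.arg(adjust)
  p_method <- match.arg(p_method)
  if (!is.null(tissue_mode)) {
    tissue_mode <- match.arg(tissue_mode, c("TA", "gastrocnemius"))
    if (tissue_mode == "TA") {
      p_threshold <- 0.01; diff_threshold <- 0.20
    } else {
      p_threshold <- 0.05; diff_threshold <- 0.10
    }
  }
  stopifnot(min_cpgs >= 2, max_cpg_gap_bp >= 1, p_threshold > 0,
            diff_threshold >= 0, diff_threshold <= 1)
  structure(list(min_cpgs = as.integer(min_cpgs),
                 max_cpg_gap_bp = as.integer(max_cpg_gap_bp),
                 p_threshold = p_threshold, diff_threshold = diff_threshold,
                 adjust = adjust, min_present = min_present,
                 p_method = p_method),
            class = "dmr_params")
}

#' Build the per-site two-group methylation matrix
#'
#' A site enters the matrix when its level is defined (covered) in at least
#' `min_present` samples of each group (default: all of them). Per-site
#' group means and their difference (group B minus group A) are attached.
#'
#' @param tables Long CpG site table containing both groups.
#' @param group_a,group_b Character vectors of sample ids.
#' @param min_present Required covered samples per group (`NULL` = all).
#' @return A `site_matrix` list: `sites` tibble (`chrom`, `pos`), numeric
#'   matrices `a` and `b` (sites x samples, NAs only below the presence
#'   threshold), and `diff` = per-site mean(B) - mean(A).
#' @export
build_site_matrix <- function(tables, group_a, group_b, min_present = NULL) {
  check_cpg_table(tables)
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("need at least 2 samples per group")
  }
  sub <- tables |>
    filter(.data$sample_id %in% c(group_a, group_b), !is.na(.data$level)) |>
    select("chrom", "pos", "sample_id", "level")
  wide <- tidyr::pivot_wider(sub, names_from = "sample_id",
                             values_from = "level") |>
    arrange(.data$chrom, .data$pos)
  for (s in setdiff(c(group_a, group_b), names(wide))) wide[[s]] <- NA_real_
  a <- as.matrix(wide[, group_a, drop = FALSE])
  b <- as.matrix(wide[, group_b, drop = FALSE])
  need_a <- min_present %||% length(group_a)
  need_b <- min_present %||% length(group_b)
  keep <- rowSums(!is.na(a)) >= need_a & rowSums(!is.na(b)) >= need_b
  if (!any(keep)) abort("empty intersection of covered sites between groups")
  a <- a[keep, , drop = FALSE]
  b <- b[keep, , drop = FALSE]
  structure(list(sites = wide[keep, c("chrom", "pos")],
                 a = a, b = b,
                 diff = rowMeans(b, na.rm = TRUE) - rowMeans(a, na.rm = TRUE)),
            class = "site_matrix")
}

# Best contiguous sub-block of d with length >= min_len maximizing
# |mean(d[i:j])|; ties broken leftmost, then longest. O(n^2) via cumsum.
best_subblock <- function(d, min_len) {
  n <- length(d)
  if (n < min_len) return(NULL)
  cs <- c(0, cumsum(d))
  best <- c(i = NA_integer_, j = NA_integer_)
  best_val <- -Inf
  for (i in seq_len(n - min_len + 1)) {
    j <- (i + min_len - 1):n
    means <- abs((cs[j + 1] - cs[i]) / (j - i + 1))
    k <- which.max(means)
    if (means[k] > best_val + 1e-12) {
      best_val <- means[k]
      best <- c(i = i, j = j[k])
    }
  }
  list(i = best[["i"]], j = best[["j"]], value = best_val)
}

segment_block <- function(d, lo, hi, min_cpgs, acc) {
  n <- hi - lo + 1
  if (n < min_cpgs) return(acc)
  sub <- best_subblock(d[lo:hi], min_cpgs)
  whole_mean <- abs(mean(d[lo:hi]))
  bi <- lo + sub$i - 1
  bj <- lo + sub$j - 1
  if ((bi == lo && bj == hi) || sub$value <= whole_mean + 1e-12) {
    return(c(acc, list(c(lo, hi))))
  }
  acc <- segment_block(d, bi, bj, min_cpgs, acc)
  acc <- segment_block(d, lo, bi - 1, min_cpgs, acc)
  segment_block(d, bj + 1, hi, min_cpgs, acc)
}

#' Segment the genome into candidate DMR blocks
#'
#' Chromosomes are first split wherever adjacent informative CpGs are more
#' than `max_cpg_gap_bp` apart. Within each pre-segment, recursive binary
#' segmentation extracts the contiguous sub-block (length >= `min_cpgs`)
#' maximizing the absolute mean per-site difference; recursion continues into
#' the block and its flanks until no sub-block improves on its parent.
#' Emitted candidates are disjoint.
#'
#' @param sm A `site_matrix` from [build_site_matrix()].
#' @param params A [dmr_params()] object.
#' @return Candidate tibble: `chrom`, `start`, `end` (0-based half-open,
#'   first to last member CpG + 1), `idx_from`, `idx_to` (row indices into
#'   `sm`), `n_cpgs`.
#' @export
segment_candidates <- function(sm, params = dmr_params()) {
  stopifnot(inherits(sm, "site_matrix"))
  out <- list()
  for (chrom in unique(sm$sites$chrom)) {
    idx <- which(sm$sites$chrom == chrom)
    pos <- sm$sites$pos[idx]
    gaps <- diff(pos)
    breaks <- which(gaps > params$max_cpg_gap_bp)
    seg_start <- c(1, breaks + 1)
    seg_end <- c(breaks, length(idx))
    for (s in seq_along(seg_start)) {
      lo <- seg_start[s]; hi <- seg_end[s]
      if (hi - lo + 1 < params$min_cpgs) next
      blocks <- segment_block(sm$diff[idx], lo, hi, params$min_cpgs, list())
      blocks <- extend_blocks(blocks, sm$diff[idx], lo, hi)
      for (b in blocks) {
        out[[length(out) + 1]] <- tibble(
          chrom = chrom,
          start = pos[b[1]], end = pos[b[2]] + 1L,
          idx_from = idx[b[1]], idx_to = idx[b[2]],
          n_cpgs = b[2] - b[1] + 1L
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  idx_from = integer(), idx_to = integer(),
                  n_cpgs = integer()))
  }
  bind_rows(out) |> arrange(.data$chrom, .data$start)
}

# Boundary refinement: the min-length argmax tends to shrink a true region
# to its strongest core under noise, so each emitted block is greedily
# extended over adjacent CpGs whose per-site difference shares the block's
# sign, up to the pre-segment edges. Extended candidates may overlap;
# call_dmrs resolves overlaps when filtering. Identical spans are collapsed.
extend_blocks <- function(blocks, d, lo, hi) {
  if (length(blocks) == 0) return(blocks)
  out <- lapply(blocks, function(b) {
    s <- sign(mean(d[b[1]:b[2]]))
    while (b[1] > lo && sign(d[b[1] - 1]) == s && d[b[1] - 1] != 0) {
      b[1] <- b[1] - 1
    }
    while (b[2] < hi && sign(d[b[2] + 1]) == s && d[b[2] + 1] != 0) {
      b[2] <- b[2] + 1
    }
    b
  })
  out <- out[!duplicated(vapply(out, paste, character(1), collapse = "-"))]
  out[order(vapply(out, function(b) as.numeric(b[1]), numeric(1)))]
}

#' Two-group statistical tests for one region
#'
#' Computes (i) a two-sample Kolmogorov-Smirnov test on the pooled per-site,
#' per-sample methylation values of the two groups and (ii) a Mann-Whitney U
#' test on the per-site group means, plus the mean methylation difference
#' (B - A). The analytic p-values are the calling default; `method =
#' "exact"` instead enumerates every assignment of the samples into two
#' groups of the observed sizes and reports permutation p-values of the KS
#' statistic and the absolute rank-sum deviation.
#'
#' @param a,b Numeric matrices (sites x samples) for groups A and B over the
#'   same sites.
#' @param method `"asymptotic"` or `"exact"`.
#' @return A one-row tibble: `p_ks`, `p_mwu`, `mean_diff`, `d_ks`.
#' @export
test_region <- function(a, b, method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) < 2 || ncol(b) < 2) abort("fewer than 2 samples per group")
  stopifnot(nrow(a) == nrow(b))
  mean_diff <- mean(rowMeans(b, na.rm = TRUE) - rowMeans(a, na.rm = TRUE))
  av <- as.vector(a); av <- av[!is.na(av)]
  bv <- as.vector(b); bv <- bv[!is.na(bv)]
  d_obs <- ks_stat(av, bv)
  if (method == "asymptotic") {
    p_ks <- suppressWarnings(
      stats::ks.test(av, bv, exact = FALSE)$p.value)
    p_mwu <- suppressWarnings(
      stats::wilcox.test(rowMeans(a, na.rm = TRUE), rowMeans(b, na.rm = TRUE),
                         exact = FALSE, correct = TRUE)$p.value)
    p_ks <- min(max(p_ks, .Machine$double.xmin), 1)
    p_mwu <- min(max(p_mwu, .Machine$double.xmin), 1)
  } else {
    res <- exact_region_pvalues(a, b)
    p_ks <- res$p_ks
    p_mwu <- res$p_mwu
  }
  tibble(p_ks = p_ks, p_mwu = p_mwu, mean_diff = mean_diff, d_ks = d_obs)
}

# Exhaustive permutation of sample labels: all C(nA+nB, nA) assignments.
# KS statistic on pooled values; MWU statistic = |rank-sum deviation| of the
# per-site means of the first pseudo-group.
exact_region_pvalues <- function(a, b) {
  all_mat <- cbind(a, b)
  n_a <- ncol(a); n_tot <- ncol(all_mat)
  combos <- utils::combn(n_tot, n_a)
  n_sites <- nrow(all_mat)
  mwu_stat <- function(ma, mb) {
    r <- rank(c(ma, mb))
    abs(sum(r[seq_len(n_sites)]) - n_sites * (2 * n_sites + 1) / 2)
  }
  stat_pair <- function(cols_a) {
    cols_b <- setdiff(seq_len(n_tot), cols_a)
    xa <- all_mat[, cols_a, drop = FALSE]
    xb <- all_mat[, cols_b, drop = FALSE]
    va <- as.vector(xa); va <- va[!is.na(va)]
    vb <- as.vector(xb); vb <- vb[!is.na(vb)]
    c(ks_stat(va, vb),
      mwu_stat(rowMeans(xa, na.rm = TRUE), rowMeans(xb, na.rm = TRUE)))
  }
  obs <- stat_pair(seq_len(n_a))
  stats_all <- apply(combos, 2, stat_pair)
  tol <- 1e-12
  list(p_ks = mean(stats_all[1, ] >= obs[1] - tol),
       p_mwu = mean(stats_all[2, ] >= obs[2] - tol))
}

#' Call differentially methylated regions between two groups
#'
#' Runs the full pipeline: site matrix construction, gap-aware recursive
#' segmentation, per-region KS and MWU tests, then the published filter:
#' `p_KS < p_threshold` and `|mean difference| > diff_threshold`. BH
#' q-values over all tested candidates are reported for transparency but do
#' not participate in the filter. Called DMRs are coordinate-sorted and
#' non-overlapping, with direction `"hyper"` (B > A) or `"hypo"`.
#'
#' @param tables Long CpG site table (coverage-filtered).
#' @param group_a,group_b Sample-id vectors (A is the reference, e.g. young
#'   WT; B the comparison, e.g. old WT).
#' @param params A [dmr_params()] object.
#' @return DMR tibble: `chrom`, `start`, `end`, `name`, `n_cpgs`,
#'   `mean_diff`, `p_ks`, `p_mwu`, `q_value`, `direction`, with the number of
#'   tested candidates in `attr(, "n_candidates")`.
#' @export
call_dmrs <- function(tables, group_a, group_b, params = dmr_params()) {
  sm <- build_site_matrix(tables, group_a, group_b, params$min_present)
  cand <- segment_candidates(sm, params)
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), n_cpgs = integer(),
                  mean_diff = double(), p_ks = double(), p_mwu = double(),
                  q_value = double(), direction = character())
  if (nrow(cand) == 0) {
    attr(empty, "n_candidates") <- 0L
    return(empty)
  }
  tests <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
    rows <- cand$idx_from[i]:cand$idx_to[i]
    test_region(sm$a[rows, , drop = FALSE], sm$b[rows, , drop = FALSE],
                method = params$p_method)
  })
  cand <- as_tibble(cbind(cand, tests))
  cand$q_value <- if (params$adjust == "BH") {
    stats::p.adjust(cand$p_ks, method = "BH")
  } else cand$p_ks
  keep <- cand$p_ks < params$p_threshold &
    abs(cand$mean_diff) > params$diff_threshold
  out <- cand[keep, , drop = FALSE] |>
    resolve_overlaps() |>
    mutate(direction = ifelse(.data$mean_diff > 0, "hyper", "hypo")) |>
    arrange(.data$chrom, .data$start) |>
    select("chrom", "start", "end", "n_cpgs", "mean_diff", "p_ks", "p_mwu",
           "q_value", "direction")
  out <- mutate(out, name = sprintf("dmr_%04d", dplyr::row_number()),
                .after = "end")
  attr(out, "n_candidates") <- nrow(cand)
  out
}

# Boundary-refined candidates can overlap; keep the best-supported DMR of
# each overlapping cluster (smallest KS p, then larger |difference|, then
# leftmost) and drop the rest, so called DMRs are disjoint.
resolve_overlaps <- function(cand) {
  if (nrow(cand) <= 1) return(cand)
  ord <- order(cand$p_ks, -abs(cand$mean_diff), cand$chrom, cand$start)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    taken <- which(keep)
    clash <- any(cand$chrom[taken] == cand$chrom[i] &
                   cand$start[taken] < cand$end[i] &
                   cand$end[taken] > cand$start[i])
    keep[i] <- !clash
  }
  cand[keep, , drop = FALSE]
}

#' Annotate DMRs with their nearest gene
#'
#' The nearest-neighbor gene of a DMR is taken as its associated gene
#' (DMRG). Distance is 0 when the DMR overlaps the gene body, otherwise the
#' gap between the intervals; ties go to the gene with the smaller start,
#' then the lexicographically smaller id. Only same-chromosome genes are
#' considered; DMRs on gene-less chromosomes get `NA` with a warning.
#'
#' @param dmrs DMR tibble from [call_dmrs()].
#' @param genes Gene annotation tibble.
#' @return The DMR tibble with added `gene_id` and `distance` columns.
#' @export
annotate_nearest_gene <- function(dmrs, genes) {
  if (is.null(genes) || nrow(genes) == 0) abort("gene list is empty")
  res <- purrr::map_dfr(seq_len(nrow(dmrs)), function(i) {
    g <- genes[genes$chrom == dmrs$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) {
      return(tibble(gene_id = NA_character_, distance = NA_integer_))
    }
    gap <- pmax(0L, pmax(g$start, dmrs$start[i]) - pmin(g$end, dmrs$end[i]))
    ord <- order(gap, g$start, g$gene_id)
    tibble(gene_id = g$gene_id[ord[1]], distance = as.integer(gap[ord[1]]))
  })
  if (any(is.na(res$gene_id))) {
    warn("some DMRs lie on chromosomes without annotated genes")
  }
  as_tibble(cbind(dmrs, res))
}
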