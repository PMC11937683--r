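#' Read a Bismark-style coverage file into a CpG site table
#'
#' Parses a tab-separated coverage file with columns
#' `chrom, start, end, methylation_percent, count_methylated, count_unmethylated`
#' where `start` is 1-based inclusive (the Bismark coverage dialect). The
#' returned table uses the package-wide convention: 0-based positions of the C
#' of each CpG on the forward strand. The percent column is never trusted;
#' `level` is recomputed from the counts and is `NA` at zero coverage.
#'
#' @param path Path to the coverage file.
#' @param sample_id Sample identifier attached to every row.
#' @param collapse_strands If `TRUE`, rows at adjacent positions (pos, pos+1)
#'   on the same chromosome are treated as the two strands of one CpG and
#'   collapsed onto the forward-strand C by summing counts.
#' @return A tibble with columns `sample_id`, `chrom`, `pos` (0-based),
#'   `meth_count`, `unmeth_count`, `level`, sorted by `(chrom, pos)`.
#' @examples
#' tf <- tempfile(fileext = ".cov")
#' writeLines("chr1\t101\t101\t50.0\t5\t5", tf)
#' read_cpg_table(tf, "s1")
#' @export
read_cpg_table <- function(path, sample_id, collapse_strands = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- suppressWarnings(readr::read_tsv(
    path,
    col_names = c("chrom", "start1", "end1", "pct", "meth_count", "unmeth_count"),
    col_types = readr::cols(
      chrom = readr::col_character(), start1 = readr::col_double(),
      end1 = readr::col_double(), pct = readr::col_double(),
      meth_count = readr::col_double(), unmeth_count = readr::col_double()
    ),
    progress = FALSE, na = c("", "NA")
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed coverage row at line %d of %s", probs$row[1], path))
  }
  bad <- which(!stats::complete.cases(raw[c("chrom", "start1", "meth_count", "unmeth_count")]))
  if (length(bad) > 0) {
    abort(sprintf("malformed coverage row at line %d of %s", bad[1], path))
  }
  if (any(raw$meth_count < 0 | raw$unmeth_count < 0)) {
    abort(sprintf("negative counts at line %d of %s",
                  which(raw$meth_count < 0 | raw$unmeth_count < 0)[1], path))
  }
  out <- tibble(
    sample_id = sample_id,
    chrom = raw$chrom,
    pos = as.integer(raw$start1 - 1),
    meth_count = as.integer(raw$meth_count),
    unmeth_count = as.integer(raw$unmeth_count)
  )
  if (collapse_strands) out <- collapse_cpg_strands(out)
  out$level <- cpg_level(out$meth_count, out$unmeth_count)
  arrange(out, .data$chrom, .data$pos)
}

# Sum counts of (pos, pos + 1) pairs onto the forward-strand C.
collapse_cpg_strands <- function(tab) {
  tab <- arrange(tab, .data$chrom, .data$pos)
  is_rev <- c(FALSE, tab$chrom[-1] == tab$chrom[-nrow(tab)] &
                tab$pos[-1] == tab$pos[-nrow(tab)] + 1L)
  anchor <- ifelse(is_rev, tab$pos - 1L, tab$pos)
  tab |>
    mutate(pos = anchor) |>
    group_by(.data$sample_id, .data$chrom, .data$pos) |>
    summarise(meth_count = sum(.data$meth_count),
              unmeth_count = sum(.data$unmeth_count), .groups = "drop")
}

#' Write a CpG site table as a Bismark-style coverage file
#'
#' Inverse of [read_cpg_table()]: positions are converted back to 1-based and
#' the methylation-percent column is recomputed from the counts (written as 0
#' for zero-coverage sites).
#'
#' @param table CpG site table (one sample).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpg_table <- function(table, path) {
  check_cpg_table(table)
  total <- table$meth_count + table$unmeth_count
  out <- tibble(
    chrom = table$chrom,
    start1 = table$pos + 1L,
    end1 = table$pos + 1L,
    pct = ifelse(total > 0, 100 * table$meth_count / total, 0),
    meth = table$meth_count,
    unmeth = table$unmeth_count
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene annotations from a BED6 file
#'
#' BED intervals are already 0-based half-open and are kept that way. The
#' transcription start site is `start` for `+` strand genes and `end - 1` for
#' `-` strand genes.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- suppressWarnings(readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "gene_id", "score", "strand"),
    col_types = "ciicic", progress = FALSE
  ))
  if (!"strand" %in% names(raw) || any(is.na(raw$strand)) ||
      !all(raw$strand %in% c("+", "-"))) {
    abort("BED6 strand column missing or not one of '+'/'-'")
  }
  if (any(raw$start >= raw$end)) {
    abort(sprintf("gene interval with start >= end at line %d",
                  which(raw$start >= raw$end)[1]))
  }
  tibble(
    gene_id = raw$gene_id, chrom = raw$chrom,
    start = raw$start, end = raw$end, strand = raw$strand,
    tss = ifelse(raw$strand == "+", raw$start, raw$end - 1L)
  )
}

#' Write gene annotations as BED6
#'
#' @param genes Gene annotation tibble as returned by [read_gene_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  out <- tibble(chrom = genes$chrom, start = genes$start, end = genes$end,
                name = genes$gene_id, score = 0L, strand = genes$strand)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

dmr_bed_cols <- c("chrom", "start", "end", "name", "n_cpgs", "mean_diff",
                  "p_ks", "p_mwu", "direction")

#' Write called DMRs as a BED file with statistics columns
#'
#' Writes 9 columns: `chrom, start, end, name, n_cpgs, mean_diff, p_ks,
#' p_mwu, direction`, 0-based half-open, preceded by a `#`-prefixed header
#' line. An empty DMR set produces a header-only file.
#'
#' @param dmrs DMR tibble from [call_dmrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#", paste(dmr_bed_cols, collapse = "\t")), con)
  if (nrow(dmrs) > 0) {
    name <- tbl_col(dmrs, "name") %||% sprintf("dmr_%d", seq_len(nrow(dmrs)))
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%.*g\t%.*g\t%.*g\t%s",
                     dmrs$chrom, dmrs$start, dmrs$end, name, dmrs$n_cpgs,
                     17L, dmrs$mean_diff, 17L, dmrs$p_ks, 17L, dmrs$p_mwu,
                     dmrs$direction)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a DMR BED file written by [write_dmr_bed()]
#'
#' @param path Path to the DMR BED file.
#' @return Tibble with the nine DMR columns.
#' @export
read_dmr_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_names = dmr_bed_cols, skip = 1,
                         col_types = "ciicidddc", progress = FALSE)
  as_tibble(raw)
}

#' Read a fed/fasted/refed phenotype table
#'
#' Expects a TSV with columns `mouse_id`, `genotype`, `state`,
#' `tissue_or_gene`, `value` (mass in mg or normalized expression). Each
#' mouse belongs to exactly one feeding state.
#'
#' @param path Path to the TSV file.
#' @return Validated tibble.
#' @export
read_feeding_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = "ccccd", progress = FALSE)
  validate_feeding_table(as_tibble(raw))
}

validate_feeding_table <- function(tab) {
  need <- c("mouse_id", "genotype", "state", "tissue_or_gene", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    abort(paste("feeding table missing columns:", paste(miss, collapse = ", ")))
  }
  if (!all(tab$state %in% c("fed", "fasted", "refed"))) {
    abort("feeding state must be one of 'fed', 'fasted', 'refed'")
  }
  multi <- tab |> distinct(.data$mouse_id, .data$state) |>
    dplyr::count(.data$mouse_id) |> filter(.data$n > 1)
  if (nrow(multi) > 0) {
    abort(sprintf("mouse %s appears in more than one feeding state",
                  multi$mouse_id[1]))
  }
  if (any(!is.finite(tab$value)) || any(tab$value <= 0)) {
    abort("feeding values must be positive and finite")
  }
  tab
}

#' Write a feeding table as TSV
#' @param table Feeding tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feeding_table <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Read a MIAMI probe table
#'
#' TSV with columns `probe_id`, `gene_id`, `hpaii_ratio`, `mspi_ratio`
#' (between-sample signal ratios on the linear scale). Log-ratios are
#' recomputed on read.
#'
#' @param path Path to the TSV file.
#' @return Tibble with ratio and log-ratio columns.
#' @export
read_miami_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (any(raw$hpaii_ratio <= 0) || any(raw$mspi_ratio <= 0)) {
    abort("MIAMI signal ratios must be positive")
  }
  as_tibble(raw) |>
    mutate(log_hpaii = log(.data$hpaii_ratio), log_mspi = log(.data$mspi_ratio))
}

#' Write a MIAMI probe table as TSV
#' @param table MIAMI probe tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_miami_table <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Read a differentially-expressed-gene list
#'
#' DEG calling itself is upstream of this package; lists are consumed as
#' plain TSV with columns `gene_id`, `log2fc`, `fdr`.
#'
#' @param path Path to the TSV file.
#' @return Tibble of DEGs.
#' @export
read_deg_table <- function(path) {
  as_tibble(readr::read_tsv(path, col_types = "cdd", progress = FALSE))
}

#' Write a methylation matrix (regions by samples) as TSV
#' @param matrix Wide methylation matrix tibble from [aggregate_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methyl_matrix <- function(matrix, path) {
  readr::write_tsv(matrix, path, progress = FALSE)
  invisible(path)
}

#' Read a methylation matrix written by [write_methyl_matrix()]
#' @param path Path to the TSV file.
#' @return Wide methylation matrix tibble.
#' @export
read_methyl_matrix <- function(path) {
  as_tibble(readr::read_tsv(path, col_types = readr::cols(), progress = FALSE))
}
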