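#' Classification thresholds for MIAMI HpaII/MspI ratios
#'
#' The published criteria for between-sample methylation differences:
#' HpaII signal ratios below 0.714 denote hypomethylation and above 1.3
#' hypermethylation, applied on the linear ratio scale. An optional MspI
#' ratio band can force probes with aberrant copy-number proxy signal to
#' "unchanged".
#'
#' @param low Lower HpaII ratio threshold (default 0.714).
#' @param high Upper HpaII ratio threshold (default 1.3).
#' @param mspi_band Optional length-2 numeric `(lo, hi)`; probes with
#'   `mspi_ratio` outside it are forced to `"unchanged"`. Default off.
#' @return A `miami_thresholds` list.
#' @export
miami_thresholds <- function(low = 0.714, high = 1.3, mspi_band = NULL) {
  stopifnot(low > 0, low < 1, high > 1)
  if (!is.null(mspi_band)) {
    stopifnot(length(mspi_band) == 2, mspi_band[1] < mspi_band[2])
  }
  structure(list(low = low, high = high, mspi_band = mspi_band),
            class = "miami_thresholds")
}

#' Classify MIAMI probes by HpaII ratio
#'
#' Probes with `hpaii_ratio < low` are called hypomethylated, `> high`
#' hypermethylated, and everything in between unchanged. When an MspI band
#' is configured, probes whose MspI ratio falls outside it are set to
#' unchanged regardless of the HpaII signal.
#'
#' @param table MIAMI probe tibble (needs positive `hpaii_ratio` and
#'   `mspi_ratio`).
#' @param thr A [miami_thresholds()] object.
#' @return The table with a `meth_class` column filled.
#' @export
classify_probes <- function(table, thr = miami_thresholds()) {
  stopifnot(inherits(thr, "miami_thresholds"))
  bad <- which(!is.finite(table$hpaii_ratio) | table$hpaii_ratio <= 0 |
                 !is.finite(table$mspi_ratio) | table$mspi_ratio <= 0)
  if (length(bad) > 0) {
    abort(sprintf("non-positive signal ratio for probe %s",
                  table$probe_id[bad[1]]))
  }
  cls <- ifelse(table$hpaii_ratio < thr$low, "hypomethylated",
                ifelse(table$hpaii_ratio > thr$high, "hypermethylated",
                       "unchanged"))
  if (!is.null(thr$mspi_band)) {
    outside <- table$mspi_ratio < thr$mspi_band[1] |
      table$mspi_ratio > thr$mspi_band[2]
    cls[outside] <- "unchanged"
  }
  mutate(table, meth_class = cls)
}

#' Summarize a classified MIAMI probe table
#'
#' @param table Classified probe tibble (from [classify_probes()]).
#' @return List with `counts` (named vector over the three classes, summing
#'   to the probe count) and deduplicated `hyper_genes` / `hypo_genes`
#'   character vectors.
#' @export
miami_summary <- function(table) {
  if (is.null(table$meth_class)) abort("table is not classified yet")
  counts <- c(
    hypermethylated = sum(table$meth_class == "hypermethylated"),
    hypomethylated = sum(table$meth_class == "hypomethylated"),
    unchanged = sum(table$meth_class == "unchanged")
  )
  gene_of <- function(cls) {
    if (is.null(table$gene_id)) return(character())
    sort(unique(table$gene_id[table$meth_class == cls & !is.na(table$gene_id)]))
  }
  list(counts = counts,
       hyper_genes = gene_of("hypermethylated"),
       hypo_genes = gene_of("hypomethylated"))
}
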