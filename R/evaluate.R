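#' Match called regions against a truth set by reciprocal overlap
#'
#' Used in simulation studies to score a DMR caller against planted
#' regions: a pair matches when the overlap covers at least
#' `min_reciprocal` of both intervals. Recall is the fraction of truth
#' regions matched; precision the fraction of called regions matched.
#'
#' @param called,truth Region tibbles (`chrom`, `start`, `end`).
#' @param min_reciprocal Minimum reciprocal overlap fraction (default 0.5).
#' @return List with `recall`, `precision`, `n_called`, `n_truth`, and the
#'   logical match vectors `called_matched`, `truth_matched`.
#' @export
match_regions <- function(called, truth, min_reciprocal = 0.5) {
  called_matched <- rep(FALSE, nrow(called))
  truth_matched <- rep(FALSE, nrow(truth))
  if (nrow(called) > 0 && nrow(truth) > 0) {
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(called$chrom,
                             IRanges::IRanges(called$start + 1L, called$end)),
      GenomicRanges::GRanges(truth$chrom,
                             IRanges::IRanges(truth$start + 1L, truth$end))
    )
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- pmin(called$end[qi], truth$end[si]) -
      pmax(called$start[qi], truth$start[si])
    ok <- ov >= min_reciprocal * (called$end[qi] - called$start[qi]) &
      ov >= min_reciprocal * (truth$end[si] - truth$start[si])
    called_matched[unique(qi[ok])] <- TRUE
    truth_matched[unique(si[ok])] <- TRUE
  }
  list(recall = if (nrow(truth) > 0) mean(truth_matched) else NA_real_,
       precision = if (nrow(called) > 0) mean(called_matched) else NA_real_,
       n_called = nrow(called), n_truth = nrow(truth),
       called_matched = called_matched, truth_matched = truth_matched)
}
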