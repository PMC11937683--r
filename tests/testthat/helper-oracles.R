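# Independent oracles used to check package computations. These deliberately
# re-derive results by the most literal route available (spreadsheet
# transcription, exhaustive enumeration, brute-force loops) and never call
# the code paths they validate.

# Cell-by-cell transcription of the published Excel definition of the Tissue
# Elasticity Score (IF / AND / ABS / MIN / MAX), scalar only.
oracle_elas <- function(Y, A) {
  if (max(Y - 100, A) == 0) {
    return(0) # division undefined; contract: score 0, flagged degenerate
  }
  value1 <- (Y - 100 + A) * min(Y - 100, A) / max(Y - 100, A)
  value2 <- if (Y - 100 > 0) value1 else -value1
  if (abs(Y - 100) > A && (Y - 100) < 0) -value2 else value2
}

# Exhaustive enumeration of every assignment of the pooled samples into two
# groups of the observed sizes; permutation p-values of the KS statistic on
# pooled values and the absolute rank-sum deviation of per-site means.
oracle_exact_p <- function(a, b) {
  m <- cbind(a, b)
  n_a <- ncol(a)
  n_tot <- ncol(m)
  ks_of <- function(x, y) {
    g <- sort(unique(c(x, y)))
    max(abs(stats::ecdf(x)(g) - stats::ecdf(y)(g)))
  }
  u_of <- function(x, y) {
    r <- rank(c(x, y))
    abs(sum(r[seq_along(x)]) - length(x) * (length(x) + length(y) + 1) / 2)
  }
  sets <- utils::combn(n_tot, n_a)
  d <- numeric(ncol(sets))
  u <- numeric(ncol(sets))
  for (k in seq_len(ncol(sets))) {
    ca <- sets[, k]
    cb <- setdiff(seq_len(n_tot), ca)
    d[k] <- ks_of(as.vector(m[, ca]), as.vector(m[, cb]))
    u[k] <- u_of(rowMeans(m[, ca, drop = FALSE]),
                 rowMeans(m[, cb, drop = FALSE]))
  }
  # column 1 of combn is the identity assignment
  list(p_ks = mean(d >= d[1] - 1e-12), p_mwu = mean(u >= u[1] - 1e-12))
}

# Brute-force per-site scan replacement for aggregate_regions.
oracle_aggregate <- function(tables, regions, min_sites = 1) {
  samples <- sort(unique(tables$sample_id))
  out <- matrix(NA_real_, nrow(regions), length(samples),
                dimnames = list(NULL, samples))
  for (r in seq_len(nrow(regions))) {
    for (s in samples) {
      sub <- tables[tables$sample_id == s &
                      tables$chrom == regions$chrom[r] &
                      tables$pos >= regions$start[r] &
                      tables$pos < regions$end[r] &
                      !is.na(tables$level), , drop = FALSE]
      if (nrow(sub) >= min_sites) out[r, s] <- mean(sub$level)
    }
  }
  out
}

# Naive O(n^3) complete-linkage agglomeration; returns merge heights in
# merge order.
oracle_complete_linkage_heights <- function(x) {
  d_full <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    best_h <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- max(d_full[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Exhaustive search over contiguous blocks of length >= min_len maximizing
# the absolute mean of d; returns c(from, to).
oracle_best_block <- function(d, min_len) {
  best <- NULL
  best_val <- -Inf
  n <- length(d)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 < min_len) next
      v <- abs(mean(d[i:j]))
      if (v > best_val + 1e-12) {
        best_val <- v
        best <- c(i, j)
      }
    }
  }
  best
}
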