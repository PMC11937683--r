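cpg_tab <- function(sample_id, chrom, pos, meth, unmeth,
                    group = NA_character_) {
  tibble::tibble(sample_id = sample_id, group = group, chrom = chrom,
                 pos = as.integer(pos), meth_count = as.integer(meth),
                 unmeth_count = as.integer(unmeth),
                 level = ifelse(meth + unmeth > 0, meth / (meth + unmeth),
                                NA_real_))
}

random_cpg_table <- function(n = 100, sample_id = "s1", seed = 1) {
  withr::with_seed(seed, {
    pos <- sort(sample.int(100000, n))
    meth <- rpois(n, 5)
    unmeth <- rpois(n, 5)
    cpg_tab(sample_id, "chr1", pos, meth, unmeth)
  })
}

# small two-group site table: shared positions, per-sample binomial counts
# around group means
two_group_tables <- function(mu_a, mu_b, n_per_group = 4, coverage = 20,
                             spacing = 50, seed = 1) {
  withr::with_seed(seed, {
    n <- length(mu_a)
    pos <- cumsum(rep(spacing, n))
    rows <- list()
    for (i in seq_len(n_per_group)) {
      tot <- rpois(n, coverage) + 1L
      rows[[paste0("a", i)]] <- cpg_tab(paste0("A_", i), "chr1", pos,
                                        rbinom(n, tot, mu_a), 0,
                                        group = "A")
      rows[[paste0("a", i)]]$unmeth_count <-
        tot - rows[[paste0("a", i)]]$meth_count
      tot <- rpois(n, coverage) + 1L
      rows[[paste0("b", i)]] <- cpg_tab(paste0("B_", i), "chr1", pos,
                                        rbinom(n, tot, mu_b), 0,
                                        group = "B")
      rows[[paste0("b", i)]]$unmeth_count <-
        tot - rows[[paste0("b", i)]]$meth_count
    }
    out <- dplyr::bind_rows(rows)
    out$level <- out$meth_count / (out$meth_count + out$unmeth_count)
    out
  })
}
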