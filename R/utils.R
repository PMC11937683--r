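#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows n across all_of rename distinct pull
#' @importFrom tibble tibble as_tibble
#' @import ggplot2
NULL

# Deterministic 32-bit sub-seed for a named random stream. Streams are keyed
# by strings such as "methylome/youngWT/2" so adding samples or stages never
# perturbs the draws of existing ones.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(paste0("s:", stream))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

with_stream_seed <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stream))
  force(code)
}

# Beta-binomial draw: size trials, mean mu, dispersion rho in [0, 1).
# rho = 0 reduces exactly to the binomial.
rbetabinom <- function(n, size, mu, rho) {
  mu <- rep_len(pmin(pmax(mu, 0), 1), n)
  size <- rep_len(size, n)
  if (rho <= 0) {
    return(stats::rbinom(n, size, mu))
  }
  theta <- (1 - rho) / rho
  p <- stats::rbeta(n, mu * theta, (1 - mu) * theta)
  # rbeta returns NaN when a shape is 0 (mu at the boundary); the limit is
  # a point mass at the boundary value.
  p[mu == 0] <- 0
  p[mu == 1] <- 1
  stats::rbinom(n, size, p)
}

# Two-sample Kolmogorov-Smirnov statistic, tie-safe.
ks_stat <- function(x, y) {
  pooled <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(pooled)
  fy <- stats::ecdf(y)(pooled)
  max(abs(fx - fy))
}

check_cpg_table <- function(x, arg = "table") {
  need <- c("sample_id", "chrom", "pos", "meth_count", "unmeth_count", "level")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("`%s` is missing CpG-table columns: %s", arg,
                  paste(miss, collapse = ", ")))
  }
  invisible(x)
}

# column accessor that returns NULL (not a tibble warning) when absent
tbl_col <- function(x, col) {
  if (col %in% names(x)) x[[col]] else NULL
}

# level = meth / total, NA when total == 0
cpg_level <- function(meth, unmeth) {
  total <- meth + unmeth
  ifelse(total > 0, meth / total, NA_real_)
}
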