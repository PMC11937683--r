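#' Normalize fed and refed values to the fasted-state mean
#'
#' Implements the first two lines of the published spreadsheet definition of
#' the Tissue Elasticity Score, within one genotype x tissue cell:
#' `X_i = fed_i / mean(fasted) * 100 - 100` per fed mouse and
#' `Y_j = refed_j / mean(fasted) * 100 - 100` per refed mouse.
#' Normalization is within genotype.
#'
#' @param table Feeding tibble (see [read_feeding_table()]).
#' @param genotype,tissue Cell selectors.
#' @return List with `X` (per fed mouse), `Y` (per refed mouse), and
#'   `fasted_mean`.
#' @export
normalize_to_fasted <- function(table, genotype, tissue) {
  cell <- table |>
    filter(.data$genotype == !!genotype, .data$tissue_or_gene == !!tissue)
  fasted <- cell$value[cell$state == "fasted"]
  if (length(fasted) == 0 || mean(fasted) == 0) {
    abort(sprintf("no usable fasted group for %s / %s", genotype, tissue))
  }
  fm <- mean(fasted)
  fed <- cell[cell$state == "fed", , drop = FALSE]
  refed <- cell[cell$state == "refed", , drop = FALSE]
  list(X = stats::setNames(fed$value / fm * 100 - 100, fed$mouse_id),
       Y = stats::setNames(refed$value / fm * 100 - 100, refed$mouse_id),
       fasted_mean = fm)
}

#' Tissue Elasticity Score for one refed mouse
#'
#' Verbatim evaluation of the published Excel formula. With `y = Y - 100`
#' and `A` the fed-group average of `(X - 100)`:
#' `Value1 = (y + A) * min(y, A) / max(y, A)`;
#' `Value2 = Value1` if `y > 0`, else `-Value1`;
#' `ElaS = -Value2` if (`|y| > A` and `y < 0`), else `Value2`.
#' The second subtraction of 100 from the already-normalized percentages is
#' part of the published formula and is applied as printed (see the methods
#' vignette); the absolute value in the final condition applies to `y` only.
#' When `max(y, A) = 0` the division is undefined; the score is reported as
#' 0 with `degenerate = TRUE`.
#'
#' @param Y Refed percent value(s) from [normalize_to_fasted()] (vectorized).
#' @param A Fed-group average of `(X - 100)` (scalar).
#' @return Tibble with columns `elas` and `degenerate`.
#' @export
elas_score <- function(Y, A) {
  stopifnot(is.finite(A), all(is.finite(Y)))
  y <- Y - 100
  lo <- pmin(y, A)
  hi <- pmax(y, A)
  degenerate <- hi == 0
  value1 <- ifelse(degenerate, 0, (y + A) * lo / hi)
  value2 <- ifelse(y > 0, value1, -value1)
  elas <- ifelse(abs(y) > A & y < 0, -value2, value2)
  elas[degenerate] <- 0
  tibble(elas = elas, degenerate = degenerate)
}

#' Elasticity scores for every genotype x tissue cell, with comparison
#'
#' Computes per-refed-mouse ElaS values (the fed-side constant `A` is fixed
#' per genotype x tissue from its fed mice), group mean and standard error,
#' and, when exactly two genotypes are present, a two-tailed unpaired
#' Student's t test per tissue (the published comparison). Degenerate scores
#' are excluded from summaries and tests.
#'
#' @param table Feeding tibble.
#' @param corrected If `TRUE`, use the arguably intended reading of the
#'   formula (no second `-100`: `y = Y`, `A = mean(X)`); default `FALSE`,
#'   i.e. the formula exactly as printed.
#' @return An `elas_result` object with `scores`, `summary`, and
#'   `comparison` tibbles.
#' @export
elas_table <- function(table, corrected = FALSE) {
  table <- validate_feeding_table(as_tibble(table))
  cells <- table |> distinct(.data$genotype, .data$tissue_or_gene)
  scores <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    gt <- cells$genotype[i]; tis <- cells$tissue_or_gene[i]
    norm <- normalize_to_fasted(table, gt, tis)
    A <- if (corrected) mean(norm$X) else mean(norm$X - 100)
    Yv <- if (corrected) norm$Y + 100 else norm$Y
    sc <- elas_score(Yv, A)
    tibble(genotype = gt, tissue = tis,
           mouse_id = names(norm$Y) %||% character(0),
           Y = unname(norm$Y), A = A,
           elas = sc$elas, degenerate = sc$degenerate)
  })
  summary <- scores |>
    filter(!.data$degenerate) |>
    group_by(.data$genotype, .data$tissue) |>
    summarise(n = n(), mean_elas = mean(.data$elas),
              se_elas = ifelse(n() > 1, stats::sd(.data$elas) / sqrt(n()),
                               NA_real_),
              .groups = "drop")
  genos <- unique(scores$genotype)
  comparison <- if (length(genos) == 2) {
    purrr::map_dfr(unique(scores$tissue), function(tis) {
      x <- scores |> filter(.data$tissue == tis, !.data$degenerate,
                            .data$genotype == genos[1]) |> pull("elas")
      y <- scores |> filter(.data$tissue == tis, !.data$degenerate,
                            .data$genotype == genos[2]) |> pull("elas")
      if (length(x) < 2 || length(y) < 2) {
        return(tibble(tissue = tis, statistic = NA_real_, df = NA_real_,
                      p_value = NA_real_))
      }
      tt <- stats::t.test(x, y, var.equal = TRUE)
      tibble(tissue = tis, statistic = unname(tt$statistic),
             df = unname(tt$parameter), p_value = tt$p.value)
    })
  } else {
    tibble(tissue = character(), statistic = double(), df = double(),
           p_value = double())
  }
  structure(list(scores = scores, summary = summary,
                 comparison = comparison, corrected = corrected),
            class = "elas_result")
}

#' @export
print.elas_result <- function(x, ...) {
  cat("Tissue Elasticity Scores (ElaS)\n")
  print(x$summary)
  if (nrow(x$comparison) > 0) {
    cat("between-genotype t tests:\n")
    print(x$comparison)
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.elas_result <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.elas_result <- function(x, ...) {
  left_join(x$summary |>
              tidyr::pivot_wider(names_from = "genotype",
                                 values_from = c("n", "mean_elas", "se_elas")),
            x$comparison, by = "tissue")
}

#' Fed/fasted/refed responsiveness of a gene panel
#'
#' For each gene (or tissue) and genotype: induction is the fasted-to-fed
#' ratio of group means; restoration measures how fully the refed mean
#' returns to the fed mean, `1 - |refed - fed| / |fasted - fed|` (1 = full
#' return, 0 = still at the fasted level). Restoration is undefined (flagged)
#' when fasted and fed means coincide.
#'
#' @param table Feeding tibble for a gene panel (all three states present).
#' @return Tibble with `tissue_or_gene`, `genotype`, `induction`,
#'   `restoration`, `restoration_defined`.
#' @export
gene_responsiveness <- function(table) {
  table <- validate_feeding_table(as_tibble(table))
  table |>
    group_by(.data$tissue_or_gene, .data$genotype) |>
    summarise(
      fed = mean(.data$value[.data$state == "fed"]),
      fasted = mean(.data$value[.data$state == "fasted"]),
      refed = mean(.data$value[.data$state == "refed"]),
      .groups = "drop"
    ) |>
    (\(d) {
      if (any(!is.finite(d$fed) | !is.finite(d$fasted) | !is.finite(d$refed))) {
        abort("each gene x genotype needs fed, fasted and refed mice")
      }
      if (any(d$fed == 0)) abort("zero fed mean")
      d
    })() |>
    mutate(
      induction = .data$fasted / .data$fed,
      restoration_defined = .data$fasted != .data$fed,
      restoration = ifelse(.data$restoration_defined,
                           1 - abs(.data$refed - .data$fed) /
                             abs(.data$fasted - .data$fed), NA_real_)
    ) |>
    select("tissue_or_gene", "genotype", "induction", "restoration",
           "restoration_defined")
}
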