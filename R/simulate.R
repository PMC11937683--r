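#' Simulation design for a 2x2 methylome experiment
#'
#' Describes the genotype (WT / Dnmt3a-Tg) by age (young / old) layout of a
#' simulated whole-genome bisulfite experiment, the genome geometry, and
#' sequencing depth. Defaults mirror a gastrocnemius-style design: 4 mice per
#' group, mean coverage 20x, one CpG per ~100 bp.
#'
#' @param n_per_group Mice per group (>= 2).
#' @param groups Subset of `c("youngWT", "oldWT", "youngTg", "oldTg")`.
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#'   Chromosomes named `chrX`/`chrY` (or `X`/`Y`) are flagged as sex
#'   chromosomes.
#' @param cpg_spacing_mean Mean CpG spacing in bp (exponential inter-CpG gaps).
#' @param coverage_mean Mean per-site read depth (Poisson).
#' @param seed Integer seed; all randomness derives per-stream sub-seeds from
#'   it so adding samples never perturbs existing ones.
#' @return A `sim_design` list.
#' @export
sim_design <- function(n_per_group = 4,
                       groups = c("youngWT", "oldWT", "youngTg", "oldTg"),
                       chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                       cpg_spacing_mean = 100,
                       coverage_mean = 20,
                       seed = 1L) {
  chrom_lengths <- unlist(chrom_lengths)  # YAML configs supply a list
  stopifnot(n_per_group >= 2, coverage_mean > 0, cpg_spacing_mean >= 2,
            all(chrom_lengths > 0), length(chrom_lengths) >= 1)
  groups <- match.arg(groups, c("youngWT", "oldWT", "youngTg", "oldTg"),
                      several.ok = TRUE)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 chrom_lengths = chrom_lengths,
                 cpg_spacing_mean = cpg_spacing_mean,
                 coverage_mean = coverage_mean, seed = as.integer(seed)),
            class = "sim_design")
}

#' Planted effect sizes for the methylome simulation
#'
#' Encodes the structure the aging analysis is meant to recover: regions that
#' gain methylation with age (age-hyperDMRs), regions that lose it
#' (age-hypoDMRs), and a Dnmt3a-Tg genotype shift that is stronger inside
#' age-hyperDMRs than inside age-hypoDMRs.
#'
#' @param baseline_beta Shape parameters `c(a, b)` of the per-CpG baseline
#'   methylation Beta distribution.
#' @param n_age_hyper,n_age_hypo Planted region counts.
#' @param region_n_cpgs CpGs per planted region (consecutive CpGs).
#' @param age_effect Methylation-proportion shift of old vs young inside
#'   planted regions (+ in hyper, - in hypo).
#' @param tg_effect_in_hyper,tg_effect_in_hypo,tg_effect_background Genotype
#'   (Tg - WT) shifts by region class.
#' @param overdispersion Beta-binomial dispersion in `[0, 1)`; 0 is binomial.
#' @return A `sim_effects` list.
#' @export
sim_effects <- function(baseline_beta = c(2, 2),
                        n_age_hyper = 50, n_age_hypo = 20,
                        region_n_cpgs = 15,
                        age_effect = 0.3,
                        tg_effect_in_hyper = 0.15,
                        tg_effect_in_hypo = 0.03,
                        tg_effect_background = 0.01,
                        overdispersion = 0.05) {
  stopifnot(length(baseline_beta) == 2, all(baseline_beta > 0),
            n_age_hyper >= 0, n_age_hypo >= 0, region_n_cpgs >= 2,
            age_effect >= 0, age_effect < 1,
            overdispersion >= 0, overdispersion < 1)
  structure(list(baseline_beta = baseline_beta,
                 n_age_hyper = as.integer(n_age_hyper),
                 n_age_hypo = as.integer(n_age_hypo),
                 region_n_cpgs = as.integer(region_n_cpgs),
                 age_effect = age_effect,
                 tg_effect_in_hyper = tg_effect_in_hyper,
                 tg_effect_in_hypo = tg_effect_in_hypo,
                 tg_effect_background = tg_effect_background,
                 overdispersion = overdispersion),
            class = "sim_effects")
}

#' Simulate a genome layout with CpG positions, genes and planted regions
#'
#' Background CpGs are laid down with exponential spacing. Planted DMR
#' regions span a fixed number of consecutive CpGs placed at half the
#' background spacing, emulating the CpG-dense regulatory context where real
#' DMRs concentrate; regions are disjoint, autosomal, and evenly allocated
#' across chromosomes. One gene is placed per ~10 kb for nearest-gene tests.
#'
#' @param design A [sim_design()] object.
#' @param effects A [sim_effects()] object (supplies planted region counts).
#' @return A list of class `methelas_genome` with elements `layout`
#'   (chrom/length/is_sex_chromosome), `cpgs` (chrom/pos, 0-based), `genes`
#'   (BED6-style tibble with TSS), and `regions` (planted regions with a
#'   `class` column, `age_hyper` or `age_hypo`).
#' @export
simulate_genome <- function(design, effects = sim_effects()) {
  stopifnot(inherits(design, "sim_design"), inherits(effects, "sim_effects"))
  layout <- tibble(
    chrom = names(design$chrom_lengths),
    length = as.integer(design$chrom_lengths),
    is_sex_chromosome = names(design$chrom_lengths) %in%
      c("chrX", "chrY", "X", "Y")
  )
  autosomes <- layout$chrom[!layout$is_sex_chromosome]
  if (length(autosomes) == 0) abort("no autosomes in the layout")

  n_regions <- effects$n_age_hyper + effects$n_age_hypo
  # allocate planted regions round-robin over autosomes weighted by length
  alloc <- integer(0)
  if (n_regions > 0) {
    w <- layout$length[match(autosomes, layout$chrom)]
    alloc <- table(factor(
      sample_weighted_roundrobin(autosomes, w, n_regions), levels = autosomes))
  }

  region_rows <- list()
  cpg_rows <- list()
  reg_idx <- 0L
  dense_gap_mean <- max(2, design$cpg_spacing_mean / 2)
  for (ci in seq_len(nrow(layout))) {
    chrom <- layout$chrom[ci]
    clen <- layout$length[ci]
    k <- if (chrom %in% autosomes && n_regions > 0) alloc[[chrom]] else 0L
    # region extent upper-ballpark; slots must be wide enough to host one
    extent <- effects$region_n_cpgs * dense_gap_mean * 4 + 2 * design$cpg_spacing_mean
    if (k > 0 && clen < k * extent * 2) {
      abort(sprintf("chromosome %s (%d bp) too short to host %d planted regions",
                    chrom, clen, k))
    }
    reg <- NULL
    if (k > 0) {
      reg <- with_stream_seed(design$seed, paste0("regions/", chrom), {
        slot <- clen / k
        starts <- floor((seq_len(k) - 1) * slot + slot / 4)
        purrr::map(starts, function(s) {
          gaps <- pmax(2, round(stats::rexp(effects$region_n_cpgs - 1,
                                            rate = 1 / dense_gap_mean)))
          pos <- s + c(0, cumsum(gaps))
          pos
        })
      })
    }
    bg <- with_stream_seed(design$seed, paste0("cpgs/", chrom), {
      n_draw <- ceiling(clen / design$cpg_spacing_mean * 1.3) + 50
      gaps <- pmax(2, round(stats::rexp(n_draw, rate = 1 / design$cpg_spacing_mean)))
      pos <- cumsum(gaps)
      pos[pos < clen]
    })
    if (!is.null(reg)) {
      # drop background CpGs inside or adjacent to planted spans
      for (pos in reg) {
        bg <- bg[bg < pos[1] - 2 | bg > pos[length(pos)] + 2]
      }
      for (pos in reg) {
        reg_idx <- reg_idx + 1L
        region_rows[[reg_idx]] <- tibble(
          chrom = chrom, start = pos[1], end = pos[length(pos)] + 1L,
          label = sprintf("planted_%03d", reg_idx)
        )
      }
      all_pos <- sort(unique(c(bg, unlist(reg))))
    } else {
      all_pos <- bg
    }
    cpg_rows[[ci]] <- tibble(chrom = chrom, pos = as.integer(all_pos))
  }
  regions <- bind_rows(region_rows)
  if (nrow(regions) > 0) {
    # first n_age_hyper planted regions are hyper, the rest hypo, assigned
    # deterministically after shuffling region order by seed
    ord <- with_stream_seed(design$seed, "region-class",
                            sample.int(nrow(regions)))
    cls <- rep("age_hypo", nrow(regions))
    cls[ord <= effects$n_age_hyper] <- "age_hyper"
    regions$class <- cls
  } else {
    regions <- tibble(chrom = character(), start = integer(), end = integer(),
                      label = character(), class = character())
  }

  genes <- purrr::map_dfr(seq_len(nrow(layout)), function(ci) {
    chrom <- layout$chrom[ci]
    n_g <- max(1L, floor(layout$length[ci] / 10000))
    start <- as.integer((seq_len(n_g) - 1) * 10000 + 3000)
    tibble(
      gene_id = sprintf("%s_g%04d", chrom, seq_len(n_g)),
      chrom = chrom, start = start, end = start + 4000L,
      strand = rep_len(c("+", "-"), n_g)
    ) |> mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L))
  })

  structure(list(layout = layout,
                 cpgs = bind_rows(cpg_rows),
                 genes = genes, regions = regions),
            class = "methelas_genome")
}

# deterministic proportional allocation: largest-remainder by weight
sample_weighted_roundrobin <- function(items, w, n) {
  share <- w / sum(w) * n
  base <- floor(share)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(items, times = base)
}

group_is_old <- function(g) g %in% c("oldWT", "oldTg")
group_is_tg <- function(g) g %in% c("youngTg", "oldTg")

#' Simulate per-sample CpG methylation count tables
#'
#' Per CpG `i` a baseline methylation proportion `pi ~ Beta(a, b)` is drawn
#' once and shared by all samples. Each group's expected level adds the
#' planted age shift (old samples, inside planted regions) and the genotype
#' shift (Tg samples, by region class), clipped to `[0, 1]`. Per-sample read
#' totals are Poisson(coverage) and methylated counts are beta-binomial with
#' the given overdispersion (binomial when 0).
#'
#' @param genome A `methelas_genome` from [simulate_genome()].
#' @param design A [sim_design()] object.
#' @param effects A [sim_effects()] object.
#' @param clip_warn_tol Warn when more than 5% of per-group expected levels
#'   had to be clipped by more than this amount.
#' @return A long tibble (one row per sample x CpG) with columns `sample_id`,
#'   `group`, `chrom`, `pos`, `meth_count`, `unmeth_count`, `level`.
#' @export
simulate_methylomes <- function(genome, design, effects = sim_effects(),
                                clip_warn_tol = 0.1) {
  stopifnot(inherits(genome, "methelas_genome"), inherits(design, "sim_design"))
  cpgs <- genome$cpgs
  n_cpg <- nrow(cpgs)
  pi0 <- with_stream_seed(design$seed, "baseline",
                          stats::rbeta(n_cpg, effects$baseline_beta[1],
                                       effects$baseline_beta[2]))
  cls <- cpg_region_class(cpgs, genome$regions)

  sample_tabs <- list()
  for (g in design$groups) {
    shift <- numeric(n_cpg)
    if (group_is_old(g)) {
      shift <- shift + effects$age_effect * (cls == "age_hyper") -
        effects$age_effect * (cls == "age_hypo")
    }
    if (group_is_tg(g)) {
      shift <- shift + effects$tg_effect_in_hyper * (cls == "age_hyper") +
        effects$tg_effect_in_hypo * (cls == "age_hypo") +
        effects$tg_effect_background * (cls == "background")
    }
    mu_raw <- pi0 + shift
    mu <- pmin(pmax(mu_raw, 0), 1)
    clipped <- mean(abs(mu_raw - mu) > clip_warn_tol)
    if (clipped > 0.05) {
      warn(sprintf("group %s: %.1f%% of expected levels clipped by > %.2f",
                   g, 100 * clipped, clip_warn_tol))
    }
    for (i in seq_len(design$n_per_group)) {
      sid <- sprintf("%s_%d", g, i)
      tab <- with_stream_seed(design$seed, paste0("counts/", g, "/", i), {
        total <- stats::rpois(n_cpg, design$coverage_mean)
        meth <- rbetabinom(n_cpg, total, mu, effects$overdispersion)
        tibble(sample_id = sid, group = g,
               chrom = cpgs$chrom, pos = cpgs$pos,
               meth_count = as.integer(meth),
               unmeth_count = as.integer(total - meth))
      })
      sample_tabs[[sid]] <- tab
    }
  }
  out <- bind_rows(sample_tabs)
  out$level <- cpg_level(out$meth_count, out$unmeth_count)
  out
}

# classify each CpG by planted-region membership
cpg_region_class <- function(cpgs, regions) {
  cls <- rep("background", nrow(cpgs))
  if (is.null(regions) || nrow(regions) == 0) return(cls)
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(cpgs$chrom,
                           IRanges::IRanges(cpgs$pos + 1L, cpgs$pos + 1L)),
    GenomicRanges::GRanges(regions$chrom,
                           IRanges::IRanges(regions$start + 1L, regions$end))
  )
  cls[S4Vectors::queryHits(hits)] <- regions$class[S4Vectors::subjectHits(hits)]
  cls
}

#' Parameters for the fasting-refeeding simulation
#'
#' Tissue masses follow state means with multiplicative lognormal noise. The
#' refed mean interpolates between fasted and fed by the elasticity
#' parameter `rho`: `refed = fasted + rho * (fed - fasted)`, so `rho = 1`
#' is full restoration and `rho = 0` none.
#'
#' @param tissues Character vector of tissue (or gene) names.
#' @param fed_mean,fasted_mean Named per-tissue state means (> 0).
#' @param elasticity_rho Named per-genotype restoration fraction in `[0, 1]`,
#'   e.g. `c(WT = 1, Tg = 0.2)`.
#' @param cv Lognormal noise sd on the log scale.
#' @param n_per_state Mice per genotype x state.
#' @param seed Integer seed.
#' @return A `feeding_params` list.
#' @export
feeding_params <- function(tissues = c("gastrocnemius", "liver"),
                           fed_mean = c(gastrocnemius = 130, liver = 1100),
                           fasted_mean = c(gastrocnemius = 105, liver = 700),
                           elasticity_rho = c(WT = 1, Tg = 0.3),
                           cv = 0.05, n_per_state = 8, seed = 1L) {
  fed_mean <- unlist(fed_mean)
  fasted_mean <- unlist(fasted_mean)
  elasticity_rho <- unlist(elasticity_rho)
  stopifnot(all(fed_mean > 0), all(fasted_mean > 0), cv > 0,
            all(elasticity_rho >= 0), all(elasticity_rho <= 1),
            n_per_state >= 1,
            all(tissues %in% names(fed_mean)),
            all(tissues %in% names(fasted_mean)))
  structure(list(tissues = tissues, fed_mean = fed_mean,
                 fasted_mean = fasted_mean, elasticity_rho = elasticity_rho,
                 cv = cv, n_per_state = as.integer(n_per_state),
                 seed = as.integer(seed)),
            class = "feeding_params")
}

#' Simulate a fed/fasted/refed tissue-weight table
#'
#' @param params A [feeding_params()] object.
#' @return A feeding tibble (`mouse_id`, `genotype`, `state`,
#'   `tissue_or_gene`, `value`) with one row per mouse x tissue; each mouse
#'   belongs to exactly one state.
#' @export
simulate_feeding <- function(params) {
  stopifnot(inherits(params, "feeding_params"))
  rows <- list()
  for (gt in names(params$elasticity_rho)) {
    rho <- params$elasticity_rho[[gt]]
    for (tis in params$tissues) {
      mu <- c(fed = params$fed_mean[[tis]],
              fasted = params$fasted_mean[[tis]],
              refed = params$fasted_mean[[tis]] +
                rho * (params$fed_mean[[tis]] - params$fasted_mean[[tis]]))
      for (st in names(mu)) {
        vals <- with_stream_seed(params$seed,
                                 paste0("feeding/", gt, "/", tis, "/", st), {
          mu[[st]] * exp(stats::rnorm(params$n_per_state, 0, params$cv))
        })
        rows[[paste(gt, tis, st)]] <- tibble(
          mouse_id = sprintf("%s_%s_%d", gt, st, seq_len(params$n_per_state)),
          genotype = gt, state = st, tissue_or_gene = tis, value = vals
        )
      }
    }
  }
  validate_feeding_table(bind_rows(rows))
}

#' Simulate a MIAMI two-enzyme probe table
#'
#' MspI log-ratios are pure noise (copy-number proxy); HpaII log-ratios add a
#' class-dependent methylation shift: `+effect_logfc` for hypermethylated
#' probes, `-effect_logfc` for hypomethylated ones. True class labels are
#' retained for recovery tests. Log-ratios are natural logs.
#'
#' @param n_probes Number of probes.
#' @param frac_hyper,frac_hypo Planted class probabilities
#'   (`frac_hyper + frac_hypo <= 1`).
#' @param effect_logfc Methylation shift on the log-ratio scale.
#' @param noise_sd Gaussian noise sd on the log scale.
#' @param seed Integer seed.
#' @return Tibble with `probe_id`, `gene_id`, `true_class`, `hpaii_ratio`,
#'   `mspi_ratio`, `log_hpaii`, `log_mspi`.
#' @export
simulate_miami <- function(n_probes = 10000, frac_hyper = 0.1,
                           frac_hypo = 0.1, effect_logfc = log(2),
                           noise_sd = 0.1, seed = 1L) {
  stopifnot(frac_hyper >= 0, frac_hypo >= 0, frac_hyper + frac_hypo <= 1,
            noise_sd >= 0)
  with_stream_seed(seed, "miami", {
    cls <- sample(c("hypermethylated", "hypomethylated", "unchanged"),
                  n_probes, replace = TRUE,
                  prob = c(frac_hyper, frac_hypo, 1 - frac_hyper - frac_hypo))
    log_mspi <- stats::rnorm(n_probes, 0, noise_sd)
    shift <- ifelse(cls == "hypermethylated", effect_logfc,
                    ifelse(cls == "hypomethylated", -effect_logfc, 0))
    log_hpaii <- log_mspi + shift + stats::rnorm(n_probes, 0, noise_sd)
    tibble(
      probe_id = sprintf("probe_%06d", seq_len(n_probes)),
      gene_id = sprintf("gene_%05d", ceiling(seq_len(n_probes) / 2)),
      true_class = cls,
      hpaii_ratio = exp(log_hpaii), mspi_ratio = exp(log_mspi),
      log_hpaii = log_hpaii, log_mspi = log_mspi
    )
  })
}
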