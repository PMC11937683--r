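pipeline_stage_order <- c("simulate", "methylome", "dmr", "aging", "miami",
                          "elas")

config_defaults <- function() {
  list(
    seed = 1L,
    output_dir = "methelas_run",
    stages = pipeline_stage_order,
    tissue_mode = "gastrocnemius",
    coverage_min = NULL,
    window_size = 100000L,
    design = list(),
    effects = list(),
    dmr = list(),
    feeding = list(),
    miami = list(n_probes = 5000, frac_hyper = 0.1, frac_hypo = 0.1,
                 effect_logfc = log(2), noise_sd = 0.1),
    miami_thresholds = list(low = 0.714, high = 1.3)
  )
}

#' Validate a pipeline configuration
#'
#' Reads (or accepts) a YAML scenario, checks it against the schema, and
#' fills defaults. The `tissue_mode` preset selects the published filter
#' pairs: `"TA"` gives coverage >= 10 reads with DMR filters p < 0.01 and
#' |difference| > 0.20; `"gastrocnemius"` gives coverage >= 5 reads with
#' p < 0.05 and |difference| > 0.10. Any value can still be overridden
#' explicitly.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  defaults <- config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key: %s", unknown[1]))
  }
  cfg <- utils::modifyList(defaults, config)
  cfg$tissue_mode <- match.arg(cfg$tissue_mode, c("gastrocnemius", "TA"))
  if (is.null(cfg$coverage_min)) {
    cfg$coverage_min <- if (cfg$tissue_mode == "TA") 10L else 5L
  }
  if (cfg$coverage_min < 1) abort("coverage_min must be >= 1")
  bad <- setdiff(cfg$stages, pipeline_stage_order)
  if (length(bad) > 0) abort(sprintf("unknown stage: %s", bad[1]))
  ord <- match(cfg$stages, pipeline_stage_order)
  if (is.unsorted(ord, strictly = TRUE)) {
    abort("stages out of dependency order")
  }
  needs <- list(methylome = "simulate", dmr = "simulate", aging = "dmr")
  for (st in names(needs)) {
    if (st %in% cfg$stages && !needs[[st]] %in% cfg$stages) {
      abort(sprintf("stage '%s' requires stage '%s'", st, needs[[st]]))
    }
  }
  dmr_args <- cfg$dmr
  if (!is.null(dmr_args$p_threshold) && dmr_args$p_threshold <= 0) {
    abort("dmr p_threshold must be positive")
  }
  if (is.null(dmr_args$tissue_mode) && is.null(dmr_args$p_threshold)) {
    dmr_args$tissue_mode <- cfg$tissue_mode
  }
  cfg$dmr_params <- do.call(dmr_params, dmr_args)
  cfg$thresholds <- do.call(miami_thresholds, cfg$miami_thresholds)
  cfg$design_obj <- do.call(sim_design,
                            utils::modifyList(cfg$design,
                                              list(seed = cfg$seed)))
  cfg$effects_obj <- do.call(sim_effects, cfg$effects)
  cfg$feeding_obj <- do.call(feeding_params,
                             utils::modifyList(cfg$feeding,
                                               list(seed = cfg$seed)))
  structure(cfg, class = "run_config")
}

samples_of <- function(tables, group) {
  unique(tables$sample_id[tables$group == group])
}

#' Run the configured pipeline end to end
#'
#' Executes the configured stages in order (simulate, methylome, dmr, aging,
#' miami, elas), writes every stage output under `output_dir`, and records a
#' JSON manifest with the seed, per-stage wall-clock, output md5 checksums
#' and status. Deterministic stages are byte-identical across reruns with
#' the same config and seed. A failing stage is recorded in the manifest
#' (written before the error propagates) and stops the run.
#'
#' @param config A `run_config` from [validate_config()] (or a path/list,
#'   validated on the fly).
#' @param output_dir Override for the configured output directory.
#' @return The manifest, invisibly (also written to
#'   `output_dir/manifest.json`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out_dir <- output_dir %||% config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    seed = config$seed,
    tissue_mode = config$tissue_mode,
    package_version = as.character(utils::packageVersion("methelas")),
    config_hash = config_hash(config),
    stages = list()
  )
  state <- new.env(parent = emptyenv())

  finish_stage <- function(name, outputs, t0) {
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = round(as.numeric(proc.time()["elapsed"]) - t0, 3),
      outputs = as.list(tools::md5sum(outputs))
    )
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  for (st in config$stages) {
    t0 <- as.numeric(proc.time()["elapsed"])
    res <- tryCatch({
      outputs <- run_stage(st, config, state, out_dir)
      finish_stage(st, outputs, t0)
      NULL
    }, error = function(e) e)
    if (!is.null(res)) {
      manifest$stages[[st]] <- list(status = "failed",
                                    error = conditionMessage(res))
      write_manifest()
      abort(sprintf("stage '%s' failed: %s", st, conditionMessage(res)))
    }
  }
  write_manifest()
  invisible(structure(manifest, class = "run_manifest"))
}

config_hash <- function(config) {
  plain <- config[setdiff(names(config),
                          c("design_obj", "effects_obj", "feeding_obj",
                            "dmr_params", "thresholds"))]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(plain[order(names(plain))]), tf)
  unname(tools::md5sum(tf))
}

run_stage <- function(st, config, state, out_dir) {
  switch(
    st,
    simulate = {
      state$genome <- simulate_genome(config$design_obj, config$effects_obj)
      state$tables <- simulate_methylomes(state$genome, config$design_obj,
                                          config$effects_obj)
      planted <- file.path(out_dir, "planted_regions.bed")
      readr::write_tsv(state$genome$regions, planted, progress = FALSE)
      genes <- file.path(out_dir, "genes.bed")
      write_gene_bed(state$genome$genes, genes)
      cov_dir <- file.path(out_dir, "coverage")
      dir.create(cov_dir, showWarnings = FALSE)
      cov_files <- purrr::map_chr(
        unique(state$tables$sample_id), function(s) {
          f <- file.path(cov_dir, paste0(s, ".cov"))
          write_cpg_table(state$tables[state$tables$sample_id == s, ], f)
          f
        })
      c(planted, genes, cov_files)
    },
    methylome = {
      state$filtered <- filter_by_coverage(state$tables, config$coverage_min)
      windows <- make_windows(state$genome$layout, config$window_size)
      state$window_matrix <- aggregate_regions(state$filtered, windows)
      mat_f <- file.path(out_dir, "window_methylation.tsv")
      write_methyl_matrix(state$window_matrix, mat_f)
      sum_f <- file.path(out_dir, "global_summary.tsv")
      readr::write_tsv(summarize_global(state$window_matrix), sum_f,
                       progress = FALSE)
      c(mat_f, sum_f)
    },
    dmr = {
      if (is.null(state$filtered)) {
        state$filtered <- filter_by_coverage(state$tables, config$coverage_min)
      }
      state$dmrs <- call_dmrs(state$filtered,
                              samples_of(state$tables, "youngWT"),
                              samples_of(state$tables, "oldWT"),
                              config$dmr_params)
      bed <- file.path(out_dir, "age_dmrs.bed")
      write_dmr_bed(state$dmrs, bed)
      state$dmrg <- annotate_nearest_gene(state$dmrs, state$genome$genes)
      dmrg_f <- file.path(out_dir, "age_dmrg.tsv")
      readr::write_tsv(state$dmrg, dmrg_f, progress = FALSE)
      c(bed, dmrg_f)
    },
    aging = {
      sets <- classify_age_dmrs(state$dmrs)
      sens <- dnmt3a_sensitivity(sets, state$filtered,
                                 samples_of(state$tables, "youngWT"),
                                 samples_of(state$tables, "youngTg"))
      sens_f <- file.path(out_dir, "dnmt3a_sensitivity.json")
      jsonlite::write_json(
        list(delta_hyper = sens$delta_hyper, delta_hypo = sens$delta_hypo,
             p_value = sens$p_value, conclusion = sens$conclusion),
        sens_f, auto_unbox = TRUE, digits = NA)
      rgm <- region_group_matrix(state$dmrs, state$filtered)
      z_f <- file.path(out_dir, "dmr_zscores.tsv")
      write_methyl_matrix(rgm$zscores, z_f)
      c(sens_f, z_f)
    },
    miami = {
      probes <- do.call(simulate_miami,
                        utils::modifyList(config$miami,
                                          list(seed = config$seed)))
      classified <- classify_probes(probes, config$thresholds)
      cls_f <- file.path(out_dir, "miami_classified.tsv")
      write_miami_table(classified, cls_f)
      summ <- miami_summary(classified)
      sum_f <- file.path(out_dir, "miami_summary.json")
      jsonlite::write_json(
        list(counts = as.list(summ$counts),
             n_hyper_genes = length(summ$hyper_genes)),
        sum_f, auto_unbox = TRUE, digits = NA)
      c(cls_f, sum_f)
    },
    elas = {
      feeding <- simulate_feeding(config$feeding_obj)
      feed_f <- file.path(out_dir, "feeding_table.tsv")
      write_feeding_table(feeding, feed_f)
      fit <- elas_table(feeding)
      scores_f <- file.path(out_dir, "elas_scores.tsv")
      readr::write_tsv(fit$scores, scores_f, progress = FALSE)
      summary_f <- file.path(out_dir, "elas_summary.tsv")
      readr::write_tsv(left_join(fit$summary, fit$comparison, by = "tissue"),
                       summary_f, progress = FALSE)
      c(feed_f, scores_f, summary_f)
    },
    abort(sprintf("unknown stage: %s", st))
  )
}
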