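#' Run the full demographic-inference pipeline from one configuration
#'
#' Orchestrates the two-phase analysis: filter genotypes, build joint
#' spectra, fit the competing base (4-population) scenarios, select the
#' decisive base model, fit the extended (6-population) scenarios, select
#' again, and optionally compute block-bootstrap confidence intervals for
#' the winning model.  Completed stages are cached in the output directory
#' and skipped on rerun; a master seed deterministically derives each
#' stage's seed, and every stage is logged with its seed in the run
#' report.
#'
#' @param config configuration list, or path to a YAML file with the same
#'   structure.  Recognized fields: `out_dir`; `seed`; `fixture` (list
#'   with `scale`, for synthetic input) or `input` (list with `vcf` and
#'   optional `pop_map` TSV of sample/population); `filter` (list:
#'   `hwe_alpha`, `cpg_bed`, `coding_bed`); `fit` (list understood by
#'   [fit_config()]); `scenarios_base`, `scenarios_ext` (character
#'   vectors); `selection_threshold`; `bootstrap` (list: `n_boot`,
#'   `runs_per_boot`, `span_bp`) or `NULL` to skip.
#' @return a run report (list): per-stage status with seeds, selected
#'   models, and the parameter table of the final model; written to
#'   `out_dir/report.json` along with TSV parameter tables.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out <- cfg$out_dir %||% abort("config needs out_dir")
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  seed <- cfg$seed %||% 1
  stages_dir <- file.path(out, "stages")
  if (!dir.exists(stages_dir)) dir.create(stages_dir)
  report <- list(seed = seed, stages = list())
  stage <- function(name, f) {
    cache <- file.path(stages_dir, paste0(name, ".rds"))
    st_seed <- derive_seed(seed, nchar(name), sum(utf8ToInt(name)))
    if (file.exists(cache)) {
      report$stages[[name]] <<- list(status = "cached", seed = st_seed)
      return(readRDS(cache))
    }
    val <- f(st_seed)
    saveRDS(val, cache)
    report$stages[[name]] <<- list(status = "done", seed = st_seed)
    val
  }
  fitcfg <- do.call(fit_config, c(cfg$fit %||% list(
    n_sims = 1e4, n_ecm_cycles = 20, n_cycles_with_monomorphic = 8,
    n_replicates = 10), list(seed = derive_seed(seed, 2))))

  # stage 1: input genotypes
  gset <- stage("input", function(s) {
    if (!is.null(cfg$input)) {
      pm <- NULL
      if (!is.null(cfg$input$pop_map)) {
        tb <- readr::read_tsv(cfg$input$pop_map, col_names = c("sample", "pop"),
                              show_col_types = FALSE)
        pm <- setNames(tb$pop, tb$sample)
      }
      g <- read_genotypes(cfg$input$vcf, "vcf", pop_map = pm)
      list(g6 = g, g4 = NULL)
    } else {
      fx <- make_sfs_study_fixture(cfg$fixture$scale %||% "mini", seed = s)
      fx[c("g6", "g4")]
    }
  })

  # stage 2: SFS site filters
  filt <- stage("filter", function(s) {
    fl <- cfg$filter %||% list()
    lapply(gset[!vapply(gset, is.null, TRUE)], function(g)
      apply_sfs_filters(g, hwe_alpha = fl$hwe_alpha %||% 1e-4,
                        cpg_mask = if (!is.null(fl$cpg_bed)) read_bed(fl$cpg_bed),
                        coding_mask = if (!is.null(fl$coding_bed)) read_bed(fl$coding_bed)))
  })

  fit_tier <- function(g, scen_names, tier, s) {
    pops <- unique(g$samples$pop)
    fits <- list()
    for (nm in scen_names) {
      scn <- scenario_library(nm)
      keep <- intersect(scn$model$populations$name, pops)
      if (length(keep) < nrow(scn$model$populations))
        abort(paste0("scenario ", nm, " needs populations absent from data"))
      dip <- table(g$samples$pop)[scn$model$populations$name]
      panel <- population_panel(scn$model$populations$name, 2L * as.integer(dip))
      obs <- mask_low_count_entries(build_joint_sfs(g, panel), fitcfg$min_count)
      fc <- fitcfg; fc$seed <- derive_seed(s, match(nm, scen_names))
      fit <- ecm_optimize(obs, scn$model, scn$space, fc,
                          constraints = scn$constraints)
      fits[[nm]] <- reestimate_likelihood(fit)
    }
    fits
  }

  sel_thr <- cfg$selection_threshold %||% 50

  base_names <- cfg$scenarios_base %||%
    c("base_common_origin", "base_early_split", "base_hybrid_origin")
  base_fits <- NULL
  base_sel <- NULL
  if (!is.null(filt$g4) && length(base_names) >= 2) {
    base_fits <- stage("fit_base", function(s)
      fit_tier(filt$g4, base_names, "base", s))
    base_sel <- stage("select_base", function(s)
      select_model(base_fits, threshold = sel_thr))
    report$base_selection <- list(best = base_sel$best,
                                  decisive = base_sel$decisive)
  }

  ext_names <- cfg$scenarios_ext %||%
    c("ext_tb_with_tibetan", "ext_tb_with_han", "ext_tb_with_muli")
  ext_fits <- stage("fit_ext", function(s)
    fit_tier(filt$g6, ext_names, "ext", s))
  ext_sel <- stage("select_ext", function(s)
    select_model(ext_fits, threshold = sel_thr))
  report$ext_selection <- list(best = ext_sel$best, decisive = ext_sel$decisive)

  best_fit <- ext_fits[[ext_sel$best]]
  params <- tidy(best_fit, kya = TRUE)
  readr::write_tsv(params, file.path(out, "parameters.tsv"))

  if (!is.null(cfg$bootstrap)) {
    ci <- stage("bootstrap_ci", function(s) {
      bs <- cfg$bootstrap
      scn <- scenario_library(ext_sel$best)
      blocks <- make_blocks(filt$g6, span_bp = bs$span_bp %||% 1e6)
      boot <- bootstrap_sfs(filt$g6, best_fit$panel, blocks,
                            n_boot = bs$n_boot %||% 100, seed = s)
      fc <- fitcfg; fc$seed <- s
      bootstrap_ci(boot, scn$model, scn$space, fc,
                   constraints = scn$constraints,
                   runs_per_boot = bs$runs_per_boot %||% 20)
    })
    report$ci <- ci$ci
    readr::write_tsv(ci$ci, file.path(out, "bootstrap_ci.tsv"))
  }

  report$parameters <- params
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
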