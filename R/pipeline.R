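#' Pipeline configuration
#'
#' Assembles the end-to-end run configuration. Either a simulation block
#' (arguments for [simulation_config()]) or explicit input paths (`matrix`,
#' `samples`, `panel`, optionally `exclusions` BED paths and `icrs`
#' definitions) must be given. Can also be loaded from a YAML file whose top
#' level mirrors these arguments.
#'
#' @param simulate list of [simulation_config()] arguments, or `NULL`.
#' @param paths list with `matrix`, `samples`, `panel`, optionally
#'   `exclusions` (character vector of BED paths) and `icrs` (TSV path).
#' @param filter list of [filter_config()] arguments.
#' @param designs named list; each element a list of [design_spec()]
#'   arguments. The default battery mirrors the study: combined (sex +
#'   cells), male-only and female-only (cells).
#' @param dmr_gap DMR merge distance (bp).
#' @param q_threshold DMC significance threshold.
#' @param pi0_mode q-value null-proportion mode.
#' @param outlier list: `method`, `alpha` for [detect_outliers_amoc()].
#' @param min_frac deconvolution panel-coverage threshold.
#' @param seed integer seed for the simulation block.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(simulate = list(), paths = NULL,
                            filter = list(),
                            designs = NULL,
                            dmr_gap = 250L, q_threshold = 0.05,
                            pi0_mode = "smoother",
                            outlier = list(method = "calibrated", alpha = 0.02),
                            min_frac = 0.9, seed = 1L, out_dir = NULL) {
  if (is.null(designs))
    designs <- list(
      combined = list(covariates = c("sex", "cells"), subset = "all"),
      male = list(covariates = "cells", subset = "males"),
      female = list(covariates = "cells", subset = "females"))
  structure(list(simulate = simulate, paths = paths, filter = filter,
                 designs = designs, dmr_gap = dmr_gap,
                 q_threshold = q_threshold, pi0_mode = pi0_mode,
                 outlier = outlier, min_frac = min_frac,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes the published stage order on simulated or file-based inputs:
#' site exclusions and coverage filtering, cell-type deconvolution, the
#' configured battery of DMC analyses, DMR merging, PC1-gap outlier
#' detection (all complete-case sites) with group/sex enrichment, ICR
#' summaries and direction tallies, and the cohort demographic table. A
#' manifest records parameters, seeds and per-stage record counts. Reruns
#' with the same configuration are bit-identical.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @return A result bundle (list) with elements `inputs`, `filtered`,
#'   `proportions`, `dmc`, `dmr`, `outliers`, `icr`, `cohort`, `truth`
#'   (when simulated), `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  manifest <- list(package = "methcapdm",
                   version = as.character(packageVersion("methcapdm")),
                   seed = config$seed, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  # --- inputs ------------------------------------------------------------
  truth <- NULL
  exclusions <- list()
  icrs <- NULL
  if (!is.null(config$paths)) {
    mm <- read_methylome_matrix(config$paths$matrix)
    sheet <- read_sample_sheet(config$paths$samples)
    panel <- read_reference_panel(config$paths$panel)
    if (!is.null(config$paths$exclusions))
      exclusions <- lapply(config$paths$exclusions, read_bed)
    if (!is.null(config$paths$icrs))
      icrs <- read_icr_definitions(config$paths$icrs)
  } else {
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    sim <- simulate_cohort(do.call(simulation_config, sim_args))
    mm <- sim$matrix; sheet <- sim$samples; panel <- sim$panel
    truth <- sim$truth
    icrs <- sim$truth$icr_regions
  }
  note("input", n_sites = nrow(mm$M), n_samples = ncol(mm$M))

  # --- filtering funnel ---------------------------------------------------
  n0 <- nrow(mm$M)
  mm <- apply_site_exclusions(mm, exclusions)
  n1 <- nrow(mm$M)
  fcfg <- do.call(filter_config, config$filter)
  mm <- apply_coverage_filter(mm, fcfg)
  note("filter", after_exclusions = n1, after_coverage = nrow(mm$M),
       removed_exclusions = n0 - n1,
       min_cov = fcfg$min_cov, max_cov = fcfg$max_cov,
       min_samples = fcfg$min_samples)

  # --- cell deconvolution -------------------------------------------------
  props <- deconvolve_cells(mm, panel, min_frac = config$min_frac)
  sheet2 <- merge(sheet, props[c("sample_id", panel$cell_types)],
                  by = "sample_id", sort = FALSE)
  sheet2 <- sheet2[match(sheet$sample_id, sheet2$sample_id), , drop = FALSE]
  note("deconvolution", n_panel_cpgs = nrow(panel$cpgs),
       n_samples = nrow(props))

  # --- differential methylation -------------------------------------------
  dmc <- lapply(config$designs, function(dargs) {
    call_dmcs(mm, sheet2, do.call(design_spec, dargs),
              q_threshold = config$q_threshold, pi0_mode = config$pi0_mode)
  })
  note("dmc", counts = lapply(dmc, function(d) d$summary$n_dmcs))

  # --- region merging -----------------------------------------------------
  dmr <- lapply(dmc, function(d) merge_dmrs(d$dmcs, gap = config$dmr_gap))
  note("dmr", counts = lapply(dmr, function(d) d$summary$n_dmrs))

  # --- outlier detection --------------------------------------------------
  cc <- complete_case_sites(mm)
  outliers <- NULL
  if (length(cc) >= 2) {
    pca <- pca_scores(beta_values(subset_sites(mm, cc)))
    rep_o <- detect_outliers_amoc(pca$scores[, 1],
                                  sample_ids = rownames(pca$scores),
                                  method = config$outlier$method,
                                  alpha = config$outlier$alpha)
    outliers <- list(
      report = rep_o, n_complete_sites = length(cc),
      enrichment_group = outlier_enrichment(rep_o$outlier_ids, sheet2, "group"),
      enrichment_sex = outlier_enrichment(rep_o$outlier_ids, sheet2, "sex"))
  }
  note("outliers", n_complete_sites = length(cc),
       n_outliers = if (is.null(outliers)) NA_integer_
       else length(outliers$report$outlier_ids))

  # --- imprinting control regions ------------------------------------------
  icr <- NULL
  if (!is.null(icrs) && nrow(icrs) > 0) {
    tal <- icr_direction_tally(mm, icrs, sheet2)
    anovas <- lapply(seq_len(nrow(icrs)), function(i) {
      s <- summarize_icr(mm, icrs[i, ], sheet2)
      if (s$empty || s$n_cpgs_captured < 2) return(NULL)
      c(list(name = s$name), icr_anova(s))
    })
    icr <- list(tally = tal, anovas = Filter(Negate(is.null), anovas))
  }
  note("icr", n_icrs = if (is.null(icrs)) 0L else nrow(icrs))

  # --- cohort statistics ---------------------------------------------------
  cat_vars <- intersect(c("sex", "complications"), names(sheet))
  cohort <- cohort_table(sheet, categorical_vars = cat_vars)
  note("cohort", n_rows = nrow(cohort))

  structure(list(inputs = list(samples = sheet, panel = panel),
                 filtered = mm, proportions = props, samples = sheet2,
                 dmc = dmc, dmr = dmr, outliers = outliers, icr = icr,
                 cohort = cohort, truth = truth, manifest = manifest,
                 config = config), class = "pipeline_result")
}

#' Summarize a pipeline result bundle as tables
#'
#' Emits the study's figure-shaped summaries as plain data.frames: per-design
#' hypo/hyper DMC counts and |difference| bins, DMR counts and sizes,
#' pairwise DMC-set overlap and direction concordance between designs,
#' the outlier decision, the per-ICR direction table, and the cohort table.
#'
#' @param bundle a `pipeline_result` from [run_pipeline()].
#' @return list of data.frames / lists; missing stages yield `NULL` entries.
#' @export
make_report <- function(bundle) {
  dmc_tab <- do.call(rbind, lapply(names(bundle$dmc), function(nm) {
    s <- bundle$dmc[[nm]]$summary
    data.frame(design = nm, n_tested = s$n_tested, n_dmcs = s$n_dmcs,
               n_hypo = s$n_hypo, n_hyper = s$n_hyper,
               bin_lt10 = s$diff_bins[1], bin_10_20 = s$diff_bins[2],
               bin_gt20 = s$diff_bins[3], pi0 = s$pi0,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  dmr_tab <- do.call(rbind, lapply(names(bundle$dmr), function(nm) {
    s <- bundle$dmr[[nm]]$summary
    data.frame(design = nm, n_dmrs = s$n_dmrs, n_singletons = s$n_singletons,
               n_dmcs_in_dmrs = s$n_dmcs_in_dmrs,
               mean_size_bp = s$mean_size_bp, stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  pairs <- utils::combn(names(bundle$dmc), 2, simplify = FALSE)
  overlap_tab <- do.call(rbind, lapply(pairs, function(pr) {
    ov <- compare_dmc_sets(bundle$dmc[[pr[1]]], bundle$dmc[[pr[2]]])
    data.frame(a = pr[1], b = pr[2], n_a = ov$n_a, n_b = ov$n_b,
               n_shared = ov$n_shared, n_same_direction = ov$n_same_direction,
               n_opposite_direction = ov$n_opposite_direction,
               n_similar_magnitude = ov$n_similar_magnitude,
               stringsAsFactors = FALSE)
  }))
  outlier_sum <- if (is.null(bundle$outliers)) NULL else list(
    outlier_ids = bundle$outliers$report$outlier_ids,
    side = bundle$outliers$report$side,
    p_group = bundle$outliers$enrichment_group$p,
    p_sex = bundle$outliers$enrichment_sex$p)
  icr_tab <- if (is.null(bundle$icr)) NULL else bundle$icr$tally$per_icr
  list(dmc = dmc_tab, dmr = dmr_tab, overlaps = overlap_tab,
       outliers = outlier_sum, icr = icr_tab, cohort = bundle$cohort,
       manifest = bundle$manifest)
}

#' Write a pipeline result bundle to disk
#'
#' Writes per-design full results and DMC tables (TSV), DMR tables (TSV),
#' estimated proportions (CSV), the outlier report and manifest (JSON), and
#' the cohort table (TSV) under `dir`.
#'
#' @param bundle a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle$dmc)) {
    data.table::fwrite(bundle$dmc[[nm]]$results,
                       file.path(dir, paste0("results_", nm, ".tsv")),
                       sep = "\t", na = "NA")
    data.table::fwrite(bundle$dmc[[nm]]$dmcs,
                       file.path(dir, paste0("dmcs_", nm, ".tsv")),
                       sep = "\t", na = "NA")
    data.table::fwrite(bundle$dmr[[nm]]$dmrs,
                       file.path(dir, paste0("dmrs_", nm, ".tsv")),
                       sep = "\t", na = "NA")
  }
  data.table::fwrite(bundle$proportions, file.path(dir, "proportions.csv"))
  data.table::fwrite(bundle$cohort, file.path(dir, "cohort_table.tsv"),
                     sep = "\t")
  if (!is.null(bundle$outliers))
    jsonlite::write_json(
      list(outlier_ids = bundle$outliers$report$outlier_ids,
           side = bundle$outliers$report$side,
           changepoint = bundle$outliers$report$changepoint,
           stat = bundle$outliers$report$stat,
           penalty = bundle$outliers$report$penalty_used,
           gaps = bundle$outliers$report$gaps),
      file.path(dir, "outliers.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
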