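#' Synthetic cord-blood methylome cohort: configuration
#'
#' Defines the generative conditions for a two-group capture-bisulfite cohort:
#' sample sizes and sex ratio, a cell-type mixture model with a marker-CpG
#' reference panel, a discretized log-normal coverage law clipped to
#' `[coverage_floor, coverage_cap]` so both tails of the 15x/500x filter are
#' exercised, beta-binomial overdispersion, completely-at-random missingness,
#' planted group effects on the logit scale with sex scopes, ~50%-methylated
#' imprinted blocks with group-by-sex shifts, and globally shifted outlier
#' samples.
#'
#' @param n_control,n_case group sizes (defaults 36 and 37, the study design).
#' @param sex_ratio fraction of males per group.
#' @param n_cpgs number of simulated CpG sites.
#' @param n_cell_types number of cell types (default 7: B cells, CD4+ T,
#'   CD8+ T, granulocytes, monocytes, NK cells, nucleated red blood cells).
#' @param dirichlet_alpha Dirichlet concentration per cell type; the default
#'   is granulocyte-dominant, emulating cord blood composition.
#' @param markers_per_type marker CpGs per cell type in the reference panel.
#' @param marker_margin minimum methylation separation between a cell type and
#'   all others at its marker CpGs (must be in (0, 0.85]).
#' @param coverage_meanlog,coverage_sdlog log-normal coverage parameters.
#' @param coverage_floor,coverage_cap total-read clip bounds.
#' @param missing_rate completely-at-random missing-cell fraction.
#' @param dispersion_rho beta-binomial intra-class correlation in \[0, 1);
#'   0 recovers exact binomial counts (the analysis model).
#' @param planted_effects data.frame with columns `site` (1-based index into
#'   the simulated site grid), `effect` (logit-scale case shift) and `scope`
#'   (one of `"both"`, `"male_only"`, `"female_only"`, `"opposite"`;
#'   `"opposite"` applies `+effect` in case males and `-effect` in case
#'   females).
#' @param icr_blocks data.frame with columns `name`, `n_sites`, `shift`
#'   (logit), `scope` describing imprinted blocks at baseline beta 0.5.
#' @param n_outliers number of globally shifted outlier samples (at most 10%
#'   of the cohort).
#' @param outlier_shift logit-scale global shift applied to outlier samples.
#' @param outlier_site_frac fraction of sites affected in each outlier.
#' @param complication_rate per-sample probability of a pregnancy
#'   complication flag.
#' @param n_invivo number of case samples labelled as the less invasive
#'   (in vivo) subgroup; the rest are in vitro.
#' @param seed integer seed; all generator randomness derives from it.
#' @return A validated `SimulationConfig` list.
#' @export
simulation_config <- function(n_control = 36L, n_case = 37L, sex_ratio = 0.5,
                              n_cpgs = 20000L, n_cell_types = 7L,
                              dirichlet_alpha = NULL,
                              markers_per_type = 50L, marker_margin = 0.5,
                              coverage_meanlog = log(80), coverage_sdlog = 0.55,
                              coverage_floor = 1L, coverage_cap = 600L,
                              missing_rate = 0.01, dispersion_rho = 0.01,
                              planted_effects = NULL, icr_blocks = NULL,
                              n_outliers = 0L, outlier_shift = -2,
                              outlier_site_frac = 0.5,
                              complication_rate = 0.3, n_invivo = NULL,
                              seed = 1L) {
  if (is.null(dirichlet_alpha)) {
    base <- c(Bcell = 2.5, CD4T = 7, CD8T = 5, Gran = 25, Mono = 3.5,
              NK = 2.5, nRBC = 4.5)
    dirichlet_alpha <- if (n_cell_types == 7L) base
      else setNames(rep(5, n_cell_types), paste0("CT", seq_len(n_cell_types)))
  }
  if (is.null(planted_effects))
    planted_effects <- data.frame(site = integer(), effect = numeric(),
                                  scope = character())
  if (is.null(icr_blocks))
    icr_blocks <- data.frame(
      name = c("ICR1", "ICR2", "ICR3"), n_sites = c(30L, 30L, 30L),
      shift = c(-0.2, -0.15, 0.2),
      scope = c("female_only", "both", "opposite"))
  if (is.null(n_invivo)) n_invivo <- round(n_case * 17 / 37)
  cfg <- list(n_control = as.integer(n_control), n_case = as.integer(n_case),
              sex_ratio = sex_ratio, n_cpgs = as.integer(n_cpgs),
              n_cell_types = as.integer(n_cell_types),
              dirichlet_alpha = dirichlet_alpha,
              markers_per_type = as.integer(markers_per_type),
              marker_margin = marker_margin,
              coverage_meanlog = coverage_meanlog,
              coverage_sdlog = coverage_sdlog,
              coverage_floor = as.integer(coverage_floor),
              coverage_cap = as.integer(coverage_cap),
              missing_rate = missing_rate, dispersion_rho = dispersion_rho,
              planted_effects = planted_effects, icr_blocks = icr_blocks,
              n_outliers = as.integer(n_outliers), outlier_shift = outlier_shift,
              outlier_site_frac = outlier_site_frac,
              complication_rate = complication_rate,
              n_invivo = as.integer(n_invivo), seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_control >= 1, cfg$n_case >= 1, cfg$n_cpgs >= 1,
            cfg$n_cell_types >= 2,
            length(cfg$dirichlet_alpha) == cfg$n_cell_types,
            all(cfg$dirichlet_alpha > 0),
            cfg$sex_ratio >= 0, cfg$sex_ratio <= 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$dispersion_rho >= 0, cfg$dispersion_rho < 1,
            cfg$coverage_floor >= 1, cfg$coverage_cap >= cfg$coverage_floor,
            all(is.finite(cfg$planted_effects$effect)),
            all(cfg$planted_effects$site >= 1),
            all(cfg$planted_effects$site <= cfg$n_cpgs),
            all(cfg$planted_effects$scope %in%
                  c("both", "male_only", "female_only", "opposite")),
            cfg$n_invivo >= 0, cfg$n_invivo <= cfg$n_case)
  n <- cfg$n_control + cfg$n_case
  if (cfg$n_outliers > 0.1 * n)
    stop("n_outliers exceeds 10% of the cohort")
  invisible(cfg)
}

# Deterministic CpG coordinate grid. Autosomal sites on chr1..chr22 with a
# repeating spacing pattern (some gaps <= 250 bp so region merging is
# exercised), plus small chrX/chrY blocks so the sex-chromosome filter has
# work to do. Pure function of n_cpgs; shared by panel and cohort.
site_grid <- function(n_cpgs) {
  n_x <- max(0L, round(0.03 * n_cpgs))
  n_y <- max(0L, round(0.01 * n_cpgs))
  n_auto <- n_cpgs - n_x - n_y
  gaps <- c(80L, 150L, 40L, 300L, 120L, 2000L, 60L, 90L, 500L, 35L)
  per_chrom <- ceiling(n_auto / 22)
  chroms <- rep(paste0("chr", 1:22), each = per_chrom)[seq_len(n_auto)]
  pos <- 10000L + cumsum(gaps[(seq_len(n_auto) - 1L) %% length(gaps) + 1L])
  pos <- pos - ave(pos, chroms, FUN = min) + 10000L
  grid <- data.frame(chrom = chroms, pos = as.integer(pos),
                     stringsAsFactors = FALSE)
  sex <- data.frame(
    chrom = c(rep("chrX", n_x), rep("chrY", n_y)),
    pos = c(10000L + 200L * seq_len(n_x), 10000L + 200L * seq_len(n_y)),
    stringsAsFactors = FALSE)
  grid <- rbind(grid, sex)
  grid <- grid[site_order(grid$chrom, grid$pos), , drop = FALSE]
  rownames(grid) <- NULL
  grid$index <- seq_len(nrow(grid))
  grid
}

cell_type_names <- function(cfg) {
  nm <- names(cfg$dirichlet_alpha)
  if (is.null(nm) || any(nm == "")) paste0("CT", seq_len(cfg$n_cell_types)) else nm
}

# deterministic layout of marker / imprinted-block site indices on the grid
grid_layout <- function(cfg) {
  grid <- site_grid(cfg$n_cpgs)
  auto <- grid$index[!is_sex_chrom(grid$chrom)]
  n_mark <- cfg$n_cell_types * cfg$markers_per_type
  n_icr <- sum(cfg$icr_blocks$n_sites)
  if (n_mark + n_icr > floor(0.6 * length(auto)))
    stop("n_cpgs too small for the requested panel and imprinted blocks")
  marker_idx <- auto[round(seq(1, floor(0.3 * length(auto)), length.out = n_mark))]
  icr_start <- floor(0.55 * length(auto))
  icr_idx <- vector("list", nrow(cfg$icr_blocks))
  at <- icr_start
  auto_chrom <- grid$chrom[auto]
  for (b in seq_len(nrow(cfg$icr_blocks))) {
    nb <- cfg$icr_blocks$n_sites[b]
    # a block must sit inside one chromosome
    while (at + nb <= length(auto) &&
           auto_chrom[at + 1L] != auto_chrom[at + nb]) at <- at + 1L
    if (at + nb > length(auto))
      stop("n_cpgs too small to place the imprinted blocks")
    icr_idx[[b]] <- auto[at + seq_len(nb)]
    at <- at + nb + 50L
  }
  list(grid = grid, marker_idx = marker_idx, icr_idx = icr_idx)
}

#' Simulate a cell-type reference panel
#'
#' Builds a marker-CpG methylation-fraction panel: for each cell type,
#' `markers_per_type` CpGs at which that cell type's methylation is separated
#' from every other cell type by at least `marker_margin` (alternating hyper-
#' and hypomethylated markers). Marker CpGs are a subset of the simulated
#' site grid, so a cohort generated from the same configuration captures them.
#'
#' @param config a [simulation_config()].
#' @return A `ReferencePanel`: list with `cpgs` (data.frame `chrom`, `pos`),
#'   `cell_types`, and `profile` (marker x cell-type fraction matrix).
#' @export
simulate_reference_panel <- function(config) {
  m <- config$marker_margin
  if (m <= 0 || m > 0.85)
    stop("marker_margin infeasible: must be in (0, 0.85] so that target and ",
         "background fraction ranges fit inside [0, 1]")
  lay <- grid_layout(config)
  k <- config$n_cell_types
  npm <- config$markers_per_type
  ct <- cell_type_names(config)
  prof <- with_local_seed(derive_seed(config$seed, "panel"), {
    P <- matrix(0, nrow = k * npm, ncol = k)
    for (j in seq_len(k)) {
      rows <- (j - 1L) * npm + seq_len(npm)
      hyper <- rep(c(TRUE, FALSE), length.out = npm)
      tgt <- ifelse(hyper, runif(npm, 0.85, 1), runif(npm, 0, 0.15))
      P[rows, j] <- tgt
      for (o in setdiff(seq_len(k), j)) {
        P[rows, o] <- ifelse(hyper, runif(npm, 0, 0.85 - m),
                             runif(npm, 0.15 + m, 1))
      }
    }
    P
  })
  colnames(prof) <- ct
  cpgs <- lay$grid[lay$marker_idx, c("chrom", "pos")]
  rownames(cpgs) <- NULL
  structure(list(cpgs = cpgs, cell_types = ct, profile = prof,
                 marker_index = lay$marker_idx),
            class = "ReferencePanel")
}

#' Simulate a methylome cohort with ground truth
#'
#' Generates a [methylome_matrix()] plus sample sheet and truth set under the
#' configured conditions: per-sample cell proportions drawn from the Dirichlet
#' law; per-site expected betas formed as cell-type mixtures at marker CpGs, a
#' bimodal baseline elsewhere, and 0.5 inside imprinted blocks; planted
#' effects and block shifts applied on the logit scale to case samples
#' according to sex scope; totals from the clipped log-normal coverage law;
#' methylated counts beta-binomial with intra-class correlation
#' `dispersion_rho`; cells masked completely at random; outlier samples
#' globally shifted at a random site subset.
#'
#' @param config a [simulation_config()].
#' @param panel optionally, a panel from [simulate_reference_panel()] built
#'   from the same configuration (generated internally when omitted).
#' @return list with elements `matrix` (`MethylomeMatrix`), `samples`
#'   (sample sheet data.frame), `truth` (`TruthSet` list: `true_dmc_sites`,
#'   `true_proportions`, `true_outlier_ids`, `true_icr_shifts`, `icr_regions`),
#'   and `panel`.
#' @export
simulate_cohort <- function(config, panel = NULL) {
  validate_simulation_config(config)
  if (is.null(panel)) panel <- simulate_reference_panel(config)
  lay <- grid_layout(config)
  grid <- lay$grid
  if (!identical(panel$cpgs$pos, grid$pos[lay$marker_idx]))
    stop("panel CpGs are not a subset of the simulated site grid; ",
         "generate panel and cohort from the same configuration")
  n_sites <- nrow(grid)
  n <- config$n_control + config$n_case
  ct <- cell_type_names(config)

  sheet <- local({
    n_m_ctrl <- round(config$n_control * config$sex_ratio)
    n_m_case <- round(config$n_case * config$sex_ratio)
    data.frame(
      sample_id = c(sprintf("CTRL%02d", seq_len(config$n_control)),
                    sprintf("ART%02d", seq_len(config$n_case))),
      group = rep(c("control", "case"), c(config$n_control, config$n_case)),
      subgroup = c(rep("none", config$n_control),
                   rep(c("in_vivo", "in_vitro"),
                       c(config$n_invivo, config$n_case - config$n_invivo))),
      sex = c(rep(c("M", "F"), c(n_m_ctrl, config$n_control - n_m_ctrl)),
              rep(c("M", "F"), c(n_m_case, config$n_case - n_m_case))),
      stringsAsFactors = FALSE)
  })

  out <- with_local_seed(derive_seed(config$seed, "cohort"), {
    sheet$complications <- rbinom(n, 1, config$complication_rate) == 1

    # per-sample cell proportions
    W <- matrix(rgamma(n * config$n_cell_types,
                       shape = rep(config$dirichlet_alpha, each = n)),
                nrow = n)
    W <- W / rowSums(W)
    colnames(W) <- ct; rownames(W) <- sheet$sample_id

    # baseline betas: bimodal genome background
    u <- runif(n_sites)
    b0 <- ifelse(u < 0.35, rbeta(n_sites, 1, 8),
                 ifelse(u < 0.70, rbeta(n_sites, 8, 1), rbeta(n_sites, 2, 2)))
    # planted-effect sites get mid-range baselines so a logit-scale effect
    # maps to an appreciable beta difference (emulating detectable DMCs)
    if (nrow(config$planted_effects) > 0)
      b0[config$planted_effects$site] <-
        rbeta(nrow(config$planted_effects), 6, 6)
    mu <- matrix(b0, n_sites, n)
    mu[lay$marker_idx, ] <- panel$profile %*% t(W)
    for (b in seq_along(lay$icr_idx)) mu[lay$icr_idx[[b]], ] <- 0.5

    eps <- 1e-6
    eta <- logit(pmin(pmax(mu, eps), 1 - eps))
    case <- sheet$group == "case"
    male <- sheet$sex == "M"
    scope_cols <- function(scope) switch(scope,
      both = case, male_only = case & male, female_only = case & !male,
      opposite = case)
    add_effect <- function(eta, rows, delta, scope) {
      cols <- scope_cols(scope)
      if (scope == "opposite") {
        eta[rows, case & male] <- eta[rows, case & male, drop = FALSE] + delta
        eta[rows, case & !male] <- eta[rows, case & !male, drop = FALSE] - delta
      } else {
        eta[rows, cols] <- eta[rows, cols, drop = FALSE] + delta
      }
      eta
    }
    pe <- config$planted_effects
    for (i in seq_len(nrow(pe)))
      eta <- add_effect(eta, pe$site[i], pe$effect[i], pe$scope[i])
    for (b in seq_len(nrow(config$icr_blocks)))
      eta <- add_effect(eta, lay$icr_idx[[b]], config$icr_blocks$shift[b],
                        config$icr_blocks$scope[b])

    outlier_ids <- character(0)
    if (config$n_outliers > 0) {
      outlier_ids <- sort(sample(sheet$sample_id, config$n_outliers))
      shift_sites <- sample.int(n_sites, round(config$outlier_site_frac * n_sites))
      for (sid in outlier_ids) {
        j <- match(sid, sheet$sample_id)
        eta[shift_sites, j] <- eta[shift_sites, j] + config$outlier_shift
      }
    }
    mu <- inv_logit(eta)

    Tt <- matrix(pmin(pmax(round(rlnorm(n_sites * n, config$coverage_meanlog,
                                        config$coverage_sdlog)),
                           config$coverage_floor), config$coverage_cap),
                 n_sites, n)
    mu_c <- pmin(pmax(mu, eps), 1 - eps)
    p <- if (config$dispersion_rho > 0) {
      s <- (1 - config$dispersion_rho) / config$dispersion_rho
      matrix(rbeta(n_sites * n, mu_c * s, (1 - mu_c) * s), n_sites, n)
    } else mu_c
    M <- matrix(rbinom(n_sites * n, as.integer(Tt), p), n_sites, n)
    if (config$missing_rate > 0) {
      miss <- matrix(runif(n_sites * n) < config$missing_rate, n_sites, n)
      M[miss] <- NA; Tt[miss] <- NA
    }
    list(M = M, Tt = Tt, W = W, sheet = sheet, outlier_ids = outlier_ids)
  })

  mm <- methylome_matrix(grid$chrom, grid$pos, out$M, out$Tt, out$sheet$sample_id)

  pe <- config$planted_effects
  eff_m <- ifelse(pe$scope %in% c("both", "male_only", "opposite"),
                  pe$effect, 0)
  eff_m[pe$scope == "female_only"] <- 0
  eff_f <- ifelse(pe$scope %in% c("both", "female_only"), pe$effect, 0)
  eff_f[pe$scope == "opposite"] <- -pe$effect[pe$scope == "opposite"]
  true_dmc <- data.frame(site = pe$site, chrom = grid$chrom[pe$site],
                         pos = grid$pos[pe$site], effect = pe$effect,
                         scope = pe$scope, effect_male = eff_m,
                         effect_female = eff_f, stringsAsFactors = FALSE)

  icr_regions <- do.call(rbind, lapply(seq_along(lay$icr_idx), function(b) {
    idx <- lay$icr_idx[[b]]
    data.frame(name = config$icr_blocks$name[b], chrom = grid$chrom[idx[1]],
               start = grid$pos[idx[1]] - 1L,        # BED half-open
               end = grid$pos[idx[length(idx)]],
               n_cpgs_total = length(idx), stringsAsFactors = FALSE)
  }))

  truth <- structure(list(
    true_dmc_sites = true_dmc,
    true_proportions = out$W,
    true_outlier_ids = out$outlier_ids,
    true_icr_shifts = cbind(config$icr_blocks,
                            icr_regions[c("chrom", "start", "end",
                                          "n_cpgs_total")]),
    icr_regions = icr_regions), class = "TruthSet")

  list(matrix = mm, samples = out$sheet, truth = truth, panel = panel)
}

#' Write / read a sample sheet
#' @param x sample sheet data.frame.
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_sample_sheet <- function(x, path) {
  data.table::fwrite(x, path)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  data.table::fread(path, data.table = FALSE)
}

#' Write / read a cell-type reference panel TSV
#'
#' Layout: `chrom`, `pos`, then one methylation-fraction column per cell type.
#' @param panel a `ReferencePanel`.
#' @param path TSV path.
#' @return `path` (write) or a `ReferencePanel` (read).
#' @export
write_reference_panel <- function(panel, path) {
  out <- cbind(panel$cpgs, as.data.frame(panel$profile))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_reference_panel
#' @export
read_reference_panel <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  ct <- setdiff(names(dt), c("chrom", "pos"))
  prof <- as.matrix(dt[ct])
  if (any(prof < 0 | prof > 1)) stop("panel fractions must lie in [0, 1]")
  structure(list(cpgs = dt[c("chrom", "pos")], cell_types = ct,
                 profile = prof), class = "ReferencePanel")
}

#' Write a truth set to JSON
#' @param truth a `TruthSet`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_set <- function(truth, path) {
  out <- truth
  out$true_proportions <- cbind(
    data.frame(sample_id = rownames(truth$true_proportions)),
    as.data.frame(truth$true_proportions))
  jsonlite::write_json(out, path, dataframe = "columns", digits = NA,
                       pretty = TRUE)
  invisible(path)
}
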