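#' Read imprinting control region (ICR) definitions
#'
#' TSV with columns `name`, `chrom`, `start`, `end` (BED semantics: 0-based
#' half-open), and optionally `parental_origin`, `icr_type`, `n_cpgs_total`
#' (total CpG dinucleotides in the region, used for capture-coverage
#' accounting).
#'
#' @param path TSV path.
#' @return data.frame of ICR definitions.
#' @export
read_icr_definitions <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  stopifnot(all(c("name", "chrom", "start", "end") %in% names(dt)))
  if (anyDuplicated(dt$name)) stop("ICR names must be unique")
  if (any(dt$start >= dt$end)) stop("ICR intervals need start < end")
  dt
}

icr_site_index <- function(x, icr) {
  which(x$sites$chrom == icr$chrom &
          x$sites$pos > icr$start & x$sites$pos <= icr$end)
}

#' Summarize methylation within one ICR
#'
#' Selects the captured CpGs inside the ICR interval and, to avoid skewing by
#' missing data, averages per-sample betas per CpG within each group-by-sex
#' cell (non-missing samples only). Also emits per-CpG group differences
#' (case - control), combined and per sex.
#'
#' @param x a filtered `MethylomeMatrix`.
#' @param icr one row of an ICR definition table (`name`, `chrom`, `start`,
#'   `end`, optionally `n_cpgs_total`).
#' @param samples sample sheet with `group` and `sex` columns.
#' @return An `ICRSummary` list: `name`, `cell_means` (data.frame chrom, pos,
#'   then mean beta per group x sex cell and per group), `diffs` (per-CpG
#'   case - control differences: combined, male, female), `n_cpgs_captured`,
#'   `coverage_fraction` (captured / `n_cpgs_total`, `NA` when the total is
#'   unknown), `empty` flag.
#' @export
summarize_icr <- function(x, icr, samples) {
  idx <- icr_site_index(x, icr)
  n_total <- if ("n_cpgs_total" %in% names(icr) && !is.na(icr$n_cpgs_total))
    icr$n_cpgs_total else NA_integer_
  if (length(idx) == 0) {
    return(structure(list(name = icr$name, cell_means = NULL, diffs = NULL,
                          n_cpgs_captured = 0L,
                          coverage_fraction = if (is.na(n_total)) NA_real_ else 0,
                          empty = TRUE), class = "ICRSummary"))
  }
  B <- beta_values(subset_sites(x, idx))
  jj <- match(samples$sample_id, x$samples)
  grp_mean <- function(sel)
    rowMeans(B[, jj[sel], drop = FALSE], na.rm = TRUE)
  case <- samples$group == "case"; male <- samples$sex == "M"
  cm <- data.frame(chrom = x$sites$chrom[idx], pos = x$sites$pos[idx],
                   case_M = grp_mean(case & male),
                   case_F = grp_mean(case & !male),
                   control_M = grp_mean(!case & male),
                   control_F = grp_mean(!case & !male),
                   case = grp_mean(case), control = grp_mean(!case),
                   stringsAsFactors = FALSE)
  for (cc in 3:8) cm[[cc]][is.nan(cm[[cc]])] <- NA_real_
  diffs <- data.frame(chrom = cm$chrom, pos = cm$pos,
                      combined = cm$case - cm$control,
                      male = cm$case_M - cm$control_M,
                      female = cm$case_F - cm$control_F,
                      stringsAsFactors = FALSE)
  structure(list(name = icr$name, cell_means = cm, diffs = diffs,
                 n_cpgs_captured = length(idx),
                 coverage_fraction = if (is.na(n_total)) NA_real_
                 else length(idx) / n_total,
                 empty = FALSE), class = "ICRSummary")
}

#' Two-way ANOVA on ICR per-CpG means
#'
#' Treats the per-CpG group-by-sex mean betas as observations in a 2x2
#' factorial (CpGs are the replicates, exactly as the per-CpG averaging rule
#' implies). Sums of squares are Type II (via `car::Anova`), which reduces to
#' the standard balanced decomposition when no cell is missing. Pairwise
#' group contrasts within each sex use the residual mean square with a
#' Bonferroni factor of 2.
#'
#' @param summary an `ICRSummary` from [summarize_icr()].
#' @return list: `anova` (data.frame term, F, p), `contrasts` (data.frame
#'   sex, estimate, t, df, p_bonferroni), `degenerate` flag.
#' @export
icr_anova <- function(summary) {
  if (summary$empty || summary$n_cpgs_captured < 2)
    stop("ICR ANOVA needs at least 2 captured CpGs")
  cm <- summary$cell_means
  long <- data.frame(
    beta = c(cm$case_M, cm$case_F, cm$control_M, cm$control_F),
    group = factor(rep(c("case", "case", "control", "control"),
                       each = nrow(cm)), levels = c("control", "case")),
    sex = factor(rep(c("M", "F", "M", "F"), each = nrow(cm)),
                 levels = c("F", "M")))
  long <- long[!is.na(long$beta), , drop = FALSE]
  if (var(long$beta) < 1e-300 || nrow(long) < 5)
    return(list(anova = data.frame(term = c("group", "sex", "group:sex"),
                                   F = NA_real_, p = NA_real_),
                contrasts = NULL, degenerate = TRUE))
  fit <- lm(beta ~ group * sex, data = long)
  a2 <- car::Anova(fit, type = "II")
  terms <- c("group", "sex", "group:sex")
  av <- data.frame(term = terms,
                   F = a2[terms, "F value"],
                   p = a2[terms, "Pr(>F)"], row.names = NULL)
  ms_res <- a2["Residuals", "Sum Sq"] / a2["Residuals", "Df"]
  df_res <- a2["Residuals", "Df"]
  contr <- do.call(rbind, lapply(c("M", "F"), function(sx) {
    ca <- long$beta[long$group == "case" & long$sex == sx]
    co <- long$beta[long$group == "control" & long$sex == sx]
    est <- mean(ca) - mean(co)
    se <- sqrt(ms_res * (1 / length(ca) + 1 / length(co)))
    tt <- est / se
    data.frame(sex = sx, estimate = est, t = tt, df = df_res,
               p_bonferroni = min(1, 2 * 2 * pt(-abs(tt), df_res)))
  }))
  list(anova = av, contrasts = contr, degenerate = FALSE)
}

#' Direction tallies of group differences across ICRs
#'
#' Per ICR with captured data: the mean of per-CpG methylation differences
#' (case - control), combined and per sex; tallies of hypo- vs
#' hypermethylated ICRs per analysis; and the count of ICRs where the female
#' difference is below the male difference. ICRs with no captured CpGs are
#' excluded from all denominators.
#'
#' @param x a filtered `MethylomeMatrix`.
#' @param icrs ICR definition data.frame (one row per ICR).
#' @param samples sample sheet.
#' @return list with `per_icr` (data.frame: name, n_cpgs_captured, mean
#'   differences) and `tallies`.
#' @export
icr_direction_tally <- function(x, icrs, samples) {
  rows <- lapply(seq_len(nrow(icrs)), function(i) {
    s <- summarize_icr(x, icrs[i, ], samples)
    if (s$empty)
      return(data.frame(name = s$name, n_cpgs_captured = 0L,
                        diff_combined = NA_real_, diff_male = NA_real_,
                        diff_female = NA_real_, stringsAsFactors = FALSE))
    data.frame(name = s$name, n_cpgs_captured = s$n_cpgs_captured,
               diff_combined = mean(s$diffs$combined, na.rm = TRUE),
               diff_male = mean(s$diffs$male, na.rm = TRUE),
               diff_female = mean(s$diffs$female, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  with_data <- per[per$n_cpgs_captured > 0, , drop = FALSE]
  tally1 <- function(d) c(hypo = sum(d < 0, na.rm = TRUE),
                          hyper = sum(d > 0, na.rm = TRUE),
                          zero = sum(d == 0, na.rm = TRUE))
  list(per_icr = per,
       tallies = list(
         n_with_data = nrow(with_data),
         combined = tally1(with_data$diff_combined),
         male = tally1(with_data$diff_male),
         female = tally1(with_data$diff_female),
         female_below_male = sum(with_data$diff_female < with_data$diff_male,
                                 na.rm = TRUE)))
}

#' Capture-coverage fractions of ICRs for two site sets
#'
#' Per ICR: the fraction of its total CpGs present in each of two site sets
#' (e.g. the capture panel after filtering vs the sites of a methylation
#' array), for comparing platform coverage of imprinted regions.
#'
#' @param icrs ICR definitions with a valid `n_cpgs_total` column.
#' @param sites_a,sites_b data.frames with `chrom`, `pos`.
#' @return data.frame: name, n_cpgs_total, n_a, frac_a, n_b, frac_b
#'   (fractions `NA`-flagged when `n_cpgs_total` is 0 or missing).
#' @export
icr_coverage <- function(icrs, sites_a, sites_b) {
  count_in <- function(sites, icr)
    sum(sites$chrom == icr$chrom & sites$pos > icr$start &
          sites$pos <= icr$end)
  do.call(rbind, lapply(seq_len(nrow(icrs)), function(i) {
    icr <- icrs[i, ]
    nt <- if ("n_cpgs_total" %in% names(icr)) icr$n_cpgs_total else NA
    na <- count_in(sites_a, icr); nb <- count_in(sites_b, icr)
    data.frame(name = icr$name, n_cpgs_total = nt, n_a = na,
               frac_a = if (!is.na(nt) && nt > 0) na / nt else NA_real_,
               n_b = nb,
               frac_b = if (!is.na(nt) && nt > 0) nb / nt else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
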