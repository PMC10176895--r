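icr_fixture <- function() {
  # 2 CpGs inside the ICR, 1 outside; 2 case + 2 control of each sex
  sheet <- data.frame(
    sample_id = paste0("s", 1:8),
    group = rep(c("case", "control"), each = 4),
    subgroup = "none",
    sex = rep(c("M", "M", "F", "F"), 2),
    complications = FALSE, stringsAsFactors = FALSE)
  M <- rbind(c(5, 6, 5, 7, 5, 5, 5, 5),
             c(7, 8, 7, 9, 5, 5, 5, 5),
             c(1, 1, 1, 1, 1, 1, 1, 1))
  Tt <- matrix(10, 3, 8)
  mm <- methylome_matrix(rep("chr11", 3), c(1000L, 1100L, 9000L), M, Tt,
                         sheet$sample_id)
  icr <- data.frame(name = "ICRtest", chrom = "chr11", start = 999L,
                    end = 1100L, n_cpgs_total = 4L)
  list(mm = mm, sheet = sheet, icr = icr)
}

test_that("ICR summaries average per CpG within group-by-sex cells", {
  fx <- icr_fixture()
  s <- summarize_icr(fx$mm, fx$icr, fx$sheet)
  expect_equal(s$n_cpgs_captured, 2L)
  expect_equal(s$coverage_fraction, 0.5)
  # case means per CpG across the 4 case samples: (5+6+5+7)/40, (7+8+7+9)/40
  expect_equal(s$cell_means$case, c(0.575, 0.775))
  expect_equal(s$cell_means$control, c(0.5, 0.5))
  expect_equal(s$diffs$combined, c(0.075, 0.275))
  # identical samples -> zero difference
  mm0 <- fx$mm; mm0$M[] <- 5
  s0 <- summarize_icr(mm0, fx$icr, fx$sheet)
  expect_equal(s0$diffs$combined, c(0, 0))
  # empty ICR flagged
  empty <- summarize_icr(fx$mm, data.frame(name = "none", chrom = "chr9",
                                           start = 0L, end = 10L,
                                           n_cpgs_total = 5L), fx$sheet)
  expect_true(empty$empty)
})

test_that("two-way ANOVA on per-CpG means matches the hand-computed balanced
           decomposition", {
  # textbook balanced 2x2 with 3 replicates (CpGs) per cell
  cells <- list(case_M = c(10, 12, 14), case_F = c(20, 22, 24),
                control_M = c(6, 8, 10), control_F = c(8, 10, 12))
  s <- structure(list(
    name = "toy", empty = FALSE, n_cpgs_captured = 3L,
    cell_means = data.frame(chrom = "chr1", pos = 1:3,
                            case_M = cells$case_M / 30,
                            case_F = cells$case_F / 30,
                            control_M = cells$control_M / 30,
                            control_F = cells$control_F / 30,
                            case = NA, control = NA)), class = "ICRSummary")
  a <- icr_anova(s)
  # hand computation on the same numbers
  y <- unlist(cells) / 30
  g <- rep(c(1, 1, 0, 0), each = 3)   # case = 1
  x <- rep(c(1, 0, 1, 0), each = 3)   # male = 1
  n <- 12
  ss <- function(v) sum((v - mean(v))^2)
  ss_total <- ss(y)
  ss_group <- 2 * 3 * sum((tapply(y, g, mean) - mean(y))^2)
  ss_sex <- 2 * 3 * sum((tapply(y, x, mean) - mean(y))^2)
  cellm <- tapply(y, interaction(g, x), mean)
  ss_cells <- 3 * sum((cellm - mean(y))^2)
  ss_int <- ss_cells - ss_group - ss_sex
  ss_res <- ss_total - ss_cells
  ms_res <- ss_res / 8
  expect_equal(a$anova$F[a$anova$term == "group"], (ss_group / 1) / ms_res,
               tolerance = 1e-9)
  expect_equal(a$anova$F[a$anova$term == "sex"], (ss_sex / 1) / ms_res,
               tolerance = 1e-9)
  expect_equal(a$anova$F[a$anova$term == "group:sex"], (ss_int / 1) / ms_res,
               tolerance = 1e-9)
  # SS identity in the balanced case
  expect_equal(ss_total, ss_group + ss_sex + ss_int + ss_res,
               tolerance = 1e-9)
  # within-sex contrasts: estimates are the cell-mean differences
  expect_equal(a$contrasts$estimate[a$contrasts$sex == "M"],
               mean(cells$case_M - cells$control_M) / 30)
  expect_true(all(a$contrasts$p_bonferroni <= 1))
})

test_that("cell means identical across the factorial give F = 0, p = 1", {
  v <- c(0.4, 0.5, 0.6, 0.45)
  s <- structure(list(
    name = "flat", empty = FALSE, n_cpgs_captured = 4L,
    cell_means = data.frame(chrom = "chr1", pos = 1:4, case_M = v,
                            case_F = v, control_M = v, control_F = v,
                            case = v, control = v)), class = "ICRSummary")
  a <- icr_anova(s)
  expect_equal(a$anova$F, rep(0, 3), tolerance = 1e-10)
  expect_equal(a$anova$p, rep(1, 3), tolerance = 1e-10)
})

test_that("planted sex-specific and opposite shifts are recovered at ICRs", {
  cfg <- simulation_config(
    n_control = 20, n_case = 20, n_cpgs = 2000, markers_per_type = 10,
    dispersion_rho = 0, missing_rate = 0,
    coverage_meanlog = log(500), coverage_sdlog = 0.01, coverage_cap = 1000,
    icr_blocks = data.frame(name = c("ICRf", "ICRopp"),
                            n_sites = c(30L, 30L),
                            shift = c(0.2, 0.4),
                            scope = c("female_only", "opposite")),
    seed = 61)
  sim <- simulate_cohort(cfg)
  mm <- apply_coverage_filter(sim$matrix, filter_config(max_cov = 1000,
                                                        min_samples = 20))
  icrs <- sim$truth$icr_regions
  s_f <- summarize_icr(mm, icrs[icrs$name == "ICRf", ], sim$samples)
  expect_equal(mean(s_f$diffs$female), plogis(0.2) - 0.5, tolerance = 0.02)
  expect_equal(mean(s_f$diffs$male), 0, tolerance = 0.02)
  # opposite-scope block: strong interaction term
  s_o <- summarize_icr(mm, icrs[icrs$name == "ICRopp", ], sim$samples)
  a_o <- icr_anova(s_o)
  expect_lt(a_o$anova$p[a_o$anova$term == "group:sex"], 1e-6)
})

test_that("direction tallies are conserved and skip ICRs without data", {
  fx <- icr_fixture()
  icrs <- rbind(fx$icr,
                data.frame(name = "absent", chrom = "chr9", start = 0L,
                           end = 10L, n_cpgs_total = 7L))
  tal <- icr_direction_tally(fx$mm, icrs, fx$sheet)
  expect_equal(tal$tallies$n_with_data, 1L)
  expect_equal(sum(tal$tallies$combined), 1L)   # hypo + hyper + zero
  expect_equal(unname(tal$tallies$combined["hyper"]), 1L)
  expect_true(is.na(tal$per_icr$diff_combined[tal$per_icr$name == "absent"]))
})

test_that("capture-coverage fractions count captured CpGs per ICR", {
  fx <- icr_fixture()
  sites_a <- fx$mm$sites                         # captures 2 of 4
  sites_b <- fx$mm$sites[3, , drop = FALSE]      # captures none
  cov <- icr_coverage(fx$icr, sites_a, sites_b)
  expect_equal(cov$frac_a, 0.5)
  expect_equal(cov$frac_b, 0)
  set.seed(9)
  sites_r <- data.frame(chrom = "chr11", pos = sort(sample(900:1200, 20)))
  cov_r <- icr_coverage(fx$icr, sites_r, sites_r)
  brute <- sum(sites_r$pos > 999 & sites_r$pos <= 1100) / 4
  expect_equal(cov_r$frac_a, brute)
})
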