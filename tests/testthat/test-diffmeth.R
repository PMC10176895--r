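two_group_X <- function(n1, n2) {
  cbind(`(Intercept)` = 1, contrast = rep(c(0, 1), c(n1, n2)))
}

test_that("symmetric two-group data force a null fit", {
  m <- rep(50, 6); t <- rep(100, 6)
  f <- fit_site_glm(m, t, two_group_X(3, 3))
  expect_equal(f$coef, 0, tolerance = 1e-10)
  expect_equal(f$p, 1, tolerance = 1e-8)
  expect_equal(f$status, "ok")
})

test_that("two-group fit matches the closed-form binomial MLE and Fisher
           information", {
  m <- c(50, 50, 50, 80, 80, 80); t <- rep(100, 6)
  f <- fit_site_glm(m, t, two_group_X(3, 3))
  coef_expected <- log(0.8 / 0.2) - log(0.5 / 0.5)       # 1.386294
  se_expected <- sqrt(1 / (300 * 0.25) + 1 / (300 * 0.16))
  expect_equal(f$coef, coef_expected, tolerance = 1e-7)
  expect_equal(f$se, se_expected, tolerance = 1e-6)
  expect_equal(f$z, 7.49917, tolerance = 1e-4)
})

test_that("swapping methylated and unmethylated counts negates the effect and
           keeps the p-value", {
  set.seed(5)
  t <- sample(30:200, 8)
  m <- rbinom(8, t, 0.4)
  X <- two_group_X(4, 4)
  f1 <- fit_site_glm(m, t, X)
  f2 <- fit_site_glm(t - m, t, X)
  expect_equal(f2$coef, -f1$coef, tolerance = 1e-8)
  expect_equal(f2$p, f1$p, tolerance = 1e-8)
})

test_that("IRLS agrees with the independent pooled-proportion MLE on random
           two-group instances", {
  set.seed(11)
  for (i in 1:20) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    t <- sample(20:300, n1 + n2, TRUE)
    p1 <- runif(1, 0.1, 0.9); p2 <- runif(1, 0.1, 0.9)
    m <- rbinom(n1 + n2, t, rep(c(p1, p2), c(n1, n2)))
    if (sum(m[1:n1]) == 0 || sum(m[1:n1]) == sum(t[1:n1])) next
    if (sum(m[-(1:n1)]) == 0 || sum(m[-(1:n1)]) == sum(t[-(1:n1)])) next
    f <- fit_site_glm(m, t, two_group_X(n1, n2))
    # the saturated two-group MLE is the pooled per-group proportion
    ph1 <- sum(m[1:n1]) / sum(t[1:n1])
    ph2 <- sum(m[-(1:n1)]) / sum(t[-(1:n1)])
    expect_equal(f$coef, log(ph2 / (1 - ph2)) - log(ph1 / (1 - ph1)),
                 tolerance = 1e-6)
  }
})

test_that("separation and insufficient data are flagged, not fatal", {
  f <- fit_site_glm(c(0, 0, 0, 100, 100, 100), rep(100, 6), two_group_X(3, 3))
  expect_equal(f$status, "separation")
  f2 <- fit_site_glm(c(5, NA, NA, NA, NA, NA), rep(100, 6), two_group_X(3, 3))
  expect_equal(f2$status, "untestable")
})

test_that("q-values with pi0 = 1 reduce to Benjamini-Hochberg", {
  expect_equal(qvalues(c(0.01, 0.02, 0.03, 0.04), "fixed_one")$q,
               rep(0.04, 4))
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(10:500, 1))^sample(1:3, 1)
    q <- qvalues(p, "fixed_one")$q
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-13)
    expect_true(all(q[order(p)] == cummax(q[order(p)])) || all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q <= 1))
  }
})

test_that("the pi0 smoother is close to 1 on uniform p-values", {
  set.seed(12)
  p <- runif(10000)
  est <- qvalues(p, "smoother")
  expect_lt(abs(est$pi0 - 1), 0.05)
})

test_that("methylation differences equal the group-mean oracle", {
  mm <- methylome_matrix(rep("chr1", 2), c(1L, 2L),
                         rbind(c(6, 8, 5, 5), c(5, 5, 5, 5)),
                         rbind(c(10, 10, 10, 10), rep(10, 4)),
                         c("a", "b", "c", "d"))
  d <- methylation_difference(mm, c("a", "b"), c("c", "d"))
  expect_equal(d, c(0.2, 0))

  mm2 <- random_matrix(seed = 17)
  ids <- mm2$samples
  d2 <- methylation_difference(mm2, ids[1:4], ids[5:8])
  B <- mm2$M / mm2$Tt
  brute <- apply(B, 1, function(r)
    mean(r[1:4], na.rm = TRUE) - mean(r[5:8], na.rm = TRUE))
  brute[is.nan(brute)] <- NA
  expect_equal(d2, brute)
})

test_that("call_dmcs recovers planted effects with matching direction and a
           covariate orthogonal to the contrast barely moves the estimate", {
  eff <- data.frame(site = seq(100, 1480, by = 20), effect = 1.2,
                    scope = "both")
  cfg <- small_sim_config(n_control = 20, n_case = 20, n_cpgs = 3000,
                          dispersion_rho = 0, planted_effects = eff,
                          coverage_meanlog = log(80), seed = 13,
                          icr_blocks = no_icr_blocks())
  sim <- simulate_cohort(cfg)
  mm <- apply_coverage_filter(sim$matrix, filter_config(min_samples = 30))
  res <- call_dmcs(mm, sim$samples, design_spec(covariates = character()),
                   pi0_mode = "fixed_one")
  key <- paste(res$dmcs$chrom, res$dmcs$pos)
  truth_key <- paste(sim$truth$true_dmc_sites$chrom,
                     sim$truth$true_dmc_sites$pos)
  hits <- truth_key %in% key
  expect_gt(mean(hits), 0.8)
  called <- res$dmcs[key %in% truth_key, ]
  expect_gt(mean(called$meth_diff > 0), 0.95)   # planted effects are positive

  res_sex <- call_dmcs(mm, sim$samples, design_spec(covariates = "sex"),
                       pi0_mode = "fixed_one")
  i <- match(truth_key, paste(res$results$chrom, res$results$pos))
  expect_equal(res_sex$results$coef[i], res$results$coef[i], tolerance = 0.2)
})

test_that("opposite-scope effects appear with opposite directions in
           sex-stratified analyses", {
  eff <- data.frame(site = seq(200, 600, by = 20), effect = 1.5,
                    scope = "opposite")
  cfg <- small_sim_config(n_control = 24, n_case = 24, n_cpgs = 2000,
                          dispersion_rho = 0, planted_effects = eff,
                          coverage_meanlog = log(100), seed = 14,
                          icr_blocks = no_icr_blocks())
  sim <- simulate_cohort(cfg)
  mm <- apply_coverage_filter(sim$matrix, filter_config(min_samples = 20))
  males <- call_dmcs(mm, sim$samples,
                     design_spec(covariates = character(), subset = "males"),
                     pi0_mode = "fixed_one")
  females <- call_dmcs(mm, sim$samples,
                       design_spec(covariates = character(), subset = "females"),
                       pi0_mode = "fixed_one")
  ov <- compare_dmc_sets(males, females)
  expect_gt(ov$n_shared, 5)
  expect_gt(ov$n_opposite_direction, ov$n_same_direction)
})

test_that("DMC set comparison counts overlap, direction and magnitude", {
  a <- data.frame(chrom = "chr1", pos = c(1, 2, 3),
                  meth_diff = c(0.08, 0.1, -0.2),
                  direction = c("hyper", "hyper", "hypo"))
  b <- data.frame(chrom = "chr1", pos = c(2, 3, 4),
                  meth_diff = c(0.12, 0.1, 0.5),
                  direction = c("hyper", "hyper", "hyper"))
  ov <- compare_dmc_sets(a, b)
  expect_equal(ov$n_shared, 2)
  expect_equal(ov$frac_a_shared, 2 / 3)
  expect_equal(ov$n_same_direction, 1)
  expect_equal(ov$n_opposite_direction, 1)
  # +0.08 vs -0.03 is opposite and not similar under the +/-5% rule
  ov2 <- compare_dmc_sets(
    data.frame(chrom = "c", pos = 1, meth_diff = 0.08, direction = "hyper"),
    data.frame(chrom = "c", pos = 1, meth_diff = -0.03, direction = "hypo"))
  expect_equal(ov2$n_opposite_direction, 1)
  expect_equal(ov2$n_similar_magnitude, 0)
  expect_equal(compare_dmc_sets(a, b[3, , drop = FALSE])$n_shared, 0)
})
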