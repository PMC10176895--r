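#' Fisher exact test for a 2x2 table
#'
#' Two-sided exact p by hypergeometric enumeration over tables with the
#' observed margins, summing the probabilities of tables no more probable
#' than the observed one (the convention of the classical R implementation,
#' with a small relative tie tolerance).
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return list: `p`, `degenerate` (TRUE when a zero margin forces p = 1).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0),
            all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p = 1, degenerate = TRUE))
  list(p = fisher.test(tab)$p.value, degenerate = FALSE)
}

#' Fisher exact test for an r x c table (Freeman-Halton)
#'
#' Exact enumeration over all tables with the observed margins when feasible,
#' or a seeded Monte-Carlo estimate with its standard error.
#'
#' @param tab r x c matrix of nonnegative integer counts.
#' @param method `"exact"` or `"montecarlo"`.
#' @param n_sim Monte-Carlo replicates.
#' @param seed seed for the Monte-Carlo estimate (isolated from the caller's
#'   RNG stream).
#' @param workspace workspace size for the exact network algorithm.
#' @return list: `p`, `method`, and for Monte Carlo `se` (binomial standard
#'   error of the estimate).
#' @export
fisher_exact_rxc <- function(tab, method = c("exact", "montecarlo"),
                             n_sim = 1e5, seed = 1L, workspace = 2e6) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), all(tab == round(tab)))
  if (method == "exact") {
    p <- tryCatch(fisher.test(tab, workspace = workspace)$p.value,
                  error = function(e)
                    stop("exact enumeration infeasible for this table (",
                         conditionMessage(e),
                         "); use method = \"montecarlo\"", call. = FALSE))
    list(p = p, method = "exact")
  } else {
    p <- with_local_seed(seed,
      fisher.test(tab, simulate.p.value = TRUE, B = n_sim)$p.value)
    list(p = p, method = "montecarlo", se = sqrt(p * (1 - p) / n_sim))
  }
}

#' Pearson chi-square test, optionally with Yates' continuity correction
#'
#' @param tab r x c matrix of counts; Yates correction applies to 2x2 only.
#' @param yates subtract 0.5 from each |O - E| (2x2 tables).
#' @return list: `chi2`, `df`, `p`, `degenerate` (TRUE when an expected count
#'   is zero).
#' @export
chi_square <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (yates && !all(dim(tab) == c(2, 2)))
    stop("Yates' correction is defined for 2x2 tables only")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                degenerate = TRUE))
  ct <- suppressWarnings(chisq.test(tab, correct = yates))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, degenerate = FALSE)
}

#' Two-sample t test from group summaries
#'
#' Unpaired two-tailed t test computed from (mean, sd, n) summaries, as
#' needed to recompute demographic-table p-values from printed values.
#' Pooled: `sp^2 = ((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2)` with
#' `df = n1+n2-2`; Welch: Satterthwaite degrees of freedom.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @param variance `"pooled"` or `"welch"`.
#' @return list: `t`, `df`, `p`.
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2)
    return(list(t = 0, df = n1 + n2 - 2, p = 1))
  if (variance == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tt <- (mean1 - mean2) / se
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

#' Demographic comparison table
#'
#' Per variable, compares the two groups of a sample sheet: numeric variables
#' by unpaired pooled t test on complete cases (mean, SD, n reported);
#' categorical variables by Fisher's exact test when any expected cell count
#' is below 5, otherwise by the (uncorrected) chi-square test. The test
#' choice is recorded per row.
#'
#' @param samples sample sheet with a 2-level `group` column.
#' @param numeric_vars,categorical_vars column names to compare.
#' @return data.frame: variable, type, test, summary (printable), p.
#' @export
cohort_table <- function(samples, numeric_vars = character(),
                         categorical_vars = character()) {
  g <- as.factor(samples$group)
  stopifnot(nlevels(g) == 2)
  lv <- levels(g)
  rows <- list()
  for (v in numeric_vars) {
    xs <- split(samples[[v]], g)
    xs <- lapply(xs, function(z) z[!is.na(z)])
    s <- t_test_summary(mean(xs[[1]]), stats::sd(xs[[1]]), length(xs[[1]]),
                        mean(xs[[2]]), stats::sd(xs[[2]]), length(xs[[2]]))
    rows[[v]] <- data.frame(
      variable = v, type = "numeric", test = "t_pooled",
      summary = sprintf("%s: %.2f (%.2f), %s: %.2f (%.2f)",
                        lv[1], mean(xs[[1]]), stats::sd(xs[[1]]),
                        lv[2], mean(xs[[2]]), stats::sd(xs[[2]])),
      p = s$p, stringsAsFactors = FALSE)
  }
  for (v in categorical_vars) {
    keep <- !is.na(samples[[v]])
    tab <- table(g[keep], as.factor(samples[[v]][keep]))
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    if (degenerate) {
      p <- NA_real_; test <- "degenerate"
    } else if (any(exp_counts < 5)) {
      p <- if (all(dim(tab) == c(2, 2))) fisher_exact_2x2(tab)$p
           else fisher_exact_rxc(tab)$p
      test <- "fisher_exact"
    } else {
      p <- chi_square(tab)$p
      test <- "chi_square"
    }
    rows[[v]] <- data.frame(
      variable = v, type = "categorical", test = test,
      summary = paste(apply(tab, 1, paste, collapse = "/"), collapse = " vs "),
      p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
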