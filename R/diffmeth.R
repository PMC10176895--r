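#' Design specification for differential methylation testing
#'
#' Describes one association analysis: which group contrast to test, which
#' covariates to adjust for, and which samples to use. Mirrors the study's
#' analysis battery: a combined model adjusted for infant sex and cell
#' proportions, sex-stratified models adjusted for cell proportions only, and
#' subgroup contrasts (in vivo / in vitro vs control, in vitro vs in vivo),
#' optionally adding a pregnancy-complications covariate.
#'
#' @param contrast length-2 character: (case level, reference level), matched
#'   against the sample sheet's `group` column, or against `subgroup` when
#'   `contrast_column = "subgroup"`.
#' @param covariates subset of `c("sex", "cells", "complications")`.
#' @param subset one of `"all"`, `"males"`, `"females"`.
#' @param contrast_column sample-sheet column holding the contrast levels.
#' @return A `DesignSpec` list.
#' @export
design_spec <- function(contrast = c("case", "control"),
                        covariates = c("sex", "cells"),
                        subset = c("all", "males", "females"),
                        contrast_column = "group") {
  subset <- match.arg(subset)
  stopifnot(length(contrast) == 2,
            all(covariates %in% c("sex", "cells", "complications")))
  if (subset != "all" && "sex" %in% covariates)
    stop("sex cannot be a covariate in a sex-stratified model")
  structure(list(contrast = contrast, covariates = covariates,
                 subset = subset, contrast_column = contrast_column),
            class = "DesignSpec")
}

# Build the model frame: selected samples, design matrix and contrast column.
# Proportion columns are taken from the sample sheet (one column per cell
# type, as produced by deconvolution). A numerically rank-deficient cell
# block (condition number > 1e10) drops its last column with a warning.
build_design <- function(samples, design, cell_types = NULL) {
  keep <- switch(design$subset, all = rep(TRUE, nrow(samples)),
                 males = samples$sex == "M", females = samples$sex == "F")
  lv <- design$contrast
  gcol <- samples[[design$contrast_column]]
  keep <- keep & gcol %in% lv
  sub <- samples[keep, , drop = FALSE]
  g <- as.numeric(sub[[design$contrast_column]] == lv[1])
  if (length(unique(g)) < 2)
    stop("both contrast levels must be present in the selected samples")
  X <- cbind(`(Intercept)` = 1, contrast = g)
  if ("sex" %in% design$covariates) {
    sx <- as.numeric(sub$sex == "M")
    if (length(unique(sx)) < 2) stop("sex covariate is constant in this subset")
    X <- cbind(X, sex = sx)
  }
  if ("cells" %in% design$covariates) {
    if (is.null(cell_types))
      cell_types <- setdiff(names(sub),
                            c("sample_id", "group", "subgroup", "sex",
                              "complications", "residual_norm"))
    if (length(cell_types) == 0)
      stop("no cell-proportion columns found in the sample sheet")
    C <- as.matrix(sub[cell_types])
    if (kappa(cbind(X, C)) > 1e10) {
      warning("cell-proportion block is numerically rank deficient; ",
              "dropping column '", cell_types[length(cell_types)], "'")
      C <- C[, -ncol(C), drop = FALSE]
    }
    X <- cbind(X, C)
  }
  if ("complications" %in% design$covariates) {
    cp <- as.numeric(sub$complications)
    if (length(unique(cp)) < 2)
      stop("complications covariate is constant in this subset")
    X <- cbind(X, complications = cp)
  }
  list(samples = sub, X = X, case_ids = sub$sample_id[g == 1],
       control_ids = sub$sample_id[g == 0])
}

#' Fit a per-site binomial logistic regression
#'
#' Regresses per-sample (methylated, unmethylated) counts on the design matrix
#' by binomial-family iteratively reweighted least squares and returns the
#' Wald test of the contrast coefficient (column named `contrast`).
#' Non-missing samples only; non-convergence (50 iterations, deviance
#' tolerance 1e-8) and complete separation are flagged, not errors.
#'
#' @param m,t methylated / total counts per sample (`NA` = missing).
#' @param X design matrix with an intercept and a `contrast` column.
#' @return list: `coef`, `se`, `z`, `p`, `status` (`"ok"`,
#'   `"separation"`, `"not_converged"`, `"untestable"`), `n_used`.
#' @export
fit_site_glm <- function(m, t, X) {
  ok <- !is.na(m) & !is.na(t) & t > 0
  out <- list(coef = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
              status = "untestable", n_used = sum(ok))
  if (sum(ok) <= ncol(X)) return(out)
  Xo <- X[ok, , drop = FALSE]
  g <- Xo[, "contrast"]
  if (length(unique(g)) < 2) return(out)
  if (qr(Xo)$rank < ncol(Xo)) return(out)
  y <- m[ok] / t[ok]
  fit <- suppressWarnings(
    glm.fit(Xo, y, weights = t[ok], family = binomial(),
            control = list(epsilon = 1e-8, maxit = 50)))
  ci <- match("contrast", colnames(Xo))
  b <- fit$coefficients[ci]
  # covariance from the converged IRLS working weights
  W <- fit$weights
  info <- crossprod(Xo * sqrt(W))
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov) || !is.finite(b)) return(out)
  b <- unname(b)
  se <- sqrt(cov[ci, ci])
  status <- "ok"
  if (!fit$converged) status <- "not_converged"
  eta <- fit$linear.predictors
  if (fit$boundary || max(abs(eta)) > 15 && abs(b) > 10) status <- "separation"
  z <- b / se
  list(coef = b, se = se, z = z, p = 2 * pnorm(-abs(z)), status = status,
       n_used = sum(ok))
}

#' Storey q-values
#'
#' False-discovery-rate q-values: for p-values sorted ascending,
#' `q(i) = min over j >= i of pi0 * m * p(j) / j`. The null proportion `pi0`
#' is estimated by the lambda-grid smoother (lambda = 0.05, 0.10, ..., 0.95;
#' cubic smoothing spline through `pi0(lambda) = mean(p > lambda)/(1-lambda)`,
#' evaluated at lambda = 0.95, clamped to (0, 1]) or fixed at 1, in which
#' case q-values coincide exactly with Benjamini-Hochberg adjusted p-values.
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` allowed; propagated).
#' @param pi0_mode `"smoother"` or `"fixed_one"`.
#' @return list with `q` (same length/order as `p`) and `pi0`.
#' @export
qvalues <- function(p, pi0_mode = c("smoother", "fixed_one")) {
  pi0_mode <- match.arg(pi0_mode)
  ok <- !is.na(p)
  pv <- p[ok]
  if (length(pv) == 0) return(list(q = p, pi0 = NA_real_))
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  pi0 <- 1
  if (pi0_mode == "smoother" && length(pv) >= 100) {
    lam <- seq(0.05, 0.95, by = 0.05)
    pi0l <- vapply(lam, function(l) mean(pv > l) / (1 - l), 0)
    sp <- smooth.spline(lam, pi0l, df = 3)
    pi0 <- predict(sp, x = 0.95)$y
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  }
  m <- length(pv)
  o <- order(pv)
  qs <- pi0 * m * pv[o] / seq_len(m)
  qs <- rev(cummin(rev(qs)))
  qs <- pmin(qs, 1)
  q <- rep(NA_real_, length(p))
  q[ok][o] <- qs
  list(q = q, pi0 = pi0)
}

#' Group methylation difference per site
#'
#' Per site: mean of per-sample betas over non-missing case samples minus the
#' same over control samples (case - control, on the fraction scale). A group
#' with no non-missing sample at a site yields `NA`.
#'
#' @param x a `MethylomeMatrix`.
#' @param case_ids,control_ids sample identifiers of the two groups.
#' @return numeric vector of differences, one per site.
#' @export
methylation_difference <- function(x, case_ids, control_ids) {
  B <- beta_values(x)
  ca <- rowMeans(B[, match(case_ids, x$samples), drop = FALSE], na.rm = TRUE)
  co <- rowMeans(B[, match(control_ids, x$samples), drop = FALSE], na.rm = TRUE)
  d <- ca - co
  d[is.nan(d)] <- NA_real_
  d
}

#' Call differentially methylated cytosines (DMCs)
#'
#' Runs the per-site binomial GLM at every site of the (filtered) matrix,
#' computes Storey q-values jointly across all testable sites, attaches the
#' group methylation difference and its direction, and returns both the full
#' results table and the records passing `q < q_threshold`. Sites flagged as
#' non-converged/separated/untestable are excluded from the q-value input and
#' tallied.
#'
#' @param x a filtered `MethylomeMatrix`.
#' @param samples sample sheet (with cell-proportion columns when the design
#'   requests the `cells` covariate).
#' @param design a [design_spec()].
#' @param q_threshold significance threshold on the q-value (default 0.05).
#' @param pi0_mode passed to [qvalues()].
#' @return An object of class `dmc_result`: list with `results` (full
#'   per-site table: chrom, pos, coef, se, z, p, q, meth_diff, direction,
#'   status, n_used), `dmcs` (rows with `q < q_threshold`), `summary`
#'   (hypo/hyper counts, |diff| bins <10% / 10-20% / >20%, status tallies,
#'   pi0), and `design`.
#' @export
call_dmcs <- function(x, samples, design = design_spec(), q_threshold = 0.05,
                      pi0_mode = "smoother") {
  dm <- build_design(samples, design)
  jj <- match(dm$samples$sample_id, x$samples)
  if (anyNA(jj)) stop("sample sheet and matrix sample sets differ")
  M <- x$M[, jj, drop = FALSE]
  Tt <- x$Tt[, jj, drop = FALSE]
  n_sites <- nrow(M)
  coefs <- ses <- zs <- ps <- rep(NA_real_, n_sites)
  status <- character(n_sites)
  nuse <- integer(n_sites)
  for (i in seq_len(n_sites)) {
    f <- fit_site_glm(M[i, ], Tt[i, ], dm$X)
    coefs[i] <- f$coef; ses[i] <- f$se; zs[i] <- f$z
    status[i] <- f$status; nuse[i] <- f$n_used
    if (f$status == "ok") ps[i] <- f$p
  }
  qq <- qvalues(ps, pi0_mode = pi0_mode)
  md <- methylation_difference(x, dm$case_ids, dm$control_ids)
  res <- data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
                    coef = coefs, se = ses, z = zs, p = ps, q = qq$q,
                    meth_diff = md,
                    direction = ifelse(md > 0, "hyper", "hypo"),
                    status = status, n_used = nuse,
                    stringsAsFactors = FALSE)
  dmcs <- res[!is.na(res$q) & res$q < q_threshold, , drop = FALSE]
  rownames(dmcs) <- NULL
  ad <- abs(dmcs$meth_diff)
  summ <- list(
    n_tested = sum(status == "ok"),
    n_untestable = sum(status != "ok"),
    status_counts = table(status),
    pi0 = qq$pi0,
    n_dmcs = nrow(dmcs),
    n_hypo = sum(dmcs$direction == "hypo", na.rm = TRUE),
    n_hyper = sum(dmcs$direction == "hyper", na.rm = TRUE),
    diff_bins = c(`<10%` = sum(ad < 0.10, na.rm = TRUE),
                  `10-20%` = sum(ad >= 0.10 & ad <= 0.20, na.rm = TRUE),
                  `>20%` = sum(ad > 0.20, na.rm = TRUE)))
  structure(list(results = res, dmcs = dmcs, summary = summ, design = design),
            class = "dmc_result")
}

#' @export
print.dmc_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "DMC analysis (%s vs %s, subset %s): %d tested, %d untestable\n",
    x$design$contrast[1], x$design$contrast[2], x$design$subset,
    s$n_tested, s$n_untestable))
  cat(sprintf("  pi0 = %.3f; %d DMCs (%d hypo / %d hyper)\n",
              s$pi0, s$n_dmcs, s$n_hypo, s$n_hyper))
  cat(sprintf("  |meth diff| bins: <10%%: %d, 10-20%%: %d, >20%%: %d\n",
              s$diff_bins[1], s$diff_bins[2], s$diff_bins[3]))
  invisible(x)
}

#' Compare two DMC sets
#'
#' Overlap report between two DMC lists keyed by (chrom, pos): shared and
#' exclusive counts, overlap fractions relative to each list, and among
#' shared sites the direction concordance and the number with similar
#' methylation-difference magnitude (|diff_a - diff_b| <= `tolerance`,
#' default +/- 5%).
#'
#' @param a,b `dmc_result` objects or data.frames with columns `chrom`,
#'   `pos`, `meth_diff`, `direction`.
#' @param tolerance beta-fraction tolerance for "similar magnitude".
#' @return list of counts and fractions.
#' @export
compare_dmc_sets <- function(a, b, tolerance = 0.05) {
  da <- if (inherits(a, "dmc_result")) a$dmcs else a
  db <- if (inherits(b, "dmc_result")) b$dmcs else b
  ka <- paste(da$chrom, da$pos)
  kb <- paste(db$chrom, db$pos)
  shared <- intersect(ka, kb)
  ia <- match(shared, ka); ib <- match(shared, kb)
  same_dir <- da$direction[ia] == db$direction[ib]
  similar <- abs(da$meth_diff[ia] - db$meth_diff[ib]) <= tolerance
  list(n_a = length(ka), n_b = length(kb), n_shared = length(shared),
       n_a_only = length(ka) - length(shared),
       n_b_only = length(kb) - length(shared),
       frac_a_shared = if (length(ka)) length(shared) / length(ka) else NA_real_,
       frac_b_shared = if (length(kb)) length(shared) / length(kb) else NA_real_,
       n_same_direction = sum(same_dir),
       n_opposite_direction = sum(!same_dir),
       n_similar_magnitude = sum(similar),
       shared_keys = shared)
}
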