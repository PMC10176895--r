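#' Sites covered in every sample
#'
#' Complete-case site subset used for PCA-based sample QC: indices of sites
#' with no missing cell.
#'
#' @param x a `MethylomeMatrix`.
#' @return integer vector of site indices.
#' @export
complete_case_sites <- function(x) {
  which(rowSums(is.na(x$Tt)) == 0)
}

#' Principal-component scores of samples on beta values
#'
#' Columns (samples) are the observations; per-site betas are centered and
#' decomposed by singular value decomposition. PC1 sign convention: each
#' component is oriented so that the sample with the largest absolute score
#' is positive.
#'
#' @param beta complete site x sample beta matrix (no missing values).
#' @param n_pcs number of components to return.
#' @return list: `scores` (sample x PC matrix), `sdev`, `constant` (TRUE when
#'   the input had no variance, in which case all scores are zero).
#' @export
pca_scores <- function(beta, n_pcs = 5L) {
  stopifnot(!anyNA(beta), ncol(beta) >= 2)
  X <- t(beta)
  cs <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(cs) < 1e-12)) {
    k <- min(n_pcs, ncol(X))
    sc <- matrix(0, nrow(X), k,
                 dimnames = list(rownames(X), paste0("PC", seq_len(k))))
    return(list(scores = sc, sdev = rep(0, k), constant = TRUE))
  }
  pr <- prcomp(cs, center = FALSE, scale. = FALSE)
  k <- min(n_pcs, ncol(pr$x))
  sc <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(sc[, j]))
    if (sc[i_max, j] < 0) sc[, j] <- -sc[, j]
  }
  list(scores = sc, sdev = pr$sdev[seq_len(k)], constant = FALSE)
}

# max over single splits of the reduction in squared error when the gap
# sequence is modelled with two segment means, scaled by a robust gap-scale
# estimate (squared MAD). Returns the best split index and its statistic.
amoc_scan_calibrated <- function(g) {
  m <- length(g)
  s2 <- mad(g)^2
  if (s2 <= 0) s2 <- .Machine$double.eps
  cs <- cumsum(g); cs2 <- cumsum(g^2)
  tot <- cs[m]; tot2 <- cs2[m]
  rss0 <- tot2 - tot^2 / m
  ks <- seq_len(m - 1)
  r1 <- (cs2[ks] - cs[ks]^2 / ks) +
    ((tot2 - cs2[ks]) - (tot - cs[ks])^2 / (m - ks))
  stat <- (rss0 - r1) / s2
  k <- which.max(stat)
  list(stat = stat[k], k = k, rss0 = rss0)
}

# literal pooled-variance likelihood-ratio scan: 2*dlogL = m*log(rss0/rss1)
amoc_scan_lr <- function(g) {
  m <- length(g)
  cs <- cumsum(g); cs2 <- cumsum(g^2)
  tot <- cs[m]; tot2 <- cs2[m]
  rss0 <- tot2 - tot^2 / m
  ks <- seq_len(m - 1)
  r1 <- (cs2[ks] - cs[ks]^2 / ks) +
    ((tot2 - cs2[ks]) - (tot - cs[ks])^2 / (m - ks))
  stat <- m * log(rss0 / pmax(r1, 1e-300))
  k <- which.max(stat)
  list(stat = stat[k], k = k, rss0 = rss0)
}

# Monte-Carlo null quantile of the calibrated statistic for n Gaussian
# scores; internally seeded so results do not depend on the caller's RNG.
calibrate_amoc_penalty <- function(n, alpha = 0.05, n_sim = 200L) {
  stats <- with_local_seed(derive_seed(760813L, paste0("amoc", n)), {
    replicate(n_sim, amoc_scan_calibrated(diff(sort(rnorm(n))))$stat)
  })
  unname(quantile(stats, 1 - alpha, type = 7))
}

#' Detect epigenetic outlier samples along PC1 (AMOC changepoint)
#'
#' Sorts the PC1 scores, computes the n-1 consecutive gap sizes, and tests
#' for a single mean shift ("at most one change") in the gap sequence. When
#' the best split exceeds the penalty, the gap bordering the elevated segment
#' is taken as the separator and the samples strictly beyond it, on the side
#' with fewer samples, are declared outliers. An interior separator leaving
#' both sides with at least half the samples declares none.
#'
#' Two methods are provided. `"calibrated"` (default) scores splits by the
#' reduction in squared error scaled by a robust (MAD-based) gap-scale
#' estimate, against a Monte-Carlo penalty calibrated to the spacings of n
#' sorted Gaussian scores at level `alpha` (default 0.02, a conservative
#' false-alarm budget of about one declared outlier set per fifty homogeneous
#' cohorts); this accounts for the natural
#' widening of extreme-order-statistic gaps, which would otherwise be flagged
#' in perfectly homogeneous cohorts. `"lr"` is the plain pooled-variance
#' Gaussian likelihood-ratio with an MBIC-style `3 ln(n-1)` default penalty,
#' the textbook single-changepoint recipe; it is kept for comparison but has
#' essentially no specificity on spacing data (see the package vignette).
#'
#' @param pc1 numeric PC1 scores, one per sample (length >= 4).
#' @param sample_ids optional identifiers (defaults to names or indices).
#' @param method `"calibrated"` or `"lr"`.
#' @param penalty numeric penalty override; by default the calibrated null
#'   quantile (`"calibrated"`) or `3 * log(n - 1)` (`"lr"`).
#' @param alpha calibration level for the default calibrated penalty.
#' @param n_sim Monte-Carlo replicates for calibration.
#' @return An `OutlierReport` list: `pc1`, `order` (ids sorted by score),
#'   `gaps`, `changepoint` (separator gap index or `NA`), `stat`,
#'   `penalty_used`, `method`, `outlier_ids`, `side` (`"low"`, `"high"`,
#'   `"none"`), `interior` flag.
#' @export
detect_outliers_amoc <- function(pc1, sample_ids = NULL,
                                 method = c("calibrated", "lr"),
                                 penalty = NULL, alpha = 0.02,
                                 n_sim = 200L) {
  method <- match.arg(method)
  n <- length(pc1)
  if (n < 4) stop("changepoint outlier detection needs at least 4 samples")
  if (is.null(sample_ids))
    sample_ids <- if (!is.null(names(pc1))) names(pc1) else as.character(seq_len(n))
  o <- order(pc1)
  g <- unname(diff(pc1[o]))
  m <- length(g)
  report <- list(pc1 = pc1, order = sample_ids[o], gaps = g,
                 changepoint = NA_integer_, stat = NA_real_,
                 penalty_used = NA_real_, method = method,
                 outlier_ids = character(0), side = "none", interior = FALSE)
  class(report) <- "OutlierReport"
  if (all(abs(g - g[1]) < 1e-12)) {
    # evenly spaced scores: zero cost reduction, nothing to detect
    report$penalty_used <- if (is.null(penalty)) NA_real_ else penalty
    return(report)
  }
  scan <- if (method == "calibrated") amoc_scan_calibrated(g) else amoc_scan_lr(g)
  if (is.null(penalty))
    penalty <- if (method == "calibrated")
      calibrate_amoc_penalty(n, alpha = alpha, n_sim = n_sim)
    else 3 * log(m)
  report$stat <- scan$stat
  report$penalty_used <- penalty
  if (!(scan$rss0 > 0) || scan$stat <= penalty) return(report)
  k <- scan$k
  left_mean <- mean(g[seq_len(k)])
  right_mean <- mean(g[(k + 1):m])
  # separator gap borders the elevated segment
  j <- if (right_mean > left_mean) k + 1L else k
  n_low <- j          # samples 1..j sit at/below the separator gap
  n_high <- n - j
  report$changepoint <- j
  if (min(n_low, n_high) >= n / 2) {
    report$interior <- TRUE
    return(report)
  }
  if (n_low < n_high) {
    report$side <- "low"
    report$outlier_ids <- sample_ids[o][seq_len(j)]
  } else {
    report$side <- "high"
    report$outlier_ids <- sample_ids[o][(j + 1):n]
  }
  report
}

#' @export
print.OutlierReport <- function(x, ...) {
  cat(sprintf("AMOC outlier report (%s): %d samples, stat %.2f vs penalty %.2f\n",
              x$method, length(x$pc1), x$stat, x$penalty_used))
  if (length(x$outlier_ids))
    cat("  outliers (", x$side, " side): ",
        paste(x$outlier_ids, collapse = ", "), "\n", sep = "")
  else cat("  no outliers declared\n")
  invisible(x)
}

#' Outlier enrichment by a sample factor
#'
#' Two-sided Fisher exact test of the outlier x factor 2x2 table (e.g. is the
#' case group, or one sex, over-represented among detected outliers).
#'
#' @param outlier_ids detected outlier sample identifiers.
#' @param samples sample sheet.
#' @param factor column name, `"group"` or `"sex"` (any 2-level column).
#' @return list: `table`, `p`, `degenerate` (TRUE when no outliers, p = 1 by
#'   convention).
#' @export
outlier_enrichment <- function(outlier_ids, samples, factor = "group") {
  stopifnot(all(outlier_ids %in% samples$sample_id))
  f <- as.factor(samples[[factor]])
  if (nlevels(f) != 2) stop("factor must have exactly two levels")
  is_out <- samples$sample_id %in% outlier_ids
  tab <- table(outlier = factor(is_out, levels = c(FALSE, TRUE)), level = f)
  if (length(outlier_ids) == 0)
    return(list(table = tab, p = 1, degenerate = TRUE))
  list(table = tab, p = fisher_exact_2x2(unclass(tab))$p, degenerate = FALSE)
}
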