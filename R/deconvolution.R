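#' Select and impute reference-panel CpGs from a methylome matrix
#'
#' Intersects the matrix sites with the panel's marker CpGs, keeps marker
#' CpGs that are non-missing in at least `min_frac` of the samples (default
#' 90%), and imputes each remaining missing beta with the mean beta of all
#' other samples at that CpG. Marker CpGs missing in every sample are dropped
#' before imputation.
#'
#' @param x a filtered `MethylomeMatrix`.
#' @param panel a `ReferencePanel`.
#' @param min_frac minimum fraction of samples with data per marker CpG.
#' @return list with `beta` (complete marker x sample beta matrix) and
#'   `panel` (the matching subset of the reference panel).
#' @export
select_panel_sites <- function(x, panel, min_frac = 0.9) {
  key_m <- paste(x$sites$chrom, x$sites$pos)
  key_p <- paste(panel$cpgs$chrom, panel$cpgs$pos)
  hit <- match(key_p, key_m)
  if (all(is.na(hit)))
    stop("no overlap between matrix sites and panel CpGs; check that the ",
         "panel and methylome use the same genome build and coordinates")
  keep_p <- which(!is.na(hit))
  B <- beta_values(x)[hit[keep_p], , drop = FALSE]
  nn <- rowSums(!is.na(B))
  ok <- nn > 0 & (nn / ncol(B)) >= min_frac
  B <- B[ok, , drop = FALSE]
  keep_p <- keep_p[ok]
  # mean-of-other-samples imputation
  if (anyNA(B)) {
    rm <- rowMeans(B, na.rm = TRUE)
    idx <- which(is.na(B), arr.ind = TRUE)
    B[idx] <- rm[idx[, 1]]
  }
  sub <- panel
  sub$cpgs <- panel$cpgs[keep_p, , drop = FALSE]
  rownames(sub$cpgs) <- NULL
  sub$profile <- panel$profile[keep_p, , drop = FALSE]
  sub$marker_index <- NULL
  list(beta = B, panel = sub)
}

#' Estimate cell-type proportions by nonnegative least squares
#'
#' Projects each sample's marker-CpG beta vector onto the reference profiles:
#' per sample, solves `min ||y - X w||_2` subject to `w >= 0` (Lawson-Hanson
#' NNLS), where `X` is the panel's CpG x cell-type fraction matrix. Estimates
#' are not renormalized to sum to one unless `normalize = TRUE`; the raw
#' projections are what enter downstream models as covariates.
#'
#' @param beta complete marker x sample beta matrix (from
#'   [select_panel_sites()]).
#' @param panel the matching `ReferencePanel`.
#' @param normalize rescale each sample's proportions to sum to 1.
#' @return data.frame with `sample_id`, one column per cell type, and
#'   `residual_norm`.
#' @export
estimate_proportions <- function(beta, panel, normalize = FALSE) {
  X <- panel$profile
  stopifnot(nrow(X) == nrow(beta))
  if (qr(X)$rank < ncol(X))
    warning("reference panel profile is rank deficient; ",
            "proportion estimates may not be unique")
  res <- vapply(seq_len(ncol(beta)), function(j) {
    fit <- pracma::lsqnonneg(X, beta[, j])
    c(fit$x, sqrt(max(fit$resid.norm, 0)))
  }, numeric(ncol(X) + 1L))
  w <- t(res[seq_len(ncol(X)), , drop = FALSE])
  rn <- res[ncol(X) + 1L, ]
  if (normalize) {
    s <- rowSums(w)
    w[s > 0, ] <- w[s > 0, , drop = FALSE] / s[s > 0]
  }
  out <- data.frame(sample_id = colnames(beta), w, residual_norm = rn,
                    stringsAsFactors = FALSE)
  names(out)[1 + seq_len(ncol(X))] <- panel$cell_types
  rownames(out) <- NULL
  out
}

#' One-call cord-blood deconvolution
#'
#' Convenience wrapper: [select_panel_sites()] then [estimate_proportions()].
#'
#' @inheritParams select_panel_sites
#' @inheritParams estimate_proportions
#' @return As [estimate_proportions()].
#' @export
deconvolve_cells <- function(x, panel, min_frac = 0.9, normalize = FALSE) {
  sel <- select_panel_sites(x, panel, min_frac = min_frac)
  estimate_proportions(sel$beta, sel$panel, normalize = normalize)
}
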