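#' Merge DMCs into differentially methylated regions (DMRs)
#'
#' Single left-to-right pass per chromosome and direction: a chain is
#' extended while the next DMC of the same direction lies within `gap` base
#' pairs (positional difference, inclusive) of the current one. Chains with
#' two or more DMCs become DMRs; chains of one remain singletons. Hypo- and
#' hypermethylated DMCs are merged separately and never joined. Region size
#' is `end - start + 2`, spanning the trailing CpG dinucleotide.
#'
#' @param dmcs data.frame with columns `chrom`, `pos`, `direction`,
#'   `meth_diff`, sorted by (chrom, pos).
#' @param gap maximum distance between consecutive member DMCs (default 250).
#' @return list with `dmrs` (chrom, start, end, n_dmcs, direction, size_bp,
#'   mean_diff), `singletons` (the unmerged DMC rows), and `summary`
#'   (counts, mean sizes with and without singletons, per-DMR DMC counts).
#' @export
merge_dmrs <- function(dmcs, gap = 250L) {
  req <- c("chrom", "pos", "direction", "meth_diff")
  stopifnot(all(req %in% names(dmcs)))
  if (nrow(dmcs) > 1) {
    r <- chrom_rank(dmcs$chrom)
    if (any(diff(r) < 0 | (diff(r) == 0 & diff(dmcs$pos) <= 0)))
      stop("DMCs must be sorted by (chrom, pos) with no duplicates")
  }
  dmrs <- list(); single <- logical(nrow(dmcs))
  for (dir in unique(dmcs$direction)) {
    idx <- which(dmcs$direction == dir)
    if (length(idx) == 0) next
    ch <- dmcs$chrom[idx]; po <- dmcs$pos[idx]
    newchain <- c(TRUE, ch[-1] != ch[-length(ch)] | diff(po) > gap)
    chain_id <- cumsum(newchain)
    for (cid in unique(chain_id)) {
      mem <- idx[chain_id == cid]
      if (length(mem) == 1L) {
        single[mem] <- TRUE
      } else {
        dmrs[[length(dmrs) + 1L]] <- data.frame(
          chrom = dmcs$chrom[mem[1]], start = dmcs$pos[mem[1]],
          end = dmcs$pos[mem[length(mem)]], n_dmcs = length(mem),
          direction = dir,
          size_bp = dmcs$pos[mem[length(mem)]] - dmcs$pos[mem[1]] + 2L,
          mean_diff = mean(dmcs$meth_diff[mem]), stringsAsFactors = FALSE)
      }
    }
  }
  dmr_df <- if (length(dmrs)) do.call(rbind, dmrs) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_dmcs = integer(), direction = character(),
               size_bp = integer(), mean_diff = numeric())
  dmr_df <- dmr_df[site_order(dmr_df$chrom, dmr_df$start), , drop = FALSE]
  rownames(dmr_df) <- NULL
  singles <- dmcs[single, , drop = FALSE]
  rownames(singles) <- NULL
  list(dmrs = dmr_df, singletons = singles,
       summary = list(
         n_dmrs = nrow(dmr_df), n_singletons = nrow(singles),
         n_dmcs_in_dmrs = sum(dmr_df$n_dmcs),
         mean_size_bp = if (nrow(dmr_df)) mean(dmr_df$size_bp) else NA_real_,
         mean_size_bp_with_singletons =
           if (nrow(dmr_df) + nrow(singles))
             mean(c(dmr_df$size_bp, rep(2L, nrow(singles)))) else NA_real_,
         dmc_count_table = if (nrow(dmr_df)) table(dmr_df$n_dmcs) else table(integer())))
}

#' Annotate CpG sites against interval families
#'
#' Assigns each site one category per annotation family (e.g. genic context,
#' CpG context, repeat class) by user-declared precedence; sites overlapping
#' nothing in a family receive that family's fallback (the last element of
#' its precedence vector). Overlapping categories absent from the precedence
#' list are an error.
#'
#' @param sites data.frame with `chrom`, `pos` (1-based CpG positions).
#' @param annotations named list of `RegionSet`s, one per family.
#' @param precedence named list of character vectors (same names as
#'   `annotations`): category order from highest precedence to the fallback.
#' @return list with `per_site` (data.frame: chrom, pos, one column per
#'   family) and `counts` (named list of per-family category count tables,
#'   each summing to `nrow(sites)`).
#' @export
annotate_sites <- function(sites, annotations, precedence) {
  stopifnot(is.list(annotations), is.list(precedence),
            all(names(annotations) %in% names(precedence)))
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, sites$pos))
  per <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    stringsAsFactors = FALSE)
  counts <- list()
  for (fam in names(annotations)) {
    rs <- annotations[[fam]]
    prec <- precedence[[fam]]
    fallback <- prec[length(prec)]
    cat_assigned <- rep(fallback, nrow(sites))
    if (nrow(rs) > 0) {
      seen <- unique(rs$category)
      unknown <- setdiff(seen, prec)
      if (length(unknown))
        stop(sprintf("family '%s': categories without precedence entry: %s",
                     fam, paste(unknown, collapse = ", ")))
      hits <- GenomicRanges::findOverlaps(gr, regions_granges(rs))
      if (length(hits)) {
        qi <- S4Vectors::queryHits(hits)
        cat_hit <- rs$category[S4Vectors::subjectHits(hits)]
        rank_hit <- match(cat_hit, prec)
        best <- tapply(rank_hit, qi, min)
        cat_assigned[as.integer(names(best))] <- prec[best]
      }
    }
    per[[fam]] <- cat_assigned
    counts[[fam]] <- table(factor(cat_assigned, levels = prec))
  }
  list(per_site = per, counts = counts)
}

#' Enrichment of a category in a foreground vs background site set
#'
#' Yates-corrected chi-square on the 2x2 table `[[k, n-k], [K, N-K]]`
#' (foreground in/out of category vs background in/out). Direction is
#' reported as enriched when `k/n > K/N`, depleted when smaller.
#'
#' @param k,n foreground sites in category / total foreground sites.
#' @param K,N background sites in category / total background sites.
#' @param yates apply the continuity correction (default TRUE).
#' @return list: `chi2`, `df`, `p`, `direction` (`"enriched"`, `"depleted"`,
#'   `"none"`), `fg_frac`, `bg_frac`, `degenerate`.
#' @export
enrichment_test <- function(k, n, K, N, yates = TRUE) {
  stopifnot(k >= 0, K >= 0, k <= n, K <= N, n > 0, N > 0)
  tab <- matrix(c(k, n - k, K, N - K), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(chi2 = NA_real_, df = 1L, p = NA_real_, direction = "none",
                fg_frac = k / n, bg_frac = K / N, degenerate = TRUE))
  ct <- suppressWarnings(chisq.test(tab, correct = yates))
  dir <- if (k / n > K / N) "enriched" else if (k / n < K / N) "depleted" else "none"
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, direction = dir, fg_frac = k / n, bg_frac = K / N,
       degenerate = FALSE)
}
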