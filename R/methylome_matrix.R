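#' Construct a methylome count matrix
#'
#' The central data object of the pipeline: per-CpG, per-sample methylated and
#' total read counts from targeted bisulfite sequencing, with missingness
#' encoded as `NA` in both count matrices. Positions are 1-based coordinates of
#' the C of the CpG dinucleotide on the forward strand, with counts assumed
#' pre-merged across strands. Sites are stored sorted by chromosome then
#' position and must be unique.
#'
#' @param chrom character vector of chromosome names (one per site).
#' @param pos integer vector of 1-based positions.
#' @param M numeric matrix (sites x samples) of methylated read counts.
#' @param Tt numeric matrix (sites x samples) of total read counts. `NA`
#'   marks a missing cell; `M` must be `NA` at exactly the same cells.
#' @param samples character vector of sample identifiers (columns).
#' @return An object of class `MethylomeMatrix`: a list with elements
#'   `sites` (data.frame `chrom`, `pos`), `samples`, `M`, `Tt`.
#' @export
methylome_matrix <- function(chrom, pos, M, Tt, samples) {
  M <- as.matrix(M); Tt <- as.matrix(Tt)
  stopifnot(length(chrom) == length(pos), nrow(M) == length(pos),
            ncol(M) == length(samples), dim(M)[1] == dim(Tt)[1],
            dim(M)[2] == dim(Tt)[2])
  if (anyDuplicated(samples)) stop("duplicate sample identifiers")
  ord <- site_order(chrom, pos)
  chrom <- as.character(chrom)[ord]; pos <- as.integer(pos)[ord]
  M <- M[ord, , drop = FALSE]; Tt <- Tt[ord, , drop = FALSE]
  if (anyDuplicated(paste(chrom, pos))) {
    i <- which(duplicated(paste(chrom, pos)))[1]
    stop(sprintf("duplicate site %s:%d", chrom[i], pos[i]))
  }
  if (any(pos < 1L)) stop("positions must be >= 1")
  dimnames(M) <- dimnames(Tt) <- list(NULL, samples)
  obj <- structure(list(sites = data.frame(chrom = chrom, pos = pos,
                                           stringsAsFactors = FALSE),
                        samples = as.character(samples), M = M, Tt = Tt),
                   class = "MethylomeMatrix")
  validate_methylome_matrix(obj)
  obj
}

validate_methylome_matrix <- function(x, line_offset = 0L) {
  bad_mask <- xor(is.na(x$M), is.na(x$Tt))
  if (any(bad_mask)) {
    idx <- which(bad_mask, arr.ind = TRUE)[1, ]
    stop(sprintf("inconsistent missingness at %s:%d, sample %s (line %d)",
                 x$sites$chrom[idx[1]], x$sites$pos[idx[1]],
                 x$samples[idx[2]], idx[1] + line_offset))
  }
  neg <- which(x$M < 0 | x$Tt < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    i <- neg[1, ]
    stop(sprintf("negative count at %s:%d, sample %s (line %d)",
                 x$sites$chrom[i[1]], x$sites$pos[i[1]],
                 x$samples[i[2]], i[1] + line_offset))
  }
  over <- which(x$M > x$Tt, arr.ind = TRUE)
  if (nrow(over) > 0) {
    i <- over[1, ]
    stop(sprintf(
      "methylated count exceeds total (m=%g > t=%g) at %s:%d, sample %s (line %d)",
      x$M[i[1], i[2]], x$Tt[i[1], i[2]], x$sites$chrom[i[1]],
      x$sites$pos[i[1]], x$samples[i[2]], i[1] + line_offset))
  }
  invisible(x)
}

#' @export
print.MethylomeMatrix <- function(x, ...) {
  cat(sprintf("MethylomeMatrix: %d CpG sites x %d samples (%.1f%% missing)\n",
              nrow(x$M), ncol(x$M), 100 * mean(is.na(x$Tt))))
  invisible(x)
}

#' @export
dim.MethylomeMatrix <- function(x) dim(x$M)

# sites as 1-bp GRanges
sites_granges <- function(x) {
  GenomicRanges::GRanges(x$sites$chrom,
                         IRanges::IRanges(x$sites$pos, x$sites$pos))
}

#' Subset a methylome matrix by site
#'
#' @param x a `MethylomeMatrix`.
#' @param keep logical or integer site index.
#' @return The subsetted `MethylomeMatrix` (site order preserved).
#' @export
subset_sites <- function(x, keep) {
  x$sites <- x$sites[keep, , drop = FALSE]
  rownames(x$sites) <- NULL
  x$M <- x$M[keep, , drop = FALSE]
  x$Tt <- x$Tt[keep, , drop = FALSE]
  x
}

#' Read a methylome count matrix from TSV
#'
#' Expected layout: columns `chrom`, `pos` (1-based), then one `<sample>_m`,
#' `<sample>_t` pair per sample. Empty fields or `NA` encode missing cells.
#'
#' @param path file path.
#' @return A [methylome_matrix()] object.
#' @export
read_methylome_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""), data.table = FALSE)
  if (!all(c("chrom", "pos") %in% names(dt)))
    stop("matrix TSV must have 'chrom' and 'pos' columns")
  cn <- setdiff(names(dt), c("chrom", "pos"))
  msuf <- grepl("_m$", cn); tsuf <- grepl("_t$", cn)
  if (!all(msuf | tsuf)) stop("sample columns must end in _m or _t")
  samples <- sub("_m$", "", cn[msuf])
  if (!setequal(sub("_t$", "", cn[tsuf]), samples))
    stop("every sample needs both an _m and a _t column")
  M <- as.matrix(dt[paste0(samples, "_m")])
  Tt <- as.matrix(dt[paste0(samples, "_t")])
  if (nrow(dt) > 1) {
    r <- chrom_rank(dt$chrom)
    dup <- diff(r) == 0 & diff(dt$pos) == 0
    bad <- diff(r) < 0 | (diff(r) == 0 & diff(dt$pos) < 0)
    if (any(dup)) {
      i <- which(dup)[1] + 1L
      stop(sprintf("duplicate site at line %d (%s:%d)", i + 1L, dt$chrom[i], dt$pos[i]))
    }
    if (any(bad)) {
      i <- which(bad)[1] + 1L
      stop(sprintf("sites not sorted by (chrom, pos): first offence at line %d (%s:%d)",
                   i + 1L, dt$chrom[i], dt$pos[i]))
    }
  }
  obj <- structure(list(sites = data.frame(chrom = as.character(dt$chrom),
                                           pos = as.integer(dt$pos),
                                           stringsAsFactors = FALSE),
                        samples = samples,
                        M = `dimnames<-`(M, list(NULL, samples)),
                        Tt = `dimnames<-`(Tt, list(NULL, samples))),
                   class = "MethylomeMatrix")
  # +1 for the header so reported line numbers match the file
  validate_methylome_matrix(obj, line_offset = 1L)
  obj
}

#' Write a methylome count matrix to TSV
#'
#' Inverse of [read_methylome_matrix()]; missing cells are written as `NA`.
#'
#' @param x a `MethylomeMatrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_methylome_matrix <- function(x, path) {
  out <- data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
                    check.names = FALSE)
  for (s in x$samples) {
    out[[paste0(s, "_m")]] <- x$M[, s]
    out[[paste0(s, "_t")]] <- x$Tt[, s]
  }
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Create a named set of genomic intervals
#'
#' Intervals use BED semantics: 0-based, half-open `[start, end)`.
#'
#' @param name label for the set.
#' @param chrom,start,end interval coordinates (BED semantics).
#' @param category optional per-interval category label; defaults to `name`.
#' @return A `RegionSet`: data.frame with attribute `name`.
#' @export
region_set <- function(name, chrom, start, end, category = NULL) {
  if (length(chrom) && any(start >= end)) stop("BED intervals need start < end")
  if (is.null(category)) category <- rep(name, length(chrom))
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), category = as.character(category),
                   stringsAsFactors = FALSE)
  df <- df[site_order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, name = name, class = c("RegionSet", "data.frame"))
}

#' Read a BED file into a RegionSet
#'
#' @param path BED file (chrom, start, end, optional name column used as the
#'   per-interval category).
#' @param name label for the set; defaults to the file name.
#' @return A [region_set()].
#' @export
read_bed <- function(path, name = basename(path)) {
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (ncol(dt) < 3) stop("BED needs at least 3 columns")
  cat_col <- if (ncol(dt) >= 4) as.character(dt[[4]]) else NULL
  region_set(name, dt[[1]], dt[[2]], dt[[3]], cat_col)
}

#' Write a RegionSet as BED
#' @param x a `RegionSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  data.table::fwrite(as.data.frame(x)[c("chrom", "start", "end", "category")],
                     path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

regions_granges <- function(rs) {
  # BED half-open [start, end) -> 1-based closed [start+1, end]
  GenomicRanges::GRanges(rs$chrom, IRanges::IRanges(rs$start + 1L, rs$end),
                         category = rs$category)
}

#' Remove CpG sites overlapping exclusion intervals
#'
#' Drops every site whose single-bp position falls in any interval of any
#' exclusion set (e.g. SNP positions, ENCODE blacklisted regions). Site order
#' is preserved.
#'
#' @param x a `MethylomeMatrix`.
#' @param exclusions a `RegionSet` or list of `RegionSet`s.
#' @return The filtered `MethylomeMatrix`.
#' @export
apply_site_exclusions <- function(x, exclusions) {
  if (inherits(exclusions, "RegionSet")) exclusions <- list(exclusions)
  if (length(exclusions) == 0) return(x)
  gr <- sites_granges(x)
  drop <- rep(FALSE, nrow(x$M))
  for (ex in exclusions) {
    if (nrow(ex) == 0) next
    drop <- drop | IRanges::overlapsAny(gr, regions_granges(ex))
  }
  subset_sites(x, !drop)
}

#' Coverage filter configuration
#'
#' Defaults reproduce the study's retention funnel: per-sample coverage within
#' \[15, 500\] reads (inclusive on both ends), sites kept only when covered in
#' at least 30 samples, and sex chromosomes removed.
#'
#' @param min_cov,max_cov inclusive per-cell total-read bounds.
#' @param min_samples minimum number of non-missing samples per site.
#' @param autosomes_only drop chrX/chrY sites.
#' @return A `FilterConfig` list.
#' @export
filter_config <- function(min_cov = 15L, max_cov = 500L, min_samples = 30L,
                          autosomes_only = TRUE) {
  stopifnot(min_cov >= 1, min_cov <= max_cov, min_samples >= 1)
  structure(list(min_cov = as.integer(min_cov), max_cov = as.integer(max_cov),
                 min_samples = as.integer(min_samples),
                 autosomes_only = isTRUE(autosomes_only)),
            class = "FilterConfig")
}

#' Apply the coverage/retention filter
#'
#' In order: (1) mask (set missing) every cell whose total coverage is below
#' `min_cov` or above `max_cov`; (2) drop sites left with fewer than
#' `min_samples` non-missing cells; (3) drop sex-chromosome sites when
#' `autosomes_only`. The operation is idempotent and monotone in its
#' thresholds.
#'
#' @param x a `MethylomeMatrix`.
#' @param cfg a [filter_config()].
#' @return The filtered `MethylomeMatrix`.
#' @export
apply_coverage_filter <- function(x, cfg = filter_config()) {
  stopifnot(inherits(cfg, "FilterConfig"))
  mask <- !is.na(x$Tt) & (x$Tt < cfg$min_cov | x$Tt > cfg$max_cov)
  x$M[mask] <- NA
  x$Tt[mask] <- NA
  keep <- rowSums(!is.na(x$Tt)) >= cfg$min_samples
  if (cfg$autosomes_only) keep <- keep & !is_sex_chrom(x$sites$chrom)
  subset_sites(x, keep)
}

#' Cumulative site counts by per-site sample coverage
#'
#' For each k from 1 to the number of samples, counts sites that are
#' non-missing in at least k samples (a cumulative distribution of per-site
#' sample support, monotone non-increasing in k).
#'
#' @param x a `MethylomeMatrix`.
#' @return data.frame with columns `k` and `n_sites`.
#' @export
coverage_cdf <- function(x) {
  n <- length(x$samples)
  supp <- rowSums(!is.na(x$Tt))
  data.frame(k = seq_len(n),
             n_sites = vapply(seq_len(n), function(k) sum(supp >= k), 0L))
}

#' Per-cell methylation fractions (beta values)
#'
#' beta = methylated / total per (site, sample); missing cells propagate as
#' `NA`. A non-missing cell with zero total coverage is an error.
#'
#' @param x a `MethylomeMatrix`.
#' @return numeric matrix (sites x samples) of fractions in \[0, 1\].
#' @export
beta_values <- function(x) {
  zero <- which(!is.na(x$Tt) & x$Tt == 0, arr.ind = TRUE)
  if (nrow(zero) > 0) {
    i <- zero[1, ]
    stop(sprintf("zero total coverage at non-missing cell %s:%d, sample %s",
                 x$sites$chrom[i[1]], x$sites$pos[i[1]], x$samples[i[2]]))
  }
  x$M / x$Tt
}
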