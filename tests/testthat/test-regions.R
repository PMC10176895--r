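dmc_df <- function(pos, direction, chrom = "chr1", diff = NULL) {
  if (is.null(diff)) diff <- ifelse(direction == "hyper", 0.1, -0.1)
  df <- data.frame(chrom = chrom, pos = as.integer(pos),
                   direction = direction, meth_diff = diff,
                   stringsAsFactors = FALSE)
  df[order(methcapdm:::chrom_rank(df$chrom), df$pos), , drop = FALSE]
}

# independent oracle: connected components over edges between sorted
# neighbouring same-direction DMCs at distance <= gap (igraph)
merge_oracle <- function(dmcs, gap = 250) {
  out <- list()
  for (dir in unique(dmcs$direction)) {
    sub <- dmcs[dmcs$direction == dir, , drop = FALSE]
    for (ch in unique(sub$chrom)) {
      po <- sort(sub$pos[sub$chrom == ch])
      if (length(po) == 1) { out[[length(out) + 1]] <- list(ch, dir, po); next }
      g <- igraph::make_empty_graph(n = length(po), directed = FALSE)
      close_pairs <- which(diff(po) <= gap)
      if (length(close_pairs))
        g <- igraph::add_edges(g, rbind(close_pairs, close_pairs + 1))
      comp <- igraph::components(g)$membership
      for (cid in unique(comp))
        out[[length(out) + 1]] <- list(ch, dir, po[comp == cid])
    }
  }
  out
}

partition_key <- function(chunks) {
  sort(vapply(chunks, function(x)
    paste(x[[1]], x[[2]], paste(x[[3]], collapse = ","), sep = "|"), ""))
}

test_that("the 250-bp same-direction rule merges exactly as forced by the
           worked example", {
  res <- merge_dmrs(dmc_df(c(100, 300, 600), rep("hypo", 3)))
  expect_equal(nrow(res$dmrs), 1)
  expect_equal(res$dmrs$start, 100L)
  expect_equal(res$dmrs$end, 300L)
  expect_equal(res$dmrs$n_dmcs, 2L)
  expect_equal(res$dmrs$size_bp, 202L)
  expect_equal(res$singletons$pos, 600L)

  # opposite directions never merge
  res2 <- merge_dmrs(dmc_df(c(100, 150), c("hypo", "hyper")))
  expect_equal(nrow(res2$dmrs), 0)
  expect_equal(nrow(res2$singletons), 2)

  # boundary: exactly 250 apart merges, 251 does not
  expect_equal(nrow(merge_dmrs(dmc_df(c(100, 350), rep("hypo", 2)))$dmrs), 1)
  expect_equal(nrow(merge_dmrs(dmc_df(c(100, 351), rep("hypo", 2)))$dmrs), 0)

  expect_error(merge_dmrs(data.frame(chrom = "chr1", pos = c(5L, 1L),
                                     direction = "hypo", meth_diff = -1)),
               "sorted")
})

test_that("merging matches the graph-components oracle on random layouts and
           conserves every DMC", {
  set.seed(20)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    pos <- sort(sample.int(5000, n))
    dirs <- sample(c("hypo", "hyper"), n, TRUE)
    chrom <- sample(c("chr1", "chr2"), n, TRUE)
    df <- dmc_df(pos, dirs, chrom = chrom)
    df <- df[!duplicated(df[c("chrom", "pos")]), ]
    res <- merge_dmrs(df)
    # conservation
    expect_equal(sum(res$dmrs$n_dmcs) + nrow(res$singletons), nrow(df))
    # compare partitions against the oracle
    oracle <- merge_oracle(df)
    got <- list()
    for (j in seq_len(nrow(res$dmrs))) {
      r <- res$dmrs[j, ]
      members <- df$pos[df$chrom == r$chrom & df$direction == r$direction &
                          df$pos >= r$start & df$pos <= r$end]
      got[[length(got) + 1]] <- list(r$chrom, r$direction, members)
      expect_gte(length(members), 2)
      expect_true(all(diff(members) <= 250))
    }
    for (j in seq_len(nrow(res$singletons))) {
      s <- res$singletons[j, ]
      got[[length(got) + 1]] <- list(s$chrom, s$direction, s$pos)
    }
    expect_equal(partition_key(got), partition_key(oracle))
  }
})

test_that("re-merging DMR member lists is idempotent", {
  set.seed(8)
  pos <- sort(sample.int(3000, 40))
  df <- dmc_df(pos, sample(c("hypo", "hyper"), 40, TRUE))
  res <- merge_dmrs(df)
  for (j in seq_len(nrow(res$dmrs))) {
    r <- res$dmrs[j, ]
    members <- df[df$chrom == r$chrom & df$direction == r$direction &
                    df$pos >= r$start & df$pos <= r$end, ]
    again <- merge_dmrs(members)
    expect_equal(nrow(again$dmrs), 1)
    expect_equal(again$dmrs$n_dmcs, r$n_dmcs)
    expect_equal(again$dmrs$start, r$start)
    expect_equal(again$dmrs$end, r$end)
  }
})

test_that("annotation assigns one category per family by precedence with a
           fallback, and counts are conserved", {
  sites <- data.frame(chrom = "chr1", pos = c(50L, 150L, 950L))
  genic <- region_set("genic", rep("chr1", 3), c(0L, 40L, 100L),
                      c(60L, 70L, 200L),
                      category = c("exon", "promoter", "intron"))
  ann <- annotate_sites(sites, list(genic = genic),
                        list(genic = c("promoter", "exon", "intron",
                                       "intergenic")))
  # site 50 overlaps exon [0,60) and promoter [40,70): promoter wins
  expect_equal(ann$per_site$genic, c("promoter", "intron", "intergenic"))
  expect_equal(sum(ann$counts$genic), nrow(sites))
  # a category missing from the precedence list is an error
  expect_error(
    annotate_sites(sites, list(genic = region_set("g", "chr1", 0L, 60L,
                                                  category = "utr")),
                   list(genic = c("promoter", "intergenic"))),
    "without precedence")
})

test_that("annotation counts match a quadratic overlap oracle", {
  set.seed(33)
  sites <- data.frame(chrom = "chr1", pos = sort(sample.int(2000, 80)))
  iv_start <- sort(sample.int(1900, 25))
  iv <- region_set("fam", rep("chr1", 25), iv_start,
                   iv_start + sample(10:120, 25, TRUE),
                   category = sample(c("a", "b", "c"), 25, TRUE))
  prec <- c("a", "b", "c", "none")
  ann <- annotate_sites(sites, list(fam = iv), list(fam = prec))
  brute <- vapply(sites$pos, function(p) {
    hit <- iv$category[iv$start < p & p <= iv$end]  # BED vs 1-based position
    if (length(hit) == 0) "none" else prec[min(match(hit, prec))]
  }, "")
  expect_equal(ann$per_site$fam, brute)
})

test_that("Yates-corrected enrichment reproduces the closed form", {
  e <- enrichment_test(10, 30, 20, 30)
  # N(|ad-bc|-N/2)^2 / (r1 r2 c1 c2) = 60*(300-30)^2/30^4 = 5.4
  expect_equal(e$chi2, 5.4, tolerance = 1e-12)
  expect_equal(e$p, 0.02013675, tolerance = 1e-6)
  expect_equal(e$direction, "depleted")

  eq <- enrichment_test(10, 30, 20, 60, yates = FALSE)
  expect_equal(eq$chi2, 0, tolerance = 1e-12)
  expect_equal(eq$direction, "none")

  tiny <- enrichment_test(2, 4, 5, 10)
  expect_gt(tiny$p, 0.5)

  degen <- enrichment_test(0, 5, 0, 10)
  expect_true(degen$degenerate)
})
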