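toy_anchors <- function(rank_b, chrom = "c1") {
  n <- length(rank_b)
  data.frame(gene_a = paste0(chrom, "_a", seq_len(n)),
             gene_b = paste0(chrom, "_b", seq_len(n)),
             chrom_a = chrom, chrom_b = chrom,
             pos_a = seq_len(n) * 1000, pos_b = rank_b * 1000,
             rank_a = seq_len(n), rank_b = rank_b, same_strand = TRUE)
}

test_that("chaining recovers forward and inverted collinear runs", {
  fw <- chainAnchors(toy_anchors(c(1, 2, 3)))
  expect_equal(nrow(fw$blocks), 1)
  expect_equal(fw$blocks$orientation, "forward")
  expect_equal(fw$blocks$n_anchors, 3)

  iv <- chainAnchors(toy_anchors(c(3, 2, 1)))
  expect_equal(nrow(iv$blocks), 1)
  expect_equal(iv$blocks$orientation, "inverted")

  dup <- rbind(toy_anchors(1:3), toy_anchors(1:3)[1, ])
  expect_error(chainAnchors(dup), "duplicate|one-to-one")
})

test_that("the chaining DP matches an exhaustive subset oracle", {
  withr::with_seed(53, {
    for (rep in 1:60) {
      n <- sample(2:10, 1)
      anc <- random_anchors(n)
      res <- chainAnchors(anc, maxRankGap = 10, minAnchors = 1)
      best_block <- max(res$blocks$n_anchors)
      oracle <- brute_force_best_chain(anc, maxRankGap = 10)
      expect_equal(best_block, oracle)
      total <- sum(res$blocks$n_anchors)
      expect_gte(total, oracle)
      # block anchor sets are disjoint
      assigned <- res$anchors$block_id[!is.na(res$anchors$block_id)]
      expect_equal(sum(res$blocks$n_anchors), length(assigned))
    }
  })
  # a tighter rank-gap cap is also honoured against the oracle
  withr::with_seed(59, {
    for (rep in 1:30) {
      anc <- random_anchors(sample(4:9, 1))
      res <- chainAnchors(anc, maxRankGap = 2, minAnchors = 1)
      expect_equal(max(res$blocks$n_anchors),
                   brute_force_best_chain(anc, maxRankGap = 2))
    }
  })
})

test_that("synteny coverage is a merged-bp percentage", {
  blocks <- data.frame(block_id = c("b1", "b2"), chrom_a = "c1",
                       chrom_b = "c1", orientation = "forward",
                       n_anchors = 3,
                       start_a = c(1, 400001), end_a = c(380000, 780000),
                       start_b = 1, end_b = 2)
  expect_equal(syntenyCoverage(blocks, c(c1 = 1e6)), 76)
  expect_equal(syntenyCoverage(blocks[0, ], c(c1 = 1e6)), 0)

  # overlapping blocks are not double-counted
  ov <- blocks
  ov$start_a <- c(1, 190001); ov$end_a <- c(380000, 380000)
  expect_equal(syntenyCoverage(ov, c(c1 = 1e6)), 38)
})

test_that("coverage is monotone in the rank-gap cap", {
  withr::with_seed(61, {
    anc <- random_anchors(30)
    covs <- vapply(c(1, 3, 10, 30), function(g) {
      syntenyCoverage(chainAnchors(anc, maxRankGap = g,
                                   minAnchors = 2)$blocks,
                      c(cA1 = 40000))
    }, numeric(1))
  })
  expect_true(all(diff(covs) >= 0))
  expect_true(all(covs >= 0 & covs <= 100))
})

test_that("breaks collect genes outside any block span", {
  blocks <- data.frame(block_id = c("b1", "b2"), chrom_a = "c1",
                       chrom_b = "c1", orientation = "forward",
                       n_anchors = 3,
                       start_a = c(100, 5000), end_a = c(1000, 9000),
                       start_b = 1, end_b = 2)
  inblock <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(c(150, 600, 5100), width = 100),
    gene_id = c("g1", "g2", "g3"))
  expect_length(findBreaks(blocks, inblock), 0)

  loose <- c(inblock, GenomicRanges::GRanges("c1",
    IRanges::IRanges(2000, width = 100), gene_id = "orphan"))
  br <- findBreaks(blocks, loose)
  expect_length(br, 1)
  expect_identical(br[["b1|b2"]], "orphan")

  tes <- c(inblock, GenomicRanges::GRanges("c1",
    IRanges::IRanges(c(2000, 2200, 12000), width = 50),
    gene_id = paste0("te", 1:3)))
  expect_equal(sum(lengths(findBreaks(blocks, tes))), 3)
})

test_that("region assignment partitions chromosomes into thirds by default", {
  r <- assignRegions(c(cI = 99))
  expect_equal(BiocGenerics::start(r), c(1, 34, 67))
  expect_equal(BiocGenerics::end(r), c(33, 66, 99))
  expect_equal(r$label, c("left_arm", "centre", "right_arm"))
  expect_equal(sum(BiocGenerics::width(r)), 99)

  bd <- data.frame(chrom = "cI", start = c(1, 21, 81),
                   end = c(20, 80, 99),
                   label = c("left_arm", "centre", "right_arm"))
  r2 <- assignRegions(c(cI = 99), bd)
  expect_equal(BiocGenerics::end(r2), c(20, 80, 99))

  bad <- bd; bad$end[1] <- 30
  expect_error(assignRegions(c(cI = 99), bad), "overlap")
  gap <- bd; gap$start[2] <- 30
  expect_error(assignRegions(c(cI = 99), gap), "partition")
})

test_that("dS contrasts use the Mann-Whitney U with the documented limits", {
  L <- 9000
  regions <- assignRegions(c(cI = L))
  mk <- function(ds_arm, ds_centre) {
    ids <- paste0("g", seq_len(length(ds_arm) + length(ds_centre)))
    pos <- c(seq(100, 2900, length.out = length(ds_arm)),
             seq(3100, 5900, length.out = length(ds_centre)))
    genes <- GenomicRanges::GRanges("cI",
      IRanges::IRanges(round(pos), width = 10), gene_id = ids)
    est <- data.frame(gene_id = ids, ds = c(ds_arm, ds_centre))
    list(est = est, genes = genes)
  }

  # identical groups: p = 1
  x <- mk(c(1, 2, 3), c(1, 2, 3))
  r <- compareRegionDs(x$est, x$genes, regions, "arm_vs_centre")
  expect_equal(r$p_value, 1.0)

  # {1,2,3} vs {4,5,6}: U = 0, exact two-sided p = 2/20
  y <- mk(c(1, 2, 3), c(4, 5, 6))
  r2 <- compareRegionDs(y$est, y$genes, regions, "arm_vs_centre")
  expect_equal(unname(r2$u_statistic), 0)
  expect_equal(r2$p_value, 0.1)
  expect_equal(unname(r2$medians), c(2, 5))
  expect_equal(unname(r2$n), c(3, 3))
})

test_that("X-versus-autosome grouping splits by chromosome name", {
  regions <- assignRegions(c(chrI = 9000, chrX = 9000))
  ids <- paste0("g", 1:8)
  genes <- GenomicRanges::GRanges(
    rep(c("chrI", "chrX"), each = 4),
    IRanges::IRanges(rep(seq(100, 6100, 2000), 2), width = 10),
    gene_id = ids)
  est <- data.frame(gene_id = ids, ds = c(5, 6, 7, 8, 1, 2, 3, 4))
  r <- compareRegionDs(est, genes, regions, "X_vs_autosome")
  expect_equal(unname(r$n), c(4, 4))
  expect_equal(unname(r$medians), c(2.5, 6.5))
  expect_lt(r$p_value, 0.05)
})

test_that("intergenic distances are computed per chromosome, floored at 0", {
  g <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1, 21), c(10, 30)),
                              gene_id = c("g1", "g2"))
  d <- intergenicDistances(g)
  expect_equal(d$distances$c1, 10)

  ov <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1, 5), c(10, 30)),
                               gene_id = c("g1", "g2"))
  expect_equal(intergenicDistances(ov)$distances$c1, 0)

  single <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 10),
                                   gene_id = "g1")
  expect_length(intergenicDistances(single)$distances$c1, 0)
})

test_that("k disjoint inversions produce k+1 blocks per chromosome", {
  withr::with_seed(67, {
    for (k in c(0, 1, 3)) {
      n <- 40
      # inversions of length 3..8 placed disjointly by hand
      starts <- c(5, 17, 29)[seq_len(k)]
      ends <- starts + sample(2:7, max(k, 1), replace = TRUE)[seq_len(k)]
      ord <- seq_len(n)
      for (i in seq_len(k)) ord[starts[i]:ends[i]] <- rev(ord[starts[i]:ends[i]])
      anc <- toy_anchors(order(ord))  # rank_b of gene i
      res <- chainAnchors(anc, maxRankGap = 10, minAnchors = 2)
      expect_equal(nrow(res$blocks), k + 1)
    }
  })
})
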