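small_params <- function(...) {
  simulationParams(nChromosomes = 2, genesPerChromosome = 12,
                   codonsPerGene = 120, targetTs = 0.2, nInversions = 1,
                   teSpec = c(full = 2, partial = 1, ltr_only = 1),
                   haplotypeSpec = list(n = 1, coverageFactor = 0.5,
                                        meanDepth = 60),
                   intergenicBp = 600, seed = 5, ...)
}

test_that("codon mutation is a no-op at zero rates and seed-deterministic", {
  cds <- random_cds(100)
  expect_identical(mutateCodonSequence(cds, 0, 0, seed = 1)$cds, cds)

  m1 <- mutateCodonSequence(cds, 0.3, 0.1, seed = 42)
  m2 <- mutateCodonSequence(cds, 0.3, 0.1, seed = 42)
  expect_identical(m1$cds, m2$cds)
  expect_identical(m1$s_subs, m2$s_subs)

  expect_error(mutateCodonSequence("ATGTAAGGG", 0.1, 0.1, seed = 1),
               "stop")
})

test_that("realised substitution counts match the requested rates", {
  withr::with_seed(71, {
    cds <- random_cds(10000)
  })
  m <- mutateCodonSequence(cds, ts = 0.1, tn = 0, seed = 7)
  expect_equal(m$n_subs, 0)
  # Poisson-ish count: mean ts * s_sites, check within 3 standard errors
  expected <- 0.1 * m$s_sites
  se <- sqrt(expected)
  expect_lt(abs(m$s_subs - expected), 3 * se)
  # NG86 on the pair recovers the synonymous divergence within 10%
  est <- estimateDsDn(CodonAlignment("g", cds, m$cds))
  expect_lt(abs(est$ds - 0.1) / 0.1, 0.10)
})

test_that("mutation never introduces stops and respects omega direction", {
  withr::with_seed(73, {
    cds <- random_cds(2000)
  })
  m <- mutateCodonSequence(cds, ts = 0.3, tn = 0.06, seed = 11)
  expect_error(regmatches(m$cds, regexpr("none", m$cds)), NA)
  idx <- seq(1, nchar(m$cds) - 2, 3)
  cods <- substring(m$cds, idx, idx + 2)
  expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
  # nonsynonymous events at a fifth of the synonymous rate per site
  expect_lt(m$n_subs / m$n_sites, m$s_subs / m$s_sites)
})

test_that("rearrangements are disjoint, logged, and absent when k = 0", {
  ord <- letters[1:12]
  r0 <- applyRearrangements(ord, 0, seed = 3)
  expect_identical(r0$order, ord)
  expect_equal(nrow(r0$log), 0)

  r <- applyRearrangements(ord, 3, seed = 3)
  expect_equal(nrow(r$log), 3)
  expect_true(all(r$log$end > r$log$start))           # >= 2 genes each
  expect_true(all(r$log$start[-1] > r$log$end[-3]))   # disjoint
  expect_setequal(r$order, ord)
  # applying the logged reversals again restores the original order
  back <- r$order
  for (k in seq_len(nrow(r$log))) {
    back[r$log$start[k]:r$log$end[k]] <- rev(back[r$log$start[k]:r$log$end[k]])
  }
  expect_identical(back, ord)

  expect_error(applyRearrangements(ord, 7, seed = 1), "disjoint")
})

test_that("simulation is fully deterministic under a fixed seed", {
  s1 <- simulateGenomePair(small_params())
  s2 <- simulateGenomePair(small_params())
  expect_identical(as.character(s1$assemblyA), as.character(s2$assemblyA))
  expect_identical(as.character(s1$cdsB), as.character(s2$cdsB))
  expect_identical(s1$truth$perGene, s2$truth$perGene)
  expect_identical(s1$coverage, s2$coverage)
})

test_that("zero divergence and zero rearrangement reproduce genome A in B", {
  p <- simulationParams(nChromosomes = 2, genesPerChromosome = 10,
                        codonsPerGene = 100, targetTs = 0, omega = 0,
                        nInversions = 0,
                        teSpec = c(full = 0, partial = 0, ltr_only = 0),
                        haplotypeSpec = list(n = 0, coverageFactor = 0.5,
                                             meanDepth = 60),
                        seed = 9)
  sim <- simulateGenomePair(p)
  expect_identical(unname(as.character(sim$cdsA)),
                   unname(as.character(sim$cdsB)))
  anch <- makeAnchors(sim$genesA, sim$genesB, sim$orthologs)
  ch <- chainAnchors(anch)
  expect_equal(nrow(ch$blocks), 2)  # one forward block per chromosome
  expect_true(all(ch$blocks$orientation == "forward"))
  expect_true(all(ch$blocks$n_anchors == 10))
})

test_that("unbiased codon usage yields Nc at the unbiased limit", {
  withr::with_seed(79, {
    nc <- vapply(1:10, function(i) computeNc(random_cds(350))$nc,
                 numeric(1))
  })
  expect_true(all(nc >= 59))
})

test_that("planted truth tables drive the downstream modules exactly", {
  sim <- simulateGenomePair(small_params())
  expect_equal(unname(table(factor(sim$teCandidates$true_class,
                                   c("full", "partial", "ltr_only")))),
               unname(c(full = 2L, partial = 1L, ltr_only = 1L)),
               ignore_attr = TRUE)
  cls <- classifyCandidates(sim$teCandidates, sim$teDomains)
  expect_identical(as.character(cls$class), cls$true_class)

  # planted haplotig is recovered by the residual-haplotype rule
  hap <- filterResidualHaplotypes(sim$assemblyA, sim$selfAlignments,
                                  sim$coverage)
  expect_identical(hap$removed, sim$truth$haplotigs)

  # inversion log matches the block structure: k+1 blocks per chromosome
  anch <- makeAnchors(sim$genesA, sim$genesB, sim$orthologs)
  ch <- chainAnchors(anch, minAnchors = 2)
  per_chr <- table(sim$truth$inversions$chrom)
  for (chr in names(per_chr)) {
    nb <- sum(ch$blocks$chrom_b == sub("^chr", "chr", chr) &
                ch$blocks$chrom_a == chr)
    expect_equal(nb, unname(per_chr[chr]) + 1)
  }
})

test_that("simulation writes standard formats that round-trip", {
  sim <- simulateGenomePair(small_params())
  dir <- tempfile("simout")
  writeSimulation(sim, dir)
  asm <- readAssembly(file.path(dir, "genomeA.fa"))
  expect_identical(as.character(asm), as.character(sim$assemblyA))
  genes <- readGeneModels(file.path(dir, "genesA.gff3"))
  expect_setequal(genes$gene_id, sim$genesA$gene_id)
  orth <- readOrthologTable(file.path(dir, "orthologs.tsv"))
  expect_equal(nrow(orth), nrow(sim$orthologs))
  cov <- readCoverageTrack(file.path(dir, "coverage.tsv"))
  expect_setequal(cov$scaffold, names(sim$assemblyA))
})

test_that("Nc calibration moves biased dS toward the unbiased value", {
  p <- simulationParams(nChromosomes = 2, genesPerChromosome = 40,
                        codonsPerGene = 200, targetTs = 0.4,
                        biasStrength = c(0, 0.8), nInversions = 0,
                        teSpec = c(full = 0, partial = 0, ltr_only = 0),
                        haplotypeSpec = list(n = 0, coverageFactor = 0.5,
                                             meanDepth = 60),
                        seed = 17)
  sim <- simulateGenomePair(p)
  est <- estimateDsDnMany(sim$orthologs$gene_a, sim$cdsA, sim$cdsB)
  adj <- ncAdjustDs(est)
  raw_med <- stats::median(est$ds)
  adj_med <- stats::median(adj$estimates$adjusted_ds)
  expect_gt(adj$slope, 0)              # bias suppresses dS, so dS rises with Nc
  expect_lt(raw_med, 0.4)              # graded bias pulls the median down
  expect_gt(adj_med, raw_med)          # calibration is upward
  expect_lt(abs(adj_med - 0.4), abs(raw_med - 0.4))  # and toward the truth
})
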