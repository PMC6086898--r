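test_that("codon alignments validate their invariants", {
  expect_error(CodonAlignment("g", "ATGTAAGGG", "ATGAAAGGG"), "stop")
  expect_error(CodonAlignment("g", "ATGA", "ATGA"), "multiple of 3")
  expect_error(CodonAlignment("g", "ATG", "ATGAAA"), "differ")
  aln <- CodonAlignment("g", "atgaaa", "ATGAAG")
  expect_equal(length(aln), 2L)
})

test_that("back-translation drops gap columns and strips terminal stops", {
  # identical 10-aa proteins -> 30 bp gap-free alignment
  cds <- "ATGGCTGGTACTCCAGTTAAAGATGAATTT"
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  aln <- buildCodonAlignment("g", prot, prot, cds, cds)
  expect_equal(nchar(aln@seqA), 30)
  expect_identical(aln@seqA, aln@seqB)

  # one gap column drops a whole codon; terminal stop is stripped
  protA <- paste0(substr(prot, 1, 5), "-", substr(prot, 6, 10))
  protB <- paste0(substr(prot, 1, 5), "K", substr(prot, 6, 10))
  cdsB <- paste0(substr(cds, 1, 15), "AAA", substr(cds, 16, 30), "TAA")
  aln2 <- buildCodonAlignment("g", protA, protB, cds, cdsB)
  expect_equal(nchar(aln2@seqA), 30)  # 11 cols - 1 gap col = 10 codons
  expect_identical(aln2@seqA, cds)

  # internal stop in a CDS is an error naming the residue
  cds_stop <- paste0(substr(cds, 1, 15), "TAA", substr(cds, 19, 30))
  expect_error(buildCodonAlignment("g", prot, prot, cds, cds_stop),
               "residue 6")
  # translation mismatch names the residue index
  expect_error(buildCodonAlignment("g", protA, sub("K", "E", protB),
                                   cds, cdsB), "residue")
})

test_that("NG86 reproduces hand-worked site and difference counts", {
  z <- estimateDsDn(CodonAlignment("id", "AAATTTGGG", "AAATTTGGG"))
  expect_equal(z$ds, 0)
  expect_equal(z$dn, 0)

  # single codon TTT vs TTA: hand enumeration gives s=0.5, n=2.5,
  # one nonsynonymous difference, pN = 0.4 -> dN = -3/4 log(1 - 4*0.4/3)
  z1 <- estimateDsDn(CodonAlignment("id", "TTT", "TTA"))
  expect_equal(z1$s_sites, 0.5, tolerance = 1e-12)
  expect_equal(z1$n_sites, 2.5, tolerance = 1e-12)
  expect_equal(z1$sd, 0)
  expect_equal(z1$nd, 1)
  expect_equal(z1$ds, 0)
  expect_equal(z1$dn, -0.75 * log(1 - 4 * 0.4 / 3), tolerance = 1e-6)

  # 30 GGT codons with a single synonymous change: pS = 1/30
  a <- strrep("GGT", 30)
  b <- paste0(strrep("GGT", 29), "GGC")
  z2 <- estimateDsDn(CodonAlignment("id", a, b))
  expect_equal(z2$s_sites, 30)
  expect_equal(z2$n_sites, 60)
  expect_equal(z2$ds, -0.75 * log(1 - 4 / (3 * 30)), tolerance = 1e-6)
  expect_equal(z2$dn, 0)
})

test_that("site counts always sum to 3 per codon and rates are symmetric", {
  withr::with_seed(29, {
    for (rep in 1:10) {
      n <- sample(20:60, 1)
      a <- random_cds(n)
      b <- mutateCodonSequence(a, ts = 0.3, tn = 0.2)$cds
      ab <- estimateDsDn(CodonAlignment("x", a, b))
      ba <- estimateDsDn(CodonAlignment("x", b, a))
      expect_equal(ab$s_sites + ab$n_sites, 3 * n)
      expect_equal(ab$ds, ba$ds)
      expect_equal(ab$dn, ba$dn)
      expect_equal(ab$sd, ba$sd)
      expect_equal(ab$nc_a, ba$nc_b)

      # invariance under a codon-block permutation of the alignment
      perm <- sample(n)
      chop <- function(s) substring(s, 3 * perm - 2, 3 * perm)
      ab2 <- estimateDsDn(CodonAlignment("x",
        paste(chop(a), collapse = ""), paste(chop(b), collapse = "")))
      expect_equal(ab2$ds, ab$ds)
      expect_equal(ab2$dn, ab$dn)
    }
  })
})

test_that("Jukes-Cantor saturation flags estimates as undefined", {
  # Phe (TTT) vs Lys (AAA) everywhere: every nonsyn site differs
  z <- estimateDsDn(CodonAlignment("id", strrep("TTT", 20),
                                   strrep("AAA", 20)))
  expect_true(is.na(z$dn))
  expect_false(z$defined)
})

test_that("Wright's Nc hits its closed-form limits and bounds", {
  expect_equal(ncFromHomozygosity(1 / 2, 1 / 3, 1 / 4, 1 / 6), 61)
  expect_equal(ncFromHomozygosity(1, 1, 1, 1), 20)

  # one codon per amino acid -> maximal bias, Nc = 20 exactly
  single <- strrep(paste0("TTT", "ATT", "GTT", "TTA"), 40)
  expect_equal(computeNc(single)$nc, 20)

  withr::with_seed(31, {
    for (rep in 1:10) {
      nc <- computeNc(random_cds(sample(100:500, 1)))$nc
      expect_gte(nc, 20)
      expect_lte(nc, 61)
    }
  })
})

test_that("computeNc matches a direct, independent evaluation of the formula", {
  # independent oracle: recompute F per amino acid straight from codon
  # counts and the genetic code, then apply Wright's formula
  oracle_nc <- function(cds) {
    cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    gc <- Biostrings::GENETIC_CODE
    cods <- cods[gc[cods] != "*"]
    classes <- list(f2 = c("F","Y","C","H","Q","N","K","D","E"),
                    f3 = "I", f4 = c("V","P","T","A","G"),
                    f6 = c("L","S","R"))
    fbar <- sapply(classes, function(aas) {
      fs <- c()
      for (a in aas) {
        obs <- cods[gc[cods] == a]
        n <- length(obs)
        if (n < 2) next
        p <- table(factor(obs, levels = names(gc)[gc == a])) / n
        f <- (n * sum(p^2) - 1) / (n - 1)
        if (f > 0) fs <- c(fs, f)
      }
      if (length(fs)) mean(fs) else NA
    })
    if (anyNA(fbar)) return(NA)
    min(max(2 + 9/fbar["f2"] + 1/fbar["f3"] + 5/fbar["f4"] + 3/fbar["f6"],
            20), 61)
  }
  withr::with_seed(37, {
    for (rep in 1:8) {
      cds <- random_cds(300)
      expect_equal(computeNc(cds)$nc, unname(oracle_nc(cds)),
                   tolerance = 1e-12)
    }
  })
})

test_that("outlier filters implement the strict-threshold rule", {
  tab <- data.frame(
    gene_id = paste0("g", 1:4),
    ds = c(1, 6, 1e-4, 1), dn = c(0.6, 0.1, 0.1, 0.1),
    defined = TRUE)
  out <- applyDivergenceFilters(tab)
  expect_equal(nrow(out$retained), 1)
  expect_equal(out$retained$gene_id, "g4")
  expect_equal(unname(out$counts), c(0, 1, 1, 1))

  expect_equal(nrow(applyDivergenceFilters(tab[0, ])$retained), 0)

  # records exactly at the boundaries are retained (strict inequalities)
  edge <- data.frame(gene_id = c("e1", "e2", "e3"),
                     ds = c(5, 0.0005, 1), dn = c(0.1, 0.1, 0.5),
                     defined = TRUE)
  expect_equal(nrow(applyDivergenceFilters(edge)$retained), 3)
})

test_that("filtering is idempotent, order-independent, and nested", {
  withr::with_seed(43, {
    tab <- data.frame(gene_id = paste0("g", 1:60),
                      ds = exp(runif(60, log(1e-5), log(10))),
                      dn = runif(60, 0, 1), defined = TRUE)
  })
  once <- applyDivergenceFilters(tab)$retained
  twice <- applyDivergenceFilters(once)$retained
  expect_identical(once, twice)
  shuffled <- applyDivergenceFilters(tab[sample(nrow(tab)), ])$retained
  expect_setequal(shuffled$gene_id, once$gene_id)
  strict <- applyDivergenceFilters(
    tab, divergenceConfig(dnMax = 0.3, dsMax = 2, dsMin = 0.01))$retained
  expect_true(all(strict$gene_id %in% once$gene_id))
})

test_that("Nc calibration shifts dS upward along the fitted slope only", {
  # collinear points with slope exactly 0.01: gene at nc 41, ds 1.0 is
  # adjusted to 1.0 + 0.01 * (61 - 41) = 1.2
  tab <- data.frame(ds = c(1.0, 1.1, 1.2), nc_a = c(41, 51, 61),
                    nc_b = c(41, 51, 61))
  adj <- ncAdjustDs(tab)
  expect_equal(adj$slope, 0.01, tolerance = 1e-12)
  expect_equal(adj$estimates$adjusted_ds[1], 1.2, tolerance = 1e-12)
  expect_equal(adj$estimates$adjusted_ds[3], 1.2, tolerance = 1e-12)

  # no correlation -> no adjustment
  flat <- data.frame(ds = c(1, 1, 1), nc_a = c(30, 45, 60),
                     nc_b = c(30, 45, 60))
  expect_equal(ncAdjustDs(flat)$estimates$adjusted_ds, flat$ds)

  # negative slope suppressed ("upward" only)
  neg <- data.frame(ds = c(1.2, 1.1, 1.0), nc_a = c(41, 51, 61),
                    nc_b = c(41, 51, 61))
  adj_neg <- ncAdjustDs(neg)
  expect_lt(adj_neg$slope, 0)
  expect_equal(adj_neg$estimates$adjusted_ds, neg$ds)

  # adjusted_ds >= ds always
  expect_true(all(adj$estimates$adjusted_ds >= adj$estimates$ds))

  expect_error(ncAdjustDs(tab[1:2, ]), "at least 3")
  same <- data.frame(ds = c(1, 2, 3), nc_a = c(50, 50, 50),
                     nc_b = c(50, 50, 50))
  expect_warning(z <- ncAdjustDs(same), "zero variance")
  expect_equal(z$estimates$adjusted_ds, same$ds)
})

test_that("the divergence clock is linear in median dS and inverse in mu", {
  est <- data.frame(adjusted_ds = 1.28457)
  r <- estimateDivergence(est)
  expect_equal(tGenerations(r), 1.28457 / 9.0e-9)
  expect_equal(tGenerations(r), 1.4273e8, tolerance = 1e-5)
  expect_equal(tYears(r), tGenerations(r) * 30 / 365.25)

  expect_equal(tGenerations(estimateDivergence(
    data.frame(adjusted_ds = 0))), 0)

  r2 <- estimateDivergence(est, divergenceConfig(mu = 1.8e-8))
  expect_equal(tGenerations(r2), tGenerations(r) / 2)

  expect_error(estimateDivergence(data.frame(adjusted_ds = numeric(0))),
               "no retained")
  expect_error(divergenceConfig(dsMin = 5, dsMax = 5), "dsMin < dsMax")
})
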