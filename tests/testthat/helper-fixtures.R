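# Shared fixture builders; everything is generated in code at test time.

# write a FASTA file from a named character vector, return its path
write_fasta_fixture <- function(seqs, wrap = 60) {
  path <- tempfile(fileext = ".fa")
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1, nchar(s))), con)
  }
  path
}

# random assembly of n scaffolds with given length range
random_assembly <- function(n, min_len = 10, max_len = 500) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  Assembly(stats::setNames(seqs, paste0("s", seq_len(n))))
}

# random coding sequence of n codons without internal stops
random_cds <- function(n_codons) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# independent exhaustive oracle for collinear chains: enumerate every
# subset of anchors (n <= 12) and return the size of the largest subset
# that forms a valid chain in either orientation under the rank-gap cap
brute_force_best_chain <- function(anchors, maxRankGap = 10) {
  n <- nrow(anchors)
  stopifnot(n <= 12)
  valid_chain <- function(rows, orientation) {
    ra <- anchors$rank_a[rows]
    rb <- anchors$rank_b[rows]
    o <- order(ra)
    ra <- ra[o]; rb <- rb[o]
    if (any(diff(ra) < 1) || any(diff(ra) > maxRankGap)) return(FALSE)
    db <- if (orientation == "forward") diff(rb) else -diff(rb)
    all(db >= 1 & db <= maxRankGap)
  }
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    rows <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(rows) <= best) next
    if (valid_chain(rows, "forward") || valid_chain(rows, "inverted")) {
      best <- length(rows)
    }
  }
  best
}

# random anchor instance on a single chromosome pair: a random permutation
# assignment of b-ranks to a-ranks
random_anchors <- function(n) {
  data.frame(gene_a = paste0("a", seq_len(n)),
             gene_b = paste0("b", seq_len(n)),
             chrom_a = "cA1", chrom_b = "cB1",
             pos_a = seq_len(n) * 1000, pos_b = sample(n) * 1000,
             rank_a = seq_len(n), rank_b = sample(n),
             same_strand = TRUE)
}

# simulate two groups of gene pairs at different synonymous divergence and
# run the arm-vs-centre contrast through compareRegionDs()
simulate_region_contrast <- function(n_per_group, ts_centre, ts_arm,
                                     n_codons = 100) {
  ids <- sprintf("g%03d", seq_len(2 * n_per_group))
  grp <- rep(c("arm", "centre"), each = n_per_group)
  ts <- ifelse(grp == "arm", ts_arm, ts_centre)
  anc <- vapply(seq_along(ids), function(i) random_cds(n_codons),
                character(1))
  der <- mapply(function(s, t) mutateCodonSequence(s, t, 0)$cds, anc, ts)
  est <- estimateDsDnMany(ids, anc, unname(der))
  # one autosome: arm genes in [1, L/3), centre genes in the middle third
  L <- 90000
  pos <- ifelse(grp == "arm",
                seq(1000, 28000, length.out = 2 * n_per_group),
                seq(32000, 58000, length.out = 2 * n_per_group))
  genes <- GenomicRanges::GRanges("chrI",
    IRanges::IRanges(round(pos), width = 100), gene_id = ids)
  regions <- assignRegions(c(chrI = L))
  compareRegionDs(est, genes, regions, "arm_vs_centre")
}
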