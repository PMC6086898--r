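## Synthetic genome-pair simulator: codon sequences evolved under a
## per-codon Gillespie substitution process with known synonymous and
## nonsynonymous rates, codon-usage bias, chromosome inversions, planted
## LTR elements and residual-haplotype scaffolds. Every stage returns the
## ground truth the analysis modules are tested against.

#' Simulation parameters
#'
#' Defaults describe the study conditions the package is exercised under: a
#' six-chromosome genome pair (five autosomes and an X), ~500 coding genes
#' of >= 300 codons, total synonymous divergence 0.4 substitutions per
#' synonymous site split equally between the lineages, dN/dS of 0.2, no
#' codon-usage bias unless requested, two inversions per chromosome, a
#' small planted LTR complement and two residual-haplotype scaffolds at
#' half coverage.
#'
#' @param nChromosomes number of chromosomes (last one is named `chrX`).
#' @param genesPerChromosome genes per chromosome.
#' @param codonsPerGene either a single codon count or `c(min, max)`
#'   sampled uniformly per gene (minimum 100).
#' @param targetTs expected synonymous substitutions per synonymous site
#'   between the two genomes (split equally between lineages).
#' @param omega dN/dS rate ratio; scalar or `c(min, max)` per gene.
#' @param biasStrength codon-usage bias in `[0, 1]` (0 = uniform usage,
#'   1 = single preferred codon per amino acid); scalar or `c(min, max)`.
#' @param nInversions inversions per chromosome applied to genome B's gene
#'   order (disjoint, each spanning at least 2 genes).
#' @param teSpec named counts of LTR elements to plant, over
#'   `full`, `partial`, `ltr_only`.
#' @param haplotypeSpec list with `n` (haplotig count), `coverageFactor`
#'   (depth of a haplotig relative to the mean, default 0.5) and
#'   `meanDepth`.
#' @param intergenicBp mean intergenic spacer length in bp.
#' @param seed integer seed; all randomness in the simulator derives from
#'   it.
#' @return a validated parameter list of class `nemadiv_sim_params`.
#' @export
simulationParams <- function(nChromosomes = 6, genesPerChromosome = 84,
                             codonsPerGene = c(300, 400), targetTs = 0.4,
                             omega = 0.2, biasStrength = 0,
                             nInversions = 2,
                             teSpec = c(full = 5, partial = 3, ltr_only = 2),
                             haplotypeSpec = list(n = 2,
                                                  coverageFactor = 0.5,
                                                  meanDepth = 60),
                             intergenicBp = 1000, seed = 1) {
  stopifnot(nChromosomes >= 1, genesPerChromosome >= 1,
            all(codonsPerGene >= 100), targetTs >= 0, all(omega >= 0),
            all(biasStrength >= 0), all(biasStrength <= 1),
            nInversions >= 0, all(teSpec >= 0), intergenicBp >= 0)
  stopifnot(all(names(teSpec) %in% c("full", "partial", "ltr_only")))
  stopifnot(haplotypeSpec$n >= 0, haplotypeSpec$coverageFactor > 0,
            haplotypeSpec$meanDepth > 0)
  structure(list(nChromosomes = nChromosomes,
                 genesPerChromosome = genesPerChromosome,
                 codonsPerGene = codonsPerGene, targetTs = targetTs,
                 omega = omega, biasStrength = biasStrength,
                 nInversions = nInversions, teSpec = teSpec,
                 haplotypeSpec = haplotypeSpec, intergenicBp = intergenicBp,
                 seed = seed),
            class = "nemadiv_sim_params")
}

## padded neighbour matrices for vectorised event-target sampling
.sim_tables <- function() {
  if (is.null(.nemadiv_cache$sim)) {
    tb <- .codon_tables()
    pad <- function(lst) {
      k <- max(vapply(lst, length, integer(1)))
      m <- matrix(NA_integer_, length(lst), k)
      for (i in seq_along(lst)) {
        if (length(lst[[i]])) m[i, seq_along(lst[[i]])] <- lst[[i]]
      }
      m
    }
    .nemadiv_cache$sim <- list(
      synM = pad(tb$syn_nb),
      synCount = vapply(tb$syn_nb, length, integer(1)),
      nonsynM = pad(tb$nonsyn_nb),
      nonsynCount = vapply(tb$nonsyn_nb, length, integer(1)))
  }
  .nemadiv_cache$sim
}

## vectorised per-codon Gillespie over unit time. `idx` are codon indices,
## `ts`/`tn` per-codon synonymous / nonsynonymous rates per NG86 site.
## Synonymous events fire at rate ts * s_sites(codon), nonsynonymous at
## tn * n_sites(codon); targets are drawn uniformly from the synonymous /
## non-stop nonsynonymous neighbours (stop-creating changes are rejected).
## Returns updated indices plus realised per-codon event counts.
.mutate_codon_vector <- function(idx, ts, tn) {
  tb <- .codon_tables()
  sm <- .sim_tables()
  if (any(tb$is_stop[idx])) stop("internal stop codon in input sequence")
  n <- length(idx)
  ts <- rep_len(ts, n)
  tn <- rep_len(tn, n)
  s_subs <- integer(n)
  n_subs <- integer(n)
  remaining <- rep(1, n)
  active <- seq_len(n)
  while (length(active)) {
    cur <- idx[active]
    rs <- ts[active] * tb$s_sites[cur]
    rn <- tn[active] * tb$n_sites[cur]
    rtot <- rs + rn
    dt <- rep(Inf, length(active))
    pos <- rtot > 0
    dt[pos] <- stats::rexp(sum(pos), rtot[pos])
    fire <- dt < remaining[active]
    act <- active[fire]
    if (!length(act)) break
    remaining[act] <- remaining[act] - dt[fire]
    cur <- idx[act]
    syn_ev <- stats::runif(length(act)) * rtot[fire] < rs[fire]
    ## synonymous targets always exist when rs > 0; nonsynonymous targets
    ## exclude stops, redirecting that rate mass to sense targets
    newc <- cur
    if (any(syn_ev)) {
      cc <- cur[syn_ev]
      pick <- 1L + floor(stats::runif(length(cc)) * sm$synCount[cc])
      newc[syn_ev] <- sm$synM[cbind(cc, pick)]
      s_subs[act[syn_ev]] <- s_subs[act[syn_ev]] + 1L
    }
    if (any(!syn_ev)) {
      cc <- cur[!syn_ev]
      pick <- 1L + floor(stats::runif(length(cc)) * sm$nonsynCount[cc])
      newc[!syn_ev] <- sm$nonsynM[cbind(cc, pick)]
      n_subs[act[!syn_ev]] <- n_subs[act[!syn_ev]] + 1L
    }
    idx[act] <- newc
    active <- act
  }
  list(idx = idx, s_subs = s_subs, n_subs = n_subs)
}

#' Evolve a coding sequence under known substitution rates
#'
#' Per-codon continuous-time (Gillespie) substitution over unit time:
#' synonymous changes accrue at rate `ts` per synonymous site and
#' nonsynonymous changes at `tn` per nonsynonymous site (NG86 site
#' definitions), with stop-creating substitutions rejected. Deterministic
#' given `seed`.
#'
#' @param cds coding sequence without internal stops.
#' @param ts,tn synonymous / nonsynonymous rates per site.
#' @param seed integer seed (or `NULL` to use the current RNG state).
#' @return a list with `cds` (derived sequence), `s_subs`, `n_subs`
#'   (realised substitution counts) and `s_sites`, `n_sites` of the input.
#' @examples
#' mutateCodonSequence(strrep("GGTACT", 50), ts = 0.2, tn = 0, seed = 7)
#' @export
mutateCodonSequence <- function(cds, ts, tn, seed = NULL) {
  stopifnot(ts >= 0, tn >= 0)
  idx <- .codon_indices(cds, "cds")
  tb <- .codon_tables()
  res <- .with_seed(seed, .mutate_codon_vector(idx, ts, tn))
  list(cds = paste(tb$codons[res$idx], collapse = ""),
       s_subs = sum(res$s_subs), n_subs = sum(res$n_subs),
       s_sites = sum(tb$s_sites[idx]), n_sites = sum(tb$n_sites[idx]))
}

## ancestral codon sampling: amino acids uniform over the 20, codon within
## the family drawn from (1-b)*uniform + b*point-mass on a preferred codon
.sample_ancestral <- function(n_codons, bias) {
  tb <- .codon_tables()
  fams <- tb$families             # sense codons per amino acid
  aas <- names(fams)
  pref <- vapply(fams, function(f) f[1], character(1))
  aa_seq <- sample(aas, n_codons, replace = TRUE)
  cod <- character(n_codons)
  use_pref <- stats::runif(n_codons) < bias
  cod[use_pref] <- pref[aa_seq[use_pref]]
  rest <- which(!use_pref)
  if (length(rest)) {
    cod[rest] <- vapply(aa_seq[rest], function(a) {
      f <- fams[[a]]
      f[sample.int(length(f), 1L)]
    }, character(1))
  }
  unname(tb$idx[cod])
}

#' Invert segments of a gene order
#'
#' Applies `nInversions` disjoint segment reversals (each spanning at least
#' two genes) to an ordering. Cut points are drawn without replacement and
#' paired consecutively, so inversions never nest or overlap.
#'
#' @param geneOrder a vector (gene ids or indices).
#' @param nInversions number of inversions.
#' @param seed integer seed (or `NULL`).
#' @return a list with `order` (rearranged vector) and `log`
#'   (`data.frame` of 1-based `start`, `end` indices per inversion, in the
#'   original ordering).
#' @export
applyRearrangements <- function(geneOrder, nInversions, seed = NULL) {
  n <- length(geneOrder)
  if (nInversions == 0L || n < 2L) {
    return(list(order = geneOrder,
                log = data.frame(start = integer(0), end = integer(0))))
  }
  if (2 * nInversions > n) {
    stop("cannot place ", nInversions, " disjoint inversions in ", n,
         " genes")
  }
  .with_seed(seed, {
    cuts <- sort(sample.int(n, 2L * nInversions))
    st <- cuts[seq(1, length(cuts), 2)]
    en <- cuts[seq(2, length(cuts), 2)]
    for (k in seq_along(st)) {
      geneOrder[st[k]:en[k]] <- rev(geneOrder[st[k]:en[k]])
    }
    list(order = geneOrder, log = data.frame(start = st, end = en))
  })
}

## random intergenic spacer of ACGT
.spacer <- function(len) {
  if (len <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Plant LTR retrotransposon elements into an assembly
#'
#' Overwrites intergenic windows with synthetic LTR elements (terminal
#' repeats starting `TG` and ending `CA`) and returns the candidate and
#' domain-hit tables describing them: `full` elements carry all four
#' protein domains at e-value 1e-30, `partial` elements a random proper
#' subset at 1e-25, and `ltr_only` elements no domains but an LTR
#' similarity of 96-99 percent. Gene coordinates are untouched (elements
#' replace spacer sequence in place).
#'
#' @param assembly an [Assembly-class].
#' @param genes `GRanges` of genes to avoid.
#' @param teSpec named counts over `full`, `partial`, `ltr_only`.
#' @param seed integer seed (or `NULL`).
#' @return a list with `assembly` (modified), `candidates` (truth candidate
#'   table with `true_class`), and `domains`.
#' @export
plantLtrElements <- function(assembly, genes, teSpec, seed = NULL) {
  classes <- rep(names(teSpec), times = teSpec)
  empty <- list(assembly = assembly,
                candidates = data.frame(
                  candidate_id = character(0), scaffold = character(0),
                  start = integer(0), end = integer(0),
                  ltr5_start = integer(0), ltr5_end = integer(0),
                  ltr3_start = integer(0), ltr3_end = integer(0),
                  source = character(0), ltr_similarity = numeric(0),
                  true_class = character(0)),
                domains = data.frame(candidate_id = character(0),
                                     domain = character(0),
                                     e_value = numeric(0)))
  if (!length(classes)) return(empty)
  .with_seed(seed, {
    seqs <- as.character(assembly)
    ## free windows: spacer regions at least 2 kb long
    gaps <- GenomicRanges::gaps(GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(genes), IRanges::ranges(genes),
      seqlengths = stats::setNames(Biostrings::width(assembly),
                                   names(assembly))))
    gaps <- gaps[BiocGenerics::strand(gaps) == "*" &
                   BiocGenerics::width(gaps) >= 1500]
    ## tile each free gap into 1.5-kb windows so several elements can share
    ## a long spacer without overlapping
    win_scaf <- character(0)
    win_start <- integer(0)
    for (gi in seq_along(gaps)) {
      w <- BiocGenerics::width(gaps)[gi]
      k <- w %/% 1500L
      win_scaf <- c(win_scaf,
                    rep(as.character(GenomeInfoDb::seqnames(gaps))[gi], k))
      win_start <- c(win_start,
                     BiocGenerics::start(gaps)[gi] + 1500L * (seq_len(k) - 1L))
    }
    if (length(win_start) < length(classes)) {
      stop("not enough intergenic space to plant ", length(classes),
           " elements")
    }
    picked <- sample(seq_along(win_start), length(classes))
    cand <- list()
    doms <- list()
    for (k in seq_along(classes)) {
      scaf <- win_scaf[picked[k]]
      elen <- sample(900:1300, 1L)
      ltr <- sample(120:250, 1L)
      st <- win_start[picked[k]] + 100L
      en <- st + elen - 1L
      ltrseq <- paste0("TG", .spacer(ltr - 4L), "CA")
      inner <- .spacer(elen - 2L * ltr)
      substr(seqs[[scaf]], st, en) <- paste0(ltrseq, inner, ltrseq)
      id <- sprintf("planted_%s_%02d", classes[k], k)
      cand[[k]] <- data.frame(
        candidate_id = id, scaffold = scaf, start = st, end = en,
        ltr5_start = st, ltr5_end = st + ltr - 1L,
        ltr3_start = en - ltr + 1L, ltr3_end = en,
        source = "planted",
        ltr_similarity = if (classes[k] == "ltr_only")
          stats::runif(1, 96, 99) else NA_real_,
        true_class = classes[k])
      if (classes[k] == "full") {
        doms[[k]] <- data.frame(candidate_id = id, domain = .LTR_DOMAINS,
                                e_value = 1e-30)
      } else if (classes[k] == "partial") {
        nd <- sample.int(3L, 1L)
        doms[[k]] <- data.frame(
          candidate_id = id,
          domain = sample(.LTR_DOMAINS, nd),
          e_value = 1e-25)
      }
    }
    list(assembly = Assembly(stats::setNames(seqs, names(assembly))),
         candidates = do.call(rbind, cand),
         domains = if (length(doms <- doms[!vapply(doms, is.null,
                                                   logical(1))]))
           do.call(rbind, doms) else empty$domains)
  })
}

#' Plant residual-haplotype scaffolds
#'
#' Copies windows of existing scaffolds into new, smaller scaffolds and
#' builds the matching coverage track (haplotigs at `coverageFactor` times
#' the mean depth) and self-alignment table (haplotigs ~97 percent
#' contained in their source scaffold).
#'
#' @param assembly an [Assembly-class].
#' @param haplotypeSpec list with `n`, `coverageFactor`, `meanDepth`.
#' @param seed integer seed (or `NULL`).
#' @return a list with `assembly` (haplotigs appended), `coverage`,
#'   `selfAlignments`, and `haplotigs` (ids planted).
#' @export
plantHaplotigs <- function(assembly, haplotypeSpec, seed = NULL) {
  n <- haplotypeSpec$n
  .with_seed(seed, {
    seqs <- as.character(assembly)
    ids <- character(0)
    aligns <- list()
    for (k in seq_len(n)) {
      src <- sample(names(assembly)[Biostrings::width(assembly) >= 20000], 1L)
      L <- nchar(seqs[[src]])
      hl <- sample(5000:min(20000, L %/% 3), 1L)
      st <- sample.int(L - hl, 1L)
      id <- sprintf("haplotig_%02d", k)
      seqs[[id]] <- substr(seqs[[src]], st, st + hl - 1L)
      ids <- c(ids, id)
      aligns[[k]] <- data.frame(scaffold = id,
                                covered_fraction = stats::runif(1, 0.95, 1))
    }
    nm <- names(seqs)
    depth <- stats::rnorm(length(nm), haplotypeSpec$meanDepth,
                          haplotypeSpec$meanDepth * 0.02)
    depth[nm %in% ids] <- depth[nm %in% ids] * haplotypeSpec$coverageFactor
    list(assembly = Assembly(stats::setNames(seqs, nm)),
         coverage = data.frame(scaffold = nm, mean_depth = pmax(depth, 0)),
         selfAlignments = if (n > 0) do.call(rbind, aligns) else
           data.frame(scaffold = character(0),
                      covered_fraction = numeric(0)),
         haplotigs = ids)
  })
}

#' Simulate a diverged genome pair with full ground truth
#'
#' Ancestral coding genes are sampled with per-gene codon-usage bias, both
#' lineages are evolved with synonymous rate `targetTs/2 * (1 - 0.5 *
#' bias)` (bias suppresses observable synonymous change, creating the
#' dS-Nc correlation the calibration step corrects) and nonsynonymous rate
#' `omega * targetTs/2`. Genome B's gene order receives disjoint
#' inversions; genome A receives planted LTR elements and residual
#' haplotigs. All coordinates are emitted in the package's standard
#' containers, and `truth` records the realised per-gene substitution
#' counts, the inversion log, the planted-TE tables and the haplotig list.
#'
#' @param params a [simulationParams()] list.
#' @return a list with `assemblyA`, `genesA`, `cdsA`, `assemblyB`,
#'   `genesB`, `cdsB`, `orthologs`, `coverage`, `selfAlignments`,
#'   `teCandidates`, `teDomains`, and `truth`.
#' @export
simulateGenomePair <- function(params = simulationParams()) {
  stopifnot(inherits(params, "nemadiv_sim_params"))
  tb <- .codon_tables()
  .with_seed(params$seed, {
    nchr <- params$nChromosomes
    chroms <- if (nchr > 1) {
      c(paste0("chr", utils::as.roman(seq_len(nchr - 1))), "chrX")
    } else {
      "chrX"
    }
    gpc <- params$genesPerChromosome
    ngene <- nchr * gpc
    ncod <- if (length(params$codonsPerGene) == 1L) {
      rep(params$codonsPerGene, ngene)
    } else {
      sample(params$codonsPerGene[1]:params$codonsPerGene[2], ngene,
             replace = TRUE)
    }
    bias <- if (length(params$biasStrength) == 1L) {
      rep(params$biasStrength, ngene)
    } else {
      stats::runif(ngene, params$biasStrength[1], params$biasStrength[2])
    }
    omega <- if (length(params$omega) == 1L) {
      rep(params$omega, ngene)
    } else {
      stats::runif(ngene, params$omega[1], params$omega[2])
    }
    ts_lineage <- (params$targetTs / 2) * (1 - 0.5 * bias)
    tn_lineage <- (params$targetTs / 2) * omega

    ## ancestral genes, concatenated for one vectorised mutation pass
    anc <- lapply(seq_len(ngene), function(i)
      .sample_ancestral(ncod[i], bias[i]))
    lens <- lengths(anc)
    flat <- unlist(anc)
    gene_of <- rep(seq_len(ngene), lens)
    tsv <- ts_lineage[gene_of]
    tnv <- tn_lineage[gene_of]
    mutA <- .mutate_codon_vector(flat, tsv, tnv)
    mutB <- .mutate_codon_vector(flat, tsv, tnv)
    cds_of <- function(idx) {
      vapply(split(tb$codons[idx], gene_of), paste, character(1),
             collapse = "")
    }
    cdsA_chr <- unname(cds_of(mutA$idx))
    cdsB_chr <- unname(cds_of(mutB$idx))
    s_subs <- tapply(mutA$s_subs + mutB$s_subs, gene_of, sum)
    n_subs <- tapply(mutA$n_subs + mutB$n_subs, gene_of, sum)
    s_sites <- tapply(tb$s_sites[flat], gene_of, sum)
    n_sites <- tapply(tb$n_sites[flat], gene_of, sum)

    idsA <- sprintf("A_%s_g%03d", rep(chroms, each = gpc),
                    rep(seq_len(gpc), nchr))
    idsB <- sub("^A_", "B_", idsA)

    ## assemble genome A: spacer + gene + spacer + ...
    ## terminal spacers are generous so there is intergenic room for
    ## planted elements without touching gene coordinates
    build_genome <- function(ids, cds, order_by_chr, strand_by_chr) {
      seqs <- character(0)
      g_chr <- character(0); g_st <- integer(0); g_en <- integer(0)
      g_strand <- character(0); g_id <- character(0)
      for (ci in seq_along(chroms)) {
        ord <- order_by_chr[[ci]]
        strand <- strand_by_chr[[ci]]
        parts <- .spacer(round(params$intergenicBp * 8))
        pos <- nchar(parts)
        st <- integer(length(ord)); en <- integer(length(ord))
        for (k in seq_along(ord)) {
          sp <- .spacer(round(stats::runif(1, 0.5, 1.5) *
                                params$intergenicBp))
          parts <- c(parts, sp)
          pos <- pos + nchar(sp)
          g <- cds[ord[k]]
          if (strand[k] == "-") {
            g <- as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(g)))
          }
          parts <- c(parts, g)
          st[k] <- pos + 1L
          en[k] <- pos + nchar(g)
          pos <- pos + nchar(g)
        }
        parts <- c(parts, .spacer(round(params$intergenicBp * 8)))
        seqs[[chroms[ci]]] <- paste(parts, collapse = "")
        g_chr <- c(g_chr, rep(chroms[ci], length(ord)))
        g_st <- c(g_st, st); g_en <- c(g_en, en)
        g_strand <- c(g_strand, strand)
        g_id <- c(g_id, ids[ord])
      }
      asm <- Assembly(seqs)
      genes <- GenomicRanges::GRanges(
        g_chr, IRanges::IRanges(g_st, g_en), strand = g_strand,
        gene_id = g_id, cds_bp = g_en - g_st + 1L, coding = TRUE,
        seqlengths = stats::setNames(Biostrings::width(asm), names(asm)))
      list(assembly = asm, genes = genes)
    }

    gene_idx_by_chr <- split(seq_len(ngene),
                             rep(seq_along(chroms), each = gpc))
    ordA <- gene_idx_by_chr
    strandA <- lapply(ordA, function(x) rep("+", length(x)))
    invlog <- list()
    ordB <- gene_idx_by_chr
    strandB <- strandA
    for (ci in seq_along(chroms)) {
      r <- applyRearrangements(seq_len(gpc), params$nInversions)
      ordB[[ci]] <- gene_idx_by_chr[[ci]][r$order]
      sb <- rep("+", gpc)
      for (k in seq_len(nrow(r$log))) {
        sb[r$log$start[k]:r$log$end[k]] <- "-"
      }
      strandB[[ci]] <- sb
      if (nrow(r$log)) {
        invlog[[ci]] <- cbind(data.frame(chrom = chroms[ci]), r$log)
      }
    }
    invlog <- if (length(invlog)) do.call(rbind, invlog) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0))

    ga <- build_genome(idsA, cdsA_chr, ordA, strandA)
    gb <- build_genome(idsB, cdsB_chr, ordB, strandB)

    te <- plantLtrElements(ga$assembly, ga$genes, params$teSpec)
    hap <- plantHaplotigs(te$assembly, params$haplotypeSpec)

    truth <- list(
      perGene = data.frame(
        gene_a = idsA, gene_b = idsB, chrom = rep(chroms, each = gpc),
        codons = ncod, bias = bias, omega = omega,
        ts_lineage = ts_lineage, tn_lineage = tn_lineage,
        s_subs = as.vector(s_subs), n_subs = as.vector(n_subs),
        s_sites = as.vector(s_sites), n_sites = as.vector(n_sites)),
      inversions = invlog,
      teCandidates = te$candidates,
      teDomains = te$domains,
      haplotigs = hap$haplotigs,
      params = params)

    list(assemblyA = hap$assembly, genesA = ga$genes,
         cdsA = Biostrings::DNAStringSet(stats::setNames(cdsA_chr, idsA)),
         assemblyB = gb$assembly, genesB = gb$genes,
         cdsB = Biostrings::DNAStringSet(stats::setNames(cdsB_chr, idsB)),
         orthologs = data.frame(gene_a = idsA, gene_b = idsB),
         coverage = hap$coverage, selfAlignments = hap$selfAlignments,
         teCandidates = te$candidates, teDomains = te$teDomains %||%
           te$domains,
         truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated genome pair to standard formats
#'
#' Emits FASTA assemblies, GFF3 gene models, CDS FASTA, the ortholog TSV,
#' coverage and self-alignment TSVs, TE candidate/domain TSVs and the
#' truth tables, all consumable by the analysis functions unchanged.
#'
#' @param sim output of [simulateGenomePair()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeAssembly(sim$assemblyA, file.path(dir, "genomeA.fa"))
  writeAssembly(sim$assemblyB, file.path(dir, "genomeB.fa"))
  writeGeneGff3(sim$genesA, file.path(dir, "genesA.gff3"))
  writeGeneGff3(sim$genesB, file.path(dir, "genesB.gff3"))
  Biostrings::writeXStringSet(sim$cdsA, file.path(dir, "cdsA.fa"),
                              width = 60L)
  Biostrings::writeXStringSet(sim$cdsB, file.path(dir, "cdsB.fa"),
                              width = 60L)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(sim$orthologs, "orthologs.tsv")
  wt(sim$coverage, "coverage.tsv")
  wt(sim$selfAlignments, "self_alignments.tsv")
  wt(sim$teCandidates, "te_candidates.tsv")
  wt(sim$teDomains, "te_domains.tsv")
  wt(sim$truth$perGene, "truth_genes.tsv")
  wt(sim$truth$inversions, "truth_inversions.tsv")
  invisible(dir)
}

#' Write gene models as GFF3
#'
#' One `gene`/`mRNA`/`CDS` trio per (intronless) gene so the file
#' round-trips through [readGeneModels()].
#'
#' @param genes `GRanges` with `gene_id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneGff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(genes)) {
    ch <- as.character(GenomeInfoDb::seqnames(genes))
    st <- BiocGenerics::start(genes)
    en <- BiocGenerics::end(genes)
    sd <- as.character(BiocGenerics::strand(genes))
    sd[sd == "*"] <- "+"
    id <- genes$gene_id
    writeLines(paste0(
      sprintf("%s\tnemadiv\tgene\t%d\t%d\t.\t%s\t.\tID=%s\n",
              ch, st, en, sd, id),
      sprintf("%s\tnemadiv\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s\n",
              ch, st, en, sd, id, id),
      sprintf("%s\tnemadiv\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s.t1",
              ch, st, en, sd, id, id)), con)
  }
  invisible(path)
}
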