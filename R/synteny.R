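## Collinear synteny-block chaining over one-to-one ortholog anchors, plus
## chromosome arm/centre partitioning and substitution-rate contrasts.

#' Build ortholog anchors from two gene sets
#'
#' One anchor per one-to-one ortholog pair: gene midpoints in bp, gene-order
#' ranks within each chromosome, and a same-strand flag.
#'
#' @param genesA,genesB `GRanges` of genes (as from [readGeneModels()]) with
#'   a `gene_id` metadata column.
#' @param orthologs `data.frame` with columns `gene_a`, `gene_b`.
#' @return a `data.frame` with columns `gene_a`, `gene_b`, `chrom_a`,
#'   `chrom_b`, `pos_a`, `pos_b`, `rank_a`, `rank_b`, `same_strand`.
#' @export
makeAnchors <- function(genesA, genesB, orthologs) {
  prep <- function(g) {
    df <- data.frame(
      gene_id = g$gene_id,
      chrom = as.character(GenomeInfoDb::seqnames(g)),
      pos = (BiocGenerics::start(g) + BiocGenerics::end(g)) / 2,
      strand = as.character(BiocGenerics::strand(g)))
    df <- df[order(df$chrom, df$pos), ]
    df$rank <- stats::ave(df$pos, df$chrom, FUN = seq_along)
    df
  }
  a <- prep(genesA)
  b <- prep(genesB)
  ia <- match(orthologs$gene_a, a$gene_id)
  ib <- match(orthologs$gene_b, b$gene_id)
  ok <- !is.na(ia) & !is.na(ib)
  data.frame(
    gene_a = orthologs$gene_a[ok], gene_b = orthologs$gene_b[ok],
    chrom_a = a$chrom[ia[ok]], chrom_b = b$chrom[ib[ok]],
    pos_a = a$pos[ia[ok]], pos_b = b$pos[ib[ok]],
    rank_a = a$rank[ia[ok]], rank_b = b$rank[ib[ok]],
    same_strand = a$strand[ia[ok]] == b$strand[ib[ok]])
}

## best collinear chain among `idx` rows of `anc` for one orientation.
## Chains require strictly increasing rank_a and strictly increasing
## (forward) or strictly decreasing (inverted) rank_b, with consecutive
## rank differences <= maxRankGap on both genomes. O(n^2) DP; ties broken
## deterministically by order after sorting on (rank_a, rank_b).
.best_chain <- function(anc, idx, orientation, maxRankGap) {
  n <- length(idx)
  if (n == 0L) return(integer(0))
  ra <- anc$rank_a[idx]
  rb <- anc$rank_b[idx]
  ord <- order(ra, rb)
  ra <- ra[ord]; rb <- rb[ord]
  L <- rep(1L, n)
  pred <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      da <- ra[i] - ra[j]
      db <- if (orientation == "forward") rb[i] - rb[j] else rb[j] - rb[i]
      if (da >= 1 && da <= maxRankGap && db >= 1 && db <= maxRankGap &&
          L[j] + 1L > L[i]) {
        L[i] <- L[j] + 1L
        pred[i] <- j
      }
    }
  }
  best <- which.max(L)           # first maximum: leftmost deterministic
  chain <- integer(0)
  k <- best
  while (!is.na(k)) {
    chain <- c(k, chain)
    k <- pred[k]
  }
  idx[ord[chain]]
}

#' Chain ortholog anchors into collinear synteny blocks
#'
#' Within each `(chrom_a, chrom_b)` group, maximum-cardinality collinear
#' chains are found by a longest-chain dynamic programme over rank pairs
#' (forward and inverted orientations; consecutive anchors may skip at most
#' `maxRankGap` gene ranks on either genome). The best chain is extracted,
#' its anchors removed, and the search repeated; blocks with fewer than
#' `minAnchors` anchors are discarded. Ties between equal-cardinality
#' chains resolve deterministically (forward first, then leftmost start).
#'
#' @param anchors `data.frame` from [makeAnchors()].
#' @param maxRankGap maximum rank gap between consecutive anchors
#'   (default 10).
#' @param minAnchors minimum anchors per reported block (default 3).
#' @return a list with `blocks` (one row per block: `block_id`, `chrom_a`,
#'   `chrom_b`, `orientation`, `n_anchors`, `start_a`, `end_a`, `start_b`,
#'   `end_b`) and `anchors` (input plus `block_id`, `NA` when unchained).
#' @export
chainAnchors <- function(anchors, maxRankGap = 10, minAnchors = 3) {
  key <- paste(anchors$gene_a, anchors$gene_b)
  if (anyDuplicated(key)) stop("duplicate anchor: ", key[duplicated(key)][1])
  if (anyDuplicated(anchors$gene_a) || anyDuplicated(anchors$gene_b)) {
    stop("anchors must be one-to-one in both genomes")
  }
  anchors$block_id <- NA_character_
  blocks <- list()
  bid <- 0L
  for (grp in split(seq_len(nrow(anchors)),
                    paste(anchors$chrom_a, anchors$chrom_b))) {
    remaining <- grp
    repeat {
      fw <- .best_chain(anchors, remaining, "forward", maxRankGap)
      iv <- .best_chain(anchors, remaining, "inverted", maxRankGap)
      pick_fw <- length(fw) > length(iv) ||
        (length(fw) == length(iv) && length(fw) > 0 &&
           min(anchors$rank_a[fw]) <= min(anchors$rank_a[iv]))
      chain <- if (pick_fw) fw else iv
      orientation <- if (pick_fw) "forward" else "inverted"
      if (length(chain) < max(minAnchors, 1L)) break
      bid <- bid + 1L
      id <- sprintf("block_%04d", bid)
      anchors$block_id[chain] <- id
      blocks[[bid]] <- data.frame(
        block_id = id,
        chrom_a = anchors$chrom_a[chain[1]],
        chrom_b = anchors$chrom_b[chain[1]],
        orientation = orientation,
        n_anchors = length(chain),
        start_a = min(anchors$pos_a[chain]),
        end_a = max(anchors$pos_a[chain]),
        start_b = min(anchors$pos_b[chain]),
        end_b = max(anchors$pos_b[chain]))
      remaining <- setdiff(remaining, chain)
      if (length(remaining) == 0L) break
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(block_id = character(0), chrom_a = character(0),
               chrom_b = character(0), orientation = character(0),
               n_anchors = integer(0), start_a = numeric(0),
               end_a = numeric(0), start_b = numeric(0), end_b = numeric(0))
  list(blocks = blocks, anchors = anchors)
}

#' Fraction of genome A covered by synteny blocks
#'
#' Block spans on genome A are merged before summation.
#'
#' @param blocks block table from [chainAnchors()].
#' @param assembly [Assembly-class] (or named scaffold lengths) of genome A.
#' @return coverage percentage in `[0, 100]`.
#' @export
syntenyCoverage <- function(blocks, assembly) {
  lens <- if (methods::is(assembly, "DNAStringSet")) {
    stats::setNames(Biostrings::width(assembly), names(assembly))
  } else {
    assembly
  }
  total <- sum(as.numeric(lens))
  if (!nrow(blocks)) return(0)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    blocks$chrom_a,
    IRanges::IRanges(round(blocks$start_a), round(blocks$end_a))))
  100 * sum(as.numeric(BiocGenerics::width(gr))) / total
}

#' Genes outside any synteny block, grouped between flanking blocks
#'
#' @param blocks block table from [chainAnchors()].
#' @param genes `GRanges` of genome-A genes with `gene_id`.
#' @return a list of character vectors of gene ids, one per inter-block
#'   break (named `"<left block>|<right block>"`, with `"."` at chromosome
#'   ends); empty list when every gene is inside a block span.
#' @export
findBreaks <- function(blocks, genes) {
  pos <- (BiocGenerics::start(genes) + BiocGenerics::end(genes)) / 2
  chrom <- as.character(GenomeInfoDb::seqnames(genes))
  out <- list()
  for (ch in unique(chrom)) {
    gi <- which(chrom == ch)
    bi <- which(blocks$chrom_a == ch)
    inside <- rep(FALSE, length(gi))
    for (b in bi) {
      inside <- inside | (pos[gi] >= blocks$start_a[b] &
                            pos[gi] <= blocks$end_a[b])
    }
    loose <- gi[!inside]
    if (!length(loose)) next
    bstart <- blocks$start_a[bi]
    bend <- blocks$end_a[bi]
    keyfun <- function(p) {
      left <- bi[bend < p]
      right <- bi[bstart > p]
      lid <- if (length(left)) blocks$block_id[left[which.max(bend[bend < p])]]
        else "."
      rid <- if (length(right))
        blocks$block_id[right[which.min(bstart[bstart > p])]] else "."
      paste(lid, rid, sep = "|")
    }
    keys <- vapply(pos[loose], keyfun, character(1))
    for (k in unique(keys)) {
      out[[k]] <- c(out[[k]], genes$gene_id[loose[keys == k]])
    }
  }
  out
}

#' Partition chromosomes into arm and centre domains
#'
#' With no explicit boundaries each chromosome is split into thirds: the
#' outer thirds are `left_arm` and `right_arm`, the middle is `centre`
#' (recombination-domain proxy; override with measured boundaries where
#' available). Explicit boundaries are validated to partition each
#' chromosome without overlap.
#'
#' @param chromLengths named numeric vector of chromosome lengths.
#' @param boundaries optional `data.frame` with columns `chrom`, `start`,
#'   `end`, `label` (1-based closed; labels in
#'   `left_arm`/`centre`/`right_arm`).
#' @return a `GRanges` with a `label` metadata column partitioning each
#'   chromosome.
#' @export
assignRegions <- function(chromLengths, boundaries = NULL) {
  labs <- c("left_arm", "centre", "right_arm")
  if (is.null(boundaries)) {
    L <- unlist(chromLengths)
    b1 <- floor(L / 3)
    b2 <- floor(2 * L / 3)
    gr <- GenomicRanges::GRanges(
      rep(names(chromLengths), each = 3),
      IRanges::IRanges(
        start = as.vector(rbind(1, b1 + 1, b2 + 1)),
        end = as.vector(rbind(b1, b2, L))),
      label = rep(labs, length(chromLengths)))
  } else {
    stopifnot(all(c("chrom", "start", "end", "label") %in% names(boundaries)))
    if (!all(boundaries$label %in% labs)) {
      stop("labels must be in: ", paste(labs, collapse = ", "))
    }
    gr <- GenomicRanges::GRanges(boundaries$chrom,
                                 IRanges::IRanges(boundaries$start,
                                                  boundaries$end),
                                 label = boundaries$label)
    for (ch in unique(boundaries$chrom)) {
      sub <- gr[GenomeInfoDb::seqnames(gr) == ch]
      r <- IRanges::ranges(sub)
      if (length(IRanges::findOverlaps(r, drop.self = TRUE,
                                       drop.redundant = TRUE))) {
        stop("overlapping region boundaries on ", ch)
      }
      cov <- IRanges::reduce(r)
      L <- chromLengths[[ch]]
      if (is.null(L) || is.na(L)) stop("unknown chromosome: ", ch)
      if (length(cov) != 1L || BiocGenerics::start(cov) != 1L ||
          BiocGenerics::end(cov) != L) {
        stop("boundaries do not partition [1, ", L, "] on ", ch)
      }
    }
  }
  gr
}

#' Compare dS between chromosome domains or X versus autosomes
#'
#' Genes are assigned to regions by their midpoint; the two groups are
#' contrasted with a two-sided Mann-Whitney U (Wilcoxon rank-sum) test:
#' exact when both groups have fewer than 10 untied observations, normal
#' approximation with tie correction otherwise.
#'
#' @param estimates `data.frame` with `gene_id` and `ds` columns.
#' @param genes `GRanges` of the same genes (genome A) with `gene_id`.
#' @param regionMap `GRanges` from [assignRegions()].
#' @param grouping `"arm_vs_centre"` (arms pooled, X excluded) or
#'   `"X_vs_autosome"`.
#' @param xChrom chromosome name treated as the X (default `"chrX"`).
#' @return a list with `grouping`, `groups` (per-group dS vectors),
#'   `u_statistic`, `p_value`, `medians`, and `n`.
#' @export
compareRegionDs <- function(estimates, genes, regionMap,
                            grouping = c("arm_vs_centre", "X_vs_autosome"),
                            xChrom = "chrX") {
  grouping <- match.arg(grouping)
  m <- match(estimates$gene_id, genes$gene_id)
  ok <- !is.na(m) & is.finite(estimates$ds)
  g <- genes[m[ok]]
  ds <- estimates$ds[ok]
  chrom <- as.character(GenomeInfoDb::seqnames(g))
  mid <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
    round((BiocGenerics::start(g) + BiocGenerics::end(g)) / 2), width = 1))
  hit <- GenomicRanges::findOverlaps(mid, regionMap, select = "first")
  label <- regionMap$label[hit]
  if (grouping == "arm_vs_centre") {
    keep <- !is.na(label) & chrom != xChrom
    grp <- ifelse(label[keep] == "centre", "centre", "arm")
    x <- ds[keep][grp == "arm"]
    y <- ds[keep][grp == "centre"]
    nms <- c("arm", "centre")
  } else {
    x <- ds[chrom == xChrom]
    y <- ds[chrom != xChrom]
    nms <- c("X", "autosome")
  }
  if (!length(x) || !length(y)) stop("one of the groups is empty")
  exact <- length(x) < 10 && length(y) < 10
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(grouping = grouping,
       groups = stats::setNames(list(x, y), nms),
       u_statistic = unname(wt$statistic),
       p_value = min(1, wt$p.value),
       medians = stats::setNames(c(stats::median(x), stats::median(y)), nms),
       n = stats::setNames(c(length(x), length(y)), nms))
}

#' Intergenic distances per chromosome
#'
#' Distances between consecutive gene spans along each chromosome
#' (strand-ignored); overlapping or book-ended genes contribute 0.
#'
#' @param genes `GRanges` of genes.
#' @return a list with `distances` (per-chromosome numeric vectors) and
#'   `medians`.
#' @export
intergenicDistances <- function(genes) {
  chrom <- as.character(GenomeInfoDb::seqnames(genes))
  st <- BiocGenerics::start(genes)
  en <- BiocGenerics::end(genes)
  dists <- lapply(split(seq_along(genes), chrom), function(ii) {
    ii <- ii[order(st[ii])]
    if (length(ii) < 2L) return(numeric(0))
    pmax(0, st[ii][-1] - en[ii][-length(ii)] - 1)
  })
  list(distances = dists,
       medians = vapply(dists, function(d)
         if (length(d)) stats::median(d) else NA_real_, numeric(1)))
}
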