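## Nei-Gojobori (1986) counting of synonymous and nonsynonymous
## substitutions with Jukes-Cantor multiple-hit correction. This is the
## package's core substitution estimator; see the methods vignette for how
## its absolute values relate to ML codon-model estimates.

#' Back-translate a protein alignment into a codon alignment
#'
#' Replaces each aligned residue by its source codon, drops every column
#' containing a gap or a non-ACGT base, and strips terminal stop codons.
#' Each protein must translate exactly from its CDS under the standard code.
#'
#' @param geneId identifier for the pair.
#' @param protA,protB aligned protein strings (equal length, `-` for gaps).
#' @param cdsA,cdsB unaligned coding sequences.
#' @return a [CodonAlignment-class].
#' @export
buildCodonAlignment <- function(geneId, protA, protB, cdsA, cdsB) {
  protA <- toupper(protA); protB <- toupper(protB)
  if (nchar(protA) != nchar(protB)) stop("aligned protein lengths differ")
  tb <- .codon_tables()
  back <- function(prot, cds, label) {
    cds <- toupper(cds)
    resid <- strsplit(prot, "")[[1]]
    aa_n <- sum(resid != "-")
    ncod <- nchar(cds) %/% 3L
    ## tolerate one terminal stop codon on the CDS
    if (ncod == aa_n + 1L) {
      last <- substr(cds, nchar(cds) - 2L, nchar(cds))
      if (!is.na(tb$idx[last]) && tb$is_stop[tb$idx[last]]) {
        cds <- substr(cds, 1L, nchar(cds) - 3L)
        ncod <- ncod - 1L
      }
    }
    if (ncod != aa_n) {
      stop("CDS of ", label, " has ", ncod, " codons but alignment has ",
           aa_n, " residues")
    }
    cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    out <- rep(NA_character_, length(resid))
    out[resid != "-"] <- cods
    ## translation check (ambiguous codons pass through; dropped later)
    k <- 0L
    for (i in seq_along(resid)) {
      if (resid[i] == "-") next
      k <- k + 1L
      ci <- tb$idx[out[i]]
      if (!is.na(ci)) {
        if (tb$is_stop[ci]) {
          stop("internal stop codon in CDS of ", label, " at residue ", k)
        }
        if (tb$aa[ci] != resid[i] && resid[i] != "X") {
          stop("translation mismatch for ", label, " at residue ", k,
               ": codon ", out[i], " encodes ", tb$aa[ci], ", alignment has ",
               resid[i])
        }
      }
    }
    out
  }
  codA <- back(protA, cdsA, "seq_a")
  codB <- back(protB, cdsB, "seq_b")
  ok <- !is.na(codA) & !is.na(codB) &
    !grepl("[^ACGT]", codA) & !grepl("[^ACGT]", codB)
  CodonAlignment(geneId, paste(codA[ok], collapse = ""),
                 paste(codB[ok], collapse = ""))
}

## workhorse on codon-index vectors; returns the NG86 quantities
.ng86_counts <- function(ia, ib) {
  tb <- .codon_tables()
  s_sites <- (sum(tb$s_sites[ia]) + sum(tb$s_sites[ib])) / 2
  n_sites <- (sum(tb$n_sites[ia]) + sum(tb$n_sites[ib])) / 2
  diff <- ia != ib
  sd <- sum(tb$Sd[cbind(ia[diff], ib[diff])])
  nd <- sum(tb$Nd[cbind(ia[diff], ib[diff])])
  c(s_sites = s_sites, n_sites = n_sites, sd = sd, nd = nd)
}

.jukes_cantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Estimate dS and dN for a codon alignment (NG86)
#'
#' Nei-Gojobori counting: synonymous/nonsynonymous site counts are averaged
#' over the two sequences; observed differences in codons differing at more
#' than one position are averaged over all substitution orderings, excluding
#' pathways passing through stop codons; proportions `pS = sd/s_sites` and
#' `pN = nd/n_sites` are corrected for multiple hits with the Jukes-Cantor
#' formula `d = -3/4 ln(1 - 4p/3)` (undefined, `NA`, when `p >= 3/4`).
#'
#' @param aln a [CodonAlignment-class], or anything accepted by
#'   `CodonAlignment()` via `geneId`, `seqA`, `seqB`.
#' @return a one-row `data.frame` with columns `gene_id`, `s_sites`,
#'   `n_sites`, `sd`, `nd`, `ds`, `dn`, `nc_a`, `nc_b` (per-sequence Wright
#'   Nc), and `defined` (FALSE when either rate is saturated/undefined).
#' @examples
#' estimateDsDn(CodonAlignment("g1", "TTT", "TTA"))
#' @export
estimateDsDn <- function(aln) {
  stopifnot(methods::is(aln, "CodonAlignment"))
  if (length(aln) == 0L) stop("zero aligned codons")
  ia <- .codon_indices(aln@seqA, "seq_a")
  ib <- .codon_indices(aln@seqB, "seq_b")
  cnt <- .ng86_counts(ia, ib)
  ps <- if (cnt[["s_sites"]] > 0) cnt[["sd"]] / cnt[["s_sites"]] else 0
  pn <- if (cnt[["n_sites"]] > 0) cnt[["nd"]] / cnt[["n_sites"]] else 0
  ds <- .jukes_cantor(ps)
  dn <- .jukes_cantor(pn)
  nc_a <- computeNc(aln@seqA)$nc
  nc_b <- computeNc(aln@seqB)$nc
  data.frame(gene_id = aln@geneId,
             s_sites = cnt[["s_sites"]], n_sites = cnt[["n_sites"]],
             sd = cnt[["sd"]], nd = cnt[["nd"]],
             ds = ds, dn = dn, nc_a = nc_a, nc_b = nc_b,
             defined = !is.na(ds) && !is.na(dn))
}

#' Estimate dS/dN for many codon-aligned CDS pairs at once
#'
#' Vectorised driver over pre-aligned CDS pairs (equal-length, gap-free,
#' e.g. simulator output or back-translated alignments).
#'
#' @param geneIds character vector of pair ids.
#' @param cdsA,cdsB character vectors (or `DNAStringSet`) of aligned CDS.
#' @return a `data.frame`, one row per pair, as in [estimateDsDn()].
#' @export
estimateDsDnMany <- function(geneIds, cdsA, cdsB) {
  cdsA <- as.character(cdsA); cdsB <- as.character(cdsB)
  stopifnot(length(geneIds) == length(cdsA), length(cdsA) == length(cdsB))
  out <- lapply(seq_along(geneIds), function(i) {
    estimateDsDn(CodonAlignment(geneIds[i], cdsA[i], cdsB[i]))
  })
  do.call(rbind, out)
}
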