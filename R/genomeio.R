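## Genome I/O, assembly statistics and the residual-haplotype filter.

#' Read a genome assembly from FASTA
#'
#' Reads a (multi-)FASTA into an [Assembly-class]: record order preserved,
#' sequences uppercased, ids taken as the first whitespace-delimited token of
#' each header. Duplicate ids, empty records and characters outside
#' `{A,C,G,T,N}` are errors (the offending scaffold and position are named).
#'
#' @param path path to a FASTA file.
#' @return an [Assembly-class].
#' @seealso [writeAssembly()]
#' @export
readAssembly <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readBStringSet(path)     # B to catch bad characters ourselves
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) {
    stop("duplicate scaffold id in ", path, ": ",
         names(x)[duplicated(names(x))][1])
  }
  w <- Biostrings::width(x)
  if (any(w == 0L)) {
    stop("empty record in ", path, ": ", names(x)[which(w == 0L)[1]])
  }
  chr <- toupper(as.character(x))
  bad <- regexpr("[^ACGTN]", chr)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("non-IUPAC (non-ACGTN) character in scaffold '", names(x)[i],
         "' at position ", bad[i])
  }
  Assembly(stats::setNames(chr, names(x)))
}

#' Write an assembly to FASTA
#'
#' Sequences are wrapped at 60 columns; a write/read round trip reproduces
#' the [Assembly-class] exactly.
#'
#' @param x an [Assembly-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAssembly <- function(x, path) {
  stopifnot(methods::is(x, "DNAStringSet"))
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' @rdname assemblyStats
#' @export
setMethod("assemblyStats", "DNAStringSet", function(x, ...) {
  if (length(x) == 0L) stop("empty assembly")
  len <- sort(Biostrings::width(x), decreasing = TRUE)
  total <- sum(as.numeric(len))
  csum <- cumsum(as.numeric(len))
  i50 <- which(csum >= total / 2)[1]
  freq <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)
  nN <- sum(freq[, "other"])
  gc <- sum(freq[, c("C", "G")])
  atgc <- sum(freq[, c("A", "C", "G", "T")])
  methods::new("AssemblyStats",
    totalBp = total, nScaffolds = length(x), n50Bp = len[i50],
    l50 = i50, largestBp = len[1], gapBp = as.numeric(nN),
    gcPercent = if (atgc > 0) 100 * gc / atgc else 0)
})

#' @rdname gapRuns
#' @export
setMethod("gapRuns", "DNAStringSet", function(x, ...) {
  out <- lapply(seq_along(x), function(i) {
    r <- IRanges::reduce(methods::as(
      Biostrings::matchPattern("N", x[[i]]), "IRanges"))
    if (length(r) == 0L) return(NULL)
    data.frame(scaffold = names(x)[i], start = BiocGenerics::start(r),
               end = BiocGenerics::end(r), width = BiocGenerics::width(r))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), width = integer(0))
  }
  rownames(out) <- NULL
  out
})

#' Remove residual-haplotype scaffolds
#'
#' A scaffold is called a residual haplotype (haplotig) and removed when it
#' is almost entirely alignable within strictly larger scaffolds
#' (aligned fraction > `minCovered`) **and** its read depth sits in a band
#' around half the assembly-wide mean depth (`depthBand` times the mean;
#' symmetric around 0.5x by default). The assembly-wide mean is the
#' length-weighted mean over all input scaffolds.
#'
#' @param assembly an [Assembly-class].
#' @param selfAlignments `data.frame` with columns `scaffold` and
#'   `covered_fraction` (fraction of the scaffold's length aligned within
#'   strictly larger scaffolds, in `[0,1]`). Scaffolds absent from the table
#'   are taken as fraction 0.
#' @param coverage `data.frame` with columns `scaffold` and `mean_depth`;
#'   every scaffold must be present.
#' @param minCovered containment-fraction threshold (default 0.90).
#' @param depthBand numeric length-2, the relative depth band (default
#'   `c(0.35, 0.65)`).
#' @return a list with elements `kept` ([Assembly-class]), `removed`
#'   (character vector of scaffold ids) and `meanDepth`.
#' @export
filterResidualHaplotypes <- function(assembly, selfAlignments, coverage,
                                     minCovered = 0.90,
                                     depthBand = c(0.35, 0.65)) {
  stopifnot(is.data.frame(coverage),
            all(c("scaffold", "mean_depth") %in% names(coverage)),
            length(depthBand) == 2L, depthBand[1] <= depthBand[2])
  nm <- names(assembly)
  missing <- setdiff(nm, coverage$scaffold)
  if (length(missing)) {
    stop("scaffold missing from coverage track: ", missing[1])
  }
  depth <- coverage$mean_depth[match(nm, coverage$scaffold)]
  if (any(depth < 0)) stop("negative depth in coverage track")
  w <- Biostrings::width(assembly)
  mean_depth <- sum(depth * as.numeric(w)) / sum(as.numeric(w))
  frac <- rep(0, length(nm))
  if (!is.null(selfAlignments) && nrow(selfAlignments)) {
    stopifnot(all(c("scaffold", "covered_fraction") %in%
                    names(selfAlignments)))
    m <- match(nm, selfAlignments$scaffold)
    frac[!is.na(m)] <- selfAlignments$covered_fraction[m[!is.na(m)]]
  }
  drop <- frac > minCovered &
    depth >= depthBand[1] * mean_depth &
    depth <= depthBand[2] * mean_depth
  list(kept = methods::new("Assembly", assembly[!drop]),
       removed = nm[drop], meanDepth = mean_depth)
}

#' Read gene models from GFF3
#'
#' Imports gene and CDS features, returning one [GenomicRanges::GRanges] row
#' per gene (1-based closed coordinates, as in GFF3) with metadata columns
#' `gene_id`, `cds_bp` (summed CDS length), and `coding` (`TRUE` when the
#' CDS length is a positive multiple of 3; otherwise the record is flagged
#' non-coding with a warning). CDS segments are carried in an `IRangesList`
#' column `cds`.
#'
#' @param path path to a GFF3 file.
#' @return a `GRanges` of genes, sorted by position within seqnames.
#' @export
readGeneModels <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  g <- rtracklayer::import(path, format = "gff3")
  genes <- g[g$type == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  gene_id <- genes$ID
  if (is.null(gene_id) || any(is.na(gene_id))) {
    stop("gene features must carry an ID attribute")
  }
  cds <- g[g$type == "CDS"]
  parent <- as.character(cds$Parent)
  ## CDS rows may point at an mRNA; fall back to matching mRNA Parent -> gene
  mrna <- g[g$type == "mRNA"]
  if (length(mrna)) {
    map <- stats::setNames(as.character(mrna$Parent), mrna$ID)
    hit <- parent %in% names(map)
    parent[hit] <- map[parent[hit]]
  }
  cdf <- data.frame(start = BiocGenerics::start(cds),
                    end = BiocGenerics::end(cds),
                    parent = factor(parent, levels = gene_id))
  cds_by_gene <- IRanges::IRangesList(lapply(
    split(cdf[, 1:2], cdf$parent), function(d)
      IRanges::reduce(IRanges::IRanges(d$start, d$end))))
  cds_bp <- sum(BiocGenerics::width(cds_by_gene))
  coding <- cds_bp > 0 & cds_bp %% 3L == 0L
  if (any(cds_bp > 0 & !coding)) {
    warning(sum(cds_bp > 0 & !coding),
            " gene model(s) with CDS length not divisible by 3; ",
            "flagged non-coding")
  }
  out <- genes
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    gene_id = gene_id, cds_bp = as.integer(cds_bp), coding = coding,
    cds = cds_by_gene)
  BiocGenerics::sort(out, ignore.strand = TRUE)
}

#' Read a one-to-one ortholog table
#'
#' Two-column TSV (`gene_a`, `gene_b`; header optional). Pairs must be
#' one-to-one: a gene id appearing in more than one pair is an error.
#'
#' @param path path to the TSV.
#' @return a `data.frame` with columns `gene_a`, `gene_b`.
#' @export
readOrthologTable <- function(path) {
  if (!file.exists(path)) stop("ortholog table not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0)))
  }
  header <- grepl("^gene_a\\b", first)
  df <- utils::read.delim(path, header = header,
                          col.names = c("gene_a", "gene_b"),
                          colClasses = "character")
  if (anyDuplicated(df$gene_a) || anyDuplicated(df$gene_b)) {
    dup <- c(df$gene_a[duplicated(df$gene_a)],
             df$gene_b[duplicated(df$gene_b)])[1]
    stop("gene appears in more than one ortholog pair: ", dup)
  }
  df
}

#' Read a per-scaffold coverage track
#'
#' @param path TSV with columns `scaffold`, `mean_depth` (header optional).
#' @return a `data.frame` with those two columns; depths must be >= 0.
#' @export
readCoverageTrack <- function(path) {
  if (!file.exists(path)) stop("coverage track not found: ", path)
  first <- readLines(path, n = 1L)
  header <- grepl("^scaffold\\b", first)
  df <- utils::read.delim(path, header = header,
                          col.names = c("scaffold", "mean_depth"))
  df$mean_depth <- as.numeric(df$mean_depth)
  if (any(is.na(df$mean_depth)) || any(df$mean_depth < 0)) {
    stop("coverage depths must be non-negative numbers")
  }
  df
}
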