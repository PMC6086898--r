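#' @import methods
NULL

#' Genome assembly container
#'
#' An `Assembly` is a [Biostrings::DNAStringSet] restricted to the alphabet
#' `{A,C,G,T,N}`, with unique, non-empty scaffold names and non-empty
#' sequences. Scaffold order is preserved from the source FASTA.
#'
#' @slot .Data inherited `DNAStringSet` payload.
#' @seealso [readAssembly()], [assemblyStats()], [gapRuns()]
#' @exportClass Assembly
setClass("Assembly", contains = "DNAStringSet")

setValidity("Assembly", function(object) {
  msgs <- character(0)
  if (length(object) == 0L) return(TRUE)
  nm <- names(object)
  if (is.null(nm) || any(!nzchar(nm))) {
    msgs <- c(msgs, "all scaffolds must be named")
  } else if (anyDuplicated(nm)) {
    msgs <- c(msgs, paste0("duplicate scaffold id: ",
                           nm[duplicated(nm)][1]))
  }
  if (length(object) && any(Biostrings::width(object) == 0L)) {
    msgs <- c(msgs, "empty scaffold sequence")
  }
  if (length(object)) {
    freq <- Biostrings::alphabetFrequency(object, baseOnly = FALSE)
    extra <- rowSums(freq) -
      rowSums(freq[, c("A", "C", "G", "T", "N"), drop = FALSE])
    if (any(extra > 0)) {
      msgs <- c(msgs, paste0("scaffold '", nm[which(extra > 0)[1]],
                             "' contains characters outside {A,C,G,T,N}"))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an Assembly from sequences
#'
#' @param x a named character vector or `DNAStringSet` of scaffold
#'   sequences. Lowercase letters are normalised to uppercase.
#' @return an [Assembly-class] object.
#' @examples
#' Assembly(c(chrI = "ACGTNNACGT", chrII = "GGCC"))
#' @export
Assembly <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  methods::new("Assembly", x)
}

#' Summary statistics of a genome assembly
#'
#' Holds the usual contiguity and composition metrics: total length, number
#' of scaffolds, N50/L50, largest scaffold, total gap (N-run) length, and
#' GC percentage computed over non-N bases.
#'
#' @slot totalBp,nScaffolds,n50Bp,l50,largestBp,gapBp numeric scalars.
#' @slot gcPercent GC fraction times 100, over non-N bases.
#' @exportClass AssemblyStats
setClass("AssemblyStats",
  representation(totalBp = "numeric", nScaffolds = "numeric",
                 n50Bp = "numeric", l50 = "numeric", largestBp = "numeric",
                 gapBp = "numeric", gcPercent = "numeric"))

setValidity("AssemblyStats", function(object) {
  msgs <- character(0)
  if (object@nScaffolds >= 1 && object@l50 < 1) {
    msgs <- c(msgs, "l50 must be >= 1 for a non-empty assembly")
  }
  if (object@n50Bp > object@largestBp || object@largestBp > object@totalBp) {
    msgs <- c(msgs, "need n50Bp <= largestBp <= totalBp")
  }
  if (object@gcPercent < 0 || object@gcPercent > 100) {
    msgs <- c(msgs, "gcPercent outside [0, 100]")
  }
  if (object@gapBp > object@totalBp) msgs <- c(msgs, "gapBp > totalBp")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn AssemblyStats-class pretty printer
#' @param object an `AssemblyStats`.
#' @export
setMethod("show", "AssemblyStats", function(object) {
  cat("AssemblyStats\n")
  cat(sprintf("  scaffolds : %d\n", as.integer(object@nScaffolds)))
  cat(sprintf("  total bp  : %s\n", format(object@totalBp, big.mark = ",")))
  cat(sprintf("  largest bp: %s\n", format(object@largestBp, big.mark = ",")))
  cat(sprintf("  N50 bp    : %s  (L50 = %d)\n",
              format(object@n50Bp, big.mark = ","), as.integer(object@l50)))
  cat(sprintf("  gaps bp   : %s\n", format(object@gapBp, big.mark = ",")))
  cat(sprintf("  GC %%      : %.2f\n", object@gcPercent))
})

#' Pairwise codon alignment
#'
#' Two aligned coding sequences after removal of gap/ambiguity columns and
#' terminal stop codons: equal length, a multiple of 3, `{A,C,G,T}` only,
#' and no internal stop codon in either sequence.
#'
#' @slot geneId identifier of the ortholog pair.
#' @slot seqA,seqB aligned coding strings.
#' @seealso [buildCodonAlignment()], [estimateDsDn()]
#' @exportClass CodonAlignment
setClass("CodonAlignment",
  representation(geneId = "character", seqA = "character",
                 seqB = "character"))

setValidity("CodonAlignment", function(object) {
  msgs <- character(0)
  a <- object@seqA
  b <- object@seqB
  if (nchar(a) != nchar(b)) msgs <- c(msgs, "aligned lengths differ")
  if (nchar(a) %% 3L != 0L) msgs <- c(msgs, "length not a multiple of 3")
  if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b)) {
    msgs <- c(msgs, "sequences must contain only A,C,G,T")
  }
  if (!length(msgs) && nchar(a) >= 3L) {
    tb <- .codon_tables()
    for (s in c(a, b)) {
      ii <- .codon_indices(s)
      if (any(tb$is_stop[ii])) {
        msgs <- c(msgs, "internal stop codon present")
        break
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CodonAlignment
#' @param geneId identifier of the ortholog pair.
#' @param seqA,seqB aligned coding strings (equal length, multiple of 3).
#' @return a [CodonAlignment-class] object.
#' @export
CodonAlignment <- function(geneId, seqA, seqB) {
  methods::new("CodonAlignment", geneId = as.character(geneId),
               seqA = toupper(seqA), seqB = toupper(seqB))
}

#' @describeIn CodonAlignment-class number of aligned codons
#' @param x a `CodonAlignment`.
#' @export
setMethod("length", "CodonAlignment", function(x) nchar(x@seqA) %/% 3L)

#' @describeIn CodonAlignment-class pretty printer
#' @param object a `CodonAlignment`.
#' @export
setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment '%s': %d codons\n",
              object@geneId, length(object)))
})

#' Configuration of the neutral divergence clock
#'
#' Parameters of the dating step: the per-site per-generation mutation rate
#' `mu`, the generation time in days used only for the year conversion, the
#' outlier thresholds applied before estimation (records with `dn > dnMax`,
#' `ds > dsMax` or `ds < dsMin` are removed), and the codon-usage reference
#' `ncReference` to which dS values are calibrated.
#'
#' @slot mu mutation rate per site per generation (default `9.0e-9`).
#' @slot generationDays days per generation (default 30).
#' @slot dnMax,dsMax,dsMin outlier thresholds (defaults 0.5, 5, 5e-4).
#' @slot ncReference Nc of unbiased codon usage (default 61).
#' @exportClass DivergenceConfig
setClass("DivergenceConfig",
  representation(mu = "numeric", generationDays = "numeric",
                 dnMax = "numeric", dsMax = "numeric", dsMin = "numeric",
                 ncReference = "numeric"))

setValidity("DivergenceConfig", function(object) {
  msgs <- character(0)
  if (object@mu <= 0) msgs <- c(msgs, "mu must be > 0")
  if (object@dsMin >= object@dsMax) msgs <- c(msgs, "need dsMin < dsMax")
  if (object@generationDays <= 0) msgs <- c(msgs, "generationDays must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DivergenceConfig
#' @param mu per-site per-generation mutation rate.
#' @param generationDays generation time in days (year conversion only).
#' @param dnMax,dsMax,dsMin outlier-removal thresholds.
#' @param ncReference Nc value representing unbiased codon usage.
#' @return a [DivergenceConfig-class] object.
#' @examples
#' divergenceConfig()
#' @export
divergenceConfig <- function(mu = 9.0e-9, generationDays = 30,
                             dnMax = 0.5, dsMax = 5, dsMin = 0.0005,
                             ncReference = 61) {
  methods::new("DivergenceConfig", mu = mu, generationDays = generationDays,
               dnMax = dnMax, dsMax = dsMax, dsMin = dsMin,
               ncReference = ncReference)
}

#' @describeIn DivergenceConfig-class pretty printer
#' @param object a `DivergenceConfig`.
#' @export
setMethod("show", "DivergenceConfig", function(object) {
  cat(sprintf(
    "DivergenceConfig: mu=%.3g/site/gen, %g d/gen, filters dN<=%g, %g<=dS<=%g, Nc ref %g\n",
    object@mu, object@generationDays, object@dnMax, object@dsMin,
    object@dsMax, object@ncReference))
})

#' Result of the neutral divergence dating
#'
#' @slot nInput,nRetained gene counts before/after outlier filtering.
#' @slot medianAdjustedDs median Nc-calibrated dS across retained genes.
#' @slot tGenerations divergence age in generations, `medianAdjustedDs / mu`.
#' @slot tYears age in years using `generationDays` and 365.25 d/yr.
#' @slot slope,intercept the dS-on-Nc regression used for calibration.
#' @slot filterCounts named tally of removals per rule.
#' @slot config the [DivergenceConfig-class] used.
#' @exportClass DivergenceResult
setClass("DivergenceResult",
  representation(nInput = "numeric", nRetained = "numeric",
                 medianAdjustedDs = "numeric", tGenerations = "numeric",
                 tYears = "numeric", slope = "numeric",
                 intercept = "numeric", filterCounts = "numeric",
                 config = "DivergenceConfig"))

setValidity("DivergenceResult", function(object) {
  msgs <- character(0)
  if (!is.na(object@tGenerations) && object@tGenerations < 0) {
    msgs <- c(msgs, "tGenerations must be >= 0")
  }
  if (object@nRetained > object@nInput) msgs <- c(msgs, "nRetained > nInput")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn DivergenceResult-class pretty printer
#' @param object a `DivergenceResult`.
#' @export
setMethod("show", "DivergenceResult", function(object) {
  cat("DivergenceResult\n")
  cat(sprintf("  genes retained    : %d / %d\n",
              as.integer(object@nRetained), as.integer(object@nInput)))
  cat(sprintf("  median adjusted dS: %.5g\n", object@medianAdjustedDs))
  cat(sprintf("  T (generations)   : %.5g\n", object@tGenerations))
  cat(sprintf("  T (years)         : %.5g\n", object@tYears))
  cat(sprintf("  dS ~ Nc slope     : %.4g (intercept %.4g)\n",
              object@slope, object@intercept))
})

#' Consolidated pipeline run report
#'
#' One record per stage (`stats`, `divergence`, `ltr`, `synteny`): either the
#' stage's headline results or the marker `skipped`. Produced by
#' [runPipeline()].
#'
#' @slot stages named list of per-stage results (or `"skipped"`).
#' @slot seed integer seed echoed from the configuration.
#' @slot version package version string.
#' @slot config the validated configuration, echoed.
#' @exportClass RunReport
setClass("RunReport",
  representation(stages = "list", seed = "numeric", version = "character",
                 config = "list"))

#' @describeIn RunReport-class pretty printer
#' @param object a `RunReport`.
#' @export
setMethod("show", "RunReport", function(object) {
  cat(sprintf("RunReport (nemadiv %s, seed %s)\n", object@version,
              format(object@seed)))
  for (nm in names(object@stages)) {
    st <- object@stages[[nm]]
    if (identical(st, "skipped")) {
      cat(sprintf("  %-10s skipped\n", nm))
    } else {
      cat(sprintf("  %-10s done\n", nm))
    }
  }
})
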