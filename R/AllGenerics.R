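#' Compute assembly summary statistics
#'
#' @param x an [Assembly-class] (or `DNAStringSet`).
#' @param ... passed to methods.
#' @return an [AssemblyStats-class] object.
#' @details N50 is the length of the scaffold at which the cumulative sum of
#'   descending scaffold lengths first reaches half the total assembly
#'   length; L50 is the number of scaffolds up to and including that one.
#'   GC is computed over non-N bases; gaps are the summed lengths of N-runs.
#' @examples
#' a <- Assembly(c(s1 = strrep("A", 50), s2 = strrep("ATGC", 10)))
#' assemblyStats(a)
#' @export
setGeneric("assemblyStats", function(x, ...) standardGeneric("assemblyStats"))

#' Locate gap (N) runs in an assembly
#'
#' @param x an [Assembly-class].
#' @param ... passed to methods.
#' @return a `data.frame` with columns `scaffold`, `start`, `end` (1-based
#'   closed coordinates) and `width`, one row per maximal N-run.
#' @examples
#' gapRuns(Assembly(c(s1 = "AANNNAA")))
#' @export
setGeneric("gapRuns", function(x, ...) standardGeneric("gapRuns"))

## ---- simple slot accessors -------------------------------------------------

#' Accessors for AssemblyStats and DivergenceResult
#'
#' Small reader functions so downstream code never touches slots directly.
#'
#' @param x an [AssemblyStats-class] or [DivergenceResult-class] object.
#' @return a numeric scalar.
#' @name accessors
NULL

#' @rdname accessors
#' @export
n50 <- function(x) x@n50Bp

#' @rdname accessors
#' @export
l50 <- function(x) x@l50

#' @rdname accessors
#' @export
totalBp <- function(x) x@totalBp

#' @rdname accessors
#' @export
largestBp <- function(x) x@largestBp

#' @rdname accessors
#' @export
gapBp <- function(x) x@gapBp

#' @rdname accessors
#' @export
gcPercent <- function(x) x@gcPercent

#' @rdname accessors
#' @export
nScaffolds <- function(x) x@nScaffolds

#' @rdname accessors
#' @export
tGenerations <- function(x) x@tGenerations

#' @rdname accessors
#' @export
tYears <- function(x) x@tYears

#' @rdname accessors
#' @export
medianAdjustedDs <- function(x) x@medianAdjustedDs

#' @rdname accessors
#' @export
nRetained <- function(x) x@nRetained

#' Convert AssemblyStats to a one-row data.frame
#'
#' @param x an [AssemblyStats-class] object.
#' @param row.names,optional,... ignored; present for generic consistency.
#' @return a one-row `data.frame`.
#' @export
as.data.frame.AssemblyStats <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(total_bp = x@totalBp, n_scaffolds = x@nScaffolds,
             n50_bp = x@n50Bp, l50 = x@l50, largest_bp = x@largestBp,
             gap_bp = x@gapBp, gc_percent = x@gcPercent)
}
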