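## Merging of LTR retrotransposon candidates from two detectors and the
## three-rule confidence classification (full / partial / LTR-only).

.LTR_DOMAINS <- c("RT", "PR", "IN", "RH")

.check_candidates <- function(x) {
  need <- c("candidate_id", "scaffold", "start", "end")
  if (!all(need %in% names(x))) {
    stop("candidate table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(x$end < x$start)) {
    stop("negative-length span for candidate ",
         x$candidate_id[which(x$end < x$start)[1]])
  }
  invisible(x)
}

#' Merge LTR candidates from two detectors
#'
#' Two candidates are merged when they lie on the same scaffold and overlap
#' reciprocally by at least `minReciprocal` of each span. The merged span is
#' the union; domain hits are unioned keeping the minimum e-value per
#' domain; `source` becomes `"merged"`. Candidates without a partner are
#' kept as-is. Spans are 1-based closed.
#'
#' @param listA,listB candidate `data.frame`s with columns `candidate_id`,
#'   `scaffold`, `start`, `end` and optionally `ltr5_start`, `ltr5_end`,
#'   `ltr3_start`, `ltr3_end`, `source`, `ltr_similarity`.
#' @param domains optional combined domain-hit `data.frame`
#'   (`candidate_id`, `domain`, `e_value`); merged candidates inherit the
#'   union of their parents' hits.
#' @param minReciprocal reciprocal-overlap threshold (default 0.5).
#' @return a list with `candidates` (merged table, new ids for merged rows)
#'   and `domains` (remapped domain table).
#' @export
mergeCandidates <- function(listA, listB, domains = NULL,
                            minReciprocal = 0.5) {
  .check_candidates(listA)
  .check_candidates(listB)
  if (!"source" %in% names(listA)) listA$source <- "detector_a"
  if (!"source" %in% names(listB)) listB$source <- "detector_b"
  common <- union(names(listA), names(listB))
  for (nm in setdiff(common, names(listA))) listA[[nm]] <- NA
  for (nm in setdiff(common, names(listB))) listB[[nm]] <- NA
  listB <- listB[, names(listA), drop = FALSE]

  grA <- GenomicRanges::GRanges(listA$scaffold,
                                IRanges::IRanges(listA$start, listA$end))
  grB <- GenomicRanges::GRanges(listB$scaffold,
                                IRanges::IRanges(listB$start, listB$end))
  hits <- GenomicRanges::findOverlaps(grA, grB)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- BiocGenerics::width(IRanges::pintersect(
    IRanges::ranges(grA)[qi], IRanges::ranges(grB)[si]))
  recip <- ov / BiocGenerics::width(grA)[qi] >= minReciprocal &
    ov / BiocGenerics::width(grB)[si] >= minReciprocal
  qi <- qi[recip]; si <- si[recip]
  ## one merge partner per candidate: keep best-overlap pair greedily
  ord <- order(-ov[recip])
  usedA <- logical(nrow(listA)); usedB <- logical(nrow(listB))
  pairs <- list()
  for (k in ord) {
    if (usedA[qi[k]] || usedB[si[k]]) next
    usedA[qi[k]] <- TRUE; usedB[si[k]] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(qi[k], si[k])
  }
  merged <- lapply(seq_along(pairs), function(m) {
    a <- listA[pairs[[m]][1], ]; b <- listB[pairs[[m]][2], ]
    out <- a
    out$candidate_id <- paste0("merged_", m)
    out$start <- min(a$start, b$start)
    out$end <- max(a$end, b$end)
    out$source <- "merged"
    if ("ltr_similarity" %in% names(out)) {
      out$ltr_similarity <- suppressWarnings(
        max(c(a$ltr_similarity, b$ltr_similarity), na.rm = TRUE))
      if (!is.finite(out$ltr_similarity)) out$ltr_similarity <- NA
    }
    out
  })
  keptA <- listA[!usedA, , drop = FALSE]
  keptB <- listB[!usedB, , drop = FALSE]
  cand <- do.call(rbind, c(merged, list(keptA, keptB)))
  rownames(cand) <- NULL

  dom <- domains
  if (!is.null(dom) && nrow(dom)) {
    stopifnot(all(c("candidate_id", "domain", "e_value") %in% names(dom)))
    map <- stats::setNames(cand$candidate_id, cand$candidate_id)
    for (m in seq_along(pairs)) {
      ida <- listA$candidate_id[pairs[[m]][1]]
      idb <- listB$candidate_id[pairs[[m]][2]]
      map[c(ida, idb)] <- paste0("merged_", m)
    }
    dom$candidate_id <- unname(map[dom$candidate_id])
    dom <- dom[!is.na(dom$candidate_id), , drop = FALSE]
    ## min e-value per (candidate, domain)
    key <- paste(dom$candidate_id, dom$domain)
    dom <- dom[order(key, dom$e_value), , drop = FALSE]
    dom <- dom[!duplicated(paste(dom$candidate_id, dom$domain)), ,
               drop = FALSE]
    rownames(dom) <- NULL
  }
  list(candidates = cand, domains = dom)
}

#' Classify LTR candidates into confidence classes
#'
#' Three-rule classification, applied in two passes so that the LTR-only
#' rule can reference the full set: (1) `full` — all four retrotransposon
#' protein domains (RT, protease PR, integrase IN, RNase H RH) present with
#' e-value < `eMax`; (2) `partial` — at least one such domain but not all
#' four; (3) `ltr_only` — no qualifying domain but LTR similarity to a
#' full element's LTRs > `minSimilarity` percent. Everything else is
#' `rejected`. Classes are mutually exclusive and exhaustive.
#'
#' @param candidates candidate `data.frame`; the column `ltr_similarity`
#'   (percent identity of the candidate's LTRs to LTRs of full elements) is
#'   consumed as input where present.
#' @param domains domain-hit `data.frame` (`candidate_id`, `domain` in
#'   `{RT, PR, IN, RH, other}`, `e_value`).
#' @param eMax e-value threshold for a qualifying domain (default 1e-20).
#' @param minSimilarity percent-identity threshold for rule 3 (default 95).
#' @return the candidate table with a `class` factor column
#'   (`full`, `partial`, `ltr_only`, `rejected`).
#' @export
classifyCandidates <- function(candidates, domains, eMax = 1e-20,
                               minSimilarity = 95) {
  .check_candidates(candidates)
  if (is.null(domains)) {
    domains <- data.frame(candidate_id = character(0), domain = character(0),
                          e_value = numeric(0))
  }
  stopifnot(all(c("candidate_id", "domain", "e_value") %in% names(domains)))
  if (any(domains$e_value < 0)) stop("negative e-value in domain table")
  qual <- domains[domains$e_value < eMax &
                    domains$domain %in% .LTR_DOMAINS, , drop = FALSE]
  ndom <- vapply(candidates$candidate_id, function(id) {
    length(unique(qual$domain[qual$candidate_id == id]))
  }, integer(1))
  cls <- rep("rejected", nrow(candidates))
  cls[ndom == length(.LTR_DOMAINS)] <- "full"          # pass 1
  cls[ndom > 0 & ndom < length(.LTR_DOMAINS)] <- "partial"
  sim <- if ("ltr_similarity" %in% names(candidates)) {
    suppressWarnings(as.numeric(candidates$ltr_similarity))
  } else {
    rep(NA_real_, nrow(candidates))
  }
  any_full <- any(cls == "full")
  ltr_only <- ndom == 0 & !is.na(sim) & sim > minSimilarity & any_full
  cls[ltr_only] <- "ltr_only"                          # pass 2
  candidates$class <- factor(cls, levels = c("full", "partial", "ltr_only",
                                             "rejected"))
  candidates
}

#' Tally LTR candidates per confidence class
#'
#' @param classified output of [classifyCandidates()].
#' @return named integer vector over `full`, `partial`, `ltr_only`,
#'   `rejected`; sums to the number of input candidates.
#' @export
summarizeLtr <- function(classified) {
  if (!nrow(classified)) {
    return(c(full = 0L, partial = 0L, ltr_only = 0L, rejected = 0L))
  }
  stopifnot("class" %in% names(classified))
  tab <- table(factor(classified$class,
                      levels = c("full", "partial", "ltr_only", "rejected")))
  stats::setNames(as.integer(tab), names(tab))
}

#' Repeat landscape: masked fraction of the genome per family
#'
#' Intervals are merged within each family before summation so overlapping
#' annotations are not double-counted.
#'
#' @param masked `data.frame` with columns `family`, `scaffold`, `start`,
#'   `end` (1-based closed).
#' @param assembly an [Assembly-class] (or named scaffold lengths) defining
#'   total genome size and scaffold bounds.
#' @return a `data.frame` with `family`, `masked_bp`, `percent_of_genome`.
#' @export
repeatLandscape <- function(masked, assembly) {
  lens <- if (methods::is(assembly, "DNAStringSet")) {
    stats::setNames(Biostrings::width(assembly), names(assembly))
  } else {
    assembly
  }
  genome_bp <- sum(as.numeric(lens))
  if (!nrow(masked)) {
    return(data.frame(family = character(0), masked_bp = numeric(0),
                      percent_of_genome = numeric(0)))
  }
  stopifnot(all(c("family", "scaffold", "start", "end") %in% names(masked)))
  unknown <- setdiff(masked$scaffold, names(lens))
  if (length(unknown)) stop("interval on unknown scaffold: ", unknown[1])
  over <- masked$end > lens[masked$scaffold] | masked$start < 1
  if (any(over)) {
    stop("interval beyond scaffold end: ", masked$scaffold[which(over)[1]],
         ":", masked$start[which(over)[1]], "-", masked$end[which(over)[1]])
  }
  fam <- split(masked, masked$family)
  out <- do.call(rbind, lapply(names(fam), function(f) {
    d <- fam[[f]]
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      d$scaffold, IRanges::IRanges(d$start, d$end)))
    bp <- sum(as.numeric(BiocGenerics::width(gr)))
    data.frame(family = f, masked_bp = bp,
               percent_of_genome = 100 * bp / genome_bp)
  }))
  rownames(out) <- NULL
  out
}

#' Write classified candidates as GFF3
#'
#' One `LTR_retrotransposon` feature per candidate with the confidence
#' class in the attributes.
#'
#' @param classified output of [classifyCandidates()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLtrGff3 <- function(classified, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(classified)) {
    writeLines(sprintf(
      "%s\tnemadiv\tLTR_retrotransposon\t%d\t%d\t.\t.\t.\tID=%s;class=%s",
      classified$scaffold, as.integer(classified$start),
      as.integer(classified$end), classified$candidate_id,
      as.character(classified$class)), con)
  }
  invisible(path)
}
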