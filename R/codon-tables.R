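## Precomputed codon lookup tables shared by the NG86 estimator, Wright's Nc
## and the codon substitution simulator. Built once per session (lazily) from
## the standard genetic code; indices 1..64 follow the A,C,G,T x A,C,G,T x
## A,C,G,T enumeration below.

.nemadiv_cache <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings GENETIC_CODE
.build_codon_tables <- function() {
  codons <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))
  codons <- sort(codons)                      # AAA, AAC, ..., TTT
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  is_stop <- aa == "*"
  n <- length(codons)
  idx <- seq_len(n)
  names(idx) <- codons

  ## single-nucleotide neighbours: 9 per codon (3 positions x 3 alternatives)
  nb <- vector("list", n)
  for (i in idx) {
    cod <- strsplit(codons[i], "")[[1]]
    out <- character(0)
    for (p in 1:3) {
      for (b in setdiff(.BASES, cod[p])) {
        alt <- cod
        alt[p] <- b
        out <- c(out, paste(alt, collapse = ""))
      }
    }
    nb[[i]] <- unname(idx[out])
  }

  ## NG86 site counts: fraction of the 3 possible changes at each position
  ## that preserve the amino acid; changes into stop codons count as
  ## nonsynonymous. s + n = 3 for every sense codon.
  s_sites <- rep(NA_real_, n)
  for (i in idx) {
    if (is_stop[i]) next
    syn <- sum(aa[nb[[i]]] == aa[i] & !is_stop[nb[[i]]])
    s_sites[i] <- syn / 3
  }
  n_sites <- ifelse(is_stop, NA_real_, 3 - s_sites)

  ## synonymous / nonsynonymous neighbour sets (stop targets excluded), used
  ## by the simulator's event sampler
  syn_nb <- lapply(idx, function(i) {
    if (is_stop[i]) return(integer(0))
    v <- nb[[i]]
    v[aa[v] == aa[i] & !is_stop[v]]
  })
  nonsyn_nb <- lapply(idx, function(i) {
    if (is_stop[i]) return(integer(0))
    v <- nb[[i]]
    v[aa[v] != aa[i] & !is_stop[v]]
  })

  ## pathway-averaged observed differences per codon pair (NG86): enumerate
  ## every ordering of the differing positions, discard paths passing through
  ## a stop codon, average synonymous / nonsynonymous step counts over the
  ## remaining paths. If every path hits a stop, fall back to averaging over
  ## all paths with stop-involving steps scored nonsynonymous.
  Sd <- matrix(0, n, n, dimnames = list(codons, codons))
  Nd <- matrix(0, n, n, dimnames = list(codons, codons))
  perms2 <- list(1:2, 2:1)
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  for (i in idx) {
    if (is_stop[i]) next
    ci <- strsplit(codons[i], "")[[1]]
    for (j in idx) {
      if (is_stop[j] || j == i) next
      cj <- strsplit(codons[j], "")[[1]]
      dpos <- which(ci != cj)
      d <- length(dpos)
      if (d == 1L) {
        syn <- as.numeric(aa[i] == aa[j])
        Sd[i, j] <- syn
        Nd[i, j] <- 1 - syn
        next
      }
      perms <- if (d == 2L) perms2 else perms3
      path_s <- numeric(0)
      path_n <- numeric(0)
      valid <- logical(0)
      for (ord in perms) {
        cur <- ci
        s <- 0
        nn <- 0
        ok <- TRUE
        for (p in dpos[ord]) {
          nxt <- cur
          nxt[p] <- cj[p]
          a1 <- aa[idx[paste(cur, collapse = "")]]
          a2 <- aa[idx[paste(nxt, collapse = "")]]
          if (a2 == "*") ok <- FALSE        # path through a stop codon
          if (a1 == a2 && a2 != "*") s <- s + 1 else nn <- nn + 1
          cur <- nxt
        }
        path_s <- c(path_s, s)
        path_n <- c(path_n, nn)
        valid <- c(valid, ok)
      }
      if (any(valid)) {
        Sd[i, j] <- mean(path_s[valid])
        Nd[i, j] <- mean(path_n[valid])
      } else {
        Sd[i, j] <- mean(path_s)
        Nd[i, j] <- mean(path_n)
      }
    }
  }

  ## amino-acid degeneracy classes for Wright's Nc (Met, Trp excluded)
  fam <- split(codons[!is_stop], aa[!is_stop])
  fam_size <- vapply(fam, length, integer(1))
  list(codons = codons, aa = aa, is_stop = is_stop, idx = idx,
       s_sites = s_sites, n_sites = n_sites,
       syn_nb = syn_nb, nonsyn_nb = nonsyn_nb,
       Sd = Sd, Nd = Nd,
       families = fam, family_size = fam_size)
}

.codon_tables <- function() {
  if (is.null(.nemadiv_cache$tables)) {
    .nemadiv_cache$tables <- .build_codon_tables()
  }
  .nemadiv_cache$tables
}

## split a coding string into codon indices (1..64); error on non-ACGT
.codon_indices <- function(cds, what = "sequence") {
  cds <- toupper(cds)
  nch <- nchar(cds)
  if (nch == 0L || nch %% 3L != 0L) {
    stop(what, " length (", nch, ") is not a positive multiple of 3")
  }
  bases <- strsplit(cds, "")[[1]]
  bad <- which(!bases %in% .BASES)
  if (length(bad)) {
    stop("non-ACGT character '", bases[bad[1]], "' in ", what,
         " at position ", bad[1])
  }
  tb <- .codon_tables()
  cods <- substring(cds, seq(1, nch, 3), seq(3, nch, 3))
  unname(tb$idx[cods])
}

## run an expression under a local, restored RNG state
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
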