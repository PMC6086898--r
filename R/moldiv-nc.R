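## Wright's effective number of codons (Nc), the codon-usage-bias statistic
## used to calibrate synonymous divergence.

## amino-acid degeneracy classes under the standard code (Met, Trp excluded)
.NC_CLASSES <- list(
  f2 = c("F", "Y", "C", "H", "Q", "N", "K", "D", "E"),
  f3 = "I",
  f4 = c("V", "P", "T", "A", "G"),
  f6 = c("L", "S", "R"))

#' Effective number of codons from class homozygosities (closed form)
#'
#' Wright's formula `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, where `Fk` is the
#' mean codon homozygosity of the k-fold degenerate amino-acid class. At the
#' uniform-usage homozygosities (1/2, 1/3, 1/4, 1/6) it equals 61 exactly;
#' when every amino acid uses a single codon (all `Fk = 1`) it equals 20.
#'
#' @param f2,f3,f4,f6 mean homozygosity per degeneracy class, each in (0,1].
#' @param clamp clamp the result into `[20, 61]` (default TRUE).
#' @return numeric Nc value.
#' @examples
#' ncFromHomozygosity(1/2, 1/3, 1/4, 1/6)  # 61
#' ncFromHomozygosity(1, 1, 1, 1)          # 20
#' @export
ncFromHomozygosity <- function(f2, f3, f4, f6, clamp = TRUE) {
  stopifnot(all(c(f2, f3, f4, f6) > 0), all(c(f2, f3, f4, f6) <= 1))
  nc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  if (clamp) nc <- min(max(nc, 20), 61)
  nc
}

#' Wright's Nc for a coding sequence
#'
#' Per amino acid with `n >= 2` observed codons, the bias-corrected
#' homozygosity is `F = (n * sum(p^2) - 1) / (n - 1)` over its synonymous
#' codon frequencies `p`. `F` values are averaged within each degeneracy
#' class (2-, 3-, 4-, 6-fold; Met and Trp carry no information and stop
#' codons are excluded). A missing 3-fold class (Ile unobserved) is
#' estimated as `(F2 + F4)/2`; any other missing class is estimated as the
#' mean of the available class means. Non-positive per-amino-acid `F`
#' (possible in tiny samples) is treated as missing. The result is clamped
#' into `[20, 61]`.
#'
#' @param cds coding sequence (length a multiple of 3; terminal stop
#'   allowed and ignored).
#' @return a list with `nc` (numeric, `NA` when undefined), `f2`, `f3`,
#'   `f4`, `f6` (class means, `NA` when unobserved), and `defined`.
#' @examples
#' computeNc(strrep("TTTAAA", 50))  # two 2-fold AAs, single codon each
#' @export
computeNc <- function(cds) {
  ii <- .codon_indices(cds, "cds")
  tb <- .codon_tables()
  ## drop stops (terminal or otherwise) from the usage counts
  ii <- ii[!tb$is_stop[ii]]
  if (!length(ii)) {
    return(list(nc = NA_real_, f2 = NA_real_, f3 = NA_real_, f4 = NA_real_,
                f6 = NA_real_, defined = FALSE))
  }
  cnt <- tabulate(ii, nbins = 64L)
  aa_of <- tb$aa
  f_aa <- function(a) {
    fam <- which(aa_of == a & !tb$is_stop)
    n <- sum(cnt[fam])
    if (n < 2L) return(NA_real_)
    p <- cnt[fam] / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f <= 0) NA_real_ else f
  }
  cls_mean <- vapply(.NC_CLASSES, function(aas) {
    v <- vapply(aas, f_aa, numeric(1))
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  obs <- cls_mean
  est <- cls_mean
  if (is.na(est[["f3"]])) {
    if (!is.na(est[["f2"]]) && !is.na(est[["f4"]])) {
      est[["f3"]] <- (est[["f2"]] + est[["f4"]]) / 2
    }
  }
  for (k in c("f2", "f4", "f6", "f3")) {
    if (is.na(est[[k]])) {
      avail <- est[!is.na(est)]
      if (length(avail)) est[[k]] <- mean(avail)
    }
  }
  if (anyNA(est)) {
    return(list(nc = NA_real_, f2 = obs[["f2"]], f3 = obs[["f3"]],
                f4 = obs[["f4"]], f6 = obs[["f6"]], defined = FALSE))
  }
  nc <- ncFromHomozygosity(est[["f2"]], est[["f3"]], est[["f4"]],
                           est[["f6"]])
  list(nc = nc, f2 = obs[["f2"]], f3 = obs[["f3"]], f4 = obs[["f4"]],
       f6 = obs[["f6"]], defined = TRUE)
}
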