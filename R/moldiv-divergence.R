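## Outlier filtering, Nc-regression calibration of dS, and the neutral
## divergence clock T = dS/mu.

#' Remove outlier substitution estimates before dating
#'
#' Drops records that are saturated/undefined (`defined == FALSE` or `NA`
#' rates) and applies the extreme-value thresholds: records with
#' `dn > dnMax`, `ds > dsMax` or `ds < dsMin` are removed (strict
#' inequalities, so boundary values are retained). High-dS records guard
#' against synonymous-rate saturation; near-zero dS flags misassigned
#' ortholog pairs.
#'
#' @param estimates `data.frame` as produced by [estimateDsDn()].
#' @param config a [DivergenceConfig-class].
#' @return a list with `retained` (filtered `data.frame`) and `counts`
#'   (named removals per rule: `undefined`, `dn_high`, `ds_high`,
#'   `ds_low`; a record failing several rules is tallied once, in that
#'   order).
#' @export
applyDivergenceFilters <- function(estimates, config = divergenceConfig()) {
  stopifnot(is.data.frame(estimates), methods::is(config, "DivergenceConfig"))
  counts <- c(undefined = 0, dn_high = 0, ds_high = 0, ds_low = 0)
  if (!nrow(estimates)) return(list(retained = estimates, counts = counts))
  def <- if ("defined" %in% names(estimates)) {
    estimates$defined & !is.na(estimates$ds) & !is.na(estimates$dn)
  } else {
    !is.na(estimates$ds) & !is.na(estimates$dn)
  }
  rule <- rep("keep", nrow(estimates))
  rule[!def] <- "undefined"
  rule[def & estimates$dn > config@dnMax] <- "dn_high"
  rule[rule == "keep" & def & estimates$ds > config@dsMax] <- "ds_high"
  rule[rule == "keep" & def & estimates$ds < config@dsMin] <- "ds_low"
  tab <- table(factor(rule, levels = c(names(counts), "keep")))
  counts[] <- tab[names(counts)]
  list(retained = estimates[rule == "keep", , drop = FALSE], counts = counts)
}

#' Calibrate dS for codon-usage bias via Nc regression
#'
#' Codon-usage bias suppresses observable synonymous divergence; genes with
#' low Nc (strong bias) underestimate dS. The calibration fits ordinary
#' least squares `ds = a + b * nc` across genes (per-gene `nc` is the mean
#' of the two sequences' Nc) and shifts each gene upward to the unbiased
#' reference: `adjusted_ds = ds + max(b, 0) * (ncReference - nc)`. A
#' negative fitted slope would adjust downward and is suppressed
#' (`adjusted_ds = ds`), as is a zero-variance Nc column (with a warning).
#'
#' @param estimates `data.frame` with columns `ds`, `nc_a`, `nc_b` (at
#'   least 3 rows with finite values).
#' @param ncReference reference Nc (default 61, no bias).
#' @return a list with `estimates` (input plus columns `nc` and
#'   `adjusted_ds`), `slope`, `intercept`.
#' @export
ncAdjustDs <- function(estimates, ncReference = 61) {
  stopifnot(is.data.frame(estimates))
  nc <- rowMeans(cbind(estimates$nc_a, estimates$nc_b))
  ok <- is.finite(estimates$ds) & is.finite(nc)
  if (sum(ok) < 3L) {
    stop("need at least 3 estimates with finite ds and nc for the ",
         "Nc regression (have ", sum(ok), ")")
  }
  if (stats::sd(nc[ok]) == 0) {
    warning("zero variance in Nc; no adjustment applied")
    slope <- 0
    intercept <- mean(estimates$ds[ok])
  } else {
    fit <- stats::lm(ds ~ nc, data = data.frame(ds = estimates$ds[ok],
                                                nc = nc[ok]))
    slope <- unname(stats::coef(fit)[["nc"]])
    intercept <- unname(stats::coef(fit)[["(Intercept)"]])
  }
  b <- max(slope, 0)
  estimates$nc <- nc
  estimates$adjusted_ds <- estimates$ds + b * (ncReference - nc)
  list(estimates = estimates, slope = slope, intercept = intercept)
}

#' Date the divergence with the neutral clock T = dS/mu
#'
#' Takes the median of the calibrated synonymous divergences and converts
#' it to an age in generations via the neutral expectation `T = dS / mu`;
#' years use the configured generation time and 365.25 days per year.
#'
#' @param adjusted output of [ncAdjustDs()] (list) or its `estimates`
#'   `data.frame` with an `adjusted_ds` column.
#' @param config a [DivergenceConfig-class].
#' @param nInput optional total gene count before filtering (for the
#'   report); defaults to the number of rows supplied.
#' @param filterCounts optional named removal tally from
#'   [applyDivergenceFilters()].
#' @return a [DivergenceResult-class].
#' @examples
#' est <- data.frame(adjusted_ds = c(1.2, 1.28457, 1.3))
#' estimateDivergence(est)
#' @export
estimateDivergence <- function(adjusted, config = divergenceConfig(),
                               nInput = NULL, filterCounts = numeric(0)) {
  slope <- NA_real_
  intercept <- NA_real_
  if (is.list(adjusted) && !is.data.frame(adjusted) &&
      all(c("estimates", "slope") %in% names(adjusted))) {
    slope <- adjusted$slope
    intercept <- adjusted$intercept
    adjusted <- adjusted$estimates
  }
  stopifnot(is.data.frame(adjusted), methods::is(config, "DivergenceConfig"))
  if (!nrow(adjusted)) stop("no retained estimates to date")
  if (!"adjusted_ds" %in% names(adjusted)) {
    stop("'adjusted_ds' column missing; run ncAdjustDs() first")
  }
  med <- stats::median(adjusted$adjusted_ds)
  t_gen <- med / config@mu
  t_yr <- t_gen * config@generationDays / 365.25
  methods::new("DivergenceResult",
    nInput = if (is.null(nInput)) nrow(adjusted) else nInput,
    nRetained = nrow(adjusted), medianAdjustedDs = med,
    tGenerations = t_gen, tYears = t_yr,
    slope = slope, intercept = intercept,
    filterCounts = filterCounts, config = config)
}

#' Full divergence pipeline over aligned CDS pairs
#'
#' Convenience driver: NG86 estimation for every pair, outlier filtering,
#' Nc calibration, and the clock.
#'
#' @param geneIds,cdsA,cdsB as in [estimateDsDnMany()].
#' @param config a [DivergenceConfig-class].
#' @return a list with `estimates` (per-gene table including
#'   `adjusted_ds`), `filterCounts`, and `result`
#'   (a [DivergenceResult-class]).
#' @export
divergencePipeline <- function(geneIds, cdsA, cdsB,
                               config = divergenceConfig()) {
  est <- estimateDsDnMany(geneIds, cdsA, cdsB)
  filt <- applyDivergenceFilters(est, config)
  adj <- ncAdjustDs(filt$retained, ncReference = config@ncReference)
  res <- estimateDivergence(adj, config, nInput = nrow(est),
                            filterCounts = filt$counts)
  list(estimates = adj$estimates, filterCounts = filt$counts, result = res)
}

#' Write per-gene substitution estimates to TSV
#'
#' @param estimates per-gene `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEstimates <- function(estimates, path) {
  utils::write.table(estimates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
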