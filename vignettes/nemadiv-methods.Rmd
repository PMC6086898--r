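---
title: "Models and methods behind nemadiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nemadiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemadiv)
```

# Scope

`nemadiv` packages the comparative analyses used when a newly assembled
nematode genome is set against a well-annotated relative (the motivating
case is a *Caenorhabditis* male/female species against *C. elegans*):

* neutral divergence dating from codon alignments of one-to-one
  orthologs, with a codon-usage-bias calibration;
* assembly statistics and removal of residual-haplotype scaffolds;
* merging and confidence classification of LTR retrotransposon
  candidates produced by two independent detectors;
* collinear synteny-block chaining and chromosome-domain contrasts of
  synonymous rates;
* a seeded simulator that generates genome pairs with known divergence,
  bias, rearrangements, planted transposable elements and haplotigs, so
  that every analysis stage can be tested against ground truth.

Upstream steps — read mapping, assembly, gene prediction, ortholog
clustering, de novo repeat detection — are out of scope; their outputs
are this package's inputs.

# Substitution estimation (NG86)

For each ortholog pair the package counts synonymous and nonsynonymous
sites and differences in the style of Nei and Gojobori (1986):

* Each codon position contributes the fraction of its three possible
  single-nucleotide changes that preserve the amino acid; changes into
  stop codons count as nonsynonymous. Site counts are averaged over the
  two sequences, so `s_sites + n_sites = 3 × codons` always holds.
* Codons differing at more than one position are scored by averaging the
  synonymous/nonsynonymous step counts over all orderings of the
  changes, excluding pathways that pass through a stop codon. In the
  degenerate case where every ordering passes through a stop, all
  orderings are used with stop-involving steps scored nonsynonymous.
* Proportions `pS = sd/s_sites` and `pN = nd/n_sites` are corrected for
  multiple hits with the one-parameter Jukes–Cantor formula
  `d = -3/4 · ln(1 − 4p/3)`. At `p ≥ 3/4` the correction diverges; the
  estimate is flagged undefined and excluded (and tallied) downstream.

The original study obtained branch-specific rates by maximum likelihood
(codeml). NG86 counting was chosen here as the core estimator because it
is self-contained and verifiable against hand enumeration; it is exposed
behind `estimateDsDn()` so an ML estimator could be slotted in without
touching the rest of the pipeline. Absolute dS from NG86 is known to be
biased downward relative to ML codon models as divergence grows (the
package's own recovery tests show <10% relative error up to a true
synonymous divergence of 0.5); pairwise values here correspond to the sum
of the two lineage-specific rates, not to either branch alone. Both
caveats matter when comparing absolute numbers with ML-based reports.

# Codon-usage bias: Wright's Nc

Codon-usage bias suppresses observable synonymous divergence: a gene
whose synonymous sites are constrained to preferred codons accumulates
fewer synonymous changes. The package quantifies bias with Wright's
effective number of codons,

```
Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6,
```

where `Fk` is the mean codon homozygosity of the k-fold degenerate
amino-acid class (Met and Trp are uninformative; Ile is the only 3-fold
amino acid). Per amino acid the small-sample-corrected homozygosity
`F = (n·Σp² − 1)/(n − 1)` is used. A missing 3-fold class is estimated
as `(F2 + F4)/2`; any other missing class as the mean of the observed
class means. Values are clamped into `[20, 61]`.

Two limits anchor the scale: uniform usage in every synonymous family
gives `F = (1/2, 1/3, 1/4, 1/6)` and `Nc = 61` exactly; a single codon
per amino acid gives all `F = 1` and `Nc = 20`. Note the corrected
estimator reaches 61 only asymptotically on finite sequences (the
correction pushes `F` below the distributional homozygosity), which is
why `ncFromHomozygosity()` exposes the closed form separately from the
sequence-level `computeNc()`.

# Calibration and the divergence clock

After removing extreme records — `dN > 0.5` (alignment or annotation
problems), `dS > 5` (synonymous saturation) and `dS < 0.0005` (likely
ortholog misassignment); all strict inequalities, so boundary values
survive — the remaining per-gene dS are calibrated for bias: ordinary
least squares of `ds` on per-gene Nc (mean of the two sequences), then

```
adjusted_ds = ds + max(b, 0) · (61 − nc).
```

The correction is upward-only by construction: bias can only have hidden
synonymous change, never created it, so a negative fitted slope (noise)
is suppressed rather than applied. The reference `Nc = 61` represents
bias-free usage and is configurable.

The neutral clock is then

```
T = median(adjusted_ds) / μ,
```

with `μ = 9.0 × 10⁻⁹` mutations per site per generation by default (a
direct *C. elegans* mutation-rate measurement). `T` is in generations;
a year conversion is reported alongside using the configured generation
time (30 days) and 365.25 days per year. These two headline numbers are
deliberately surfaced side by side and not reconciled: at 30-day
generations, 142.73 million generations converts to ≈11.7 My, not the
≈10.5 My sometimes quoted with the same inputs, so the package reports
generations as primary and years as derived.

# LTR retrotransposon classification

Candidates from two detectors are merged when they lie on the same
scaffold and overlap reciprocally by ≥50% of each span (union span;
domain hits unioned at the best e-value per domain). Classification is
two-pass with three rules:

1. **full** — all four retrotransposon protein domains (RT, protease,
   integrase, RNase H) present with e-value < 1e−20;
2. **partial** — at least one qualifying domain but not all four;
3. **ltr_only** — no qualifying domain, but LTR similarity > 95% to the
   LTRs of a class-full element (the similarity is consumed as an input
   column; computing it is the detector's job).

Everything else is rejected. The e-value threshold is applied to rule 1
as well as rule 2 (configurable); "intact" element counts are the
class-full counts, with no additional structural criteria. Repeat
landscapes merge intervals within a family before computing masked
percentages, so overlapping annotations are never double-counted.

# Synteny and chromosome domains

Anchors are one-to-one ortholog pairs with gene-order ranks per
chromosome. Chaining is a longest-chain dynamic programme over rank
pairs: within a chromosome pair and orientation (forward = both ranks
increasing, inverted = second genome decreasing), consecutive anchors
may skip at most `maxRankGap = 10` ranks on either genome. The best
chain is extracted, removed, and the search repeated; blocks under
`minAnchors = 3` are dropped. Cardinality scoring (rather than the
bp-weighted scoring of chain-detection tools like DAGchainer) was chosen
because it admits an exhaustive oracle, which the test suite exercises
on every instance up to 10 anchors; published coverage figures obtained
with other scoring schemes are therefore reproduced only approximately.
Ties between equal-size chains resolve deterministically (forward first,
then leftmost start).

Synteny coverage is merged block bp on the focal genome divided by total
assembly bp (gene-count-based definitions give slightly different
numbers). Arm/centre domains default to chromosome thirds — an explicit,
crude stand-in for recombination-map boundaries, overridable with a
boundary table — and dS contrasts (arms vs centre on autosomes; X vs
autosomes) use a two-sided Mann–Whitney U test: exact for small untied
groups (<10 per group), normal approximation with tie correction
otherwise.

# The simulator and what it does (not) emulate

`simulateGenomePair()` draws ancestral genes (amino acids uniform;
codons within a family from `(1−b)·uniform + b·preferred`, `b` the
per-gene bias), then evolves each lineage with a per-codon Gillespie
process over unit time: synonymous events at rate `ts` per NG86
synonymous site, nonsynonymous at `tn = ω·ts_base` per nonsynonymous
site, stop-creating changes rejected. The per-lineage synonymous rate is
`ts = (targetTs/2)·(1 − 0.5·b)`: bias suppresses realised synonymous
change with coefficient 0.5 (configurable), which manufactures exactly
the dS–Nc correlation the calibration step must correct — a directional
test, not a claim about the true magnitude of the effect in nematodes.

Genome B's gene order receives disjoint inversions (≥2 genes each;
single-gene inversions are order-neutral and are never drawn), so with
`k` inversions of length ≤ `maxRankGap` a chromosome yields exactly
`k+1` blocks — the ground truth used by the synteny tests. Planted LTR
elements carry domain tables matching their class definitions; planted
haplotigs are verbatim subsequences of larger scaffolds at half the mean
read depth.

Default study conditions: 6 chromosomes (five autosomes and `chrX`),
84 genes each (504 pairs), 300–400 codons per gene, total synonymous
divergence 0.4, ω = 0.2, two inversions per chromosome, ten planted
elements (5 full / 3 partial / 2 LTR-only) and two haplotigs at 0.5×
depth. These sizes keep a full simulate–estimate cycle in seconds while
leaving the median dS estimator with ~500 genes — ample for a 10%
recovery tolerance.

The simulator deliberately omits indels, introns, segmental
duplications, GC-content heterogeneity, and population-level processes.
Passing its recovery tests therefore demonstrates correctness of the
implemented estimators under their own model assumptions, not robustness
to alignment error or annotation noise in real data.

# Numerical and interface choices

* Coordinates are 1-based closed throughout, the Bioconductor
  convention; GFF3 needs no conversion and FASTA round-trips are exact.
* The residual-haplotype rule — containment fraction > 0.90 in strictly
  larger scaffolds AND depth within `[0.35, 0.65]×` the length-weighted
  mean — operationalises "half the average coverage" as a symmetric band
  around 0.5×; both knobs are arguments.
* GC% is computed over non-N bases; gap length is the summed length of
  maximal N-runs.
* Undefined (saturated) dS/dN estimates are removed and counted, never
  silently coerced.
* All stochastic functions take a `seed` and restore the caller's RNG
  state; pipeline outputs are byte-identical across reruns with the same
  configuration and seed.

# Known limitations

* NG86 pairwise estimates differ systematically from branch-specific ML
  estimates; divergence dates inherit that difference.
* The Nc calibration is a first-order (linear, upward-only) correction;
  the underlying expected-dS-given-Nc relationship is unlikely to be
  exactly linear.
* Default arm/centre boundaries (thirds) are a placeholder for measured
  recombination-domain boundaries, which should be supplied when
  available.
* Synteny coverage depends on chaining parameters; values are comparable
  across runs of this package, not across chaining tools.
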