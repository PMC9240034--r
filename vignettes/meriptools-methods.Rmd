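---
title: "Models and methods behind meriptools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meriptools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meriptools)
```

meriptools implements the standard desk-scale analysis recipe for m⁶A
epitranscriptomics: sliding-window MeRIP-seq peak calling on the longest
isoform, landscape profiling, knockout-versus-wild-type differential
methylation, actinomycin-D decay analysis, ΔΔCt, and TPM-based
differential expression, with a ground-truth simulator wired through every
stage. This vignette is the package's own account of the statistical
choices, their assumptions, and what the passing test suite does and does
not establish.

## Transcript models and coordinates

All internal coordinates are 0-based half-open; GTF is converted from its
1-based closed dialect at the boundary, and BED output is 0-based
half-open. The longest isoform per gene is selected deterministically
(ties broken by lexicographically smallest transcript id — annotation
formats do not order isoforms, and reproducible scans need a fixed rule).
Coding transcripts are partitioned into 5′UTR/CDS/3′UTR by half-open
comparison against the transcript-relative CDS span, so a summit exactly at
the CDS start is CDS and one exactly at the CDS end is 3′UTR. Non-coding
transcripts are scanned for peaks like any other, but are excluded from
metagene and segment summaries, whose axes are defined only for coding
architecture.

## Window scan and exclusion rule

The scan uses 100-nt windows advanced in 10-nt steps (both configurable).
Transcripts shorter than one window get a single whole-transcript window.
When the transcript length minus the window width is not a multiple of the
step, a final flush window ending at the transcript's 3′ end is added:
without it the stepped scan systematically leaves up to step−1 terminal
bases unscanned, and 3′-terminal methylation is precisely where m⁶A
biology concentrates.

The low-count exclusion rule drops a window only when its summed count is
*strictly below* 1/20 of the transcript's top window in **both** the IP
and the input assay; a window at exactly the threshold is retained, and a
window healthy in either assay survives. The per-transcript top window is
computed separately in IP and input, with replicates summed within assay.
An "either" mode (exclude on one failing assay) is available as a switch.
Exclusion fraction 0 disables the filter.

## Enrichment testing and FDR

Each retained window is tested with a one-sided Fisher's exact test of its
IP count against its input count, with the remainder of each library as
the complementary cell — the alternative being IP enrichment. The exact
hypergeometric tail is computed directly; the test suite verifies it
against full enumeration of every 2×2 table with margins up to 50.
Benjamini–Hochberg adjustment is applied across all tested windows of a
run (not per transcript), and windows at q ≤ 0.05 are merged when they
overlap or are bookended. The merged peak inherits the minimum window p
and q; its summit is the midpoint of the minimum-p window (first such
window on ties). The 0.5 pseudocount appears only in reported log₂
enrichments, never inside the test.

Two properties of this design deserve emphasis:

* **What the FDR controls.** BH controls the false-discovery proportion
  among *windows*. After merging, the ~10 significant windows that tile
  one true site collapse into a single peak while an isolated false window
  stays its own peak, so the FDP *among peaks* is not bounded by the
  window-level q threshold — with perfectly calibrated p-values a
  window-level FDR of 5% can correspond to a peak-level FDP several times
  larger. The recovery experiments therefore measure the realized FDP at
  the window level (the quantity the procedure controls), and the
  null-simulation experiment checks that with no signal anywhere the
  per-run probability of calling any peak stays within 1.5× the nominal
  level. Users who need peak-level FDP guarantees should require multiple
  significant windows per peak or use replicate-aware GLM methods, both
  outside this package's scope.

* **Sensitivity to overdispersion.** Fisher's exact test assumes the two
  counts are (conditionally) hypergeometric, which holds when window
  counts are Poisson draws from library-proportional rates. BH's step-up
  threshold engages the extreme tail of the null (α/m ≈ 10⁻⁵ at typical
  window counts), where even a few percent of extra-Poisson variance
  inflates exceedance probabilities severalfold. The simulator therefore
  draws window counts as Poisson sequencing-sampling noise by default
  (`nb_dispersion = 0`); setting a biological-replicate-scale dispersion
  (0.05–0.2) demonstrably breaks the calibration of the pooled Fisher
  test — which is exactly why the field developed replicate-aware
  negative-binomial GLMs for differential methylation, a non-goal here.

## Differential methylation

Peaks are called on all samples pooled; per peak, the counts of its
constituent windows (those contained in the merged span — using all
*overlapping* windows would dilute the signal with up to a window-width of
flanking background) are summed per genotype × assay. Significance comes
from a two-sided Fisher's exact test on the raw 2×2 genotype × assay
table, BH-adjusted across peaks. The reported effect is the log₂ ratio of
library-size-normalized IP/input enrichment, positive when methylation is
higher in the knockout; swapping labels negates it exactly. Library sizes
are median-of-ratios factors computed over all windows rather than raw
column totals: when the knockout gains IP mass at strongly differential
peaks, raw totals shift by that gained mass and bias *every* peak's ratio
downward (a composition effect of order log₂ of the totals ratio), whereas
the median window ratio is untouched by a small fraction of differential
windows. With no differential signal the two normalizations coincide.

## Landscape

Each peak contributes its summit — using the whole footprint would weight
wide peaks by their width and double-count the same molecule of evidence.
Summits are mapped to the segment-normalized coordinate (position within
segment ÷ segment length, offset by 0/1/2 for 5′UTR/CDS/3′UTR) and binned
into 33 bins per segment (99 total; the bin count is a display choice, not
asserted by any analysis). The histogram is normalized to exact unit area.
Segment fractions use the same summits via the half-open segment rule.

The DRACH test counts summit ± 50 nt windows (clipped at transcript ends,
with the clip count reported) containing at least one match of the IUPAC
pattern DRACH, and compares that rate with equal-width windows sampled
uniformly from the same transcriptome (10,000 seeded draws) by an exact
one-sided binomial tail. This is a calibrated presence/absence enrichment
test, not de novo motif discovery: published HOMER p-values depend on
their data and tool internals and are not reproduction targets.

## Decay and ΔΔCt

Residual fractions are (target/reference)(t) ÷ (target/reference)(0)
within each replicate series, so the reference (an 18S rRNA stand-in,
effectively stable over a chase of a few hours) cancels multiplicative
batch effects and the fraction at t = 0 is 1 by construction. Half-lives
come from ordinary least squares of log fraction on time with a **free
intercept**: forcing the fit through 1 at t = 0 would push the t = 0
measurement noise into the slope, whereas the free intercept absorbs it;
log-linear LS is stable at the 3–5 timepoints of a real chase, where
nonlinear exponential fitting adds nothing. Replicate series are pooled
into one regression by default (per-replicate fits remain available by
subsetting). A non-decaying series is reported with k ≤ 0 and t½ = ∞
rather than an error, since flat series are a legitimate biological
outcome. Genotype comparison uses two-tailed Welch t tests per
post-treatment timepoint plus a percentile bootstrap (2,000 seeded
resamples of replicate series) for the half-life difference, negative when
the knockout is destabilized.

ΔΔCt is the textbook closed form
2^−((Ct_t−Ct_ref)_sample − (Ct_t−Ct_ref)_calibrator); one extra target
cycle halves the result, which the tests assert over a parameter grid.

## Expression

TPM follows the per-kilobase-rate definition with columns summing to 10⁶
exactly. The differential test is a deliberate stand-in: Welch t on log₂
(median-of-ratios-normalized count + 0.5), BH-adjusted. It is documented
as not a negative-binomial GLM, and its acceptance checks are calibration
properties of *this* test (type-I error within [0.03, 0.07] on 10⁴ null
genes), never published DEG counts, which are data- and tool-version
specific. DEG classification uses the *raw* p-value at 0.05 with inclusive
|log₂FC| ≥ 1 boundaries, the literal reading of the stated criteria; a
q-value mode is a flag. Gene-set enrichment is the one-sided
hypergeometric tail within a fixed universe.

## The simulator: what it emulates, and what it does not

The generator is a pure function of (config, seed); each assay stage draws
under seed + stage offset so stages are independently reproducible. Per
gene it draws segment lengths (5′UTR 100–300, CDS 300–1500, 3′UTR 200–600
nt), a 1–3-exon structure on alternating strands, a random sequence, and
planted DRACH 5-mers at recorded positions — 80% within 100 nt of the stop
codon, emulating the stop-proximal concentration characteristic of m⁶A.
Input window means are proportional to a per-gene lognormal expression
factor times window width at 30 expected reads per full window per
library; IP means multiply that by 4 at site-overlapping windows, and by a
further 2-fold at the 5 designated target genes in the knockout (the
demethylase-loss direction). Decay uses half-life 2 h for non-targets in
both genotypes and 4 h → 2 h for targets (destabilized upon knockout),
timepoints 0/2/4/6 h, lognormal CV 0.1, 5 replicates. qPCR encodes a
4-fold target change as a 2-cycle Ct shift with σ = 0.1 cycles. The
expression matrix plants |log₂FC| = 2 in 10% of genes at 3 replicates per
condition.

Features of real data deliberately *not* emulated: read-level fragment
placement (counts are drawn per window, independently — real overlapping
windows share reads and are strongly autocorrelated); biological replicate
overdispersion (see above); isoform mixtures and annotation error (the
1/20 exclusion rule exists for those, and is exercised here only by its
literal arithmetic); GC and length biases; and partial methylation
stoichiometry. Passing recovery tests therefore establishes that the
implementation computes its statistics correctly and recovers planted
truth under its stated noise model — not that the pipeline is robust to
every pathology of real libraries.

## Problem sizes and numerical choices

The test suite runs the recovery experiments at 200 simulations of 50
genes (peak recovery), 200 simulations of 200 genes with 5 targets
(differential methylation — five targets mirrors the five target mRNAs of
the motivating biology, and a 2.5% target fraction keeps the library
composition shift negligible), 200 decay simulations, and 10⁴ null genes
for calibration; the acceptance script uses 50-run versions of the two
expensive loops. These sizes give Monte-Carlo standard errors comfortably
below the asserted tolerances. Exact-test fidelity is checked to 10⁻⁹
against enumeration; the metagene area and TPM column sums to 10⁻⁹ and
10⁻⁶ relative. All file outputs are written atomically (temp-then-rename)
and the pipeline is byte-deterministic given a seed; the manifest records
parameters and input checksums but no timestamps, precisely so that runs
are comparable by hash.

## Known limitations

Single-window peaks are permitted, and peak-level FDP is accordingly
looser than window-level FDR (discussed above). The Fisher test pools
replicates and cannot exploit replicate concordance. The exclusion rule's
pooled-versus-per-replicate behavior follows the pooled reading. The
motif test is presence/absence within a fixed flank. The decay comparison
bootstraps replicate series, so with very few replicates the CI is coarse.
None of these limitations is hidden by the tests: each is either exercised
directly or stated here.
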