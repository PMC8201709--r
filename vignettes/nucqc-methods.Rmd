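---
title: "Methods and design of nucqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of nucqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `nucqc`, the parameters that
matter, the choices made where the design was genuinely open, and what
the synthetic tests do and do not establish about real data.

## Signal model

### Occupancy

MNase-protected fragments mark nucleosomes; the best point estimate of a
nucleosome's position from one fragment is the fragment midpoint (the
dyad under a mononucleosomal size selection). `build_occupancy_track()`
therefore reduces each fragment to `floor((start + end) / 2)` and
extends it to a fixed 147 bp footprint — the canonical length of DNA in
the nucleosome core particle — clipped at chromosome ends. Occupancy at
a base is the number of footprints covering it.

Normalization divides by the genome-wide mean so the track has mean 1.
This matters in three places: the depletion level becomes a ratio of
comparable quantities across samples, cross-sample window correlations
(used in pooling) are not dominated by depth, and array scores are
scale-free by construction. Raw counts remain available with
`normalize = FALSE`.

Using a fixed footprint instead of the raw fragment extent discards
fragment-length variation deliberately: a 250 bp fragment is evidence of
one nucleosome somewhere under it, not of 250 bp of nucleosome. The
fragment-length distribution is still used by the QC panel.

### Array regularity

Phased nucleosome arrays produce locally periodic occupancy with a
repeat length of roughly 150–220 bp in mammals. `build_array_track()`
quantifies this with a windowed autocorrelation: for a 2 kb window
centered on every 100 bp bin, the occupancy is mean-subtracted and the
normalized autocorrelation is maximized over lags 150–220 bp; the value
(clipped to [0, 1]) is assigned to the whole bin. A flat window has zero
variance and scores 0 by convention.

Parameter roles: the *window* (2 kb, ~10 nucleosomes) sets how local the
statistic is; the *step* (100 bp) its resolution; the *lag range* the
repeat lengths counted as "nucleosomal". A window below twice the
maximum lag would leave fewer than one full period of evidence per lag
and is rejected. The statistic is invariant to positive scaling of the
occupancy, which the tests verify. The implementation evaluates all
windows simultaneously with cumulative sums and is verified against a
direct per-window autocorrelation oracle.

This windowed-autocorrelation definition of "array signal" is this
package's own, parameter-light realization of nucleosome-array
regularity; it sits behind the track-role abstraction, so an alternative
definition can be swapped in without touching the consumers (QC,
features, TF prediction).

## The QC panel

Six per-sample measurements; every one except sequencing coverage also
carries a Pass/Fail label.

**Coverage fold** — total fragment bases over genome size. Five-fold is
the floor for a usable reference landscape (see selection below).

**Fragment length** — mode of the 1 bp length histogram. Clean
mononucleosomal libraries peak near 146 bp; samples are ranked by
|mode − 146|. With fewer than 100 fragments the value is flagged
low-confidence.

**Dinucleotide periodicity** — nucleosomal DNA shows an ~10 bp
rotational phasing of AA/TT/AT dinucleotides. The positional {AA, TT,
AT} frequency is profiled over 147 bp windows centered on fragment
midpoints, and the score is the fraction of the (DC-removed) spectral
power in the 9–11 bp period band — a number in [0, 1] that needs no
genome-specific calibration. Without a genome FASTA the metric is NA,
labelled Fail, and given rank quantile 0 (conservative: an unverifiable
sample never outranks a verified one).

**TSS depletion** — mean of the per-TSS depletion level (below).
Active-promoter NFRs make this high in informative samples.

**TSS fuzziness** — the coefficient of variation (population SD over
mean) of the three spacings between the +1, +2, +3 and +4 nucleosomes
called on the *aggregate* strand-aware TSS profile (minus-strand
profiles are reversed before averaging). The Pass rule is fixed:
CV < 0.4, strictly. Two open choices were resolved as follows:
the CV uses the population SD (dividing by k = 3 — a CV of a tiny
fixed-size set, documented so the 0.4 boundary is exactly reproducible),
and the profile is aggregated *before* calling rather than per-TSS and
averaged, because the aggregate is robust at modest coverage where
individual promoters are too noisy to call four nucleosomes. Fewer than
four aggregate peaks gives NA and Fail.

**DHS array enrichment** — mean array signal over DHS ± 1 kb divided by
the genome-wide mean. Values above 1 mean phased arrays concentrate
around accessible chromatin.

The four thresholds other than the fuzziness rule (depletion ≥ 0.2,
enrichment ≥ 1.2, length within 146 ± 20 bp, periodicity ≥ 2× the
white-noise band share of 3/73) are package defaults, overridable
through `assign_labels(thresholds = ...)`. The periodicity default uses
the analytic white-noise null — for an uninformative profile the
expected band share is simply the number of band bins over the number of
positive-frequency bins — rather than a per-run shuffled-genome null,
keeping labelling deterministic and cheap.

## Ranking, pooling, reference selection

Per metric, samples are ranked in the metric's quality direction (ties
get average ranks) and ranks are mapped to quantiles
`1 − (rank − 1)/(n − 1)`; a singleton collection gets quantile 1. Three
indicators then order samples within a cell type / treatment group:

* `N_good` — number of Pass labels (0–5);
* `C_better` — number of metrics whose quantile strictly exceeds the
  group's mean quantile for that metric (strictness makes the singleton
  case well-defined: a lone sample has `C_better = 0`; the group mean
  includes the sample itself);
* `R_better` — sum of the six quantiles.

The order is lexicographic on (`N_good`, `C_better`, `R_better`)
descending. Residual ties are broken by coverage fold and then sample
id, so the ordering — and everything downstream — is total and
deterministic; tests verify invariance under input permutation.

Pooling correlates occupancy averaged in non-overlapping 1 kb windows;
windows with zero occupancy in both members of a pair are excluded so
shared unmappable deserts cannot inflate *r*. Pairs with Pearson
*r* > 0.6 (strict) are joined; pools are the connected components of
that graph. Single-linkage components were chosen over cliques because
pooling is read as transitive ("samples that agree get merged"), and the
correlation is computed on *normalized* occupancy so depth differences
do not suppress agreement.

The top-ranked sample — the High Quality Sample — is the group's
referenced landscape unless it belongs to a pool, in which case the
pooled sample (fragments concatenated, fold = sum of member folds) is.
The five-fold coverage floor is applied to the final candidate, not to
ranking membership; a failing candidate leaves the group with no
reference rather than silently substituting a lower-ranked sample.

## Locus features

The depletion level at a site `s` compares the maximum occupancy of the
central 200 bp bin `[s−100, s+100)` with the maximum over the two
flanking bins `[s−300, s−100)` and `[s+100, s+300)`:
`1 − N_center/N_background`, clamped to 0 when the center exceeds the
background, and 0 when the background is 0. "Central 200 bp bin" is
interpreted as symmetric half-open intervals around the site point.
Windows falling off the chromosome give NA rather than a silently
clipped value.

Nucleosome calling scans the occupancy 1 kb from the anchor (strictly
excluding offset 0, so an NFR-edge maximum at the anchor itself is never
the +1), smooths with a centered moving average (50 bp default — wide
enough to suppress footprint-level jaggedness, well under the
internucleosomal distance; edge windows are truncated and renormalized
so no positions are lost), and takes strict local maxima with plateaus
resolved to their leftmost base for determinism. The smoothed values are
quantized at 1e-9 before maximum detection so cumulative-sum rounding on
flat stretches cannot fabricate peaks. Maxima closer than 100 bp are
resolved iteratively by removing the globally lowest offender (ties drop
the peak farther from the anchor), which makes the result independent of
scan direction; two equal maxima exactly 100 bp apart both survive.

Linker length is the mean adjacent spacing minus 147 bp; spacings
between 100 and 147 bp therefore give *negative* linkers, which are
reported as computed (they are informative about over-close calls)
rather than clipped. The linker SD is the population SD of the spacings.
Sentinels: no +1 → position, linker and SD all −1; fewer than two
nucleosomes → linker and SD −1; fewer than three → SD −1.

DHS records are computed without strand (reference orientation) on both
sides of the anchor — the summit (narrowPeak-style offset column) when
present, otherwise the interval midpoint — yielding a −1 nucleosome and
upstream linker statistics alongside the downstream set.

One geometric caveat: on synthetic footprint piles the smoothed profile
has near-flat tops, and the plateau-leftmost rule reports the left edge
(~35–50 bp left of the dyad). Spacings, and hence linker statistics, are
unaffected because all calls shift together; real pileup profiles are
rounded and do not show the effect at this magnitude.

## TF binding prediction

Motif hits are labelled bound iff they overlap a peak by at least 1 bp
(half-open intervals; the paper-style "overlapping" with no fraction).
Predictors at the hit center delegate to the locus-feature operations,
unstranded. Both models (motif-only and motif + four nucleosome
predictors) are maximum-likelihood logistic regressions fitted on
identical stratified folds with a fixed default seed (1234); under
complete separation the fit falls back to an effectively unpenalized
ridge (λ = 1e-6) so out-of-fold probabilities stay defined. AUC is the
rank-statistic (Mann–Whitney) form, equivalent to trapezoidal ROC
integration and verified against an independent ROC implementation in
the tests. The primary AUC pools out-of-fold probabilities across folds
(one number per model, stable for modest n); per-fold means are also
reported. Threshold-0.5 classification metrics (sensitivity,
specificity, precision, F1, FPR) accompany the AUCs. The improvement
statistic is the difference of the pooled out-of-fold AUCs.

## Synthetic study conditions

`synthetic_spec()` defaults define the conditions every test runs under:
two 300 kb chromosomes; ten promoters and ten DHSs per chromosome; a
300 bp nucleosome-free region at each anchor with five-nucleosome phased
arrays (190 bp repeat) downstream of promoters and on both sides of
DHSs; 60,000 fragments with lengths Normal(147, 15) truncated to
[80, 250] (≈ 14.7-fold coverage, comfortably above the five-fold floor);
per-fragment positional jitter SD 20 bp; 10% uniformly placed background
fragments. The NFR width of 300 bp puts the first dyad at ±223 bp so a
clean promoter's +1 footprint stays out of the central depletion bin —
the generator's definition of an unambiguous NFR. Dinucleotide test
genomes plant AA at a 10 bp phase within each positioned footprint.
Binding data places motif hits at least 340 bp apart so that
peak-overlap labelling reproduces the simulated labels exactly, draws
motif scores from N(0, 1) and labels from the logistic model with
user-chosen true coefficients.

Everything is deterministic given the seed, and the truth tables (dyad
positions, expected spacing, true coefficients) suffice to compute every
expected feature independently of the implementation under test.

What the generator does *not* emulate: MNase digestion sequence bias,
sequence-dependent nucleosome affinity, fragment-length/rotational
coupling, mappability gaps, and realistic genome-scale heterogeneity of
promoter architecture. Green tests therefore establish that the
operations implement their definitions and recover planted structure —
not that the QC thresholds are optimally calibrated for any particular
public dataset.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; BED is native, SAM/BAM
  positions are converted at the boundary.
* Unknown-chromosome and out-of-bounds fragments are dropped with a
  warning, never clipped — clipping would quietly distort coverage.
* Zero-variance windows: array score 0, periodicity score 0, fuzziness
  NA; zero background: depletion 0; empty fragment sets are fatal.
* bedGraph is written run-length encoded with zero runs omitted;
  reading validates per-chromosome non-overlap and reports the offending
  line number. bigWig I/O is available through rtracklayer.
* Test and example problem sizes (hundreds of kb, tens of thousands of
  fragments, ≤ 2,000 binding sites) were chosen so the full suite
  completes in about a minute while leaving every statistical assertion
  comfortable margins.

## Known limitations

* The fuzziness metric needs four callable aggregate peaks; very shallow
  or very disordered samples return NA (label Fail) rather than a noisy
  number.
* The position caller has no peak-height floor, so an isolated stray
  footprint inside an NFR can be called as the +1 nucleosome in
  low-background synthetic data; aggregate-level metrics are unaffected.
* `C_better` compares against the group mean including the sample
  itself, which slightly compresses the indicator in small groups (and
  zeroes it for singletons, intentionally).
* The pooled sample inherits no per-member weighting: members contribute
  fragments proportionally to their depth.
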