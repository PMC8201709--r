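# nucqc

Quality control, reference-landscape selection and feature quantification
for MNase-seq nucleosome organization maps.

## The problem

MNase-seq maps nucleosomes genome-wide by sequencing the DNA fragments
that micrococcal nuclease leaves protected. Public MNase-seq samples vary
enormously in quality and depth, so any analysis that compares nucleosome
organization across cell types first has to answer three questions:

1. **Is this sample any good?** — a QC panel specific to nucleosome data.
2. **Which map should represent a cell type?** — ranking the samples of a
   cell type and, where several agree well, pooling them into a deeper
   combined map.
3. **What does the chosen map say at my loci?** — per-promoter and
   per-enhancer nucleosome features, and whether they carry information
   (for example, for predicting transcription-factor binding).

`nucqc` implements that computational core for R users: signal-track
construction from fragments, a six-metric QC panel with Pass/Fail labels,
QC-driven ranking and correlation-based pooling to select a *referenced
nucleosome organization landscape* per cell type, per-TSS/per-DHS feature
tables, and a logistic-regression experiment that measures how much
nucleosome features improve motif-based TF binding-site prediction. A
synthetic data generator with known ground truth makes the whole pipeline
testable without any downloads.

## Methods at a glance

**Tracks.** Each fragment is reduced to its midpoint and extended to a
147 bp nucleosome footprint; per-base *occupancy* counts overlapping
footprints and is normalized to genome-wide mean 1. The *array* track
scores local spacing regularity: for 2 kb windows every 100 bp, the
maximum normalized autocorrelation of the mean-subtracted occupancy over
lags 150–220 bp (the nucleosome repeat-length range), clipped to [0, 1].

**QC panel.** Six measurements per sample:

| metric | definition | better | label rule |
|---|---|---|---|
| coverage fold | Σ fragment bases / genome size | higher | none |
| dinucleotide periodicity | AA/TT/AT spectral power at 9–11 bp over fragment windows | higher | ≥ 2× white-noise band share |
| fragment length | mode of the length histogram | nearer 146 bp | within 146 ± 20 bp |
| TSS depletion | mean per-TSS depletion level | higher | ≥ 0.2 |
| TSS fuzziness | CV of the +1..+4 nucleosome spacings on the aggregate TSS profile | lower | **Pass iff CV < 0.4** |
| DHS array enrichment | mean array signal at DHS ± 1 kb over genome mean | higher | ≥ 1.2 |

**Ranking and pooling.** Per metric, samples get rank quantiles (1 =
best; fragment length is ranked by |mode − 146|, fuzziness ascending, the
other four descending). Within a cell type, samples are ordered by
`N_good` (number of Pass labels), then `C_better` (metrics whose quantile
beats the cell-type average), then `R_better` (sum of the six quantiles).
Occupancy is averaged in 1 kb windows genome-wide; sample pairs with
Pearson *r* > 0.6 are pooled (single-linkage components). The top-ranked
*High Quality Sample* is the reference, unless it belongs to a pool, in
which case the pooled sample is. References under five-fold coverage are
discarded.

**Locus features.** For a site *s*: depletion level
`1 − N_center / N_background` (max occupancy in [s−100, s+100) vs the two
flanking 200 bp bins; clamped to 0 when the center exceeds the
background), mean occupancy over the central 100 bp, and the 1 kb
up/downstream array score. Nucleosome positions are local maxima of the
smoothed occupancy scanned 1 kb from the anchor; adjacent maxima closer
than 100 bp keep only the higher one. The first position is the +1 (or
−1) nucleosome; linker length = mean adjacent spacing − 147 bp. Undefined
quantities use the −1 sentinel (no +1 → all −1; fewer than 2 nucleosomes
→ linker −1; fewer than 3 → linker SD −1).

**TF binding prediction.** Motif hits overlapping a ChIP-seq peak are
*bound*, the rest *unbound*. Two logistic regressions — motif score only,
and motif score + (depletion, occupancy, up/down array score) at the hit
center — are compared by stratified 10-fold cross-validated ROC AUC
(rank-statistic AUC on pooled out-of-fold probabilities). The headline
number is `AUC(motif + nucleosome) − AUC(motif)`.

## Worked example

```r
library(nucqc)

sim <- simulate_sample(synthetic_spec(seed = 1))     # synthetic study conditions
occ <- build_occupancy_track(sim$fragments, sim$assembly)
arr <- build_array_track(occ)

compute_sample_qc(sim$fragments, sim$assembly, sim$tss, sim$dhs,
                  occ = occ, arr = arr)
#> <sample_qc> sim_seed1 (synthetic/none)
#>   coverage_fold               14.6945
#>   dinucleotide_periodicity         NA [Fail]
#>   fragment_length            147.0000 [Pass]
#>   tss_depletion                0.9784 [Pass]
#>   tss_fuzziness                0.0066 [Pass]
#>   dhs_array_enrichment         2.4519 [Pass]
```

The sample is 14.7-fold deep; its promoters are strongly depleted
(0.98 on a 0–1 scale), its downstream arrays essentially perfectly phased
(CV 0.007, far below the 0.4 Pass bound), and arrays are 2.45× enriched
at DHSs. The dinucleotide metric is NA (and conservatively labelled Fail)
because no genome FASTA was attached.

```r
head(tss_feature_table(occ, arr, sim$tss), 3)
#>        name depletion_level occupancy array_score_down plus1_position linker_length nucleosome_count
#> 1 chr1_tss1           0.970     0.097             3.24            220         43.25                5
#> 2 chr1_tss2           0.975     0.198             3.97            223         42.50                5
#> 3 chr1_tss3           0.978     0.253             3.66            218         44.00                5
```

Each promoter shows the planted architecture: a deep NFR, five
downstream nucleosomes at a 190 bp repeat (linker ≈ 190 − 147 = 43 bp)
and array scores well above the genome average.

```r
bind <- simulate_binding(sim, occ, arr, n_sites = 1500,
                         beta = c(motif_score = 0.8, depletion = 2))
sites <- extract_predictors(
  label_sites(bind$hits[, c("chrom", "start", "end", "motif_score")],
              bind$peaks), occ, arr)
fit_and_evaluate(sites, folds = 10, seed = 1234)
#> <tf_model_result> n=1500, 10-fold CV
#>   motif-only AUC: 0.6888 (pooled), 0.6900 (mean fold)
#>   full model AUC: 0.7302 (pooled), 0.7312 (mean fold)
#>   AUC improvement: +0.0414
```

Binding was simulated to depend on depletion beyond the motif score, and
the cross-validated comparison recovers that: adding the nucleosome
predictors raises the AUC by 0.04.

A thin command-line wrapper over these functions ships in
`inst/cli/nucqc.R` (subcommands `tracks`, `qc`, `select`, `features`,
`tfpredict`, `simulate`).

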