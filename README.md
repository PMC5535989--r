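# rhythmiR

Rhythmicity detection for short serum-shock expression time courses.

Serum-shock entrainment synchronizes the circadian clocks of cultured cells;
afterwards, a subset of transcripts — including miRNAs — oscillates with a
period near 24 h. Detecting those features from a microarray time course of
only 8 points (4 h spacing, a 0–28 h window) is fragile: a sinusoid fitted
to so few points often fits noise convincingly. rhythmiR is for analysts who
need that detection step *and* the controls around it: randomization null
models that show which parts of the signal are real structure, restrictive
classification thresholds, phase clustering, cross-cell-line overlap
statistics, and ΔΔCt processing of the qPCR series used for validation.
Because such microarray datasets are rarely deposited, the package includes
a seeded synthetic-data generator with ground-truth labels that stands in
for the real arrays and makes the whole pipeline testable.

## The model

Each mean-level-adjusted series is fit with a single bounded cosine

```
g(t) = β · cos(ω·t + φ),   β ∈ [0, 30],  ω ∈ [0, π] rad/h,  φ ∈ [−π, π)
```

by profiled least squares: for fixed ω the model is linear in
(β cos φ, −β sin φ), so the search is a dense multi-start over ω with local
refinement, ties broken toward smaller ω. The *cosine correlation* r is the
Pearson correlation between the fitted curve and the centered data. A
feature is called rhythmic when

```
r > 0.82   and   0.22 ≤ ω ≤ 0.29 rad/h   and   β > 0.045
```

(ω = 2π/24 ≈ 0.2618 rad/h is a 24 h rhythm, so the band covers periods of
roughly 21.7–28.6 h). Null data come from five matrix shuffles — TL
(time-label), RW (row-wise), CW (column-wise), RCW (row-then-column), RCWB
(row-and-column within contiguous time blocks) — compared to the
experimental fits by KS tests on r, ω and peak phase. Set overlaps between
cell lines use the upper-tail hypergeometric test. qPCR series are
quantified per replicate as fold = 2^−ΔΔCt and rhythm-tested with a
permutation test (best cosine correlation over 20–28 h periods against
time-shuffles) — a deliberately simple, clearly labeled substitute for
meta-analytic rhythm detectors.

See the methods vignette (`vignettes/rhythmicity-detection.Rmd`) for the
full statistical account.

## Worked example

```r
library(rhythmiR)

cfg  <- simConfig(n_features = 500, seed = 7)      # 7.5% rhythmic by default
sim  <- generateExpressionDataset(cfg)
fits <- fitCosineMatrix(sim$exprs)
fits
#> CosineFitSet: 500 features over 8 timepoints
#>   r: median 0.825 | omega: median 0.467 rad/h | beta: median 0.0231

calls <- classifyRhythmic(fits)                     # default thresholds
sum(calls$is_rhythmic)
#> [1] 37

summarizeCalls(list(sim = calls), universe_size = 500)$summary
#>   dataset n_rhythmic pct_rhythmic
#> 1     sim         37          7.4

head(calls[calls$is_rhythmic,
           c("feature_id", "period_h", "peak_phase_h", "amplitude", "r")], 4)
#>    feature_id period_h peak_phase_h amplitude      r
#> 21  feat00021    23.66       18.281    0.1350 0.9943
#> 22  feat00022    23.78       17.605    0.4659 0.9994
#> 59  feat00059    24.37       22.106    0.4310 0.9983
#> 90  feat00090    22.85        5.725    0.4581 0.9987
```

Every called feature reports its period (h), first peak time (h) and
amplitude (log10 intensity). Against the generator's ground truth this run
has sensitivity 0.974 and precision 1.000: the thresholds are restrictive by
design — near-threshold amplitudes are sacrificed rather than admitting
noise. Median r across *all* 500 features is 0.825 even though only 7.5%
are truly rhythmic; that is the short-series overfitting the null models
exist to quantify:

```r
null  <- randomizeMatrix(sim$exprs, "RCWB", seed = 11)
cmp   <- compareNull(fits, fitCosineMatrix(null))
cl    <- clusterByPhase(calls, k = 6)               # Ward on the phase circle
table(cl$cluster)
#> 1 2 3 4 5 6
#> 6 9 5 5 5 7

# is an overlap of 25 rhythmic miRNAs between two cell lines surprising?
overlapSignificance(setA, setB, universe_size = 2006)  # |A|=143, |B|=183
#> $overlap ... 25     $p_value ... 0.00075
```

An end-to-end, manifest-logged run (simulate → normalize → fit → classify →
null comparisons → cluster → overlaps → report) is one call:

```r
runPipeline(list(seed = 1, out_dir = "run1"))
```

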