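---
title: "Methods: simulating and scoring crowdsourced TMA annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring crowdsourced TMA annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdtma)
```

## The problem

Scoring immunohistochemically (IHC) stained tissue-microarray (TMA) cores is
a bottleneck in translational cancer research: each core must be checked for
the presence of cancer cells and, where present, scored for the fraction of
stained cells and the staining intensity. Crowdsourcing distributes this work
to many lay raters, each individually less accurate than a pathologist, and
recovers accuracy by aggregation. `crowdtma` implements the full analysis
chain for such a study:

1. grid-based cancer detection — each TMA image is overlaid with a 6×6 grid
   and every square is labelled `cancer`, `no_cancer` or `no_tissue`;
2. IHC scoring — per image, a stained proportion (0–100% in steps of 5) and,
   when positive, an intensity grade 1–3; their product is the McCarty
   H-score (0–300);
3. consensus — majority vote across raters per square, median across raters
   per image;
4. agreement — sensitivity, specificity, F1, Cohen's kappa, ROC AUC on the
   per-square vote fraction, Spearman correlation of aggregate H-scores
   against the expert reference;
5. resampling — bootstrap curves of accuracy versus crowd size;
6. a 2×2 factorial linear model for the effect of two tutorial components
   (annotated example images, feedback-based training) on individual
   performance.

Because no public rater-level data set exists for this design, the package
ships a first-class synthetic-data generator whose defaults encode the study
conditions, so that every downstream stage is testable end to end.

## Detection model and binarization

Each rater is a `rater_profile` with three error rates. Conditional on the
true square label the reported label is drawn independently per square:

* truth `cancer`: reported `cancer` with probability *sensitivity*, else
  `no_cancer`;
* truth `no_cancer`: reported `no_cancer` with probability *specificity*,
  else `cancer`;
* truth `no_tissue`: reported `no_tissue` with probability
  *tissue recognition*, else one of the two tissue labels uniformly — the
  least-informative split, since nothing is known about how raters
  misread empty squares.

All analysis is binary: `cancer` is positive, and `no_cancer` and
`no_tissue` are both negative (a blank is a statement that no cancer was
seen). Squares that truly contain no tissue whatsoever would inflate
specificity, so squares unanimously labelled `no_tissue` by the expert panel
are masked out of every detection metric. Unanimity is the default because
"no tissue whatsoever" is naturally read as no expert seeing any tissue;
`mask_rule = "majority"` is available as a switch and is recorded in the
output metadata.

Errors are i.i.d. across squares. Real annotation noise is spatially
correlated (a rater who misreads a tissue region misreads adjacent squares
together), raters learn and tire over a session, and paid and volunteer
raters may differ; none of this is modelled. Passing tests therefore
demonstrate the correctness of the aggregation and inference machinery under
the stated error model, not robustness to structured noise.

## Consensus rules

Per square, the crowd consensus is positive iff the positive vote fraction
strictly exceeds 0.5. Exact ties resolve **negative**: odd expert panels
never tie, but bootstrap-resampled groups do, and since lay crowds
historically over-call cancer, ties are not promoted to positives. The tie
rule is a parameter (`tie`) so its effect can be examined.

The expert detection reference is the majority vote over binarized expert
labels under the same tie rule. The expert IHC reference per image is the
median proportion and the median intensity over experts reporting a positive
proportion (absent when the median proportion is 0); the reference H-score is
the product of the two medians. Even-count medians take the midpoint of the
two central values, so reference intensities can be non-integer; downstream
treats them as real numbers rather than forcing them back onto the 1–3 grid.

## IHC noise model

The reported proportion is the true proportion plus Gaussian noise (SD
`proportion_sd`, default 10 percentage points for lay raters), rounded to
the nearest multiple of 5 and clipped to [0, 100]; the rounding and clipping
reproduce the discrete rating scale, and the symmetric noise reproduces the
property that crowd medians track the expert reference. The reported
intensity is drawn from the row of a 3×3 confusion matrix indexed by the
true intensity whenever the reported proportion is positive. One edge the
rating scale forces: if noise lifts a reported proportion above 0 when the
true proportion is 0, there is no true intensity to confuse, and the
reported intensity is drawn uniformly from {1, 2, 3}. A reported proportion
of 0 always has absent intensity, and H-scores are always derived, never
stored, so files cannot carry inconsistent scores.

## Default study conditions

The generator's defaults are fixed once and encode the scale of the study
the package emulates:

| parameter | default | rationale |
|---|---|---|
| images × grid | 10 × (6×6) = 360 squares | the detection task size |
| `p_cancer` | 0.40 | typical cancer-square fraction in tumour-bearing cores |
| `p_no_tissue` | 0.15 | reproduces ≈53/360 empty squares |
| lay sensitivity | Beta, mean 0.74, SD 0.14 | observed mean individual rate; SD back-computed from a ±0.04 95% CI of the mean at ~50 raters |
| lay specificity | Beta, mean 0.66, SD 0.14 | as above |
| tissue recognition | 0.85 | empty squares are easy but not trivial |
| expert rates | 0.95 / 0.95 / 0.95 | small high-accuracy panel, k = 3 (5 for one sample type) |
| IHC study | 30 images, 45 raters × 10 images | the bladder-marker arm; the lung arm (21 images, 35 raters) is a parameter change |
| bootstrap | sizes 3–40, 500 resamples (AUC); 10,000 resamples (Spearman) | the published procedure constants |
| factorial | 50 raters/cell; feedback +0.0877 sens, −0.0759 spec; annotated +0.0269 sens, +0.0118 spec | effect sizes matching the reported coefficient pattern, applied as shifts to the cell means |

## Agreement statistics

`performance()` applies the exact formulas sensitivity = TP/(TP+FN),
specificity = TN/(TN+FP), F1 = 2TP/(2TP+FP+FN). A statistic with a zero
denominator is reported as `NA` with a named reason — never silently 0 —
and propagates as flagged-missing. Per-participant statistics pool all
unmasked squares across images (global counts, not per-image averages).

`cohens_kappa()` is the unweighted two-category kappa
$(p_o - p_e)/(1 - p_e)$; when both raters are constant on the same category
($p_e = 1$, which forces $p_o = 1$) it returns 1 by convention.

`roc_auc()` uses the Mann–Whitney identity: the AUC is the probability that
a random positive square outscores a random negative one, with half credit
for ties, computed in rank form. The score variable is the per-square
positive vote fraction — the only continuous statistic available from binary
votes, adopted explicitly. `spearman_r()` is the Pearson correlation of
mid-ranks (ties averaged), delegated to `stats::cor(method = "spearman")`
behind a guard that reports constant inputs as undefined rather than `NaN`.

## Bootstrap procedures

The resampling unit is the **rater**. For a group size $n$, each of the
`n_boot` resamples draws $n$ rater ids with replacement; a rater drawn twice
contributes two votes. For detection, the resample's vote fractions are
scored by AUC and the per-size point estimate is the **mean** over
resamples; for IHC, each resample's per-image aggregate is the median
H-score over the drawn raters who scored that image (images left uncovered
by the draw are dropped from that resample's correlation), scored by
Spearman r, with the **median** over resamples as the point estimate —
matching how each curve is conventionally displayed. Intervals are plain
percentile intervals, `quantile()` type 7 (linear interpolation), at 2.5%
and 97.5%; no BCa or studentization. A resample with an undefined statistic
(single-class reference, fewer than 3 covered images, constant aggregate)
is redrawn and counted in `n_redrawn`, keeping `n_boot` exact.

Every generator and bootstrap derives per-rater / per-size child seeds from
the master seed through a deterministic hash, so results are bit-reproducible
and extending a crowd never perturbs existing raters.

## Factorial model

`fit_factorial_glm()` is homoscedastic OLS of one outcome on the two 0/1
tutorial indicators and their interaction, with treatment coding — the
intercept is the double-control cell mean and each coefficient is the
estimated change when adding a factor, reported ×100 with Wald 95% CIs and
two-sided t-test p-values, uncorrected for multiple comparisons (a
Bonferroni switch exists, off by default). Each outcome (F1, specificity,
sensitivity) is fitted separately. Outcomes are ratios fitted linearly; no
logistic or beta regression is attempted, matching the design being
replicated. An empty design cell makes the interaction inestimable and is
reported by name.

## Problem sizes used in the shipped analyses

The numbered drivers under `analysis/` and `scripts/acceptance.R` run the
study at its native scale: 50 detection raters, 3 experts, 360 squares;
45 IHC raters over 30 images; 500 AUC resamples per size and 10,000
resamples for the full-population Spearman CI. The IHC size-curve in
`analysis/04_group_size.R` uses 2,000 resamples per size over a coarse size
grid {3, 5, 10, 20, 40} — the median-based curve is visually stable well
below 10,000 resamples, which are reserved for the reported full-population
interval. The test suite exercises the same code paths at reduced sizes and
at 200 replicate simulations for the consensus-beats-individual property.

## Known limitations

* No spatial error correlation, rater drift, or rater-truth joint inference
  (no Dawid–Skene style model): aggregation is plain majority/median by
  design.
* Expert labels are simulated from the same error model as lay raters (with
  better rates); real expert disagreement is structured, not i.i.d.
* Detection and IHC crowds are drawn independently; a shared-rater design
  would induce correlation between the two analyses that is not modelled.
* The factorial generator shifts underlying sensitivity/specificity rates;
  outcome-scale effects (especially F1) emerge indirectly and are close to,
  but not algebraically equal to, the injected shifts.
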