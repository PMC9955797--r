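---
title: "Radiomic texture features and wrapper-based classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic texture features and wrapper-based classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radtex)
```

## The problem

Multiparametric MRI is the standard imaging route to prostate biopsy, but
PI-RADS reading is subjective and says little about tumour aggressiveness.
`radtex` implements a radiomic pipeline that asks whether quantitative
texture of a segmented lesion, on paired T2-weighted and apparent diffusion
coefficient (ADC) volumes, combined with two bedside covariates (digital
rectal examination and the patient's maximum PI-RADS score), predicts
clinically significant prostate cancer — a biopsy Gleason sum of at least 7
(ISUP grade $\ge 2$); Gleason 6 and benign biopsies form the negative
class.

The pipeline is: per-case feature extraction (484 image features + 2
clinical), wrapper feature selection with a random-forest evaluator, and
cross-validated ROC evaluation. A seeded synthetic-cohort generator stands
in for patient data, which are not redistributable, so every stage is
testable end to end.

## Feature extraction

All statistics are computed from in-mask voxels only; both endpoints of
every co-occurrence pair, and the full neighbourhood of every LBP code,
must lie inside the lesion mask. Perturbing out-of-mask voxels provably
(and, in the test suite, empirically) cannot change a feature.

### First-order block (12 per modality)

From the in-mask intensity histogram (64 equal-width bins over the in-mask
range by default): `mean`, `sd`, `skewness`, `kurtosis` are population
moments of the raw intensities — plain, not excess, kurtosis, so a Gaussian
gives about 3; `range` is max − min; `width` is the full width at half the
absolute-maximum bin height, in intensity units; `energy` $\sum_i p_i^2$;
`entropy` $-\sum_i p_i \log_2 p_i$; `max_height` and `max_level` are the
tallest bin's probability and centre; `n_rel_maxima` counts relative maxima
after length-3 moving-average smoothing (window truncated at the
boundaries, runs of equal values count once, boundary bins compare against
their single neighbour); `energy_rel_maxima` sums $p_i^2$ over bins within
two of any relative maximum. A zero-spread VOI takes skewness and kurtosis
0 by convention. Twelve statistics per modality gives 24.

### TOP-LBP block (48 per modality)

A 2D local binary pattern compares each pixel with its $P = 8$ ring
neighbours at radius $R = 1$ (the classic, hand-checkable configuration;
there is no subpixel interpolation): bit $j$ is set iff neighbour $j$ is
strictly brighter than the centre, bits read from east counter-clockwise,
weighted $2^j$. Three variants post-process the code: rotation-invariant
(`ri`, minimum over the 8 circular bit rotations; 36 distinct codes),
uniform (`u2`, codes with at most two circular transitions keep their
value, all others share one overflow bin; 58 + 1 bins), and `riu2` (number
of set bits if uniform, else $P + 1$; 10 labels).

The three orthogonal planes through the rounded in-mask centroid (XY, XZ,
YZ) extend the construction to 3D: codes valid on each plane (full
neighbourhood in-plane and in-mask) are pooled across the three planes into
one histogram per variant. Pooling, rather than keeping three histograms,
is what the arithmetic demands: 4 variants × 12 first-order statistics of
the code histogram = 48 features per modality, 96 for the pair. A plane
with fewer than $P + 1$ valid pixels contributes nothing; a VOI whose three
planes are all too small cannot be encoded and is an error. Code
histograms use one bin per possible code value with unit bin width; the
moment statistics are computed on the mapped code values themselves (the
overflow bin of `u2` takes the value $2^P$).

Note a deliberate asymmetry: `riu2` summaries are exactly invariant under
90° volume rotations (bit count and transition count survive reflections),
while `ri` is only invariant under in-plane rotations — a 90° rotation about
an axis mirrors one of the two swapped orthogonal planes, and a mirrored
ring reverses the circular bit string, which the rotation minimum does not
absorb. The tests check each variant for the invariance it actually has.

### GLCM3 block (182 per modality)

In-mask intensities are requantized to $N = 2^m$ grey levels by min–max
binning, $\mathrm{level} = \lfloor N (x - \min)/(\max - \min) \rfloor$
clipped to $[0, N-1]$, with $m = 5$ (32 levels) by default. Native MRI bit
depths (12–16) would make $N^2$ co-occurrence cells astronomically sparse;
min–max requantization is the standard radiomics remedy, and setting $m$
to the stored bit depth recovers the unquantized construction.

For each of the 26 signed unit displacements $d \in \{-1,0,1\}^3 \setminus
\{0\}$, the co-occurrence matrix counts ordered voxel pairs $(p, p+d)$ with
both endpoints in-mask; matrices are directed (opposite displacements are
transposes of each other, kept separately). On the normalized matrix
$p(i,j)$ with grey levels $i, j$: autocorrelation $\sum ij\,p$, homogeneity
$\sum p/(1+|i-j|)$, entropy $-\sum p \log_2 p$, energy $\sum p^2$,
covariance $\sum (i-\mu_i)(j-\mu_j) p$, inertia $\sum (i-j)^2 p$, and
absolute contrast (dissimilarity) $\sum |i-j|\,p$. An empty matrix (VOI too
thin for the displacement) yields a zero-filled, flagged feature set.
26 displacements × 7 measures × 2 modalities = 364 features.

### Assembly

The image block is ordered first-order T2, first-order ADC, TOP-LBP T2,
TOP-LBP ADC, GLCM3 T2, GLCM3 ADC — 484 values — followed by `dre` (0/1) and
`pirads_max` (kept ordinal 3/4/5; a tree ensemble needs no one-hot
encoding), 486 columns in total. The source study reports 487 features
while enumerating 484 + 2; the text does not say what the extra column is,
so this package emits 486 and keeps the clinical block configurable so
alternative reconstructions remain expressible.

## Wrapper selection

`best_first_select()` is a forward search: each round scores every
remaining candidate appended to the current subset with
`inner_cv_score()` — stratified k-fold cross-validation (folds drawn once
from the config seed) of a `ranger` random forest, pooled out-of-fold
accuracy. The best candidate joins the running subset; the *returned*
subset only advances when the score strictly improves (tolerance 1e-12 —
ties reject, and among tied candidates the earlier column wins, making
duplicated features resolve deterministically). The search tolerates
`stall_limit` consecutive non-improving expansions before stopping
(bounded backtracking); full open-list best-first costs far more and, with
a greedy evaluator as noisy as CV accuracy, buys nothing reproducible.
Defaults: 10 inner folds, 100 trees, `mtry` $=\lfloor\sqrt{|S|}\rfloor$,
stall 5. Accepted-step scores are strictly increasing by construction, and
the whole trace is returned for inspection (`tidy()`, `autoplot()`).

## Evaluation

`cross_validated_scores()` scores each case out-of-fold by the fraction of
trees voting for the significant class. `roc_auc()` is the Mann–Whitney
probability with ties counted one half (checked in the tests against both
exhaustive pair counting and pROC). The operating point maximizes Youden's
J, ties resolved to the lower cutoff; accuracy, precision and sensitivity
for the significant class are reported with 95% Wilson intervals, the AUC
with its DeLong interval (via pROC). Per-feature univariate AUCs are
reported unflipped — a feature anti-correlated with the label shows an AUC
below 0.5, as in the source study's univariate table.

Two protocols are provided. **Paper-faithful** (default, matching the
published protocol): select once on the full cohort, then k-fold CV of the
selected subset on the same data. **Nested**: re-run selection inside each
outer training fold and score the held-out fold with that fold's own
subset. Paper-faithful is *optimistic*: the selected features were chosen
partly for dataset-specific noise, which same-data CV re-detects. On
null cohorts (no class signal anywhere, 486 candidate features, n = 120)
paper-faithful evaluation lands around AUC 0.55–0.75, while nested
evaluation is centred at 0.5. The acceptance suite therefore checks type-I
control (null AUC in [0.35, 0.65]) in nested mode — the only protocol under
which that band is a meaningful null property — and separately checks that
paper-faithful AUC exceeds nested AUC on average, which quantifies the
optimism itself. Nested is the protocol we recommend for any real use.

## Synthetic cohorts

`generate_phantom()` builds each case from three independently switchable
class contrasts inside an ellipsoidal lesion on a 32×32×16 grid (defaults):

* **correlation length** — white noise convolved with a separable Gaussian
  kernel (class sd 1.2 vs 2.6 voxels), standardized to unit variance;
  perturbs the co-occurrence and LBP families;
* **noise level** — additive in-lesion white noise (sd 1.0 vs 0.5);
  perturbs first-order spread (total in-lesion sd 1.41 vs 1.12). The noise
  contrast deliberately points the *same* way as the correlation-length
  contrast: additive noise attenuates lag-1 co-occurrence correlation by
  the factor $1/(1+\sigma_\varepsilon^2)$, so a noisier significant class
  would cancel the smoothness signal it is supposed to carry;
* **mean shift** — in-lesion offset (0 vs 0.8); perturbs first-order
  location.

`effect` $\in [0,1]$ interpolates the class-1 parameters from class 0, so
`effect = 0` makes the class distributions literally identical. The
background is independent white noise — out-of-mask voxels carry no signal,
which the mask-isolation tests exploit. T2-like and ADC-like volumes are
drawn independently with shared class parameters on a common mask (paired
masks add no testable structure). Covariates follow the published cohort's
shape: 43% prevalence at n = 91, PI-RADS-max concentrated at 3 for
negative and 5 for positive cases, and DRE Bernoulli probabilities
(0.2, 0.7) whose closed-form two-Bernoulli AUC is 0.75.

What the phantoms do *not* emulate: scanner noise models (e.g. Rician),
bias fields, anisotropic spacing effects, anatomy, or inter-scanner
intensity shifts. Passing tests therefore demonstrate that the pipeline's
statistics, search and evaluation machinery behave correctly and that
texture contrasts of the modelled kind are recoverable — not that the
published clinical performance transfers to any particular scanner or
cohort.

## Numerical choices and degenerate inputs

* Quantization and histogram binning are min–max with final-bin clipping;
  constant inputs map to the lowest bin, so constant VOIs are valid
  everywhere (features take their point-mass limits: energy 1, entropy 0).
* Strict inequality in LBP comparisons (equality gives bit 0), so constant
  planes code to 0.
* Entropies are base-2 throughout.
* Empty co-occurrence matrices and constant univariate features are
  zero-filled/0.5-valued and flagged rather than NaN.
* All forests run single-threaded with explicit seeds; fold assignment is
  drawn once per config seed, so every reported number is reproducible
  bit for bit from its embedded config + seed.

## Problem sizes used by the automated checks

The test and acceptance runs are sized for a single CPU: pipeline-level
checks use n = 120 cohorts (10 seeds for the null and power properties, 20
replicates for the optimism ordering), wrapper settings of 3 inner folds,
15 trees and stall limit 1, nested evaluation over 3 outer folds, and the
optimism-ordering replicates run on the first-order + clinical feature
subset (26 candidates) — the ordering is a property of the protocol, not of
the candidate count. Module defaults are unchanged by these choices.

## Known limitations

* The TOP-LBP plane choice (through the lesion centroid) reads one slice
  triplet per case; very flat lesions can lose one or two planes.
* `width` (FWHM) on multimodal histograms reports the main peak only.
* Greedy-with-stall search can miss interacting feature pairs that only
  help jointly; that is inherent to forward wrapper search.
* The paper-faithful protocol is reproduced for fidelity but should not be
  used to report generalization performance; use nested mode.
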