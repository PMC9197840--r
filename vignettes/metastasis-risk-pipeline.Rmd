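---
title: "Whole-slide metastasis-risk analysis: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-slide metastasis-risk analysis: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metrisk)
```

## The problem

Primary cutaneous squamous cell carcinoma (cSCC) usually stays local, but a
minority of tumors metastasize — most of them quickly, within about six
months of diagnosis — and metastatic disease carries high mortality.
Established staging systems (AJCC-8, BWH) summarize diameter, invasion
depth and perineural invasion, yet their discrimination of which primary
tumor will metastasize is modest. `metrisk` implements a complete,
testable version of an image-based approach to this question: classify
tiles cut from an annotated hematoxylin–eosin whole-slide image (WSI) of
the primary tumor as coming from a rapidly metastatic versus a
non-metastatic tumor, aggregate the tile scores into a slide-level call,
and then fold that call into counting risk-factor models (RFMs) and
survival summaries alongside the conventional clinicopathological
variables.

Patient-level WSIs from the original study cannot be shared, so the
package is built around two substitutes, both first-class and tested:

* a **synthetic study-material generator** producing annotated slide
  images, cohort tables with the published per-cohort marginal
  distributions, and right-censored survival records; and
* the **published contingency counts** of the risk tables, bundled
  verbatim, from which every odds ratio and concordance AUROC of the
  downstream statistics is exactly recomputable.

## Synthetic study material

`generate_slide()` renders a pale (glass-like) background, an irregular
annotated tumor region filled with eosin-pink tissue, and dark
nucleus-like ellipses inside the annotation. The two texture classes
differ only through `texture_effect` $\in [0,1]$: the rapidly metastatic
cohort receives $1 + 0.6\,e$ times the nucleus density and $1 + 0.35\,e$
times the nucleus radius. At $e = 0$ the class-conditional pixel
distributions are identical by construction, which gives the pipeline a
usable null; at $e = 1$ the classes are cleanly separable, which gives a
recovery target. The slowly metastatic cohort reuses the non-metastatic
texture, since no separate morphological claim is made about it; it is
generated but unused by default.

The generator emulates what the analysis *assumes* about real H&E
material — a bright background, darker tissue, nucleus-scale dark objects
whose density/size carries the class signal, an annotation mask with
possible exclusions — and nothing more. It does not emulate stain
variability, tissue architecture (nests, stroma, inflammation), scanner
noise patterns, pen marks or out-of-focus regions. A passing recovery
test therefore shows the pipeline's plumbing and statistics are correct,
not that the classifier would reach any particular performance on real
slides.

Cohort tables (`generate_cohort()`) sample each categorical variable
independently within cohort from the published marginal frequencies
(e.g. diameter ≥ 30 mm in 54.5% of rapidly metastatic vs 10.2% of
non-metastatic tumors). Joint structure between variables is *not*
emulated; the RFM machinery is exercised by the bundled real counts where
the joint structure matters. Survival times (`generate_survival()`) are
exponential per stratum, administratively censored at 1826 days (five
years from primary diagnosis). Default hazards were set once so the
overall-survival pattern matches the published ordering — median OS near
1.2 years (rapid metastasis), 3.4 years (slow), about 70% five-year OS
(non-metastatic) — and disease-specific survival is derived by flipping a
per-cohort fraction of deaths to censored (all of them in the
non-metastatic cohort, 10% in the rapid cohort), so DSS events are a
subset of OS events.

### Scale

Synthetic slides default to 4096×4096 px in `synthetic_slide_spec()`,
where a 512-px tile grid is 8×8. The pipeline default
(`pipeline_config()`) uses 1024×1024 px slides with 128-px tiles — the
*same* 8×8 grid at one sixteenth the pixel count. Every downstream
contract (validity fractions, smoothing, aggregation, cross-validation)
depends on the grid geometry, not the pixel count, so the smaller scale
exercises identical code paths; test and acceptance runs use it with 20
slides per class (40 patients) for the recovery run and 50 per class for
the null run. Nucleus radii scale with the slide so tile content remains
plausible.

## Tiling rules

Tiles are cut on a non-overlapping grid from the image origin, row-major,
0-based, with half-open pixel boxes; partial edge tiles are discarded
rather than padded, so no tile mixes image content with undefined
pixels. Two strict thresholds decide a tile's role:

* **valid** iff more than 50% of its pixels are tissue, where a pixel is
  tissue iff its grayscale value is below *both* a fixed background
  cutoff (220/255) and the per-image Otsu split (`compute_tissue_mask()`).
  Taking the minimum of the two thresholds makes the rule robust on
  near-empty slides: on a constant image, where Otsu is undefined, the
  fixed cutoff alone applies.
* **tumor** iff more than 50% of its pixels lie inside the annotation
  mask. Manual exclusion regions are simply mask value 0. Both rules are
  strict inequalities: a fraction of exactly 0.5 does not qualify.

Training sets use valid tumor tiles only; all tiles inherit the slide's
cohort label. Otsu is implemented as an exhaustive 256-bin
between-class-variance search; on histograms with an empty plateau
between modes any plateau point is a maximizer, and the first one is
taken (the induced split is what matters and is tested against an
independent implementation). Tiles destined for a classifier input are
resized to 299×299 by bilinear interpolation (`get_tile_image()`); the
target size is fixed by the published design, the kernel is a package
choice.

Three input-sampling modes mirror the published model variants:
every valid tumor tile (`single`), tiles at the invasive front
(`select_invasive_front()`; a tumor tile with a 4-connected non-tumor
neighbor is on the inside front, a non-tumor tile with a tumor neighbor
on the outside front; grid borders are not fronts), and disjoint random
stacks of `n` tiles per slide (`make_tile_stacks()`; leftovers dropped,
no tile reused, so the effective dataset shrinks `n`-fold).

## The tile classifier

The published classifier is an 18-layer residual CNN with a custom head
of average pooling and two dense layers under heavy dropout, trained
with binary cross-entropy under patient-exclusive cross-validation.
`metrisk`'s classifier keeps that architecture's decision structure at
desk scale: feature extraction (`tile_features()`) computes pooled
morphometric descriptors of a tile — intensity statistics and quantiles,
dark-pixel fractions at nucleus-scale cutoffs, connected dark-blob
density and size (nucleus proxies), gradient energy, stain-color
contrast — playing the role of the convolutional trunk plus global
average pooling; on top of these sits a trainable residual dense network
(identity-skip blocks $z \mapsto z + \mathrm{ReLU}(zW_1 + b_1)W_2 + b_2$)
with the published head: one dense layer under inverted dropout
(default 0.5, "heavy"), then a single sigmoid unit, trained with binary
cross-entropy and Adam. Forward pass, backpropagation and the optimizer
are implemented in the package and are fully deterministic given the
seed.

Depth presets: `tiny` (2 blocks, width 32) is the tested default —
deeper models overfit small tile sets, which is also why the original
study settled on its shallower variant; `resnet18_like` and
`resnet50_like` widen and deepen the trunk in the same spirit. The
optimizer, learning rate (10⁻³) and batch size (64) are not stated in
the published setup; they are package defaults, documented in
`classifier_config()` and fixed by seeds rather than guessed at
fidelity. Class weighting for the 59-vs-22 imbalance is available but
off by default. Color/geometry augmentation (`augment_tile()`:
flips, right-angle rotations, HSV jitter) is provided and tested; the
feature representation is largely invariant to it, so the default
training path does not spend time on it.

Cross-validation (`assign_folds()`, `train_cv()`) partitions *patients*,
stratified by cohort, and every tile inherits its patient's fold — no
patient's tiles can reach both a training and a validation split. Each
fold's held-out tiles receive exactly one out-of-fold (OOF) probability
from the model that never saw that patient.

## From tiles to slides

An OOF probability $p$ becomes a tile score $s = 100p - 50 \in [-50, 50]$
(`shift_scale()`; affine, exactly invertible). Scores live on the tile
grid (`score_grid()`) with a validity mask; invalid cells carry no score.

`median_smooth()` implements the spatial median filter precisely as the
mapping convention requires, because several details are easy to get
wrong silently:

* a forward window anchored at the cell, covering rows $[r, r+w)$ and
  columns $[c, c+w)$, clipped at the grid borders (window size $w = 2$
  by default);
* only valid scores inside the window enter the median; a cell whose
  window holds no valid score keeps its value;
* an even number of values takes the arithmetic mean of the two central
  order statistics (so smoothing commutes with negating all scores);
* invalid cells stay invalid.

The slide decision (`slide_score()`) is the sign of the *mean* smoothed
valid score against threshold 0 — the operational form of the "majority
vote" — with a mean of exactly 0 resolving conservatively to
non-metastatic. A literal tile-count majority is available as
`vote = "count"`; the two differ on slides where a few extreme tiles
outweigh a numeric majority, and the mean rule is the default because it
is the rule the slide-level results are defined by. ROC curves and
AUROCs (`roc_curve()`, `auroc()`) use the tie-corrected concordance
$(W + T/2)/(n_1 n_0)$, verified in the tests against a brute-force
all-pairs oracle. Probability maps (`render_probability_map()`) color
tiles with a diverging blue–white–red palette over $[-50, 50]$, leave
non-annotated area white, and embed a legend strip.

## Risk-factor statistics

All Table-style statistics operate on `contingency_counts` — ordered
case/control counts per predictor level, with unknown levels excluded
per variable (not listwise), which is why denominators differ between
variables.

* `odds_ratio()` computes the cross-product ratio $(ad)/(bc)$ with the
  Woolf log-scale interval
  $\exp(\ln \mathrm{OR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$. Any zero cell
  is reported not estimable — matching the published NA rows — rather
  than continuity-corrected. `fit_logistic()` provides the
  logistic-regression route (IRLS via `glm`), which for a single
  categorical predictor reproduces the same per-level ORs; complete
  separation is flagged and the affected levels reported not estimable.
* `ordinal_auc()` is the grouped-counts form of the tie-corrected
  concordance; applied to the bundled counts it reproduces the published
  AUROCs (AI-RFM 0.917, conventional RFM 0.862, diameter 0.804, BWH
  0.818, Clark 0.788, pathologist 0.694) at the printed precision.
* `build_rfm()` counts selected binary risk factors per tumor (AI
  metastatic, Clark level 5, diameter ≥ 30 mm for the AI-RFM; subsets
  and the grade-extended variant are configurable) and tabulates the
  count as an ordinal predictor; tumors missing any selected factor are
  excluded from that model only.
* `association_test()` routes 2×2 tables with any expected cell at or
  below 5 to Fisher's exact test and everything else to the uncorrected
  Pearson χ²; `pearson_correlation_matrix()` is pairwise-complete with
  zero-variance columns flagged.

One known inconsistency is deliberately not reproduced: the published
alternative diameter grouping (≥ 20 mm) prints an odds ratio of 14.39,
but its own printed counts (17/5 cases, 13/46 controls) give
$(17 \times 46)/(5 \times 13) = 12.03$ by the cross-product formula. The
package implements the formula; the bundled `diameter_ge20` fixture
carries the printed counts, and no test targets the printed 14.39.

Display rounding follows the printed convention (two decimals for ORs,
three for AUROCs, half-up); exact values are always retained internally.

## Survival

`km_estimate()` wraps the product-limit estimator
$S(t) = \prod_{t_j \le t}(1 - d_j/n_j)$ (delegated to the standard
survival machinery) in a light curve object; events precede censorings
at tied times, the conventional choice. `survival_at()` evaluates the
right-continuous step function (evaluation beyond the last observed time
returns the last value with an `extrapolated` flag), and
`median_survival()` returns the smallest time with $S(t) \le 0.5$ or
"not reached". Times are days internally — records are day-resolved and
the follow-up cap is 1826 days — with years used only for display.
Five-year summaries are evaluated at exactly 1826 days. Greenwood-based
confidence bounds exist behind `conf = TRUE` and are off by default, as
the reported curves carry none.

## Reproducibility and numerical choices

All randomness flows from one master seed through named sub-streams
(`derive_seed()`), so any stage can be rerun in isolation and two runs
of one configuration produce byte-identical artifacts; `run_pipeline()`
writes a manifest listing every output file with its MD5 checksum and
the seeds used. Degenerate inputs have defined behavior throughout:
constant images fall back to the fixed tissue threshold, slides with no
valid tumor tile refuse a slide score with a clear error, single-class
training splits abort before training, zero-cell tables report
not-estimable, and empty annotations yield empty fronts.

Problem sizes in the test suite were chosen once as the package's
desk-scale study conditions: 8×8 tile grids; 20 slides per class for the
strong-signal recovery run (slide AUROC expected above 0.9) and 50 per
class for the null run (slide AUROC expected within [0.35, 0.65]);
n = 400 per stratum for the five-year Kaplan–Meier recovery of a 0.97
versus 0.40 survival contrast within ±0.05. The published real-data
performance (slide AUROC 0.747, tile AUROCs 0.754–0.814) is *not* a
target anywhere: it is unattainable without the patient WSIs, and the
synthetic recovery/null properties stand in for it.

## Limitations

* Synthetic slides are statistical caricatures; no claim about real-WSI
  classifier performance follows from them.
* The classifier's convolutional stage is a fixed morphometric pooling,
  not a learned trunk; it is the right scale for CPU-bound testing and
  for the texture family the generator produces, and it would need a
  learned feature extractor for real histology.
* Cohort tables emulate marginal, not joint, distributions; RFMs on
  synthetic cohorts therefore have more independent factors than real
  ones. The bundled published counts cover the joint-structure cases.
* Proprietary scanner formats and annotation files are out of scope;
  inputs are generic TIFF/PNG images plus mask images.
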