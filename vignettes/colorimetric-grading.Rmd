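---
title: "Colorimetric grading of herbal medicines: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colorimetric grading of herbal medicines: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbgrade)
```

## The problem

Market quality of many traditional herbal medicines is judged by sensory
characteristics, color above all. For rhubarb (*Rheum* spp.) the chemical
ground truth is the total content of five hydroxyanthraquinone derivatives
(aloe-emodin, rhein, emodin, chrysophanol, physcion), written T~HAQs~ in
mg/g. Three quality grades are defined by thresholds on that total:
grade 1 at T~HAQs~ ≥ 40 mg/g, grade 3 at T~HAQs~ ≤ 25 mg/g, and grade 2
in between (`assign_grade()`; the thresholds are the boundary-inclusive
defaults of `grade_thresholds()`).

`herbgrade` implements the quantitative side of color-based grading:

1. color capture as 8-bit RGB triples from five *color sources* — the
   herb's outside surface, its fracture surface, and its powder, the
   latter two optionally after alkaline color development (the
   Bornträger reaction turns hydroxyanthraquinones red, so developed
   colors carry more chemical signal);
2. a small back-propagation network regressing the grade number on RGB;
3. projection of colors into the CIE 1931 xy chromaticity plane and a
   printable *colorimetric grading scale* read like pH indicator paper.

The packaged reference dataset (`herb_table1()`) has 34 samples with RGB
triples for all five sources and grade labels; `herb_table2()` carries 15
replicate RGB readings of one object under natural light and in a
standard lightbox.

## Measurement reproducibility

Repeatability of the color measurement is summarized per channel by the
relative standard deviation, RSD = 100·s/x̄, with the *sample* (n−1)
standard deviation. The n−1 convention is fixed deliberately: it is the
convention under which the packaged replicate readings reproduce their
reference per-channel RSDs exactly to two decimals (about 10–12% under
natural light versus 1–2% in the lightbox, which is the argument for
standardized lighting). Reported RSDs are rounded half up to 2 decimals,
matching the reference formatting.

```{r}
sapply(herb_table2(), reproducibility_report)
```

`extract_mean_rgb()` standardizes what used to be a manual image-editor
readout: the per-channel arithmetic mean over a rectangular region of
interest, rounded half up to integers. Mean-over-ROI is our choice — the
original readout procedure specified no aggregation rule. Images are
assumed white-balanced; no color correction is applied.

## The grade-prediction network

`bp_config()` / `init_network()` / `bp_train()` implement a fully
connected 3–7–1 feed-forward network: three inputs (R, G, B), one hidden
layer of hyperbolic-tangent units, one linear output regressing the grade
number as a continuous value. Choices that deserve justification:

* **Hidden width 7** is the 2N+1 heuristic for N = 3 inputs and is the
  default; 21 (an alternative reference layer size) is available through
  `n_hidden`.
* **Scalar linear output** rather than three indicator outputs: the grade
  is an ordered quantity, and the binning rule that defines a correct
  prediction (below) is stated on a single continuous value.
* **Standardization** is the z-score (mean 0, sample SD 1) of inputs
  *and* target, with statistics estimated on the training set only and
  stored in the model for prediction and inverse transform
  (`standardize()`).
* **Optimizer**: full-batch gradient descent on the mean squared error
  with momentum 0.9 and an adaptive learning rate starting at 0.05
  (multiplied by 1.05 after an epoch that lowers the error, by 0.7 after
  a rejected uphill step, with the momentum buffer reset on rejection).
  Momentum and the two adaptation factors are the conventional defaults
  of this training scheme; all are configurable. Training stops at a goal
  MSE of 10⁻⁶ (standardized scale) or after 4500 epochs; an unattainable
  goal simply runs to the epoch cap. A non-finite error aborts with the
  offending epoch.
* **Initialization** draws weights uniformly from [−0.5, 0.5] under the
  configuration seed with zero biases — data-independent, so identical
  seeds give identical models. The analytic gradients are property-tested
  against central finite differences.

**Binning.** The continuous output maps to grades through right-closed
intervals: (0.51–1.50] → 1, (1.51–2.50] → 2, (2.51–3.50] → 3; values
below 0.51 or above 3.50 are invalid predictions (always counted as
incorrect). The stated intervals leave 0.01-wide gaps at 1.50–1.51 and
2.50–2.51; `bin_output()` closes them by nearest-integer rounding with
halves down, which agrees with every stated endpoint.

**Experiment harness.** `run_grade_experiment()` trains on the reference
calibration split — 21 listed samples, 7 per grade, drawn from the middle
of each grade's content range — and evaluates the 13 held-out samples and
the full dataset. Only training rows ever reach the trainer (a test
asserts that corrupting held-out labels cannot change any model output).
Because the only stochastic ingredient is the weight initialization, the
harness repeats training over a list of seeds and summarizes with the
*modal* correct count (ties broken toward the count nearest the median,
then the smaller — deterministic). Accuracies are percentages rounded
half up to 1 decimal.

**What the network can and cannot do on the reference data.** The 34
reference samples' grade clusters overlap substantially in RGB space —
the dataset contains near-identical colors with different grade labels in
the training set itself. A network trained to the stated schedule fits
the 21 training samples essentially exactly and, like any interpolator of
overlapping classes, generalizes to the held-out samples much less well;
`scripts/acceptance.R` computes the modal held-out accuracies honestly
from scratch. Early stopping, validation sets and regularization, which
would trade training fit for smoothness, are deliberately out of scope.
On synthetic clusters whose grades actually separate (≥5× the
within-grade spread) the same network recovers held-out labels at ≥95%
in nearly every seed, which is the property-level evidence that the
implementation is sound.

## Chromaticity and the grading scale

`rgb_to_tristimulus()` scales channels by 1/255, optionally applies a
transfer function, and multiplies by a 3×3 RGB→XYZ matrix;
`tristimulus_to_chromaticity()` normalizes to x = X/(X+Y+Z),
y = Y/(X+Y+Z) (so x + y + z = 1 and chromaticity is invariant to
positive scaling, both property-tested). Three conventions ship with
`color_convention()`:

* `srgb_linear` (default): sRGB/D65 primaries, channels treated as
  linear. This is the simplest defensible default; the original study
  cites standard conversion references without naming a matrix, and its
  own expectation-point coordinates are not reproduced by any of the
  three standard conventions here, so the convention is configurable and
  recorded in every scale model rather than hard-coded.
* `srgb_gamma`: same primaries with the sRGB transfer function.
* `cie_rgb`: the CIE 1931 RGB primaries, equal-energy white.

`chromaticity_to_rgb()` inverts the pipeline given a luminance Y,
clipping out-of-gamut colors to the displayable range with a warning and
a `gamut_clipped` flag (card rendering must always produce a color).
In-gamut round trips reproduce the input within ±1 per channel.

**Scale geometry.** `build_scale()` converts the representative samples
of each grade (default: the 16 reference ids, selectable) to
chromaticity, averages them into the per-grade expectation points O₁–O₃
(simple component-wise means — they satisfy the centroid relation below,
which a fitted distribution center need not), and puts the division point
D at the centroid (O₁+O₂+O₃)/3. The approximately-80%-of-maximum-distance
criterion by which the 16 representatives were originally chosen is not
re-implemented as an algorithm; the id list itself is the reproducible
artifact.

`classify_point()` assigns an unknown chromaticity p to the grade whose
ray D→Oᵢ makes the smallest angle with D→p. The source description
("grades distribute away from D in three directions") does not state a
decision rule; minimal angle to the O-rays is the natural formalization
of "direction", it is invariant to the distance of p from D (asserted by
scaling test points along their rays), and a nearest-expectation-point
Euclidean rule is available via `rule = "nearest"`. Ties, including
p = D exactly, break toward the smaller grade number — arbitrary but
deterministic and recorded here. A scale in which two expectation points
coincide with D has no usable directions and errors.

**Rendering.** `render_scale_card()` draws four solid tiles (D, O₁, O₂,
O₃) at the scale's luminance. Chromaticity fixes only (x, y); the
rendering luminance default Y = 0.35 is a mid-tone chosen once for
visual legibility of the brownish-red herb colors and is configurable —
no luminance is derivable from the scale itself.

## The synthetic-data generator

`generate_samples()` draws per-grade RGB clusters: channels independent
Gaussians around configurable per-grade means, truncated to [0, 255] *by
rejection* (clipping would bias means of clusters near the gamut edge),
then rounded to integers; each color source receives an independent draw.
Total-HAQ contents come from per-grade normals truncated to the grade's
threshold band, so labels are consistent with `assign_grade()` by
construction. Defaults — cluster means near the observed
powder-after-coloration centers of the three grades, within-grade SD 8
channel units, 20 samples per grade, HAQ means 45/32.5/18 mg/g with SD
3 — were fixed once as a realistic emulation of the reference material.

What the generator deliberately does *not* emulate: inter-channel
covariance (channels are independent within a grade),
lighting drift, spatial texture within a sample, and, importantly, the
heavy between-grade overlap of the real dataset. Passing recovery tests
on synthetic clusters therefore demonstrates correctness of the
machinery, not field performance on real, overlapping material.

`generate_repeats()` produces replicate readings with Gaussian channel
noise for reproducibility statistics.

## Train/test splitting by content

Besides the canonical reference split, `intermediate_band_split()`
selects training candidates whose T~HAQs~ lies within a relative band
(default ±20%) of the grade's defining threshold(s). The verbal rule it
formalizes is ambiguous; this interpretation — |T~HAQs~ − threshold| ≤
fraction·threshold, with grade 2 tested against both of its thresholds —
is documented as an approximation, is deterministic, and degenerates at
fraction 0 to exactly the threshold values. The reference split remains
canonical for all reference-data work.

## Numerical conventions and problem sizes

* All half-way rounding is half up (R's `round()` is banker's rounding
  and would break agreement with the reference RSD and accuracy
  formatting).
* Model and scale files are JSON written with 17 significant digits, so
  save/load round trips are lossless for doubles.
* Seeded operations save and restore the caller's RNG state.
* Test and acceptance runs use the dataset itself (34 samples), 10–40
  initialization seeds for modal accuracies, 1000-point oracle
  comparisons for the sector classifier, and synthetic sets of 20–25
  samples per grade (1000 per grade only for the distributional CLT
  check) — sizes at which every result above is reproduced in well under
  a minute each.

## Known limitations

* Camera hardware, shooting-condition optimization, wet-lab coloration
  chemistry and chromatographic quantification of the HAQs are out of
  scope; `haq_total` is an input, never measured here.
* The exact RGB→XYZ convention behind the reference expectation-point
  coordinates is unresolved; consequently only the internal centroid
  relation of a scale — not the coordinates themselves — is treated as a
  checkable invariant.
* Held-out accuracy of the network on the real 34-sample dataset is
  limited by genuine label overlap in color space, as discussed above;
  the grading scale inherits the same physical limitation.
* Printed-card color fidelity (printer calibration, Munsell-style
  standards) is a hardware concern outside the package.
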