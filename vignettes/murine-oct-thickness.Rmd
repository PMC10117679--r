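---
title: "Quantifying murine retinal thickness from OCT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying murine retinal thickness from OCT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octnorm)
library(dplyr)
```

## The problem

Spectral-domain OCT of the mouse eye produces volumes of 512 B-scans, each
of 512 A-scans with 1024 axial samples spanning a 1.4 mm imaging depth
(1.3672 µm per sample). From such a volume one wants, per retinal
layer, an en-face thickness map; quality-controlled region-of-interest
summaries; a normative database stratified by group, age and eye; and a
statistical account of how thickness differs between groups and evolves
with age. `octnorm` implements that chain for the eight standard murine
layers/aggregates — RNFL-GCL, IPL, INL, OPL, ONL, ILS, OLS, RPE — plus the
total retinal thickness (TRT), defined as the distance from the
vitreous–RNFL interface to the RPE–choroid interface, so that TRT is
exactly the sum of the eight layer thicknesses.

Because OCT volumes of living animals cannot ship with a package, every
stage is validated against a synthetic phantom whose ground truth is known
by construction. The phantom is a first-class, tested module, not a
fixture: its defaults are calibrated so that the grid-mean thickness of
every layer reproduces the bundled normative reference table
(`reference_thickness()`) at each tabulated age.

## The phantom model

An A-scan at en-face position (row $r$, column $c$; row 0 superior,
column 0 temporal in right-eye convention) has layer-$k$ thickness

$$ t_k(r, c) = \mathrm{base}_k(\text{age}) +
   g_k\left(\tfrac{r}{n_r - 1} - \tfrac12\right) +
   a_k\left(\tfrac12 - \tfrac{c}{n_c - 1}\right) +
   \eta_k + \varepsilon, $$

floored at 1 µm, where

* $\mathrm{base}_k$ interpolates the reference table piecewise-linearly
  through its seven ages (1, 2, 3, 4, 8, 12, 16 months) and is constant
  beyond them — the table reports discrete ages, not a functional form;
* $g_k$ is the superior→inferior gradient (the imaged area sits directly
  above the optic disc, which lies inferior; total-retina default 8 µm,
  split across layers proportionally to base thickness);
* $a_k$ is the temporal–nasal asymmetry (temporal thicker; total-retina
  default 4 µm). Both spatial terms are centred so the grid mean of every
  layer equals its age-trend value — this is what makes the calibration
  targets exact;
* $\eta_k \sim N(0, \sigma_k^2)$ is one per-(animal, layer) effect,
  persistent across ages and shared by both eyes, with $\sigma_k$ the
  per-layer mean of the reference SD columns — the simplest structure that
  supports repeated-measures analyses;
* $\varepsilon$ is white per-A-scan jitter (default SD 0.3 µm). The
  reference data say nothing about within-volume spatial covariance, so no
  claim of device fidelity is made here: fields are smooth plus white
  noise.

Rendering assigns each axial sample the mean reflectivity of the structure
it falls in (vitreous, eight layers, sub-RPE; adjacent reflectivities must
differ by a configurable contrast margin) and multiplies by unit-mean gamma
speckle, the standard surrogate for coherent-imaging noise. The default
shape parameter 9 (intensity CV ≈ 0.33) represents a frame-averaged
acquisition; fully developed speckle (shape 1) can be requested. Left eyes
are rendered mirrored along the A-scan axis, so the downstream left-eye
mirroring rule acts on geometry that genuinely needs it. No vessel
shadows, motion artifacts, or physical light propagation are modelled —
passing tests demonstrate correctness of the measurement chain, not
robustness to every artifact of real acquisitions.

```{r phantom}
ph <- generate_phantom(phantom_spec("WT"), dims = c(35, 35, 256), seed = 1)
ph$volume
```

## Segmentation and the monotone projection

Per-sample classification uses a compact fully convolutional
encoder–decoder: two encoder levels of 3×3 convolution + ReLU + 2×2 max
pooling, a bottleneck, and a mirrored decoder with nearest-neighbour
upsampling and skip concatenations, ending in a 1×1 classification layer
over ten classes (vitreous, eight layers, sub-RPE — the two background
classes give boundary extraction explicit above/below context). The input
has two channels: per-image standardised intensity and the normalised
axial depth coordinate. The coordinate channel conditions the problem —
layers are depth-ordered bands — and, together with
inverse-√frequency class weighting of the softmax cross-entropy (thin
layers such as ILS and OLS are otherwise drowned out), lets desk-scale
training (32 downscaled 256×128 B-scans, 10 epochs, Adam at 5·10⁻³)
converge on a single CPU in about two minutes. Training is exactly
reproducible from `unet_config(seed =)`; the backward pass is verified
against finite differences in the test suite.

A per-sample classifier knows nothing about anatomy, so its argmax labels
can violate layer ordering. The projection step restores it: per A-scan,
find integer cuts $0 \le c_0 \le \dots \le c_8 \le n$ maximising the
number of samples whose class agrees with the monotone labelling the cuts
induce. A dynamic program over (class, position) solves this exactly in
$O(n \times \text{classes})$; ties are broken toward the
lexicographically smallest cut vector, which both fixes determinism and
pushes ambiguous boundaries upward consistently. The suite proves the DP
equal to exhaustive search over all monotone cut vectors on hundreds of
small random instances. Boundaries sit at integer cuts; sub-sample
refinement is deliberately out of scope, and the quality-control step
below accounts for the resulting quantisation.

The `oracle_classmap()` path — the ideal labelling induced by ground-truth
boundaries — lets every downstream stage be tested independently of
network quality. Its labelling rule (sample $s$ has class $k$ iff
$b_k \le s < b_{k+1}$) has the exact inverse $c_k = \lceil b_k \rceil$,
so oracle-driven recovery is accurate to better than one axial sample
pointwise and to a fraction of a sample in grid means.

## Thickness, quality control, blocks

Layer thickness is boundary separation times 1.3672 µm/sample; TRT is
$b_8 - b_0$, which telescopes to the layer sum exactly. A-scans whose
boundaries cross are invalidated, never reported as negative thickness.

Three A-scan exclusion criteria mirror standard segmentation QC. Their
exact published formulations are not available, so the following surrogates
are declared and parameterised in `qc_params()`:

1. **Contrast** (`w = 3` samples, `c_min = 0.05`): Michelson-style
   contrast $|\bar I_\text{below} - \bar I_\text{above}| /
   (\bar I_\text{below} + \bar I_\text{above} + \epsilon)$ across each
   boundary must reach `c_min`; a flat (corrupted) A-scan fails at any
   positive threshold.
2. **Consistency** (`J = 15` samples): no boundary may jump more than `J`
   against its four neighbouring A-scans.
3. **Distribution** (`z_star = 4`): each layer's thickness must lie within
   `z_star` robust z-scores of the volume-wide median, with scale
   1.4826·MAD. The MAD is floored at one axial sample (1.3672 µm):
   integer cuts quantise thickness, and on clean low-variance volumes the
   raw MAD collapses to zero, which would flag quantisation noise as
   outliers. The floor is the measurement resolution, nothing more.

Left-eye maps are mirrored (columns reversed) so the left half of every
map is temporal. The 512×512 grid is cropped by its one-pixel frame — the
unique symmetric crop to 510×510 — and partitioned into nine 170×170
blocks, B1 (superior-temporal) to B9 (inferior-nasal), row-major. A block
is discarded when *strictly more than* 10% of its A-scans failed QC; the
comparison is done on integer counts, so a block at exactly 2890 of 28900
excluded is retained and 2891 is not. We read the 10% rule as applying to
the block's own A-scans (the alternative — 10% of the volume — would make
single-block exclusion almost unreachable). The whole-area summary
averages all retained A-scans of the cropped grid regardless of block
retention.

## Normative database and abnormality

`build_normative()` aggregates per-volume block summaries into one entry
per group × age × eye × layer × region, with mean and SD taken **across
volumes**, never across A-scans, and the raw per-volume values retained.
Eyes are kept separate by default (whole-area reference tables pool them;
`pool_eyes = TRUE` reproduces that convention). Kernel density summaries
use a Gaussian kernel with Silverman's rule and a minimum-bandwidth guard;
quartiles always come from the empirical values, not the smoothed curve.

A subject's block value is scored as $z = (x - \mu)/\sigma$ against its
matched entry with two-sided Gaussian tail probability
$p = 2(1 - \Phi(|z|))$, flagged below a chosen $\alpha$. The Gaussian
choice reflects that the overwhelming majority of observed thickness
distributions pass normality testing; a nonparametric percentile mode
(rank among the normative raw values) is available where that assumption
is unwanted. Blocks without a usable entry (missing cell, $n < 2$, zero
SD) are reported not-evaluable rather than silently unflagged. Under the
null the empirical flag rate matches $\alpha$ within binomial error — the
suite checks this at $n = 1000$.

Longitudinal block maps are displayed after per-layer min–max
normalisation over all (block, age) cells jointly; the convention (also
recorded in the database metadata) makes layers with very different
absolute thickness comparable on one colour scale, and maps a constant
layer to 0.5.

## The statistical battery

* **Normality gating** uses a Lilliefors-style statistic — the KS distance
  with estimated mean and SD — referred to a seeded Monte-Carlo null
  (m = 2000, cached per sample size), with the 10% gating convention.
  Estimated parameters invalidate the textbook KS null; the Monte-Carlo
  reference restores calibration and is exactly reproducible.
* **Two-group comparisons**: Welch's t-test when both samples pass the
  gate, otherwise Mann–Whitney U (exact below n = 21, normal approximation
  with tie and continuity correction above). Welch rather than pooled
  variance is the default because group SDs genuinely differ; a pooled
  option exists. Bonferroni correction uses m = 8 for the eight per-layer
  comparisons at each age; TRT is its own single-test family.
  `welch_from_summary()` applies the identical formulas to printed
  mean/SD/n triples.
* **Longitudinal analyses** operate on complete cases only (subjects
  measured at every requested age, `complete_cases()`). One-way
  repeated-measures ANOVA (subject blocking, within-subject F) is fitted
  via `aov(value ~ time + Error(subject))`, with Friedman's rank test
  substituted when any time point fails the gate; the suite checks the F
  statistic against a hand-computed sums-of-squares decomposition. No
  sphericity correction is applied by default. The two-way mixed design
  tests the between-subject group effect against subject-within-group
  error and time and group×time within subjects.
* **Post-hoc**: Tukey–Kramer on the repeated-measures error term,
  $q = |m_i - m_j| / \sqrt{MS_\text{error}/n}$ against the studentized
  range distribution; at two time points this reduces exactly to the
  paired comparison ($q = \sqrt2\,|t|$).

All routes are calibration-tested: empirical type-I error within two
binomial standard errors of nominal at 500 null replicates, and
Tukey–Kramer family-wise error at most 0.07 at $\alpha = 0.05$.

## Problem sizes and numerical choices

The package's own test and demonstration sizes are chosen to keep a
single-CPU run comfortable while preserving every structural property of
the full geometry: 35×35×256 phantoms for pipeline and QC tests (the
en-face grid must be $3k + 2$ so the framed crop splits into 3×3 blocks),
128×128×512 for parameter-recovery checks, and 256×128 B-scans for
desk-scale network training. Full-size 512×512×1024 volumes work
identically and are the `oct_volume` default.

Other numerical conventions: 0-based, half-open index ranges throughout;
B-scan stacking follows lexicographic filename order (acquisition order is
not recorded in the TIFF export, and a fixed convention makes runs
reproducible); volume metadata travels in YAML sidecars rather than TIFF
tags (tag dialects are not portable); every stochastic stage takes an
explicit seed and restores the caller's RNG state; CSV outputs are
byte-identical across reruns of the same configuration.

## Known limitations

The phantom's geometry is deliberately simple — linear spatial trends, no
curvature of the retinal surface, no vessels, no motion. The QC formulas
are surrogates with exposed parameters, not reconstructions of any
device's internal rules. The network is trained and evaluated on synthetic
data only; no transfer to real scanner output is claimed. Abnormality
probabilities inherit the Gaussian assumption of the normative entries
unless the percentile mode is chosen, and entries built from fewer than
two volumes are never used for scoring.
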