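---
title: "From shadowgraph frames to driver attribution: the eddyscape pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From shadowgraph frames to driver attribution: the eddyscape pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eddyscape)
```

## The problem

Towed shadowgraph line-scan imagers photograph tens to hundreds of litres of
water per second while undulating through the upper ocean, producing millions
of grayscale frames per transect. Turning that imagery into ecology takes a
chain of steps: finding organisms in frames, post-processing the output of an
automated classifier into trustworthy counts, converting counts into
volume-normalised concentrations on a regular transect grid, delineating the
water masses the transect crossed, and finally asking which physical and
biological drivers structure a taxon's distribution. `eddyscape` implements
that chain for the canonical study design of a plankton-imaging transect
crossing a mesoscale eddy embedded in a fast boundary current, together with
a synthetic-data module that generates every input with known ground truth so
the whole pipeline can be validated end to end.

## Segmentation

Line-scan geometry makes the illumination a function of the cross-scan
(column) position only, so flat-fielding divides each pixel by a per-column
background profile (`background_profile()`, `flat_field()`); the profile is a
running mean over a window of frames (default 100, causally if requested).
A frame equal to its background maps to all ones, and organisms — dark on a
bright background by shadowgraph convention — fall below one.

Foreground detection clusters the flat-fielded intensities with k-harmonic
means (`khm_cluster()`). The KHM objective

$$\mathrm{KHM}(X, C) = \sum_i \frac{k}{\sum_j \lVert x_i - c_j\rVert^{-p}}$$

replaces k-means' hard minimum with a harmonic mean, which down-weights
points already close to some centre and boosts poorly fitted ones, making
the optimum far less sensitive to initialisation. We use the standard
harmonic weighted centre recursion with two numerical safeguards worth
recording:

* distances are factored as $d_{ij} = d^{\min}_i r_{ij}$ with $r_{ij} \ge 1$,
  so the per-point weights $\left(d^{\min}_i\right)^{p-2} r_{ij}^{-p-2} /
  (\sum_l r_{il}^{-p})^2$ stay finite; computing $d^{-p-2}$ directly
  overflows catastrophically when a point coincides with a centre, whereas
  the factored form shows the weight actually *vanishes* there (for
  $p > 2$);
* an update that would increase the objective is rejected and iteration
  stops, so the reported objective sequence is non-increasing by
  construction;
* default initial centres are spread across the full data range. With all
  centres inside one dense intensity mode (the typical situation for a
  mostly background frame) the batch update oscillates between the mode and
  the dark tail; range-spread initialisation avoids this.

Defaults are $k = 2$ (foreground/background) and $p = 3.5$, a common
literature value for the harmonic power. Clustering is intensity-only.
The darkest cluster's pixels are labelled 8-connected (`detect_rois()`),
and components of at least `min_area_px = 25` pixels become ROIs — at a
66 µm pixel pitch that is roughly a third of a millimetre of organism,
below which vignettes carry no identifiable morphology. Frames whose two
centres differ by less than 0.05 in normalised intensity are declared
featureless rather than segmented, which keeps uniform frames from emitting
noise components.

## Classifier post-processing

The classifier is out of scope; `eddyscape` consumes its output: one
predicted fine class and a probability vector per vignette. Fine classes
(e.g. 124 morphotypes) are mapped onto broader ecological groups (e.g. 40)
with `map_to_groups()`. From true/predicted group labels, `group_metrics()`
computes per-group true positives, false positives and false negatives, and

$$P = \frac{TP}{TP+FP},\qquad R = \frac{TP}{TP+FN},\qquad
F_1 = \frac{2PR}{P+R}.$$

Filtered vignettes (`"unknown"`) count as false negatives for their true
group and as false positives nowhere. Weighted averages weight groups by
their true-label support; groups that received no predictions have undefined
precision and are excluded from the weighted means.

`fit_thresholds()` raises a per-fine-class confidence cut-off until the
class's broad group reaches a target precision (default 0.90): over a
threshold grid (step 0.01) the precision of the kept set is recomputed, the
precision-versus-threshold curve is smoothed by local regression
(span 0.5), and the threshold is the smallest grid point whose smoothed
precision reaches the target. The response variable is the precision of the
*kept* set at each cut — the natural estimand for "what do I trust after
filtering". Classes whose curve never reaches the target are unattainable:
their threshold is set to their largest observed confidence so that strict
filtering (`max_prob > t` keeps; `apply_thresholds()`) removes all of them.
Classes with fewer than 20 predicted test vignettes inherit their group's
pooled curve — a per-class curve fit to a handful of points is noise.

Counts are corrected by $CF = P/R$ (`correction_factors()`): multiplying a
predicted count by precision removes the false-positive share, dividing by
recall restores the missed share, so in expectation the corrected count
equals the true count when the confusion structure is homogeneous across
the transect. That identity holds *with the metrics computed on the
filtered test set*, which is how the package computes them, and it is what
the abundance-recovery test checks (corrected counts within 5% of truth at
$n = 10^5$). The worked example from the metrics table — precision 88.2%
and recall 41.2% give $F_1 = 56.2\%$ and $CF = 2.14$ — is reproduced in the
test suite and the acceptance script.

## Concentrations and kriging

`bin_vignettes()` accumulates counts per broad group in half-open 1-m depth
strata crossed with along-track cells (default 500 m), and converts tow
residence time to imaged volume at `volume_rate = 0.168` m³/s, inside the
150–185 L/s envelope of the instrument class. Bins visited by the tow but
empty of detections are kept with zero counts — absence is data.
`to_concentration()` divides by imaged volume and applies the correction
factor; uncorrectable groups (zero recall) pass through flagged.

Gridding uses ordinary kriging (`krige_field()`) under a variogram fitted
by weighted least squares with Cressie weights on a 15-bin empirical
semivariogram (`fit_variogram()`; spherical by default). Transect geometry
is extremely anisotropic (kilometres by metres), so both fitting and
kriging scale coordinates by the target resolutions (along-track / 500 m,
depth / 1 m) and use a single isotropic model in scaled space. The kriging
system is solved once in covariance form with the unbiasedness constraint;
weights sum to one at every node (checked to 1e-8 in tests), prediction at
a datum is exact when the nugget is zero, and duplicate data locations are
averaged before solving because they make the system singular. A singular
system is retried once with a jittered diagonal. Negative concentration
predictions can be clipped to zero with the clip count reported.

## Water masses

`uv_to_speed_dir()` converts zonal/meridional velocity to speed and a
flow-toward bearing (0° = north, 90° = east) — the oceanographic
convention, deliberately not the flow-from convention of wind tooling,
because "northward flowing water" should mean direction 0.
`cluster_water_masses()` runs k-means on standardized $(\lvert u\rvert,
\lvert v\rvert, \mathrm{speed})$ with 25 restarts and a fixed seed; the
number of clusters comes from the elbow (maximum second difference) of the
total within-cluster sum of squares over $k = 2\ldots8$, overridable to the
three-water-mass setting. Clusters are named by speed rank: slowest = eddy
(ED), fastest = boundary current (FC), intermediate = interface (IF). We
cluster magnitudes rather than signed components because rotation reverses
the sign of the velocity across an eddy core while leaving the regime the
same; a signed mode is available behind a flag. `distance_to_fc()` is the
minimum Euclidean distance to any FC cell in (km, km) coordinates — the
vertical term is retained but negligible. `mixed_layer_depth()` applies the
density-threshold criterion (default 0.125 kg/m³ against a 5-m reference,
matching tows that start a few metres down) with linear interpolation to
the crossing; `anomaly()` removes the along-track mean per depth level.

## Driver attribution

`compare_water_masses()` runs a one-way ANOVA per taxon on raw
concentrations (a log1p option exists behind a flag) and, where significant
at 0.05, Tukey HSD pairwise comparisons with family-wise adjusted p-values.
`fit_rf()` grows a 500-tree random-forest regression with 14 candidate
predictors per split — the same settings for every model so that fits with
different predictor sets remain comparable — and reports out-of-bag
variance explained ($1 - \mathrm{MSE}_{OOB}/\mathrm{Var}(y)$) plus both
importance measures (permutation MSE increase, node-purity gain). The
water-mass factor is handled natively by the tree backend, so its
importance needs no summing over indicator columns.

`compute_ale()` implements accumulated local effects. For a continuous
predictor the observed range is cut at quantile boundaries into 20 bins;
within each bin the prediction difference between the predictor at the
bin's upper versus lower boundary (other columns untouched) is averaged,
differences are accumulated, and the curve is centred so its data-weighted
mean is zero. Because only within-bin differences enter, the curve is not
inflated by correlated covariates — the package's tests verify the defining
decorrelation property on strongly correlated pairs and the closed form
$\mathrm{ALE}(x) = 3x - 1.5$ for $f = 3x_1$ on $U(0,1)$. Categorical
predictors are ordered by similarity of their covariate distributions
(summed Kolmogorov–Smirnov distances embedded to one dimension by classical
MDS), consecutive-level effects are accumulated along that ordering, and
the curve is centred by level frequencies. Empty bins contribute a zero
local difference, which is equivalent to merging them with the neighbour
below.

`ablate_predictor()` refits the forest without one predictor under
identical settings and seed and reports the change in out-of-bag variance
explained. This is the package's probe for prey coupling: if a prey field
carries information beyond the shared physics, ablating it costs variance
explained; if prey and predator merely respond to the same physical
drivers, the delta is near zero.

## What the synthetic generators emulate — and what they do not

The synthetic module defines the study conditions for every test:

* **Frames** (`gen_frames()`): dark soft-edged ellipses on a bright
  background with a smooth multiplicative illumination field and Gaussian
  noise. Blobs are placed without overlap — organisms in the thin imaged
  slab occupy distinct positions — and the recorded truth box bounds the
  ellipse itself (the soft-edge margin is only a placement buffer). Default
  scenes use 160×240 px frames, a Poisson mean of 5 organisms per frame,
  contrasts 0.4–0.5 and noise sd 0.02. Not emulated: out-of-focus halos,
  overlapping or touching organisms, streak artefacts, real morphology.
  Detection scores on these fixtures therefore certify the clustering and
  labelling machinery, not performance on real imagery.
* **Classifier output** (`gen_classified_vignettes()`): true classes drawn
  from specified abundances, predictions from a row-stochastic confusion
  matrix, and top-1 confidence from two Beta laws — Beta(9, 2) (mode ≈ 0.89)
  when correct, Beta(4, 3) (mode 0.6) when wrong. Nothing is published
  about the real classifier's confidence shape; the Beta model is an
  assumption chosen once to make threshold filtering informative but not
  trivial, and it is flagged as such here. Confidence is clamped just above
  $1/K$ so a probability vector with the remaining mass spread evenly has
  its argmax at the prediction.
* **Transect scenario** (`gen_transect()`): a 40 km × 80 m section at
  500 m × 1 m resolution crossing an 8-km-radius eddy (rim speed 0.25 m/s,
  solid-body interior) centred 14 km along, inside a 0.8 m/s northward
  boundary current, with a 4-km interface band per side whose speed plateau
  is the midpoint of the two regimes; smooth blends are confined to 5% of
  the band at each edge so each labelled regime is internally homogeneous —
  the construction for "three well-separated flow regimes" that the
  clustering-recovery tests assume. Water masses are vertically coherent;
  hydrography is a linear stratification plus an isopycnal-shoaling bump at
  the interface. Taxa respond additively on the log scale to water mass,
  speed and distance-to-FC, with an optional prey-coupling term
  (default 0.5 from larval fish to their copepod prey) and lognormal noise
  (sd 0.3). Not emulated: eddy asymmetry, vertical shear, diel migration,
  advective patchiness beyond the response functions.

Problem sizes in the tests and the acceptance script — $10^5$ vignettes for
the filtering and abundance checks, 30 frames for detection, the full
6400-cell scenario for water masses, and 2000-cell subsamples for the
forest fits (five seeds for the null-ablation average) — were chosen as the
smallest sizes at which the binomial and Monte-Carlo error of each check is
comfortably below its tolerance.

## Numerical choices and degenerate inputs

* KHM: safeguarded descent, range-spread initialisation, degenerate
  (single-valued) input returns one effective centre with the rest `NA`.
* Variogram: constant fields return a zero-sill model flagged `"constant"`;
  near-pure-nugget fits are flagged `"weak_structure"`.
* Kriging: duplicate locations averaged; singular systems jittered once.
* Thresholds: strict inequality at the cut (a confidence exactly equal to
  the threshold is filtered); unattainable classes keep nothing.
* Distance-to-FC with no FC cells: all-`NA`, flagged, with a warning.
* MLD: threshold never exceeded returns the deepest sampled depth, flagged;
  a zero threshold returns the reference depth.
* `uv_to_speed_dir(0, 0)`: speed 0, direction reported 0 and flagged.
* All generators draw every random quantity from the seed stored in their
  spec, so identical specs give bit-identical output.

## Known limitations

Thresholds and correction factors are estimated once from a test set and
applied globally; if the confusion structure drifts along a transect the
corrected counts are biased, and nothing in the package detects that. The
kriging neighbourhood is global, which is exact but scales cubically with
the number of bins; very long transects should be kriged in blocks. The
elbow rule for choosing $k$ is a heuristic — for the three-regime eddy
design, fixing $k = 3$ is the better-posed choice. ALE curves are defined
on the observed range only and say nothing about extrapolation. And all
recovery results certify the pipeline against its own generative
assumptions; they are evidence of correct implementation, not of field
performance.
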