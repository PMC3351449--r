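---
title: "Quantifying aberrant dorsal axon outgrowth with axonquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aberrant dorsal axon outgrowth with axonquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonquant)
```

## The measurement

Anterior dorsal telencephalic (ADt) neurons of the zebrafish forebrain
normally extend axons ventrally into the anterior commissure and the
supraoptic tract. Perturbations of guidance signaling (e.g. morpholino
knockdown of the netrin receptor Dcc) cause some of these neurons to send
processes dorsally instead. `axonquant` quantifies this aberrant dorsal
outgrowth from multi-channel confocal z-stacks of labeled neurons.

The core statistic is deliberately simple and rank-friendly: the **sum of
pixel intensities over adaptively thresholded axon pixels** in a
soma-masked maximum-intensity z-projection of the labeled channel.
Formally, for projection $P$ (8-bit gray), soma mask $M$ and index map

$$ I(y,x) = \mathbf{1}\!\left[(y,x) \notin M \;\wedge\;
   P(y,x) > \bar{P}_{w}(y,x) + c\right], $$

where $\bar{P}_{w}$ is the local mean over an odd $w \times w$ window
computed over unmasked pixels only, the score is
$S = \sum_{y,x} I(y,x)\, P(y,x)$ (in ADU). Scores are then binned into
ordinal phenotypic grades:

| Grade | score (ADU) |
|-------|-------------|
| 0 | below 5,000 |
| 1 | 5,000 – 24,999 |
| 2 | 25,000 – 44,999 |
| 3 | 45,000 and above |

A score falling exactly on a boundary is promoted to the higher grade; the
verbal scheme ("less than" / "greater than") leaves exact equality open and
a deterministic convention is required. Group severity is summarized by the
average phenotypic score (a.p.s., the mean grade, in $[0,3]$), the grade
distribution, and penetrance (percent of embryos with grade $\ge 1$).

## Pipeline stages and their parameters

`quantify_embryo()` composes the full chain
`select_channel` → `max_project_z` → `crop` → `apply_soma_mask` →
`adaptive_threshold` → `score_projection`:

* **Projection** — per-column maximum over z. Projections are rescaled to
  8-bit gray by default so that the grade boundaries refer to a fixed
  intensity scale; `rescale_8bit = FALSE` keeps the native depth.
* **Crop** — a half-open, 0-based rectangle confining scoring to the
  dorsal region containing the aberrant axons. Cropping replaces the
  interactive step of the original procedure with a config-supplied
  rectangle; it is optional, but without it bright ventral tracts inflate
  every score by a large common offset.
* **Soma mask** — masked pixels are zeroed *and* excluded from the local
  neighborhood statistics. Excluding them from the statistics matters:
  a zeroed soma would otherwise depress local means around its rim and
  create a halo of spuriously indexed pixels. `auto_soma_mask()` replaces
  manual masking deterministically: pixels above an intensity quantile
  (default 0.99) are labeled; components of at least `min_area` px
  (default 50) are kept, optionally only if compact
  ($4A/\pi d^2 \ge$ `compactness_min`, with $d$ the bounding-box diagonal
  — about 0.5 for a disc, near 0 for a tube), then dilated by 3 px.
* **Adaptive threshold** — local mean + offset with an odd square window.
  Defaults: `window = 25` px, `offset = 10` ADU on the 8-bit scale. The
  window must be large relative to the axon diameter (a few px after PSF
  blur) so that the local mean tracks background, and the offset must sit
  above the background noise amplitude (Poisson + read noise of a few ADU)
  while staying below axonal signal. Borders use reflective padding. Both
  parameters are exposed everywhere; the local-mean form is the canonical
  adaptive method and the one all oracle tests certify.

Low-severity caveat: when axon intensity approaches `offset`, threshold
truncation of the blurred tube's tails biases the score low (the package's
own tests observe roughly −5% at mid severities and up to about −20% for
signal barely above the offset). This does not disturb the ordinal grading,
which is the statistic used for inference.

## Statistics

* **Mann–Whitney U, exact and tie-aware** (`mann_whitney_exact()`): U from
  mid-ranks; for $n_1+n_2 \le 20$ the two-tailed p is computed from the
  complete permutation distribution of U over all
  $\binom{n_1+n_2}{n_1}$ group assignments of the observed values, with
  $p = P(|U - n_1 n_2/2| \ge |U_{obs} - n_1 n_2/2|)$ — the appropriate
  exact treatment for heavily tied ordinal grades. Beyond the limit a
  tie-corrected normal approximation with continuity correction takes
  over; the report records which path ran. Tests operate on grades by
  default (rank-based conclusions are then independent of the particular
  score matrix), but any numeric severity values can be passed.
* **ANOVA on replicate penetrances** (`anova_penetrance()`): fixed-effects
  one-way ANOVA across treatment groups of per-injection-replicate
  penetrance percentages, with Tukey HSD post hoc. Replicate penetrances
  are treated as exchangeable observations; no mixed-effects modeling of
  the replicate structure is attempted.
* **Penetrance** defaults to grade $\ge 1$ (score $\ge$ 5,000) as the
  operational definition of "developed aberrant dorsal axons"; the rule is
  a parameter. Dose–response curves report per-dose mean ± SD across
  replicates; a dose observed in a single replicate reports a missing SD,
  never zero.

## Single-neuron origin and trajectory calls

For mosaically labeled single neurons, calls consume traced geometry only
(JSON polylines and soma contours; automated tracing is out of scope):

* the soma's dorsoventral extent is taken over the union of all slices'
  soma pixels, and the midline is its midpoint;
* the emergence point's normalized DV position $u \in [0,1]$ (0 = dorsal
  pole) gives the origin call, with a **middle band** of the central 10% of
  the extent (`middle_band = 0.1`) operationalizing "close to the middle"
  — the boundary is not quantified in the field's descriptions, so the
  band is explicit and reported with results;
* a process is a **dorsal trajectory** when its distal endpoint ends more
  than `dead_zone = 5` px dorsal of the soma midline (the dead zone
  absorbs jitter for near-lateral processes; within it the call defaults
  to ventral);
* processes shorter than 10 px are rejected as untraceable, and emergence
  points farther than 1.5 px from the soma boundary are rejected as
  inconsistent annotations.

`flip_dv()` mirrors stacks, projections, traces and simulator configs
along the DV axis; origin and trajectory calls swap dorsal↔ventral under
the flip (middle is fixed), which the test suite exercises as an
invariant.

## The synthetic stack generator

Because no original imaging data are redistributable, every stage is
validated against `sim_config()` / `render_embryo()` /
`render_single_neuron()`, which emulate the study's image classes:

* a cluster of soma spheres in the dorsal half of a frontal-view frame
  (default six somata of radius 3 px, peak 180 ADU, jittered within a
  9 px cluster — jitter is drawn once at config construction so geometric
  transforms act on it);
* two ventrally projecting tracts (commissure/tract analogs) as
  constant-intensity discs swept along polylines;
* an optional aberrant dorsal process whose **target integrated projected
  mass** (ADU) is the severity knob. The tube is rendered at unit
  intensity, PSF-blurred, projected, and scaled linearly so its projected
  mass outside the dilated soma footprint equals the target exactly —
  ground truth is exact by construction up to bit-depth clipping (defaults
  keep peaks below 255, verified up to ~60,000 ADU of mass);
* anisotropic Gaussian PSF (default $\sigma$ = 1.2, 1.2, 1 px in y, x, z)
  and a camera model of Poisson shot noise plus additive Gaussian read
  noise (sd 2 ADU) over a 5 ADU background, applied after ground truth is
  extracted from the noise-free scene.

Defaults are chosen so the severity knob sweeps all four grades on 8-bit
projections of a 128×128×12 stack. Single neurons are rendered as one
sphere with 1–4 straight radial processes at specified perimeter angles
(0° = dorsal pole); emergence sites closer along the perimeter than the
tube width are rejected.

The generator reproduces the *geometry and photon statistics* that the
pipeline is sensitive to. It does **not** attempt optical realism: no
depth-dependent attenuation, no spectral bleed-through, no refractive
aberrations, no autofluorescence texture, and processes are piecewise
straight rather than tortuous. Passing tests therefore certify the
algorithmic chain (projection, masking, thresholding, scoring, grading,
statistics) and its ground-truth recovery under a controlled noise model —
not performance on any particular microscope's data, where mask and
threshold parameters may need adjustment.

## Numerical choices

* Reflective (edge-duplicating) padding for all windowed operations.
* 0-based half-open crop rectangles; 1-based voxel indices inside R.
* Stacks are `(y, x, z[, channel])` arrays (column-major R layout; TIFF
  pages are z-slices, channel-major, declared in a JSON sidecar).
* One master seed per embryo; geometry and noise use deterministically
  derived sub-streams, so identical configs re-render bit-identically and
  cohort CSVs are byte-stable.
* Degenerate inputs fail loudly: empty volumes, even or oversized
  threshold windows, out-of-volume geometry, single-pixel somata, empty
  groups, single-replicate SDs.

## Validation problem sizes

The shipped test suite certifies: the grading worked examples; loop-oracle
equivalence of projection, thresholding and scoring on hundreds of random
instances up to 32×32; exact Mann–Whitney agreement with a pair-counting
enumeration oracle on 500 random tied ordinal datasets with
$n_1+n_2 \le 10$; the $F = t^2$ identity on 100 random two-group datasets;
ground-truth recovery on a 40-embryo cohort spanning the four severity
classes (Spearman ≥ 0.9 between score and true dorsal mass, strictly
increasing mean a.p.s.); ≥ 90% Mann–Whitney rejection over 200 simulated
control-vs-severe cohorts of n = 40 per group; and DV-flip symmetry of
origin/trajectory calls on 100 seeded single-neuron renders.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(dorsal_process = list(mass = 30000, path = NULL,
                                        width = 7), seed = 42)
r <- render_embryo(cfg)
mask <- r$truth$soma_mask_proj
mask[48:128, ] <- TRUE            # exclude the ventral half (normal tracts)
sc <- quantify_embryo(r$stack, mask = mask, embryo_id = "demo")
sc
assign_grade(sc$score)
```

## Known limitations

* The metric is a 2D projected intensity sum: no 3D tracing,
  skeletonization or branch analysis, and no registration across embryos.
* Scores depend on the acquisition intensity scale; the grade boundaries
  presume 8-bit projections, so native-depth scoring needs re-calibrated
  boundaries.
* Severely saturated stacks violate the linearity that ground-truth
  scaling and scoring rely on.
* Single-neuron calls depend on supplied traces; annotation errors
  propagate directly.
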