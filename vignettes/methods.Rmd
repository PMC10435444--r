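---
title: "Methods: on-the-go NIR estimation of grapevine stem water potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: on-the-go NIR estimation of grapevine stem water potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vinespec` models the complete measurement chain of vehicle-based NIR
assessment of vine water status: a spectrometer looking sideways into the
canopy while the vehicle drives the rows, a live similarity filter that
keeps only leaf-like frames, block-averaged reflectance paired with
pressure-chamber stem water potential (Ψs), a PLS calibration, and a
classed map of the plot. This vignette is the package's own account of the
science in each stage: the models, their assumptions, the tunable
parameters, the numerical choices, and what the synthetic data can and
cannot establish.

```{r setup}
library(vinespec)
```

## The synthetic campaign and what it emulates

No field data ship with the package; the generator produces campaigns with
the statistical structure the analysis assumes.

**Leaf optics.** A leaf reflectance spectrum is a smooth baseline carved by
Gaussian absorption bands in a Beer–Lambert-style exponential:

$$R(\lambda) = B(\lambda)\, \exp\!\Big(-\textstyle\sum_k A_k
  e^{-(\lambda-\mu_k)^2 / 2\sigma_k^2}\Big),$$

with water bands at μ = 978, 1454 and 1935 nm (the O–H second overtone,
first overtone, and combination region) whose amplitudes grow linearly
with leaf water content W, and weak fixed dry-matter bands at 1720 and
2100 nm. W links linearly to the stem water potential, W = w0 + w1·Ψs
(defaults w0 = 0.85, w1 = 0.25 MPa⁻¹, chosen so W spans roughly 0.3–0.8
over the campaign's Ψs range); no leaf water-content data exist to fit
this link, so it is a configurable modelling assumption. Band widths and
amplitudes were fixed at design time so that two structural properties
hold: water absorption dominates the spectrum (dry-matter amplitudes an
order of magnitude below the 1454/1935 bands, as in fresh leaves), and —
because derivative preprocessing relocates regression importance to band
*flanks*, roughly 1.5σ from the center — the 1454 nm band uses σ = 25 nm
so its flanks stay inside the 1404–1504 nm neighborhood of the band.
This is deliberately not a radiative-transfer model (no PROSPECT-style
leaf structure): the pipeline only needs a monotone, band-localized water
signal plus removable scatter.

**Scatter and noise.** Each frame receives multiplicative/additive scatter
a·R + b with a ~ U[0.9, 1.1], b ~ U[−0.02, 0.02] — the artifact SNV
exists to remove — and i.i.d. Gaussian channel noise (default sd 0.005
reflectance units, a moderate leaf-level SNR for a moving platform).

**Interference.** Between vines the sensor sees sky gaps, wood, trellis
wire, irrigation pipe, or berries (frame-wise leaf probability defaults to
0.7). Each class is a stylized template with the material's own NIR
structure — atmospheric water-vapour bands for the open path, a
lignin/cellulose feature for wood, polyethylene C–H bands for pipe, a weak
specular return for wire. Purely flat templates would *not* be rejected by
a cosine filter (two smooth positive spectra correlate above 0.99), which
is itself informative: the 0.985 threshold only works because non-leaf
materials have distinctive absorption structure. Every generated
interference frame is certified at generation time to have cosine
similarity below 0.985 against leaf spectra spanning the Ψs range, with up
to five jittered retries before an error.

**Trial design.** The default layout is 12 rectangular blocks (15 vines per
traversed row, 1.2 m vine and 2.6 m row spacing) with irrigation
treatments T0/T1/T2 cycled across blocks. Ψs is drawn per (date,
treatment): date means follow a six-date dry-down from −1.13 to −1.82 MPa
with per-date SD 0.15 MPa, treatments offset ±0.15 MPa around the date
mean, all values clamped to [−2.2, −0.05] MPa. Three marked vines per
block (one per 5-vine group) yield 36 references per date, 216 per
campaign; a 9-block layout yields 27 per date. The number of dates is a
parameter. The vehicle moves at 3 km/h; frames arrive at the sensor rate
(12.5 Hz for the 118-channel micro-spectrometer, the default device) and a
20 Hz GPS track accompanies each pass.

**What passing tests do not show.** The generator has no canopy geometry,
no illumination drift, no temperature effects on band shape, no spatial
autocorrelation of Ψs within a block beyond the shared block draw, and its
Ψs–spectrum link is exact by construction. Green tests therefore establish
that the *pipeline* is correct and self-consistent — filtering separates
what it should, preprocessing removes what it claims, the regression and
its validation are leak-free — not that a real vineyard would yield the
same error statistics. On this synthetic link the cross-validated errors
(≈0.05 MPa) are optimistic relative to any field campaign.

## Acquisition and filtering

Reflectance calibration is the standard two-point form
R = (S − D)/(W − D) per channel; a channel where white equals dark is a
hard error naming the channels. Values outside [0, 1] (noise at the
calibration edges) are kept, not clipped — SNV is scale-invariant and
clipping would only distort. The workflow is a strict state machine (dark
→ white → signature → measure) mirroring the field software's button
sequence; each step records the mean of the five largest channel values as
a live sanity statistic.

Frames are paired with the nearest-in-time GPS fix within 0.5 s (the
12.5–14 Hz sensors against a 20 Hz receiver make the nearest fix
unambiguous); a frame without a fix inside the tolerance is flagged
unlocated but still filtered. Filtering is cosine similarity on calibrated
reflectance against the single-leaf signature, acceptance at ≥ threshold
with the boundary accepted (the equality case is not specified by the
field tools; accepting it is this package's documented choice, and it is
tested). The default threshold 0.985 is the value used in the field
deployments. Accepted frames are allocated to blocks by point-in-polygon
(even–odd rule) and averaged channel-wise; the block-mean spectrum is
paired with each of the block's three marked-vine references, so the
sample unit is (block-mean spectrum, vine-group Ψs) — 36 samples per date
on the 12-block layout, matching the reference counts of the trial design.
Pairing the block mean with the block-mean Ψs instead (12 samples per
date) is the main alternative reading of the protocol; the per-group
pairing was adopted because the trial's stated sample counts require it.

## Preprocessing

SNV is per-spectrum centering and scaling with the sample (n−1) standard
deviation; a zero-variance spectrum is an error. The Savitzky–Golay
operator is a least-squares local polynomial fit per channel; derivatives
are scaled by the channel spacing (units per nm). Edge channels refit the
polynomial on the truncated window, so output length equals input length —
keeping the wavelength grid stable for regression-vector and VIP indexing,
at the cost of noisier first/last channels (visible as edge artifacts in
VIP profiles; tests exclude the outermost channels from localization
assertions). Stencils are computed by QR on a scaled abscissa, which stays
well conditioned up to saturated polynomial orders. Defaults: window 15
channels for dense grids (≥ 300 channels; ≈30 nm at 2 nm spacing), window
7 otherwise (≈57 nm at 8.2 nm); polynomial order 2, first derivative. The
default order is SNV then derivative; the reverse is selectable
(`preproc_config(steps = c("savgol", "snv"))`). Which exact settings
produced the original field models is not recoverable; these defaults
smooth comparable wavelength neighborhoods on both grids. All steps are
per-spectrum (no training statistics), so the identical code path runs at
calibration and prediction time, with the recipe serialized inside the
model.

## PLS, model selection, and validation

PLS1 by NIPALS (single response; SIMPLS and multivariate-Y PLS2 are out of
scope): columns of X and y are mean-centered, then for each latent
variable a the weight w_a = X'y/‖X'y‖, score t_a = Xw_a, loadings
q_a = t_a'y/t_a't_a and p_a = X't_a/t_a't_a, with rank-one deflation of
both X and y. The regression vector is b = W(P'W)⁻¹q. If deflation
exhausts the correlation between X and y before the requested number of
components, the model is returned with fewer components and a warning (a
constant response collapses to the null model predicting the mean).
Scores are mutually orthogonal (tested at 1e−8) and the full-complexity
model on tall full-rank X equals the least-squares solution (tested
against the normal equations).

**Cross-validation.** Ten-fold venetian blinds: sample i joins fold
(i − 1) mod 10 + 1 in stored dataset order (date-major, block-minor — the
conventional interleaved split for serially ordered chemometric data).
Preprocessing and centering are recomputed inside each training fold;
a permutation check (shuffling y drives R²cv to ≈ 0) guards against
leakage. The retained complexity is the *first local minimum* of RMSECV:
the smallest A with RMSECV(A) < RMSECV(A+1), ties advancing, a monotone
curve selecting the scan limit. This deliberately prefers fewer latent
variables than the absolute minimum, as overfitting protection. The scan
limit defaults to 20 and is truncated to what every fold's rank supports.

**VIP.** VIP_j = √(p · Σ_a SSY_a (w_ja/‖w_a‖)² / Σ_a SSY_a) with
SSY_a = q_a²·t_a't_a the response sum of squares explained by dimension a.
The mean of squared scores is exactly 1, so VIP > 1 flags influential
wavelengths. On campaign models the influential channels sit on the flanks
of the 1454 nm water band — the derivative preprocessing moves importance
from band centers to flanks, which is the expected signature of a
band-localized water signal.

**External validation.** Seven samples per date are drawn (reproducibly
under a seed) into a held-out prediction set, *excluding* each date's
maximum and minimum Ψs so outliers stay in calibration; over six 36-sample
dates this reserves 42 of 216 samples, about 20%. Metrics are
R² = 1 − SSE/SST about the evaluation-set mean (squared Pearson
correlation is also reported, since chemometrics software varies) and
RMSE in MPa.

## Mapping

Point predictions (or references) are interpolated by a thin-plate spline:
kernel r²·log r plus an affine part, solved from the bordered system; the
smoothing parameter λ ≥ 0 ridges the kernel block, with λ = 0 giving exact
interpolation (and an informative singularity error for
collinear/duplicate points). TPS reproduces constants and planes exactly,
which anchors the surface's behaviour between data points. The proprietary
"empirical spline" of commercial GIS tools is not publicly specified; the
thin-plate spline is this package's documented stand-in with the same
qualitative behaviour. Longitude/latitude are projected to a local metric
plane about the plot centroid before distances are computed (TPS needs
metric distances; plot extents are far below where earth curvature
matters). The grid cell defaults to 2 m — below the 2.6 m row spacing, so
row-level structure stays visible — and cells beyond one row spacing
outside the convex hull of the points are masked. Classification uses at
most five zones (decision-support granularity), by quantiles (near-equal
cell counts) or equal intervals, ordered from most to least negative; maps
are compared cell-wise by Pearson r, RMSD and the fraction of cells in the
same class. Class agreement on five quantile zones is a deliberately harsh
statistic — adjacent-class swaps near break values count as disagreement
even when the surfaces correlate above 0.9.

## Problem sizes, determinism, and reproduction

The packaged analyses and tests run the study-scale campaign — 6 dates ×
12 blocks × 3 references (n = 216) on the 118-channel grid, about 3 000
frames per pass — which keeps a full simulate–filter–train–validate–map
cycle in the tens of seconds on one core; structural tests use a 3-block,
3-date layout. Every random stage takes an explicit integer seed
(campaigns derive per-pass seeds from it), and identical seeds reproduce
campaigns, models and serialized artifacts bit for bit.
`scripts/acceptance.R` regenerates the campaign from scratch, fits the
cross-validated model (at most 16 latent variables) and writes the mean of
squared VIP scores — the analytically fixed normalization constant of the
VIP definition — as its machine-checkable output.

## Known limitations

* The Ψs–spectrum link is a two-parameter linear stand-in; real leaves
  saturate and hysterese.
* Interference templates are stylized material spectra validated against
  the cosine threshold, not measured libraries.
* The first-local-minimum rule is sensitive to RMSECV jitter at low
  complexity; a one-standard-error rule would be more conservative but is
  not what the field workflow used.
* Thin-plate interpolation is exact but global; strongly anisotropic
  within-row variation would call for kriging with a fitted variogram,
  which is out of scope.
* The per-group sample pairing triples the block-mean spectrum per date;
  venetian folds therefore often place near-replicates in different folds,
  and RMSECV is correspondingly optimistic on synthetic data.
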