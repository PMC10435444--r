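# vinespec

On-the-go NIR chemometrics for grapevine water status.

Deficit irrigation in viticulture needs frequent, spatially resolved
knowledge of vine water status, but the reference measurement — stem water
potential (Ψs, MPa) with a Schölander pressure chamber — is destructive and
slow. `vinespec` implements, as a tested and reusable R pipeline, the
alternative: a vehicle-mounted NIR spectrometer driven along the rows at
3 km/h, whose reflectance stream is screened against a single-leaf spectral
signature, averaged per replication block, and regressed on
pressure-chamber references to give a calibration that predicts Ψs and maps
it across the plot. The package is aimed at plant-phenotyping and precision
viticulture researchers who want to study this workflow end to end without
field hardware: every input is produced by a synthetic campaign generator
with the statistical structure the analysis assumes.

## What is inside

* **Synthetic campaign generator** — two virtual spectrometers (1100–2100 nm
  / 2 nm / 501 channels / 14 Hz, and 900–1860 nm / 8.2 nm / 118 channels /
  12.5 Hz), Beer–Lambert-style leaf spectra whose water bands at 978, 1454
  and 1935 nm deepen with leaf water content linked linearly to Ψs,
  non-leaf interference frames (canopy gaps, wood, wire, irrigation pipe,
  berries), a blocked T0/T1/T2 irrigation trial drying down over six dates
  with per-date Ψs distributions, and 20 Hz RTK GPS tracks.
* **Acquisition replay** — the field software's strict workflow: dark
  reference → white reference → leaf signature → streaming measurement,
  with two-point reflectance calibration `R = (S − D)/(W − D)`, the
  top-5-channel sanity statistic, GPS pairing, and live cosine filtering.
* **Filtering** — cosine similarity against the leaf signature at the field
  threshold 0.985, point-in-polygon block allocation, per-block averaging.
* **Preprocessing** — standard normal variate and Savitzky–Golay
  derivatives (least-squares local polynomials, per-nm scaling,
  truncated-window edges).
* **Chemometrics** — PLS1 by NIPALS written from scratch: ten-fold
  venetian-blind cross-validation, the first-local-minimum rule for the
  number of latent variables, VIP wavelength importance
  (`mean(VIP²) = 1`, influential if VIP > 1), an external validation split
  that reserves seven non-extreme samples per date (~20% of the data), and
  R²c/R²cv/R²p, RMSEC/RMSECV/RMSEP metrics.
* **Mapping** — thin-plate-spline interpolation of predicted and reference
  Ψs into plot surfaces, classified into at most five irrigation zones,
  with map-to-map agreement reports and GeoJSON export.

The model core is the usual chemometrics regression: with centered spectra
X and response y, NIPALS extracts successive latent variables
(w_a ∝ X'y, t_a = X w_a, deflation by t_a p_a'), giving the regression
vector b = W(P'W)⁻¹q; wavelength importance is
VIP_j = √( p · Σ_a SSY_a (w_ja/‖w_a‖)² / Σ_a SSY_a ) with
SSY_a = q_a² t_a't_a.

## Worked example

```r
library(vinespec)

camp    <- simulate_campaign(field_layout(), water_status_model(),
                             scene_mix(), sensor2(), rng_seed = 42)
samples <- build_samples(camp)      # acquisition replay + cosine filter
m       <- psi_model(samples)       # SNV + SG 1st derivative, PLS1, CV
summary(m)
```

```
<campaign: 6 dates x 12 blocks, 216 psi references>
<psi samples: n=216, 118 channels, 6 dates, psi -2.20..-0.63 MPa>
Stem water potential calibration
<preprocessing: snv -> savgol (window=auto, polyorder=2, deriv=1)>
  n = 216, LV = 5 (first local RMSECV minimum)
  R2c  = 0.978   RMSEC  = 0.049 MPa
  R2cv = 0.971   RMSECV = 0.055 MPa
  influential wavelengths (VIP > 1): 32
  top VIP wavelengths:
 wavelength_nm  vip
          1490 3.01
          1499 2.91
          1417 2.71
```

216 samples are 6 dates × 12 blocks × 3 marked vines. Cross-validated
error of 0.055 MPa is small against the campaign's Ψs span (−2.2 to
−0.6 MPa), and the influential wavelengths cluster on the flanks of the
1454 nm O–H water band — the model is reading water, not an artifact.

External validation and mapping:

```r
sp  <- external_split(samples, rng_seed = 49)  # 7 per date, extremes held in
val <- evaluate_model(psi_model(sp$train), sp$validation)
# R2p = 0.971, RMSEP = 0.057 MPa (n = 42)

maps <- map_campaign_date(m, samples, "2021-09-15")
maps$agreement
# $r 0.94   $rmsd 0.05 MPa   $class_agreement 0.62 (five quantile zones)
```

`run_pipeline(seed = 1, out_dir = "runs/demo")` chains everything and
writes stream files, the reference CSV, a manifest, the serialized model
(JSON), predictions and the two GeoJSON maps. A thin command-line wrapper
lives at `inst/cli/vinespec.R`.

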