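---
title: "Dual-band NIR calibration of meat quality traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-band NIR calibration of meat quality traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirstew)
```

## The problem

Ready-to-eat stewed meat products vary widely in fat, protein, collagen,
ash and sodium content, and the wet-chemistry reference methods
(solvent extraction, Kjeldahl-type digestion, muffle-furnace ashing) are
slow and destructive. Near-infrared reflectance spectroscopy offers a
rapid, non-destructive alternative: C–H, O–H and N–H overtone and
combination bands in the 650–1660 nm region carry compositional
information that a multivariate calibration can exploit. `nirstew`
implements the full calibration workflow for two instrument bands — a
visible/NIR band trimmed to 650–950 nm (0.35 nm pitch) and an NIR band
trimmed to 960–1660 nm (3.6 nm pitch) — together with a synthetic
spectra generator that reproduces the statistical structure of such a
study, so that every stage of the pipeline can be validated end to end
without access to proprietary spectra.

## Partial least squares regression

The core model is single-response PLSR fitted by NIPALS. With the
calibration spectra `X` (n × p) and a trait vector `y` mean-centred,
each latent variable takes

* weight `w = X'y / ||X'y||`,
* score `t = X w`,
* x-loading `p = X't / t't`, y-loading `q = y't / t't`,

after which `X` and `y` are deflated by `t p'` and `q t`. After `A`
components the regression vector is assembled as
`beta = W (P'W)^{-1} q` and folded back to the raw scale with an
intercept, so prediction is a single affine map. The implementation is
a small C++ core (via RcppArmadillo): a leave-one-out curve over 15
candidate component counts for a 97 × 857 matrix refits the model 97
times, and the wavelength-selection chain below needs on the order of
two thousand such curves per run. The test suite pins the core against
independent routes: ordinary least squares at full rank, an R-language
NIPALS re-implementation, simple linear regression in the univariate
case, and a brute-force double-loop cross-validation oracle.

Only mean-centring is applied to `X` — no autoscaling — which is the
dominant convention for spectral data, where the variance pattern
across wavelengths is itself informative. The LV count is chosen by
leave-one-out cross-validation: centring is recomputed inside every
fold, and the optimum is the global RMSECV minimum with ties broken
toward fewer components. All preprocessing operators in the package act
on one spectrum at a time, so applying them before the fold loop is
exactly equivalent to applying them inside it; no refitting flag is
needed.

## Preprocessing

Five options are screened, as is routine for diffuse-reflectance data:

* **none** — raw reflectance. Spectra are modelled in the stored
  intensity units throughout; no `log(1/R)` transform is applied
  anywhere in the pipeline.
* **SNV** — per spectrum, subtract the mean and divide by the n−1
  standard deviation. This removes exactly the per-sample positive
  affine (multiplicative scatter + offset) corruption, a property the
  tests assert directly.
* **SNVD** — SNV followed by a second-degree polynomial detrend in
  wavelength, removing residual baseline curvature.
* **Der1 / Der2** — first and second Savitzky–Golay derivatives with a
  second-order polynomial in a 15-point window. Derivatives are scaled
  by the physical pitch (per nm), making the two bands' derivative
  magnitudes comparable. `(window−1)/2 = 7` points are dropped at each
  edge rather than extrapolated: fabricating edge values would inject
  model assumptions into the most extrapolation-sensitive region.

## Wavelength selection

Two complementary selectors reduce the full grid to a handful of
wavelengths suitable for a multi-spectral instrument:

* **Regression-coefficient extrema (RC).** Interior peaks and valleys
  of the `beta` curve are located sign-aware, ranked by `|beta|`, and
  the top `nSel` retained. The default request sizes are 7 (fat) and 8
  (other traits).
* **Random frog (RF).** A reversible-jump MCMC-style chain over
  variable subsets: candidate subset sizes are proposed from
  `Normal(q, theta·q)`; shrink moves keep the largest-`|beta|` members,
  grow moves sample `omega` times the deficit from outside and keep the
  top candidates by `|beta|`; acceptance compares LOOCV RMSECV, with
  worse candidates accepted at probability `eta` times the RMSECV
  ratio. Selection probability is the fraction of the `N = 1000`
  iterations in which a wavelength sat in the accepted subset. Defaults
  `qInit = 10`, `theta = 0.3`, `omega = 3`, `eta = 0.1` follow common
  practice for the published algorithm; the submodel LV count is chosen
  by the submodel's own LOOCV capped at 5, which keeps a thousand
  iterations at interactive speed without letting large subsets
  overfit.

Selection operates on the calibration rows only; the prediction set is
never consulted until final evaluation, and a dedicated test corrupts
the prediction spectra and asserts that every calibration-side choice
is unchanged.

## Evaluation

Models are summarised by Pearson correlation and RMSE in calibration
(R~c~, RMSEC), cross-validation (R~cv~, RMSECV) and prediction (R~p~,
RMSEP), plus RPD = SD(prediction-set reference) / RMSEP. RPD below 1.5
marks an inadequate model, 2.5 or more a good one, and 5 or more
analytical quality. The pipeline's gate advances a trait to wavelength
selection only when its best full-spectrum model reaches RPD ≥ 1.5.
"Best" is judged by minimum RMSECV on the calibration set — not by
prediction-set performance, which would leak the held-out data into
model selection.

## The synthetic study design

Because the original spectra are not deposited, the generator is a
first-class module that emulates the study conditions: 97 samples split
70/27, trait distributions with calibration-set means/SDs/ranges of
(fat 51.2 ± 33.2 g/kg on [16.5, 162.5], protein 256.2 ± 56.4,
collagen 26.1 ± 18.6, ash 28.0 ± 5.3, Na 8.5 ± 2.4), an ash–Na
correlation of 0.77 and a collagen–protein correlation of 0.35.

Two numerical choices deserve note:

* **Moment-matched truncation.** Clipping a `Normal(51.2, 33.2²)` draw
  to the fat range would shift the sample mean upward by about
  9 g/kg, because the lower bound sits at z ≈ −1.05. The generator
  instead solves for the underlying normal parameters whose
  *truncated* law has the requested mean, weighting the mean equation
  heavily. For fat, the truncated-normal family cannot reach the full
  requested SD on that range (the achievable maximum at this mean is
  ≈ 31.5 g/kg), so the realised fat SD is about 5% below its nominal
  value while the mean is matched; all other traits match both
  moments.
* **Correlated children.** Collagen and Na are affine functions of
  protein and ash respectively plus Gaussian noise, clipped to their
  ranges; the slope and noise SD are set from the target correlation.

Spectra are rendered as a Beer–Lambert-style linear mixture of
Gaussian absorption bands: water at 771, 979 and 1450 nm, fat at 813
and 1220 nm, protein at 872, 1020, 1180, 1423 and 1510 nm, and
collagen sharing the protein positions at 40% amplitude. The water
concentration is a mass balance (1000 g/kg minus the organics), so the
water bands dominate the 979 and 1450 nm regions and carry an
anti-correlated image of total organic content. Ash and Na contribute
no absorption at all — inorganic ions are NIR-silent — so any apparent
predictivity for them can only come through their correlations with
the organic traits. Band widths (18–45 nm) are broad NIR overtone
widths; the sub-950 nm bands are an order of magnitude weaker than
their NIR counterparts, as higher overtones are.

On top of the clean mixture each sample receives multiplicative
scatter (gain ~ `Normal(1, 0.08)`), an additive offset (SD 0.03),
linear and quadratic baseline drift about the band centre, and white
channel noise with SD 0.05 — drawn independently for the two
instruments. These levels were fixed once so that the full-spectrum
NIR models land in a realistic quality regime (R~p~ roughly 0.93–0.99
for fat and protein across seeds, |R~p~| ≤ 0.3 for Na, collagen RPD
near 1) while the RPD ≥ 1.5 gate retains exactly fat and protein — the
qualitative pattern a real dual-band meat study shows. What the
synthetic design does **not** emulate: instrument line shape, detector
nonlinearity, temperature-dependent water band shifts, sample
heterogeneity between probe positions, and reference-method error in
the trait values. Passing the end-to-end tests therefore demonstrates
that the pipeline recovers structure it is designed to recover — not
that any particular real instrument will achieve these numbers.

## Problem sizes and tolerances

The shipped tests run the complete study design (two bands, five
preprocessings, five traits, LOOCV up to 15 LVs) on the 97-sample
fixture, 25-replicate random-frog recovery experiments at p = 100 and
p = 195 with N = 1000 iterations, and 50-run coefficient-extrema
recovery simulations — a few minutes in total. Exact linear-algebra
identities are asserted at 1e-8 to 1e-12; Savitzky–Golay
finite-difference oracles at 1e-6 on smooth test signals (widths ≥
120 nm, where the window-scale truncation error sits below that
bound); Monte-Carlo quantities at the tolerances their sampling noise
supports. Degenerate inputs (zero-variance spectra, rank-deficient
folds, empty trims, off-grid selections) raise errors naming the
offending sample or wavelength; rank-deficient LOOCV curves are
truncated with a warning rather than silently padded.

## Known limitations

* PLS1 only: each trait is modelled separately (no multi-response
  PLS2), matching the study design.
* The random-frog acceptance rule uses the damped-ratio heuristic of
  the published algorithm, not a formally detailed-balance-correct
  kernel; its output is a ranking heuristic, not a posterior.
* Report tables round to three decimals (one for CV%), so re-reading a
  written report loses precision relative to the in-memory objects.
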