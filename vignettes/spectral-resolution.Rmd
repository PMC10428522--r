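---
title: "Resolving severely overlapping binary spectra: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving severely overlapping binary spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specres)
```

## The problem

Triclabendazole (TCB) and levamisole HCl (LVM) are co-formulated
anthelmintics whose UV absorption spectra overlap almost completely below
280 nm: LVM has a single band near 214 nm, TCB a stronger band at 220 nm
and a weaker one at 304 nm. Direct absorbance reads on a mixture are
therefore useless below ~280 nm. What rescues the analysis is that TCB's
304 nm band *extends* into a region (roughly 290--306 nm on zero-order
spectra, 280--315 nm on first derivatives) where LVM contributes nothing.
`specres` implements nine mathematical-filtration routes that exploit this
asymmetry to quantify both drugs from one mixture scan, without
separation.

All routes are compositions of a small operator algebra on sampled
spectra: pointwise combination, division, first derivative,
normalization, factorization, amplitude reads and plateau extraction
(`sp_combine()`, `sp_divide()`, `sp_derivative()`, `sp_normalize()`,
`sp_factorize()`, `read_response()`, `plateau_constant()`).

## The central identity

Under Beer--Lambert linearity a binary mixture spectrum is

$$ M(\lambda) = c_X\,a_X(\lambda) + c_Y\,a_Y(\lambda), $$

with $a$ the per-unit (1 µg/mL) absorptivity curves and $Y$ the extended
component. Dividing by a pure divisor spectrum $c'\,a_Y(\lambda)$ gives

$$ \frac{M(\lambda)}{c' a_Y(\lambda)} = \frac{c_Y}{c'}
   + \frac{c_X}{c'}\,\frac{a_X(\lambda)}{a_Y(\lambda)}. $$

In the extended region $a_X \approx 0$, so the ratio is flat and equals
the concentration ratio $c_Y/c'$ — the *plateau constant* $k$. Every
route is one way of cashing in this identity:

* **RS-SS** (ratio subtraction + spectrum subtraction): subtract $k$ from
  the ratio spectrum, multiply back by the divisor; what remains is the
  non-extended component. Subtracting that from the mixture returns the
  extended one.
* **CM-SS** (constant multiplication): $k \times$ divisor reconstructs
  the extended component directly; subtraction yields the other.
* **FC-SS** (factorized spectrum): no divisor at all — read the mixture
  at a wavelength where only the extended component absorbs (304 nm) and
  multiply with the pure spectrum pre-scaled to read 1 there.
* **DS-SS, D¹CM-SS, D¹FC-SS**: the same three algorithms applied verbatim
  to first-derivative spectra, where the usable extended window widens to
  280--315 nm and the factorization reference moves to 310 nm.
* **DD¹** (derivative of ratio spectra): divide by a pure spectrum of
  *either* component and derivatize; the divisor component's contribution
  becomes a constant and vanishes, leaving an amplitude proportional to
  the other component alone (read at P 230--220 nm for TCB over a
  4.0 µg/mL LVM divisor, at 219 nm for LVM over a 3.0 µg/mL TCB divisor).
* **CV / CNV** (constant value / concentration value): divide by the
  *normalized* (per 1 µg/mL) extended spectrum. The plateau then equals
  the concentration itself; CV maps it through a regression fitted the
  same way from standards (essentially the identity line), CNV reads it
  directly.

Because all operators are linear, the six spectrum-subtraction routes
satisfy `resolved_X + resolved_Y = mixture` *by construction*; the test
suite asserts this to 1e-10 as a regression guard rather than as a
scientific claim.

## What the synthetic generator emulates — and what it does not

No instrument spectra ship with the package. `component_model()` builds
Gaussian-band Beer--Lambert models; `default_models()` fixes

* TCB-like: bands at 220 nm (σ = 9 nm, 0.1322 AU·mL/µg) and 304 nm
  (σ = 10 nm, 0.0533 AU·mL/µg);
* LVM-like: one band at 214 nm (σ = 8 nm, 0.0834 AU·mL/µg).

The heights are the per-unit responses of the real pair at those maxima,
so noiseless calibration slopes reproduce them exactly. The widths are
not reported anywhere; 8--10 nm was chosen once so that the 214/220 nm
bands overlap severely while the 214 nm band decays below 1e-6 AU·mL/µg
beyond 285 nm, keeping the extended region clean by construction (a
Gaussian at 285 nm is 71/8 ≈ 8.9 σ from its center). They are
config-exposed, not tuned.

Real spectra are not Gaussian: they have asymmetric bands, baseline
drift, stray light and wavelength-registration error, none of which the
generator models. Passing the exactness tests therefore shows that the
*algebra* is implemented correctly and self-consistently — it does not
certify accuracy on any particular instrument. That is the role of the
recovery/precision/t/F/ANOVA machinery, which operates on whatever
results you feed it.

Noise, when requested, is i.i.d. Gaussian per grid point (default 0.002 AU, a
typical photometric noise figure), added to mixture
scans only; calibration standards are treated as noiseless averages
unless a noise level is passed to `build_calibrations()`.

## Numerical choices

* **Grid.** 200--400 nm at 0.5 nm (`default_grid()`): the usual benchtop
  UV scan range for this assay, at a common sampling interval. All binary operators require a shared grid;
  `sp_resample()` (linear interpolation, no extrapolation) brings spectra
  onto one.
* **Derivative.** Δλ = 4 nm window, presentation scale 10 — the
  conventional settings for this assay. Vendor kernels vary; `sp_derivative()` uses the
  Savitzky--Golay quadratic first derivative over the ±2 nm window, which
  is exact on straight lines, antisymmetric (so a symmetric band's
  derivative crosses zero at its center), and has lower noise gain than a
  bare two-point difference. The output loses half a window at each end.
* **Division guard.** Points where the divisor magnitude is below 1e-4 AU
  are masked, carried with the spectrum, and refuse amplitude reads;
  plateau extraction simply skips them (at least 3 clean points are
  required). The D¹ TCB divisor, for instance, is exactly zero at 304 nm
  (band center) — one masked point inside the 280--315 nm plateau, which
  the mean ignores.
* **Plateau flatness.** The plateau RSD is reported with the constant; it
  warns above 2% instead of failing, because drifting plateaus are a fact
  of life on real spectra and the user should see the number, not lose
  the result. At near-zero plateau means (no extended component) the RSD
  is meaningless and the warning is expected.
* **Wavelength reads.** On-grid wavelengths (every read point of the bundled
  configuration, on the default grid) are read exactly; off-grid requests are
  linearly interpolated between unmasked neighbours.
* **LOD/LOQ.** The package adopts the ICH/VICH residual form LOD = 3.3 s/|slope|, LOQ = 10 s/|slope| with s
  the residual SD (or a supplied blank SD). On noiseless synthetic data
  both collapse to ~0.
* **CV regression.** The "regression at 304 nm" is read as the
  plateau-amplitude-versus-concentration line built from standards
  divided by the normalized divisor (its slope is ~1 on ideal data), with 304 nm labelling the analyte band
  rather than a second amplitude read. Under this reading CV and CNV
  must agree, which the tests assert to 0.5%.
* **Below-LOD results** are flagged, never clipped.

## Calibration ranges and the study layout

Default calibration series follow the assay's linearity ranges: TCB
2--20 µg/mL for the 304/310 nm-class reads, DD¹ and CV; 1--10 µg/mL for
the more sensitive 220 and P 228--216 nm reads; LVM 2--14 µg/mL. The
specificity grid (`table_ratio_grid()`) uses the five TCB:LVM ratios
2:3, 3:4, 1:1, 4.5:2.5 and 4:2.5 (the dosage-form ratio), scaled by 2
into those ranges. `run_study()` runs every requested route over the
grid with `replicates = 3` per cell (the usual n = 3 ± SD reporting
convention), and the problem sizes throughout the tests — 100 noise
replicates at the 1:1 point, 1000 replicates for the noise-bias check —
were chosen to make Monte-Carlo error comfortably smaller than the
quantities asserted while keeping a full run in seconds.

## Greenness scoring

Three rubrics are implemented exactly as far as their rules are public:
NEMI's four quadrant flags; the Analytical Eco-Scale (penalty points:
amount class × pictogram count × signal-word multiplier per reagent,
instrument energy 0/1/2, vapour emission 3, waste amount 0/1/3/5 plus
treatment 0/1/3; score = 100 − ΣPP, excellent > 75, acceptable > 50);
and AGREE as a weighted mean of twelve [0, 1] principle scores reported
to two decimals. The GAPI pictogram and the RGB/whiteness spreadsheet
are *not* implemented: their published outputs are colors and a single
total without a reproducible rubric, and inventing one would be worse
than omitting it. AGREE's twelve per-principle inputs are likewise
user-supplied — the package does not guess hazard data.

## Known limitations

* Binary mixtures only; no extended-ratio-subtraction or constant-center
  variants for three-component systems.
* First derivatives only (the nine routes need nothing higher).
* The Gaussian generator is a surrogate: conclusions about real TCB/LVM
  formulations require instrument spectra, loaded via
  `read_spectrum_csv()` and processed with the same functions.
* The factorized routes assume zero interferent response at the
  reference wavelength; `resolve_fc_ss()` can quantify the bias when
  handed the interferent spectrum (it is exactly the leaked amplitude
  over the per-unit response), but it cannot detect leakage from the
  mixture alone.
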