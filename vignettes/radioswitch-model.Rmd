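---
title: "The radioswitch model: radiolytic dosimetry and activation kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The radioswitch model: radiolytic dosimetry and activation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radioswitch)
```

## The system being modelled

Azobenzene photoswitches flip between a thermodynamically stable *trans*
form and a metastable *cis* form. Attaching a gadolinium chelate turns the
switch into a *radioswitch*: clinically relevant doses of ionising radiation
(gamma rays, X-rays, electron beams — all low-LET) convert the *cis* isomer
to *trans* not by direct photon absorption but through the hydroxyl radicals
(HO•) produced by water radiolysis. This package implements that causal
chain quantitatively:

1. **Dose → HO•.** A dose $D$ (Gy = J/kg) produces hydroxyl radicals at a
   radiochemical yield $G(\mathrm{HO}^\bullet)$, expressed either in
   µmol/J or in molecules per 100 eV of absorbed energy. The two units
   differ by the exact factor $10^6/(100\,e\,N_A) \approx 0.10364$
   (CODATA constants, not the rounded "100 eV ≈ 1.60·10⁻¹⁷ J", since the
   rounded value changes nothing at the reported precision).
2. **Conditions modify HO•.** The effective yield is
   $$G_\mathrm{eff} = G_\mathrm{base}\times f_\mathrm{gas}\times
   (1 + E(c_\mathrm{Gd})),$$
   where $f_\mathrm{gas}=2$ under N₂O saturation (hydrated electrons are
   converted into additional HO•), $f_\mathrm{gas}=1$ otherwise (N₂ only
   strips oxygen and is modelled as a no-op), and $E(c)$ is the fractional
   enhancement contributed by Gd³⁺ ions.
3. **HO• → isomerisation.** The *trans* fraction follows a monoexponential
   approach to complete conversion in cumulative dose:
   $$\theta(D) = 1 - (1-\theta_0)\,e^{-k_\mathrm{eff} D},\qquad
   k_\mathrm{eff} = k \,\frac{G_\mathrm{eff}}{G_\mathrm{ref}}.$$
   The linear scaling of $k_\mathrm{eff}$ with $G_\mathrm{eff}$ is the
   package's central modelling assumption; it is what makes "equivalent
   dose" constructions work (dose under N₂O ≡ twice the dose in water) and
   it is exactly the invariance the property tests exercise.
4. **Dark reversal.** Between measurements the *cis* isomer relaxes
   thermally with first-order kinetics and half-life $t_{1/2}$
   (default 2.3 h at 37 °C). Both the forward model and the paired-plate
   estimator account for it.

## Baseline parameters and their defaults

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `g_ho_base` (GR / XR / E) | 0.280 / 0.200 / 0.280 | µmol/J | homogeneous bulk G(HO•) ~10⁻⁷ s after energy deposition |
| `k_act_per_Gy` | 0.21 | Gy⁻¹ | activation constant at the reference yield |
| `reference_g_ho` | 0.280 | µmol/J | yield at which `k_act_per_Gy` is defined |
| `pss1_cis_fraction` | 0.90 | — | cis content of the UV photostationary state |
| `thermal_half_life_h` | 2.3 | h | dark cis→trans half-life at 37 °C |
| `efficiency_a`, `efficiency_b` | −0.036, 0.1304 | G-value/µM | logarithmic dose-efficiency model |
| coumarin `conversion_yield` | 0.031 | — | fraction of coumarin + HO• events giving 7-OH-coumarin |

The XR baseline is lower than GR/E because 1–100 keV photons deposit energy
in denser spurs, where more HO• recombines before diffusing into the bulk;
the package stores the measured bulk yields and does not model spur
chemistry (that is an explicit non-goal).

## The Gd³⁺ enhancement curve

Only two points of the enhancement curve are hard measurements: a +33%
maximum at 200 µM for the X-ray source and a +20% maximum at 500 µM for the
gamma source. The qualitative shape — rise over 10–200 µM, plateau over
25–500 µM, decline towards 2000 µM — is known but not tabulated. The
package therefore represents the curve as *data*: per-source anchor tables
(`gd_curve()`, also shipped in `inst/extdata/presets.yaml`) joined by a
shape-preserving Fritsch–Carlson piecewise-cubic interpolant in
$\log(1+c)$. The interpolant is fitted per monotone run of the anchors so
it can never overshoot them; consequently the curve's maximum over the
anchored range is exactly the anchored maximum, which is what
`enhancement_profile()` must recover. Outside the anchored 0–2000 µM range
the value is clamped to the nearest endpoint with a warning rather than
extrapolated.

Two deliberate simplifications: the electron-beam source reuses the
gamma-source anchors (it shares the gamma baseline yield and no separate
enhancement data exist), and the curve measured for free Gd³⁺ ions is
exposed as swappable data rather than asserted to hold for chelated Gd.

```{r gd-curve}
conc <- c(0, 50, 200, 500, 1000, 2000)
data.frame(conc_uM = conc,
           GR = round(gd_enhancement(conc, gd_curve("GR")), 3),
           XR = round(gd_enhancement(conc, gd_curve("XR")), 3))
```

## Scavengers and the Fenton branch

Scavenger competition follows standard homogeneous kinetics: solute $i$
captures a fraction $k_i c_i / \sum_j k_j c_j$ of the HO• budget
(`scavenging_fractions()`). What happens to the captured fraction is stored
as a qualitative fate per scavenger — `quench` removes it from the
oxidising budget, `convert_to_oxidant` leaves the budget unchanged — mirroring
the binary classification the mechanism studies use, with no attempt to
simulate the secondary radical chemistry. Rate constants in the presets are
standard aqueous-phase literature values except coumarin's, which is the
probe constant used for dosimetry (1.05×10¹⁰ L mol⁻¹ s⁻¹).

The Fenton branch (`fenton_ho_budget()`) is explicitly phenomenological:
$[\mathrm{HO}^\bullet] = y\,c_\mathrm{Fe}(1-e^{-r\,c_{\mathrm{H_2O_2}}t})$,
monotone in each input and zero when any input is zero. Its two defaults
were calibrated once, by requiring that the budget produced by the
experimental recipe (50 mM H₂O₂, 75 µM Fe²⁺, 5 min), read back through the
monoexponential via `fenton_equivalent_dose()`, reproduces the observed
16.7% → 48.4% *trans* jump (≈ 2.28 Gy-equivalent). They are not mechanistic
rate constants and should not be reused outside that regime.

## Estimators

All estimators are ordinary least squares (`stats::lm`) on the model's
linearisation, and each is the exact inverse of the corresponding generator
on noiseless data — a property the test suite asserts directly.

- `fit_activation_constant()`: slope of
  $\ln[(A_0 - A_\infty)/(A_t - A_\infty)]$ against dose, through the origin
  by default because the transform is identically zero at zero dose. A free
  intercept is available as a diagnostic. The log transform carries a
  second-order (Jensen) bias of order $\sigma^2/(A_t - A_\infty)^2$
  (~10⁻⁴ Gy⁻¹ at the noise levels simulated here), negligible against the
  ±0.02 Gy⁻¹ experimental uncertainty but visible to a large enough Monte
  Carlo ensemble; the recovery tests bound it at 0.5% of $k$.
- `fit_g_value()`: the paired-plate correction. Both plates are prepared at
  the photostationary state and measured at matched timestamps; the dark
  plate measures thermal drift, which is subtracted point-by-point
  (invariant under any common drift). The corrected fraction increase times
  the switch concentration, divided by dose, is the yield in µmol/J.
  Whether the correction was applied is carried in the result
  (`corrected_for_thermal`), since published per-dose activation
  percentages do not always state it.
- `fit_g_ho()`: coumarin dosimetry. Fluorescence → 7-OH-coumarin
  concentration via the standard curve, OLS slope against dose
  (µM/Gy ≡ µmol/J), divided by the 3.1% conversion yield.
- `fit_thermal_half_life()`: OLS of $\ln(1-\theta)$ on time; saturated
  points are filtered with a warning, and at least four usable points are
  required.
- `fit_efficiency_model()`: OLS of the per-concentration G-value slope on
  $\ln D$.

Uncertainties are regression standard errors (the half-life via the delta
method); no bootstrap is applied by default since the emulated experiments
report mean ± SD of three runs.

## The synthetic-data generator

`gen_dose_response()` emulates the two-plate design: both plates start at
the photostationary composition, relax thermally between consecutive
measurements (the `lag_h` parameter — the real experiments stagger UV
preparation so both plates are read concurrently, and the lag is not
published, so it is exposed as a knob defaulting to 0), and the irradiated
plate additionally receives each dose increment. Replicate wells receive
independent noise and are averaged, as plate experiments report means.
Noise defaults (`assay_noise()`: 0.01 absolute on fractions, 0.005 OD on
absorbance, 3% relative on fluorescence) were chosen once so triplicate
scatter sits at the 2–5% relative scale typical of these assays.

Randomness is controlled by one root seed per generator call;
`child_seeds()` derives deterministic sub-stream seeds for replicate
ensembles, and identical seeds give bit-identical files through the I/O
layer. Pure-isomer spectra are Gaussian bands (cis centred at 322 nm, trans
at 367 nm with much higher intensity); only the two-point 367 nm mixing
rule is load-bearing for inference, the rest of the band shape is cosmetic.

What the generator does *not* emulate — and therefore what passing recovery
tests cannot certify about real data: instrument drift and plate-position
effects, HPLC integration error, deviations from strict first-order
kinetics at high conversion, photoproduct impurities, and any dose-rate
dependence (dose is the only radiation variable, per the standard-dose-rate
regime being modelled).

## Numerical choices and degenerate inputs

- Problem sizes: recovery ensembles use 200 replicates of 4–9-point
  assays, enough to pin ensemble means to ~0.1% while keeping the whole
  suite in a few seconds.
- The activation fit requires readouts strictly inside the open interval
  $(A_\infty, A_0)$ and names the offending dose otherwise; series shorter
  than 3 non-zero doses, flat relaxation courses, degenerate standard
  curves and all-zero scavenger competitions raise typed errors rather
  than returning nonsense.
- A negative thermally corrected increment (possible with noisy controls)
  is reported as-is with a warning, not clipped, so ensemble averages stay
  unbiased.
- The efficiency model is clipped at zero yield (with a warning) where the
  fitted logarithm goes negative, beyond ~37 Gy at the default
  coefficients.

## Known limitations

The package carries two yield models that do not agree: the single-point
anchor (G ≈ 81 per 100 eV at 2 Gy and 50 µM, i.e. ≈ 1.6 G-value/µM) and
the logarithmic efficiency model (0.13 G-value/µM at 1 Gy). The
concentration range behind the efficiency fit is not published, so the two
cannot be reconciled from the available numbers; both are implemented
faithfully and kept separate (`fit_g_value()` vs `predict_g_trans()`). A
coherence check at the order-of-magnitude level — the 81-per-100 eV anchor
implies conversion of ~37% of a 45 µM cis pool at 2 Gy, consistent with
the measured one-third — is part of the test suite at loose tolerance.

Other limits: no spur/track or Monte Carlo secondary-electron physics, no
explicit hydrated-electron kinetics, no Arrhenius temperature scaling of
the half-life (override the parameter instead), no UV photokinetics beyond
the fixed photostationary endpoint, and no modelling of activation
saturation at high dose beyond what the monoexponential implies.

## A worked pass through the pipeline

```{r pipeline}
# simulate a paired assay at the gamma defaults, with realistic noise
series <- gen_dose_response(doses_Gy = c(0, 0.5, 1, 1.5, 2),
                            noise = assay_noise(fraction_sigma = 0.018,
                                                seed = 42),
                            replicates = 3)
fit_activation_constant(series)

# coumarin dosimetry under N2O: the estimator sees the doubled yield
assay <- gen_coumarin_assay(conditions = solution_conditions(gas = "N2O"),
                            noise = assay_noise(seed = 42))
fit_g_ho(assay)

# and the equivalent-dose bookkeeping that doubling implies
equivalent_dose(5, solution_conditions(gas = "N2O"),
                solution_conditions(), ir_source("GR"))
```
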