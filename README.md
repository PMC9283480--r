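# radioswitch

Quantitative modelling of **radiation-triggered azobenzene photoswitch
activation** — "radioswitches": photoswitches carrying a high-Z gadolinium
chelate so that ionising radiation, rather than light, drives their
*cis* → *trans* isomerisation via water-radiolysis hydroxyl radicals
(HO•). The package is aimed at radiation chemists and photopharmacology
groups who need to plan, simulate or analyse dose–response assays for such
systems.

## The model

The causal chain dose → HO• → isomerisation is modelled as:

- **Radiochemical yield (G-value) bookkeeping.** A dose *D* (Gy) produces
  HO• at a yield *G* expressible in µmol/J or molecules per 100 eV
  (exact conversion factor 10⁶/(100 · e · N_A) ≈ 0.10364). Built-in
  low-LET sources: gamma (662 keV, G = 0.280 µmol/J), X-ray generator
  (80 keV mean, 0.200) and 4.5 MeV electron beam (0.280).
- **Condition modifiers.** G_eff = G_base × f_gas × (1 + E(c_Gd)):
  N₂O saturation doubles the yield (f_gas = 2), N₂ is a no-op, and E(c) is
  a per-source Gd³⁺ enhancement curve interpolated through anchor tables
  (maxima +33% at 200 µM for X-rays, +20% at 500 µM for gamma). Scavenger
  competition follows f_i = k_i c_i / Σ k_j c_j with per-scavenger
  quench/convert fates.
- **Switch kinetics.** Starting from the UV photostationary state
  (90% *cis*), the *trans* fraction follows
  θ(D) = 1 − (1 − θ₀) e^(−k_eff D) with
  k_eff = k · G_eff/G_ref (default k = 0.21 Gy⁻¹ at 0.280 µmol/J), plus
  first-order thermal back-relaxation (t½ = 2.3 h at 37 °C) and the
  empirical dose-efficiency model Y = −0.036 ln D + 0.1304 (G-value/µM).
- **Estimators with paired-control correction.** OLS estimators invert
  each piece — activation constant, per-dose G-values corrected by the
  paired dark plate, G(HO•) from coumarin/7-OH-coumarin fluorescence
  dosimetry (3.1% conversion yield), thermal half-life, Gd enhancement
  profile, efficiency coefficients — and a seeded synthetic-assay
  generator verifies every estimator by parameter recovery.

See `vignettes/radioswitch-model.Rmd` for assumptions, defaults and
limitations.

## Worked example

```r
library(radioswitch)

# simulate a noisy triplicate dose-response assay at the gamma defaults
series <- gen_dose_response(doses_Gy = c(0, 0.5, 1, 1.5, 2),
                            noise = assay_noise(fraction_sigma = 0.018,
                                                seed = 42),
                            replicates = 3)
fit_activation_constant(series)
#> <activation_fit> k = 0.2153 +/- 0.0065 /Gy (r2 = 0.9973, n = 4, 0.5-2 Gy)

# coumarin dosimetry under N2O: the estimator sees the doubled yield
assay <- gen_coumarin_assay(conditions = solution_conditions(gas = "N2O"),
                            noise = assay_noise(seed = 42))
fit_g_ho(assay)
#> G(HO.) = 0.5843 umol/J  (5.638 per 100 eV)

# the doubling rule and the equivalent-dose construction it implies
effective_g_ho("GR", solution_conditions(gas = "N2O"))
#> G(HO.) = 0.56 umol/J  (5.403 per 100 eV)
equivalent_dose(5, solution_conditions(gas = "N2O"),
                solution_conditions(), ir_source("GR"))
#> [1] 10
```

The fitted k = 0.2153 ± 0.0065 Gy⁻¹ recovers the generating activation
constant (0.21 Gy⁻¹) within its standard error; the dosimetry fit recovers
the N₂O-doubled hydroxyl-radical yield (0.56 µmol/J) within the 3%
fluorescence noise; and a 5 Gy exposure under N₂O is water-equivalent to
10 Gy because exactly twice the HO• is generated per gray.

A command-line wrapper with `simulate | fit | convert | report | fixtures |
defaults` subcommands ships at `inst/scripts/radioswitch-cli.R`.

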