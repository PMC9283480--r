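# Built-in presets: radiation sources, scavenger panel, Gd3+ enhancement
# anchor curves. Same values as the package constructors; edit a copy of
# this file and pass it to load_presets() to run with custom inventories.
sources:
  GR: {particle: photon, mean_energy_keV: 662, g_ho_base_umol_per_J: 0.280}
  XR: {particle: photon, mean_energy_keV: 80, g_ho_base_umol_per_J: 0.200}
  E: {particle: electron, mean_energy_keV: 4500, g_ho_base_umol_per_J: 0.280}
scavengers:
  tBuOH: {rate_constant_ho: 6.0e+08, ho_fate: quench, electron_fate: inert}
  mannitol: {rate_constant_ho: 1.9e+09, ho_fate: quench, electron_fate: inert}
  ethanol: {rate_constant_ho: 1.9e+09, ho_fate: quench, electron_fate: inert}
  NaN3: {rate_constant_ho: 1.2e+10, ho_fate: convert_to_oxidant, electron_fate: inert}
  DMSO: {rate_constant_ho: 7.1e+09, ho_fate: convert_to_oxidant, electron_fate: inert}
  selenate: {rate_constant_ho: 1.0e+06, ho_fate: quench, electron_fate: convert_to_oxidant}
  Cd(ClO4)2: {rate_constant_ho: 1.0e+06, ho_fate: quench, electron_fate: convert_to_inert}
  coumarin: {rate_constant_ho: 1.05e+10, ho_fate: quench, electron_fate: inert}
gd_enhancement_anchors:
  GR:
    concentrations_uM: [0, 10, 25, 100, 200, 500, 1000, 2000]
    factors: [0.0, 0.05, 0.10, 0.15, 0.18, 0.20, 0.12, 0.02]
  XR:
    concentrations_uM: [0, 10, 25, 50, 100, 200, 500, 1000, 2000]
    factors: [0.0, 0.08, 0.15, 0.22, 0.28, 0.33, 0.30, 0.18, 0.05]
  E:
    concentrations_uM: [0, 10, 25, 100, 200, 500, 1000, 2000]
    factors: [0.0, 0.05, 0.10, 0.15, 0.18, 0.20, 0.12, 0.02]
switch:
  k_act_per_Gy: 0.21
  pss1_cis_fraction: 0.90
  thermal_half_life_h: 2.3
  reference_g_ho_umol_per_J: 0.280
  efficiency_a: -0.036
  efficiency_b: 0.1304
fenton:
  yield_per_fe: 0.01
  consumption_rate_per_mM_min: 7.632e-03
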