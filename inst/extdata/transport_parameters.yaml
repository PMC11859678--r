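# Drug-transport and pharmacokinetic constants (SI units).
# Pressures in Pa, conductivities in m/Pa/s, permeabilities in m/s,
# diffusion in m^2/s, rates in 1/s (PK rates tabulated in 1/h).
#
# Tumour notes:
#  * S_over_V baseline 2.0e4 1/m corresponds to a microvascular density of
#    200 1/cm for untreated nodules; 1.0e4 1/m is the high-collagen preset.
#  * P_i 1400 Pa is the interstitial fluid pressure assigned to untreated
#    2 mm nodules; the literature value 2670 Pa is kept under `alternatives`.
tumor:
  L_p: 2.10e-11
  S_over_V: 2.0e4
  P_c: 1.43e-6
  P_v: 2080.0
  P_i: 1400.0
  pi_v: 2670.0
  pi_i: 1330.0
  c_osm: 0.82
  sigma: 0.95
  D: 3.0e-9
  beta: 7.32e-4
normal:
  L_p: 2.7e-12
  S_over_V: 7.0e3
  P_c: 2.2e-9
  P_v: 2080.0
  P_i: 133.0
  pi_v: 2670.0
  pi_i: 1330.0
  c_osm: 0.91
  sigma: 0.95
  D: 3.0e-9
  beta: 7.32e-4
alternatives:
  tumor_P_i_literature: 2670.0
  tumor_S_over_V_low_mvd: 1.0e4
pk:
  K12_per_h: 2.8
  K21_per_h: 1.1
  Ke_per_h: 3.9
  # Rat-scale total blood volume (64 mL/kg x 0.25 kg); not tabulated in the
  # source data, used only where absolute plasma concentrations are needed.
  V_blood_m3: 1.6e-5
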