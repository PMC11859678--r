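# Steady-state surface temperature plateaus induced during 30 min HIPEC on
# the peritoneal/retroperitoneal surfaces of seven abdominal organs, for two
# catheter setups, together with the oxaliplatin IC50 at those temperatures.
# These plateaus are consumed as fixtures by the nodule-scale model; they are
# outputs of an abdomen-scale conjugate heat-transfer simulation that this
# package does not reproduce.
#
# tau_s: surrogate first-order time constants for the surface drug
# concentration rise (setup 2 saturates faster; the intestine and left kidney
# are the slow sites of setup 1).
setup1:
  - {organ: pancreas,  temp_c: 41.3, ic50_uM: 241, tau_s: 180}
  - {organ: liver,     temp_c: 40.4, ic50_uM: 285, tau_s: 180}
  - {organ: intestine, temp_c: 40.1, ic50_uM: 305, tau_s: 300}
  - {organ: l_kidney,  temp_c: 38.4, ic50_uM: 338, tau_s: 300}
  - {organ: r_kidney,  temp_c: 40.7, ic50_uM: 265, tau_s: 180}
  - {organ: stomach,   temp_c: 41.7, ic50_uM: 234, tau_s: 180}
  - {organ: spleen,    temp_c: 41.7, ic50_uM: 234, tau_s: 180}
setup2:
  - {organ: pancreas,  temp_c: 41.8, ic50_uM: 232, tau_s: 90}
  - {organ: liver,     temp_c: 40.6, ic50_uM: 271, tau_s: 90}
  - {organ: intestine, temp_c: 41.0, ic50_uM: 245, tau_s: 90}
  - {organ: l_kidney,  temp_c: 40.5, ic50_uM: 278, tau_s: 90}
  - {organ: r_kidney,  temp_c: 40.9, ic50_uM: 251, tau_s: 90}
  - {organ: stomach,   temp_c: 42.0, ic50_uM: 229, tau_s: 90}
  - {organ: spleen,    temp_c: 41.9, ic50_uM: 231, tau_s: 90}
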