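# Organ-specific thermal properties.
# w_b_ml_min_kg: blood perfusion as tabulated (mL blood / min / kg tissue);
# converted to 1/s internally using the tissue density.
# Skin and peritoneal wall rows carry no density/conductivity/heat-capacity
# values; the `defaults` block supplies soft-tissue stand-ins for them.
organs:
  - {organ: liver,     w_b_ml_min_kg: 860,  rho_t: 1079, k_t: 0.52, c_t: 3540}
  - {organ: pancreas,  w_b_ml_min_kg: 767,  rho_t: 1087, k_t: 0.51, c_t: 3164}
  - {organ: intestine, w_b_ml_min_kg: 765,  rho_t: 1088, k_t: 0.54, c_t: 3655}
  - {organ: spleen,    w_b_ml_min_kg: 1557, rho_t: 1089, k_t: 0.53, c_t: 3690}
  - {organ: kidneys,   w_b_ml_min_kg: 3795, rho_t: 1066, k_t: 0.53, c_t: 3763}
  - {organ: stomach,   w_b_ml_min_kg: 460,  rho_t: 1088, k_t: 0.53, c_t: 3690}
  - {organ: skin,            w_b_ml_min_kg: 106, rho_t: null, k_t: null, c_t: null}
  - {organ: peritoneal_wall, w_b_ml_min_kg: 33,  rho_t: null, k_t: null, c_t: null}
defaults: {rho_t: 1050.0, k_t: 0.52, c_t: 3600.0}
blood: {rho_b: 1050.0, c_b: 3617.0}
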