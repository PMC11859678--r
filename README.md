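# hipecsim

Multiscale simulation of oxaliplatin delivery to peritoneal tumour nodules
during 30-minute (hyperthermic) intraperitoneal chemotherapy, with and
without bevacizumab-induced vascular normalization.

## Who this is for

Computational pharmacology of intraperitoneal chemotherapy: after
cytoreductive surgery for peritoneal metastasis of colorectal cancer,
residual nodules (≤ 2.5 mm) are bathed in heated oxaliplatin solution.
Treatment benefit hinges on whether the drug penetrates deep enough to
exceed cytotoxic levels throughout a nodule before washing out through the
leaky tumour microvasculature. Anti-VEGF pretreatment (bevacizumab) prunes
microvessels, tightens vessel walls and lowers interstitial fluid pressure;
this package quantifies how much that helps.

## The model

For a 2 mm nodule half-embedded in host tissue, the tissue concentration
C(r, z, t) obeys an axisymmetric diffusion–reaction equation

∂C/∂t − ∇·(D∇C) = −β·C − P_c·(S/V)·Pe_v/(e^{Pe_v} − 1)·y(T)·C

where β is first-order cellular elimination, P_c·(S/V) the diffusive
transvascular exchange (microvascular permeability × exchange area
density), Pe_v = L_p[P_v − P_i − c(π_v − π_i)](1 − σ)/P_c the Starling
transvascular Péclet number, and y(T) = −0.04715·T + 2.744555 the empirical
reduction of washout under mild hyperthermia. The exposed hemisphere
carries the perfusate concentration C₀(1 − e^{−t/τ}) with the steady
organ-surface temperature plateau of the chosen catheter setup; washout
feeds a linear two-compartment systemic PK model (rates K12, K21, Ke).
Outcomes are the tumour AUC, the effective penetration depth d_eff (depth
where C exceeds 10% of the temperature-specific IC50 for CMS4 colorectal
cancer, thermal enhancement included), and the pharmacokinetic advantage
PA = AUC_tumor / AUC_plasma. Vascular normalization enters as parameter
transforms: 0.5 mg/kg (microvascular density −45%), and 5 mg/kg (density
−65%, permeability and hydraulic conductivity −22%, IFP 1.4 → 0.25 kPa).

## Worked example

One control nodule on the intestine surface (40.1 °C, catheter setup 1)
versus the same nodule after 5 mg/kg vascular normalization:

```r
library(hipecsim)

b   <- generate_boundary("intestine", setup = 1)   # 160 µM, 30 min
fit <- solve_nodule(b, dt = 1)                     # ~3 s, 10,316 cells
glance(fit)
#>   tumor_auc_mol_s_m3 mean_tumor_final_mol_m3 mass_balance_rel_error ...
#> 1               95.1                  0.0642                2.2e-15

ic50 <- ic50_at_temperature(40.1)                  # 304.7 µM
effective_penetration_depth(fit, ic50_uM = ic50, normalized = TRUE)
#> [1] 0.496

combo <- solve_nodule(b, tumor_params =
  apply_bevacizumab(transport_params("tumor"), 5), dt = 1)
tumor_auc(combo) / tumor_auc(fit)
#> [1] 1.36
```

Read: at the end of 30 minutes the untreated nodule averages 64 µM
(exposure AUC ≈ 95 mol·s/m³ ≈ 95,000 µM·s) and the drug exceeds the
cytotoxic threshold over 0.50 of the nodule diameter; the discrete mass
balance closes to machine precision. The 5 mg/kg transform raises tumour
exposure by 36% and the penetration fold is 1.71 at this site. Full
experiment sweeps (organ × setup × arm grids, stiffness and permeability
sensitivity, dose equivalence) run through `experiment_config()` and
`run_experiment()`, or from a shell via `inst/exec/hipecsim`.

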