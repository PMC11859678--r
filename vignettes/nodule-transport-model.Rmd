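---
title: "Modelling oxaliplatin delivery to peritoneal tumour nodules during (H)IPEC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oxaliplatin delivery to peritoneal tumour nodules during (H)IPEC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipecsim)
```

## The problem

After cytoreductive surgery for peritoneal metastasis of colorectal cancer,
residual tumour nodules up to about 2.5 mm remain on the peritoneal and
retroperitoneal surfaces. Hyperthermic intraperitoneal chemotherapy (HIPEC)
bathes these nodules in heated (41-43 °C) oxaliplatin solution for 30
minutes. Whether the drug actually reaches cytotoxic concentrations
throughout a nodule depends on a competition between diffusion from the
exposed surface and two loss channels: first-order cellular uptake and
washout through the tumour microvasculature into the systemic circulation.
Anti-VEGF treatment (bevacizumab) "normalizes" the tumour vasculature -
pruning microvessels, tightening their walls, and lowering the interstitial
fluid pressure - which should reduce washout and deepen drug penetration.
`hipecsim` implements that whole chain as a deterministic simulation
pipeline so the treatment arms can be compared quantitatively.

## Model structure

The pipeline has four coupled stages, each a package module:

1. **Organ-surface boundary conditions** (`generate_boundary()`,
   `organ_surface_fixture()`). The abdomen-scale perfusion problem is not solved
   here; its outputs are consumed as fixtures: per-organ steady surface
   temperature plateaus for two catheter setups, and a surrogate surface
   drug-concentration time course
   $C_b(t) = C_0\,(1 - e^{-t/\tau})$ rising to the perfusate dose.
2. **Nodule transport** (`solve_nodule()`). The core computation: an
   axisymmetric diffusion-reaction equation for a 2 mm spherical nodule half
   embedded in host tissue,
   $$\partial_t C - \nabla\!\cdot\!(D \nabla C) =
     -\underbrace{\beta C}_{\text{cellular}}
     -\underbrace{P_c \tfrac{S}{V} \tfrac{Pe_v}{e^{Pe_v}-1}\, y(T)\, C}_{\text{vascular washout}},$$
   with the transvascular Péclet number
   $Pe_v = L_p [P_v - P_i - c(\pi_v - \pi_i)](1-\sigma)/P_c$ built from the
   Starling pressures, and $y(T) = -0.04715\,T + 2.744555$ the empirical
   reduction of washout under mild hyperthermia ($y(37) \approx 1$).
3. **Systemic pharmacokinetics** (`integrate_pk()`). The vascular washout,
   volume-integrated over the tissue, feeds a linear two-compartment
   (systemic/peripheral) model with first-order transfer and elimination.
4. **Evaluation metrics** (`tumor_auc()`, `effective_penetration_depth()`,
   `pa_ratio()`, `dose_equivalence_search()`). Exposure is the time integral
   of the volume-averaged tumour concentration; the effective penetration
   depth $d_{eff}$ is the depth along the symmetry axis over which the
   end-of-treatment concentration exceeds 10% of the temperature-specific
   IC50 for CMS4 colorectal cancer; the pharmacokinetic advantage (PA) is
   the tumour-to-plasma AUC ratio.

A one-dimensional Pennes bioheat slab with a lumped arterial update
(`bioheat_slab()`, `update_arterial()`) verifies the thermal model at
property level, and a well-mixed cavity balance (`simulate_cavity()`)
provides a self-consistent alternative source of boundary series. Neither
replaces the fixture temperatures, which come from an abdomen-scale
simulation outside this package's scope.

## Parameters

All physical constants live in human-readable YAML under `inst/extdata/` and
load through `transport_params()`, `thermal_properties()`,
`cytotoxicity_table()` and `organ_surface_fixture()`. Everything internal is SI;
doses and IC50 values cross the interface in µM (1 µM = $10^{-3}$ mol/m³).
Noteworthy choices:

* **Tumour interstitial fluid pressure.** The tabulated literature value
  (2.67 kPa) refers to larger tumours; untreated 2 mm nodules are assigned
  1.4 kPa, and that is the default. The literature value remains available
  via `transport_params("tumor", use_literature_ifp = TRUE)`.
* **Baseline microvascular density** 200 cm⁻¹, i.e. exchange area density
  $S/V = 2\times10^4$ m⁻¹. The two tabulated $S/V$ values are reinterpreted
  as the low/high collagen-density presets of `apply_stiffness()`.
* **Bevacizumab transforms** (`apply_bevacizumab()`): 0.5 mg/kg - MVD −45%,
  leakiness and $L_p$ unchanged, IFP 1.4 kPa; 5 mg/kg - MVD −65%, $L_p$ and
  $P_c$ −22%, IFP 0.25 kPa. Only tumour parameters are ever transformed;
  host tissue always keeps the normal-tissue column.
* **TER is stored, never derived.** The tabulated thermal enhancement ratios
  are means of per-cell-line ratios and do not equal the ratios of the mean
  IC50 values; recomputing them would be wrong, so the table is verbatim.
* **IC50 interpolation is linear** between the 1 °C grid points. This choice
  is validated, not assumed: it reproduces all fourteen printed
  organ-surface IC50 values within ±1 µM (an acceptance test).
* **Perfusion-rate conversion** from mL/min/kg to s⁻¹ multiplies by the
  tissue density; the skin and wall rows lack a printed density and use a
  generic 1050 kg/m³.

## The boundary surrogate and what it does (not) emulate

The real organ-surface drug kinetics come from cavity-scale flow; only their
qualitative features are documented: concentrations rise smoothly to
comparable steady levels, and the second catheter setup covers the intestine
and left kidney faster. The surrogate encodes exactly that: exponential
saturation to the administered dose with τ = 180 s (setup 1; 300 s for its
slow sites, intestine and left kidney) and τ = 90 s (setup 2). Fold-change
metrics between arms that differ only in tumour parameters are insensitive
to τ in the 60-300 s range. Two caveats matter when comparing against
abdomen-scale simulations:

* The surrogate saturates at the *full* perfusate concentration. If the
  true surface-averaged plateau sits materially below the administered dose,
  absolute penetration depths are overestimated and between-arm penetration
  folds are compressed (the threshold sits deeper in the profile's
  logarithmic tail). This is the main caveat for the penetration-fold and
  dose-equivalence comparisons.
* The temperature is applied as a constant plateau per organ, because the
  nodule stage uses the surface-averaged steady temperature to set the
  washout factor; no thermal gradient inside the nodule is modelled.

## Numerical choices

* **Discretization.** Cell-centred finite volumes on a uniform axisymmetric
  (r, z) grid, 0.05 mm spacing (40 cells across the tumour diameter); the
  host block extends 5 mm radially and axially (five times the tumour size).
  Diffusivity is harmonically averaged at faces, which enforces flux
  continuity at the tumour-host interface. Dirichlet faces on the
  stair-stepped hemisphere use the exact distance from the cell centre to
  the spherical surface (clamped to [0.05 h, h]), which brings the AUC shift
  under mesh halving below 1%.
* **Time stepping** is backward Euler with the linear sink folded into the
  system matrix; one sparse Cholesky factorization per scenario, one
  triangular solve per step. The scheme is unconditionally stable and
  discretely conservative: the reported mass-balance residual is at machine
  precision, and the tests assert 0.5%.
* **Boundary conditions.** The perfusate concentration is imposed on the
  exposed tumour hemisphere only; the host surface plane is drug-sealed by
  default (`host_surface = "sealed"`), matching the model's printed
  boundary-condition set. The far host boundaries are zero-gradient. With
  `tumor_diameter = 0` the solver degenerates to a host slab with a fully
  exposed surface, the configuration used to verify the solver against the
  $\mathrm{erfc}$ closed form and a brute-force explicit integration.
* **$d_{eff}$ reading.** The exceedance region is read contiguously from
  the exposed pole (first crossing below threshold, linearly interpolated,
  capped at the diameter). The alternative "largest exceeding depth" is
  available (`rule = "any"`) but degenerate whenever host-side supply keeps
  the embedded pole above threshold. End-of-treatment is the default
  evaluation time; `at = "max"` evaluates the pointwise maximum over stored
  snapshots. Normalization is by tumour diameter.
* **Péclet factor.** $Pe_v/(e^{Pe_v}-1)$ is evaluated by series below
  $|Pe_v| < 10^{-6}$; the printed constants give a small *negative* Péclet
  number ($\approx -3\times10^{-4}$), which the factor handles as written.
* **PK integration** steps exactly through the matrix exponential per
  source interval (piecewise-constant, interval-mean source), so it is
  stiff-safe and preserves non-negativity; the cavity balance uses the same
  exact stepping.
* **Dose scaling by linearity.** The transport chain is linear in the
  perfusate concentration (verified as a test property), so monotherapy
  arms at different doses are evaluated by scaling one reference solve;
  the dose-equivalence search exploits this and breaks ties toward the
  lower dose. Quartiles across the seven organ sites use linear
  interpolation (type 7), stated because n = 7 makes the convention
  visible.

## The systemic source split

The plasma compartment is fed by vascular washout integrated over tissue.
The simulated domain only contains one nodule and its host block, while the
real abdomen exchanges drug over the whole peritoneum, so
`peritoneal_source()` adds a surrogate normal-tissue term: a 1 mm-deep
exchange layer over a 0.0125 m² rat-scale peritoneal area, held in
quasi-steady balance with the surface concentration (layer mean
$\bar C = C_b (\ell/\delta)\tanh(\delta/\ell)$ with
$\ell = \sqrt{D/(\beta + k_v)}$). Total blood volume defaults to 16 mL
(64 mL/kg × 250 g); it scales absolute plasma concentrations but cancels
from PA-ratio comparisons. The area/depth of the exchange layer attenuate -
but never create - between-arm PA differences, because the term is
identical across tumour-parameter scenarios at a given dose. Absolute
plasma concentrations are therefore reported but not asserted; only ratio
comparisons are meaningful at this fidelity.

## Bioheat and cavity components

The bioheat slab verifies the Pennes equation implementation against the
analytic steady profile $T = T_a + \Delta T\, e^{-x/\sqrt{k/(\rho_b w_b c_b)}}$
(first-order grid convergence) and checks discrete energy conservation per
step. The lumped arterial update balances metabolic gain, perfusion
exchange, and configurable linear skin/tail losses; metabolic heat defaults
to zero with a configuration hook, and the loss coefficients are chosen so
a coupled run stays near-normothermic over 30 minutes. The cavity balance
closes convective transport with per-organ film coefficients calibrated so
all organ surfaces reach 95% of the dose within 15 minutes; its volume
(80 mL) and film coefficients are surrogate rat-scale quantities and are
labelled as such in outputs.

## Problem sizes

The reference configuration solves roughly 10,300 active cells per scenario
with 1 s implicit steps over the 1800 s treatment; a full three-arm sweep
over 7 organ sites × 2 catheter setups is 42 such solves plus the
permeability and pharmacokinetic chains. Unit and property tests run on
coarsened variants (0.1-0.2 mm meshes, shorter horizons) whose agreement
with the reference resolution is itself a tested property (≤1% AUC shift on
mesh halving, ≤0.5% on time-step halving).

## Known limitations

* No interstitial convection: transport inside the tissue is
  diffusion-reaction only, appropriate for a small-molecule drug but not
  for macromolecules.
* A single uniform IFP per region; no radial IFP profile, so the
  normalization effect enters only through the Starling driving pressure in
  $Pe_v$.
* No back-flux from plasma to tissue: the systemic compartment never
  re-enters the nodule equation, so late re-distribution is absent.
* The boundary surrogate's saturation level and time constants, the
  peritoneal exchange area, the blood volume, and the cavity film
  coefficients are rat-scale surrogates; conclusions should be drawn from
  between-arm comparisons, not absolute values.
* Organ-surface temperatures are fixture plateaus; conjugate heat transfer
  between cavity flow and tissue is out of scope.
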