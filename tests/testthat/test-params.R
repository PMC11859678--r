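test_that("transport parameter presets load the tabulated values", {
  tum <- transport_params("tumor")
  expect_equal(tum$L_p, 2.10e-11)
  expect_equal(tum$S_over_V, 2.0e4)
  expect_equal(tum$P_c, 1.43e-6)
  expect_equal(tum$P_v, 2080)
  expect_equal(tum$P_i, 1400) # 2 mm-nodule IFP
  expect_equal(tum$pi_v, 2670)
  expect_equal(tum$pi_i, 1330)
  expect_equal(tum$c_osm, 0.82)
  expect_equal(tum$sigma, 0.95)
  expect_equal(tum$D, 3e-9)
  expect_equal(tum$beta, 7.32e-4)
  nor <- transport_params("normal")
  expect_equal(nor$L_p, 2.7e-12)
  expect_equal(nor$S_over_V, 7e3)
  expect_equal(nor$P_c, 2.2e-9)
  expect_equal(nor$P_i, 133)
  expect_equal(nor$c_osm, 0.91)
  # literature IFP preset is retained as an alternative
  expect_equal(transport_params("tumor", use_literature_ifp = TRUE)$P_i, 2670)
  expect_error(transport_params("tumor", nonsense = 1), "unknown")
})

test_that("perfusion-rate conversion round-trips and matches hand arithmetic", {
  # liver: 860 mL/min/kg at 1079 kg/m^3 -> 860e-6/60*1079 1/s
  expect_equal(perfusion_to_per_s(860, 1079), 860e-6 / 60 * 1079)
  w <- perfusion_to_per_s(c(860, 3795), c(1079, 1066))
  expect_equal(perfusion_to_ml_min_kg(w, c(1079, 1066)), c(860, 3795))
  tp <- thermal_properties()
  expect_equal(nrow(tp), 8L)
  expect_true(all(tp$w_b > 0 & tp$rho_t > 0 & tp$k_t > 0 & tp$c_t > 0))
})

test_that("washout factor evaluates the linear law and decreases with heat", {
  expect_equal(washout_factor(37), 1.000005, tolerance = 1e-12)
  expect_equal(washout_factor(43), 0.717105, tolerance = 1e-12)
  temps <- seq(37, 43, by = 0.5)
  expect_true(all(diff(washout_factor(temps)) < 0))
  expect_gte(washout_factor(100), 0) # clamped, never negative
  expect_error(washout_factor(NaN), "finite")
})

test_that("IC50 interpolation hits printed worked examples and clamps", {
  expect_equal(ic50_at_temperature(37), 537.7)
  expect_equal(ic50_at_temperature(40.1), 305, tolerance = 1 / 305)
  expect_equal(ic50_at_temperature(38.4), 338, tolerance = 1 / 338)
  expect_equal(ic50_at_temperature(45), 220) # clamp to the 43 degC endpoint
  expect_equal(ic50_at_temperature(30), 537.7)
  expect_error(ic50_at_temperature(Inf), "finite")
  ct <- cytotoxicity_table()
  expect_true(all(diff(ct$ic50_uM) < 0)) # strictly decreasing with heat
  expect_equal(ct$ter[ct$temp_c == 37], 1.0)
})

test_that("bevacizumab transform applies the dose-specific changes and is pure", {
  base <- transport_params("tumor")
  id <- apply_bevacizumab(base, 0)
  expect_identical(unclass(id), unclass(base))
  lo <- apply_bevacizumab(base, 0.5)
  expect_equal(lo$S_over_V, 2e4 * 0.55) # MVD -45%
  expect_equal(lo$P_c, base$P_c)        # leakiness unchanged at 0.5 mg/kg
  expect_equal(lo$L_p, base$L_p)
  expect_equal(lo$P_i, 1400)
  hi <- apply_bevacizumab(base, 5)
  expect_equal(hi$S_over_V, 7e3)        # MVD -65%
  expect_equal(hi$L_p, base$L_p * 0.78) # -22%
  expect_equal(hi$P_c, base$P_c * 0.78)
  expect_equal(hi$P_i, 250)
  # purity: the base object is untouched
  expect_equal(base$S_over_V, 2e4)
  expect_equal(base$P_i, 1400)
  expect_error(apply_bevacizumab(base, 1), "unsupported")
  expect_error(apply_bevacizumab(transport_params("normal"), 5), "tumour")
})

test_that("stiffness presets assign the collagen-density pairs from the base", {
  base <- transport_params("tumor")
  lo <- apply_stiffness(base, "low")
  expect_equal(lo$D, 3e-9)
  expect_equal(lo$S_over_V, 2e4)
  hi <- apply_stiffness(base, "high")
  expect_equal(hi$D, 1.5e-9) # diffusivity halved in dense matrix
  expect_equal(hi$S_over_V, 1e4)
  # pure function of the base: low o high o low == low
  again <- apply_stiffness(apply_stiffness(lo, "high"), "low")
  expect_equal(unclass(again), unclass(lo))
  expect_error(apply_stiffness(transport_params("normal"), "low"), "tumour")
})

test_that("Peclet number matches direct arithmetic and its limits", {
  pe <- peclet_number(transport_params("tumor"))
  # L_p (P_v - P_i - c (pi_v - pi_i)) (1 - sigma) / P_c with printed constants
  expect_equal(pe, -3.0751e-4, tolerance = 1e-4)
  expect_equal(peclet_number(transport_params("tumor", sigma = 1)), 0)
  p0 <- transport_params("tumor")
  p0 <- transport_params("tumor", P_i = p0$P_v - p0$c_osm * (p0$pi_v - p0$pi_i))
  expect_equal(peclet_number(p0), 0)
  expect_error(peclet_number(transport_params("tumor", P_c = 0)), "undefined")
})

test_that("Peclet factor handles the removable singularity and decreases", {
  expect_equal(peclet_factor(0), 1)
  expect_equal(peclet_factor(1), 1 / (exp(1) - 1), tolerance = 1e-12)
  expect_equal(peclet_factor(1), 0.5820, tolerance = 1e-4)
  pe <- seq(-3, 3, by = 0.25)
  expect_true(all(diff(peclet_factor(pe)) < 0))
  # series and direct branches agree across the switch point
  expect_equal(peclet_factor(1e-6 * (1 - 1e-9)), peclet_factor(1e-6 * (1 + 1e-9)),
               tolerance = 1e-9)
})

test_that("sink rate combines cellular and heat-modulated vascular terms", {
  p <- transport_params("tumor")
  expect_equal(sink_rate(0, p, 40), 0)
  p_novasc <- transport_params("tumor", P_c = 0)
  expect_equal(sink_rate(0.16, p_novasc, 40), 7.32e-4 * 0.16) # 1.1712e-4
  # y applies to the vascular component only
  vas37 <- sink_rate(1, p, 37) - p$beta
  vas43 <- sink_rate(1, p, 43) - p$beta
  expect_equal(vas43 / vas37, washout_factor(43) / washout_factor(37),
               tolerance = 1e-12)
  expect_equal(vas43 / vas37, 0.7171, tolerance = 1e-4)
  expect_error(sink_rate(-1, p, 40), "non-negative")
})
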