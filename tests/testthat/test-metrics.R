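test_that("mean concentration agrees with a brute-force volume quadrature", {
  fit <- coarse_fit(t_f = 200, dt = 10)
  tum <- fit$field[fit$field$region == "tumor", ]
  brute <- sum(tum$volume_m3 * tum$conc_mol_m3) / sum(tum$volume_m3)
  expect_equal(mean_concentration(fit, max(fit$times)), brute,
               tolerance = 1e-3)
  expect_equal(mean_concentration(fit, 0), 0)
  # linear interpolation between stored times
  mid <- mean_concentration(fit, 15)
  expect_equal(mid, (mean_concentration(fit, 10) + mean_concentration(fit, 20)) / 2)
  expect_error(mean_concentration(fit, 1e6), "horizon")
})

test_that("AUC reproduces closed forms for constant and ramp profiles", {
  tt <- seq(0, 1800, by = 10)
  expect_equal(tumor_auc(fake_fit(tt, rep(0.1, length(tt)))), 0.1 * 1800)
  expect_equal(tumor_auc(fake_fit(tt, 0.1 * tt / 1800)), 0.1 * 1800 / 2)
  expect_error(tumor_auc(fake_fit(0, 0)), "two")
})

test_that("AUC is insensitive to halving the time step", {
  a1 <- tumor_auc(coarse_fit(t_f = 300, dt = 10))
  a2 <- tumor_auc(coarse_fit(t_f = 300, dt = 5))
  expect_lt(abs(a2 - a1) / a1, 0.005)
})

test_that("effective penetration depth handles saturation and empty fields", {
  fit <- coarse_fit(t_f = 300, dt = 10)
  # threshold far below any concentration -> full diameter, normalized 1
  expect_equal(effective_penetration_depth(fit, ic50_uM = 1e-6,
                                           normalized = TRUE), 1)
  # threshold above everything -> zero
  expect_equal(effective_penetration_depth(fit, ic50_uM = 1e9), 0)
  zero <- coarse_fit(boundary = const_boundary(0), t_f = 100, dt = 10)
  expect_equal(effective_penetration_depth(zero, ic50_uM = 305), 0)
})

test_that("on an identical field heated thresholds penetrate at least as deep", {
  fit <- coarse_fit(boundary = rising_boundary(160, temp_c = 41),
                    t_f = 600, dt = 5)
  d_hipec <- effective_penetration_depth(fit, modality = "HIPEC")
  d_ipec <- effective_penetration_depth(fit, modality = "IPEC")
  expect_gte(d_hipec, d_ipec) # IC50(41) = 245 < 537.7 at 37 degC
  expect_gt(d_hipec, 0)
})

test_that("penetration depth is monotone in dose and in the IC50", {
  fit <- coarse_fit(t_f = 600, dt = 5)
  ic <- 305
  doses <- seq(160, 320, by = 40)
  # dose scaling via linearity: dose d is threshold scaling ic * 160/d
  depths <- vapply(doses, function(d) {
    effective_penetration_depth(fit, ic50_uM = ic * 160 / d)
  }, numeric(1))
  expect_true(all(diff(depths) >= 0))
  ics <- c(220, 245, 305, 340, 537.7)
  by_ic <- vapply(ics, function(i) effective_penetration_depth(fit, ic50_uM = i),
                  numeric(1))
  expect_true(all(diff(by_ic) <= 0))
})

test_that("PA ratio divides compatible units and rejects a zero denominator", {
  expect_equal(pa_ratio(1, 1000), 1) # 1 mol s/m^3 == 1000 uM s
  expect_equal(pa_ratio(2, 1000), 2)
  expect_error(pa_ratio(1, 0), "positive")
})

test_that("dose equivalence search returns the reference dose for identical arms", {
  fits <- list(intestine = coarse_fit(t_f = 300, dt = 10),
               liver = coarse_fit(t_f = 300, dt = 10,
                                  boundary = rising_boundary(160, 40.4)))
  ic <- c(intestine = 305, liver = 285)
  pick <- dose_equivalence_search(fits, fits, ic)
  expect_equal(as.numeric(pick), 160) # ties resolve to the lower dose
  expect_error(dose_equivalence_search(fits, fits, ic, dose_grid = numeric(0)),
               "empty")
})

test_that("across-organ summary matches hand-computed quartiles and folds", {
  res <- tibble::tibble(
    arm = rep(c("control", "treated"), each = 7),
    organ = rep(paste0("o", 1:7), 2),
    d_eff_norm = c(1:7 / 10, 2 * (1:7) / 10),
    tumor_auc_mol_s_m3 = c(1:7, 3 * (1:7))
  )
  s <- summarize_across_organs(res)
  ctrl <- s[s$arm == "control", ]
  # 7 values 0.1..0.7: median 0.4; type-7 quartiles at positions 2.5 and 5.5
  expect_equal(ctrl$median, 0.4)
  expect_equal(ctrl$q25, 0.25)
  expect_equal(ctrl$q75, 0.55)
  expect_equal(s$fold_median[s$arm == "treated"], 2)
  fc <- fold_change_by_organ(res)
  expect_true(all(fc$fold[fc$arm == "treated"] == 3))
  expect_true(all(fc$fold[fc$arm == "control"] == 1))
  bad <- res[-14, ]
  expect_error(summarize_across_organs(bad), "organ set")
})
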