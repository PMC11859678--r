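fast_num <- list(mesh_spacing = 2e-4, dt = 10, t_f = 300, snapshot_every = 1000L)

test_that("scenario resolution applies transforms in the documented order", {
  spec <- scenario_spec("combo", bevacizumab_dose = 5,
                        permeability_multiplier = 2)
  p <- resolve_parameters(spec)
  expect_equal(p$P_c, 1.43e-6 * 2 * 0.78) # sweep scales baseline, then -22%
  expect_equal(p$S_over_V, 2e4 * 0.35)
  expect_equal(p$P_i, 250)
  stiff <- resolve_parameters(scenario_spec("s", collagen = "high"))
  expect_equal(stiff$D, 1.5e-9)
  expect_error(scenario_spec("x", bevacizumab_dose = 2), "unsupported")
  expect_error(scenario_spec("x", collagen = "medium"), "collagen")
})

test_that("a control-only config over 7 organs and 2 setups yields 14 cells", {
  cfg <- experiment_config("figure3_organ_sweep")
  cfg$scenarios <- cfg$scenarios[cfg$scenarios$arm == "control", ]
  cells <- list_scenarios(cfg)
  expect_equal(nrow(cells), 14L)
  res <- run_experiment(cfg, numerics = fast_num)
  expect_equal(nrow(res), 14L)
  expect_false("error" %in% names(res))
  expect_true(all(res$tumor_auc_mol_s_m3 > 0))
  expect_true(all(res$d_eff_norm >= 0 & res$d_eff_norm <= 1))
  expect_true(all(res$pa > 0))
})

test_that("an identical configuration reproduces results bit-identically", {
  cfg <- experiment_config("figure4_stiffness")
  cfg$scenarios <- cfg$scenarios[1:2, ]
  r1 <- run_experiment(cfg, numerics = fast_num)
  r2 <- run_experiment(cfg, numerics = fast_num)
  expect_identical(r1, r2)
})

test_that("configs validate and round-trip; bad organs are rejected", {
  for (nm in c("figure3_organ_sweep", "figure4_stiffness",
               "figure4_permeability", "figure5_dose_equivalence")) {
    expect_true(validate_config(experiment_config(nm)))
  }
  cfg <- experiment_config("figure4_stiffness")
  cfg$organs <- "gallbladder"
  expect_error(validate_config(cfg), "unknown organ")
})

test_that("every result row carries a resolved-parameter hash", {
  cfg <- experiment_config("figure3_organ_sweep")
  cfg$scenarios <- cfg$scenarios[cfg$scenarios$arm != "bev_5", ]
  cfg$organs <- "intestine"
  cfg$setups <- 1L
  res <- run_experiment(cfg, numerics = fast_num)
  expect_true(all(nchar(res$scenario_hash) == 32L))
  expect_equal(length(unique(res$scenario_hash)), nrow(res))
})

test_that("normothermic perfusion evaluates at 37 degC and penetrates less", {
  hip <- run_scenario(scenario_spec("h"), "stomach", 1, numerics = fast_num)
  ipe <- run_scenario(scenario_spec("i", modality = "IPEC"), "stomach", 1,
                      numerics = fast_num)
  expect_equal(ipe$eval_temp_c, 37)
  expect_equal(ipe$ic50_uM, 537.7)
  expect_equal(hip$eval_temp_c, 41.7)
  expect_lt(ipe$d_eff_m, hip$d_eff_m)
  expect_lt(ipe$tumor_auc_mol_s_m3, hip$tumor_auc_mol_s_m3)
})

test_that("failing cells are recorded without aborting the run", {
  cfg <- experiment_config("figure4_stiffness")
  cfg$scenarios <- cfg$scenarios[1, ]
  bad <- modifyList(fast_num, list(dt = -1)) # invalid time step
  res <- run_experiment(cfg, numerics = bad)
  expect_true("error" %in% names(res))
  expect_match(res$error[1], "dt")
})

test_that("results can be written to disk alongside a provenance summary", {
  dir <- withr::local_tempdir()
  cfg <- experiment_config("figure4_stiffness")
  cfg$scenarios <- cfg$scenarios[1, ]
  run_experiment(cfg, numerics = fast_num, output_dir = dir)
  expect_true(file.exists(file.path(dir, "results.csv")))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$config, "figure4_stiffness")
})
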