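test_that("fractional inhibition is the clipped relative complex reduction", {
  expect_equal(inhibition(2, 1), 0.5)
  expect_equal(inhibition(2, 2), 0)
  expect_equal(inhibition(2, 0), 1)
  expect_equal(inhibition(2, 2 + 1e-15), 0)   # clipped at tolerance
  expect_error(inhibition(0, 1), class = "igfnet_undefined_inhibition")
})

test_that("a zero-dose antibody reproduces the baseline", {
  ctx <- ab_baseline_context()
  trt <- treatment(concentration = 0.25)
  base <- steady_state(trt, ctx)
  for (tgt in c("ligand", "receptor")) {
    with_ab <- simulate_antibody_scenario(trt, ctx,
                                          antibody(tgt, kd = 1, dose = 0))
    expect_equal(with_ab$state[["c1_1r"]], base$state[["c1_1r"]],
                 tolerance = 1e-8)
  }
})

test_that("a huge high-affinity receptor blocker abolishes receptor occupancy", {
  ctx <- ab_baseline_context()
  trt <- treatment(concentration = 0.25)
  base <- steady_state(trt, ctx)
  blocked <- simulate_antibody_scenario(
    trt, ctx, antibody("receptor", kd = 0.01, dose = 1000))
  expect_lt(blocked$state[["c1_1r"]], 0.01 * base$state[["c1_1r"]])
})

test_that("a ligand antibody with IGFBP-matched affinity and dose acts like doubling IGFBP", {
  ctx <- ref_context()
  trt <- treatment(concentration = 0.25)
  tbp <- igfbp_total_nM(ctx)
  via_ab <- simulate_antibody_scenario(
    trt, ctx, antibody("ligand", kd = 0.1, dose = tbp, k_on = 1))
  doubled <- steady_state(trt, cellular_context(igfbp_per_cell = 2 * 1.21e-8))
  expect_equal(via_ab$state[["c1_1r"]], doubled$state[["c1_1r"]],
               tolerance = 1e-6)
})

test_that("scenario grids validate their axes and produce the full Cartesian sweep", {
  expect_error(scenario_grid(antibody_kds = numeric(0)),
               class = "igfnet_invalid_grid")
  expect_error(scenario_grid(igfbp_multipliers = -1),
               class = "igfnet_invalid_grid")
  g <- scenario_grid(antibody_kds = c(0.1, 10), antibody_doses = c(1, 100),
                     igf1_levels = 0.1, igfbp_multipliers = c(0.1, 10))
  res <- run_test_matrix(g)
  expect_equal(nrow(res), 2 * 2 * 1 * 2)
  expect_true(all(is.na(res$error)))
  expect_true(all(res$inhibition_ligand >= 0 & res$inhibition_ligand <= 1))
  expect_true(all(res$inhibition_receptor >= 0 &
                    res$inhibition_receptor <= 1))
})

test_that("inhibition responds monotonically to dose, affinity and IGFBP level", {
  res <- run_test_matrix(
    scenario_grid(antibody_kds = c(0.1, 1, 10),
                  antibody_doses = c(0.1, 1, 10),
                  igf1_levels = 0.1,
                  igfbp_multipliers = c(0.1, 1, 10)))
  tol <- 1e-6
  # non-decreasing in dose, for each (kd, bp) cell
  by_dose <- dplyr::group_by(dplyr::arrange(res, antibody_dose_nM),
                             antibody_kd_nM, igfbp_multiplier)
  expect_true(all(dplyr::summarise(
    by_dose, ok = all(diff(inhibition_ligand) >= -tol) &
      all(diff(inhibition_receptor) >= -tol), .groups = "drop")$ok))
  # non-increasing in Kd (weaker affinity)
  by_kd <- dplyr::group_by(dplyr::arrange(res, antibody_kd_nM),
                           antibody_dose_nM, igfbp_multiplier)
  expect_true(all(dplyr::summarise(
    by_kd, ok = all(diff(inhibition_ligand) <= tol) &
      all(diff(inhibition_receptor) <= tol), .groups = "drop")$ok))
  # more IGFBP: the neutralizing antibody loses ground, the blocker does not
  by_bp <- dplyr::group_by(dplyr::arrange(res, igfbp_multiplier),
                           antibody_kd_nM, antibody_dose_nM)
  expect_true(all(dplyr::summarise(
    by_bp, ok = all(diff(inhibition_ligand) <= tol) &
      all(diff(inhibition_receptor) >= -tol), .groups = "drop")$ok))
  # headline claim: blocking beats neutralizing in every scenario
  expect_true(all(res$inhibition_receptor >= res$inhibition_ligand - tol))
})

test_that("fresh media yields more receptor occupancy than conditioned media", {
  d <- tibble::tibble(per_cell_complexes = c(0, 1e-11, 2e-11),
                      delta_proliferation = c(2, 6, 10))
  map <- fit_proliferation_map(d, max_per_cell = 2.23e-11)
  cmp <- compare_media_scenarios(0.25, ref_context(), map = map)
  expect_equal(cmp$media, c("conditioned", "fresh"))
  expect_gt(cmp$complexes_nM[2], cmp$complexes_nM[1])
  expect_gte(cmp$predicted_proliferation[2], cmp$predicted_proliferation[1])
  # degenerate equality: no IGFBPs in the conditioned scenario
  cmp0 <- compare_media_scenarios(0.25,
                                  cellular_context(igfbp_per_cell = 0))
  expect_equal(cmp0$complexes_nM[1], cmp0$complexes_nM[2], tolerance = 1e-9)
  # zero dose: nothing to bind, both predictions collapse to the intercept
  cmp_zero <- compare_media_scenarios(0, ref_context(), map = map)
  expect_equal(cmp_zero$predicted_proliferation, rep(map$intercept, 2))
})
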