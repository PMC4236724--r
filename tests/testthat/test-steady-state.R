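test_that("initial conditions come from treatment, context and antibody dose", {
  ctx <- ref_context()
  ini <- build_initial_state(treatment(concentration = 0.25), ctx)
  expect_equal(ini[["c1"]], 0.25)
  expect_equal(ini[["c1r"]], REF_TR)
  expect_equal(ini[["cbp"]], REF_TBP)
  expect_equal(ini[["c1_1r"]], 0)
  expect_equal(ini[["c1_bp"]], 0)

  fresh <- build_initial_state(treatment(concentration = 0.25,
                                         media = "fresh"), ctx)
  expect_equal(fresh[["cbp"]], 0)

  zero <- build_initial_state(treatment(concentration = 0), ctx)
  expect_equal(zero[["c1"]], 0)

  ab <- antibody("receptor", kd = 1, dose = 5)
  ini_ab <- build_initial_state(treatment(concentration = 0.25), ctx, ab)
  expect_equal(ini_ab[["c_ab"]], 5)
  expect_equal(ini_ab[["c1r_ab"]], 0)
})

test_that("the closed-form oracle matches the single-binder quadratic", {
  eq <- equilibrium_oracle(0.25, 0, REF_TBP, 1, 0.1)
  expect_equal(eq[["c1_bp"]], quadratic_complex(0.25, REF_TBP, 0.1),
               tolerance = 1e-10)
  expect_equal(eq[["c1_bp"]], 0.2303650, tolerance = 1e-6)
  expect_equal(eq[["c1_bp"]] / 0.25, 0.9214599, tolerance = 1e-6)
  # no binders: everything stays free
  eq0 <- equilibrium_oracle(0.25, 0, 0, 1, 0.1)
  expect_equal(eq0[["c1"]], 0.25)
  expect_equal(eq0[["c1_1r"]] + eq0[["c1_bp"]], 0)
  # receptor-only reduces to its quadratic too
  eq_r <- equilibrium_oracle(0.5, 2, 0, 1, 0.1)
  expect_equal(eq_r[["c1_1r"]], quadratic_complex(0.5, 2, 1),
               tolerance = 1e-10)
})

test_that("the oracle solves the full two-binder equilibrium", {
  eq <- equilibrium_oracle(0.25, REF_TR, REF_TBP, 1, 0.1)
  expect_equal(eq[["c1"]], 0.01963042, tolerance = 1e-6)
  expect_equal(eq[["c1_1r"]], 4.980232e-05, tolerance = 1e-6)
  # conservation and Kd balance hold exactly
  expect_equal(eq[["c1"]] + eq[["c1_1r"]] + eq[["c1_bp"]], 0.25,
               tolerance = 1e-9)
  expect_equal(eq[["c1"]] * eq[["c1r"]] / eq[["c1_1r"]], 1,
               tolerance = 1e-9)
  expect_equal(eq[["c1"]] * eq[["cbp"]] / eq[["c1_bp"]], 0.1,
               tolerance = 1e-9)
  expect_error(
    equilibrium_oracle(1, 1, 1, 1, 0.1,
                       antibody("receptor", kd = 1, dose = 1)),
    class = "igfnet_inconsistent_scenario")
})

test_that("integrator agrees with the oracle across randomized scenarios when depletion is off", {
  set.seed(101)
  for (i in 1:8) {
    T1 <- runif(1, 0, 10); TR <- runif(1, 0, 10); TBP <- runif(1, 0, 10)
    kdr <- 10^runif(1, -2, 1); kdb <- 10^runif(1, -2, 1)
    r <- rate_coefficients(k_neg1 = kdr, k_neg2 = kdb, k3_0 = 0)
    ctx <- cellular_context(igfbp_per_cell = TBP / 116000 / 1000,
                            igf1r_per_cell = TR / 116000 / 1000)
    ss <- steady_state(treatment(concentration = T1), ctx, rates = r,
                       residual_tol = 1e-10)
    eq <- equilibrium_oracle(T1, TR, TBP, kdr, kdb)
    expect_rel_equal(ss$state, eq, tol = 1e-6)
    expect_true(ss$converged)
  }
})

test_that("a ligand-free system stays put with zero residual", {
  ss <- steady_state(treatment(concentration = 0), ref_context())
  expect_equal(ss$state[["c1"]], 0)
  expect_equal(ss$state[["c1_1r"]], 0)
  expect_equal(ss$state[["cbp"]], REF_TBP)
  expect_equal(ss$residual, 0)
  expect_true(ss$converged)
})

test_that("most of a 0.25 nM dose ends up sequestered by IGFBPs in conditioned media", {
  ss <- steady_state(treatment(concentration = 0.25), ref_context())
  expect_true(ss$converged)
  expect_gte(ss$state[["c1_bp"]] / 0.25, 0.90)
  expect_equal(ss$per_cell_complexes,
               concentration_to_per_cell(ss$state[["c1_1r"]], 116000, 1))
})

test_that("steady-state occupancy is monotone in ligand and binding protein", {
  ctx <- ref_context()
  occ_vs_igf1 <- purrr::map_dbl(c(0.05, 0.1, 0.25, 0.5, 1, 2.5), function(t1) {
    steady_state(treatment(concentration = t1), ctx,
                 horizon = 8, max_horizon = 8)$state[["c1_1r"]]
  })
  expect_true(all(diff(occ_vs_igf1) > 0))

  occ_vs_bp <- purrr::map_dbl(c(0.1, 0.5, 1, 2, 10), function(m) {
    cx <- cellular_context(igfbp_per_cell = 1.21e-8 * m)
    steady_state(treatment(concentration = 0.25), cx,
                 horizon = 8, max_horizon = 8)$state[["c1_1r"]]
  })
  expect_true(all(diff(occ_vs_bp) < 0))
})

test_that("occupancy saturates at, and never exceeds, the receptor endowment", {
  ss <- steady_state(treatment(concentration = 100), ref_context())
  expect_lte(ss$per_cell_complexes, 2.23e-11)
  expect_gte(ss$per_cell_complexes, 0.95 * 2.23e-11)
})

test_that("tidy() flattens a steady-state result to one row", {
  td <- tidy(steady_state(treatment(concentration = 0.25), ref_context()))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_true(all(c("c1", "c1_1r", "per_cell_complexes", "residual",
                    "converged") %in% names(td)))
})
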