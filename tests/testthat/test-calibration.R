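test_that("depletion-rate estimation is exact on noise-free exponentials", {
  tc <- tibble::tibble(time = 0:4, free_igf1 = 0.25 * exp(-0.1 * (0:4)))
  expect_equal(estimate_k3_0(tc, 116000, 116000), 0.1)
  # scale invariance in the initial concentration
  tc10 <- dplyr::mutate(tc, free_igf1 = free_igf1 * 10)
  expect_equal(estimate_k3_0(tc10, 116000, 116000), 0.1)
  # rescaling to the reference cell number inverts the proportionality
  expect_equal(estimate_k3_0(tc, 58000, 116000), 0.2)
  # constant series: no depletion
  flat <- tibble::tibble(time = 0:4, free_igf1 = rep(0.25, 5))
  expect_equal(estimate_k3_0(flat, 116000, 116000), 0)
  # two-point half-life agrees with the regression on clean data
  expect_equal(estimate_k3_0(tc, 116000, 116000, method = "halflife"), 0.1)
})

test_that("cell-free control decay is subtracted before rescaling", {
  t <- 0:6
  cells <- tibble::tibble(time = t, free_igf1 = 0.25 * exp(-0.15 * t))
  blank <- tibble::tibble(time = t, free_igf1 = 0.25 * exp(-0.05 * t))
  expect_equal(estimate_k3_0(cells, 116000, 116000,
                             cell_free_control = blank), 0.1)
})

test_that("depletion-rate estimation rejects bad data and warns on growth", {
  expect_error(estimate_k3_0(tibble::tibble(time = 1, free_igf1 = 1),
                             1e5, 1e5),
               class = "igfnet_data_error")
  expect_error(
    estimate_k3_0(tibble::tibble(time = c(0, 0), free_igf1 = c(1, 1)),
                  1e5, 1e5),
    class = "igfnet_data_error")
  expect_error(
    estimate_k3_0(tibble::tibble(time = 0:2, free_igf1 = c(1, 0, 1)),
                  1e5, 1e5),
    class = "igfnet_data_error")
  expect_warning(
    estimate_k3_0(tibble::tibble(time = 0:2, free_igf1 = c(1, 2, 4)),
                  1e5, 1e5),
    "negative")
})

test_that("depletion rate is recovered within 5% from noisy synthetic series", {
  set.seed(202)
  k_true <- 0.017
  ests <- purrr::map_dbl(1:50, function(i) {
    tc <- sim_depletion_timecourse(k_true, 116000, 116000, 0.25,
                                   noise = noise_model(scale = 0.05))
    estimate_k3_0(tc, 116000, 116000)
  })
  expect_lt(abs(mean(ests) - k_true) / k_true, 0.05)
})

test_that("free IGFBP follows from the complex and free ligand by the Kd balance", {
  expect_equal(free_igfbp_from_complex(0.2304, 0.0196, 0.1), 1.1755102,
               tolerance = 1e-7)
  expect_equal(free_igfbp_from_complex(0, 0.5, 0.1), 0)
  expect_equal(free_igfbp_from_complex(0.2, 0.1, 0.1), 0.2)
  expect_error(free_igfbp_from_complex(0.2, 0, 0.1),
               class = "igfnet_division_by_zero")
})

test_that("total IGFBP back-calculation matches hand arithmetic and rejects inconsistency", {
  expect_equal(estimate_total_igfbp(0.25, 0.025, 0.1), 1.125)
  expect_equal(estimate_total_igfbp(0.25, 0.25, 0.1), 0)
  expect_error(estimate_total_igfbp(0.25, 0.3, 0.1),
               class = "igfnet_measurement_inconsistency")
})

test_that("total IGFBP round-trips through the binding equilibrium", {
  # no receptor: exact identity
  for (tbp in c(0.2, REF_TBP, 5)) {
    free <- equilibrium_oracle(0.25, 0, tbp, 1, 0.1)[["c1"]]
    expect_equal(estimate_total_igfbp(0.25, free, 0.1), tbp,
                 tolerance = 1e-8)
  }
  # with the (tiny) receptor pool present the recovery is approximate
  free <- equilibrium_oracle(0.25, REF_TR, REF_TBP, 1, 0.1)[["c1"]]
  expect_equal(estimate_total_igfbp(0.25, free, 0.1), REF_TBP,
               tolerance = 1e-3)
})

test_that("the proliferation map is an OLS line with a saturation cap", {
  d <- tibble::tibble(per_cell_complexes = c(0, 1, 2, 4),
                      delta_proliferation = 2 + 3 * c(0, 1, 2, 4))
  m <- fit_proliferation_map(d, max_per_cell = 10)
  expect_equal(m$slope, 3)
  expect_equal(m$intercept, 2)
  expect_equal(predict_proliferation(m, 4), 14)
  expect_equal(predict_proliferation(m, 0), 2)
  # saturation: anything above the cap predicts like the cap
  expect_equal(predict_proliferation(m, 25), predict_proliferation(m, 10))
  # monotone, bounded above by the capped value
  x <- seq(0, 20, length.out = 50)
  y <- predict_proliferation(m, x)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y <= predict_proliferation(m, 10)))

  expect_error(fit_proliferation_map(d[1, ], 10),
               class = "igfnet_insufficient_data")
  same_x <- tibble::tibble(per_cell_complexes = c(1, 1, 1),
                           delta_proliferation = 1:3)
  expect_error(fit_proliferation_map(same_x, 10),
               class = "igfnet_degenerate_fit")
})

test_that("proliferation-map slope is recovered within 10% from noisy data", {
  true_map <- fit_proliferation_map(
    tibble::tibble(per_cell_complexes = c(0, 2.23e-11),
                   delta_proliferation = c(2, 2 + 3e11 * 2.23e-11)),
    max_per_cell = 2.23e-11)   # slope 3e11 %/(nmol/cell), intercept 2
  set.seed(303)
  x <- seq(1e-12, 2e-11, length.out = 12)
  d <- tibble::tibble(
    per_cell_complexes = x,
    delta_proliferation = predict_proliferation(true_map, x) +
      rnorm(12, sd = 0.5))
  m <- fit_proliferation_map(d, max_per_cell = 2.23e-11)
  expect_lt(abs(m$slope - 3e11) / 3e11, 0.10)
})

test_that("tidy and glance summarise a proliferation map", {
  d <- tibble::tibble(per_cell_complexes = c(0, 1, 2, 4),
                      delta_proliferation = c(2.1, 4.9, 8.2, 13.8))
  m <- fit_proliferation_map(d, max_per_cell = 10)
  td <- tidy(m)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(nrow(glance(m)), 1)
  expect_equal(glance(m)$nobs, 4)
  expect_equal(predict(m, 2), predict_proliferation(m, 2))
})
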