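#' Estimate the cell-mediated depletion rate from a time course
#'
#' Half-life analysis of a free-IGF1 depletion time course measured with no
#' IGFBPs present (fresh serum-free media), where the model predicts a pure
#' exponential decay at rate k3. The default fits a single exponential by
#' least squares on the log concentrations, using every time point; the
#' `"halflife"` method uses only the first and last points, which is the
#' classical two-point half-life calculation and what the regression
#' reduces to on two points. The fitted rate is rescaled to the reference
#' cell number (inverse of [scale_depletion_rate()]). An optional cell-free
#' control time course corrects for losses not mediated by cells (plate
#' adsorption, spontaneous degradation): its fitted decay rate is
#' subtracted before rescaling.
#'
#' @param timecourse Data frame with numeric columns `time` (hours,
#'   strictly increasing, >= 2 points) and `free_igf1` (nM, > 0).
#' @param n_cells Cell number of the measured condition.
#' @param n_ref Reference cell number to which the estimate is scaled.
#' @param cell_free_control Optional data frame with the same columns,
#'   measured without cells.
#' @param method `"regression"` (log-linear least squares, default) or
#'   `"halflife"` (two-point).
#' @return Estimated k3_0 (hr^-1) at the reference cell number.
#' @export
#' @examples
#' tc <- tibble::tibble(time = 0:4, free_igf1 = 0.25 * exp(-0.1 * (0:4)))
#' estimate_k3_0(tc, n_cells = 116000, n_ref = 116000)  # 0.1
estimate_k3_0 <- function(timecourse, n_cells, n_ref,
                          cell_free_control = NULL,
                          method = c("regression", "halflife")) {
  method <- match.arg(method)
  rate <- fit_decay_rate(timecourse, method)
  if (!is.null(cell_free_control)) {
    rate <- rate - fit_decay_rate(cell_free_control, method)
  }
  if (rate < 0) {
    warn("Fitted depletion rate is negative (concentrations increase over time); returning the best-effort estimate.")
  }
  rate * n_ref / n_cells
}

fit_decay_rate <- function(timecourse, method) {
  tc <- as.data.frame(timecourse)
  if (!all(c("time", "free_igf1") %in% names(tc))) {
    abort("Time course needs columns `time` and `free_igf1`.",
          class = "igfnet_data_error")
  }
  t <- tc$time; y <- tc$free_igf1
  if (length(t) < 2) {
    abort("Need at least two time points for half-life analysis.",
          class = "igfnet_data_error")
  }
  if (any(diff(t) <= 0)) {
    abort("`time` must be strictly increasing.", class = "igfnet_data_error")
  }
  if (any(!is.finite(y)) || any(y <= 0)) {
    abort("All concentrations must be positive for the log fit.",
          class = "igfnet_data_error")
  }
  if (method == "halflife") {
    n <- length(t)
    log(y[1] / y[n]) / (t[n] - t[1])
  } else {
    -unname(coef(lm(log(y) ~ t))[2])
  }
}

#' Free IGFBP from the measured complex and free ligand
#'
#' The steady-state balance of the IGF1-IGFBP reaction gives the free
#' binding protein directly from measurable quantities:
#' `CBP = Kd_BP * C1:BP / C1`.
#'
#' @param c1_bp IGF1-IGFBP complex concentration (nM).
#' @param c1 Free IGF1 concentration (nM), > 0.
#' @param kd_bp IGF1-IGFBP dissociation constant (nM).
#' @return Free IGFBP concentration (nM).
#' @export
free_igfbp_from_complex <- function(c1_bp, c1, kd_bp) {
  if (any(c1_bp < 0) || any(kd_bp < 0)) {
    abort("Inputs must be >= 0.", class = "igfnet_data_error")
  }
  if (any(c1 <= 0)) {
    abort("Free IGF1 must be > 0: the steady-state balance divides by it, so the free ligand must be measurable.",
          class = "igfnet_division_by_zero")
  }
  kd_bp * c1_bp / c1
}

#' Total IGFBP level from a conditioned-media equilibrium measurement
#'
#' Back-calculates the total (lumped) IGFBP concentration from a spiked
#' known IGF1 total and the free IGF1 measured at equilibrium: the bound
#' pool is total minus free, the free binding protein follows from the
#' steady-state balance ([free_igfbp_from_complex()]), and the total is
#' their sum. Receptor binding is negligible on this scale (receptor totals
#' are ~500-fold below the IGFBP pool) and is ignored, as in the
#' measurement protocol this mirrors.
#'
#' @param total_igf1_added Spiked IGF1 concentration (nM).
#' @param free_igf1_measured Free IGF1 at equilibrium (nM), in
#'   `(0, total_igf1_added]`.
#' @param kd_bp IGF1-IGFBP dissociation constant (nM).
#' @return Estimated total IGFBP concentration (nM).
#' @export
#' @examples
#' estimate_total_igfbp(0.25, 0.025, 0.1)  # 1.125 nM
estimate_total_igfbp <- function(total_igf1_added, free_igf1_measured,
                                 kd_bp = 0.1) {
  if (any(free_igf1_measured > total_igf1_added)) {
    abort("Measured free IGF1 exceeds the amount added; measurements are inconsistent.",
          class = "igfnet_measurement_inconsistency")
  }
  complex <- total_igf1_added - free_igf1_measured
  complex + free_igfbp_from_complex(complex, free_igf1_measured, kd_bp)
}

#' Fit the linear receptor-occupancy to proliferation map
#'
#' The increase in proliferation over vehicle control rises linearly with
#' the steady-state level of IGF1-IGF1R complexes per cell, up to the
#' saturation of the receptor pool: once every receptor is occupied,
#' further IGF1 produces no further response. This fits the line by
#' ordinary least squares and stores the per-cell receptor endowment as the
#' saturation cap.
#'
#' @param data Data frame with numeric columns `per_cell_complexes`
#'   (nmol/cell) and `delta_proliferation` (percentage points of
#'   proliferation increase over control); >= 2 distinct x values.
#' @param max_per_cell Receptor-saturation cap (nmol/cell), > 0; the
#'   per-cell IGF1R endowment of the cell line.
#' @return An object of class `prolif_map` with fields `slope`
#'   (%/(nmol/cell)), `intercept` (%), `max_per_cell_complexes`
#'   (nmol/cell) and the underlying `lm` fit.
#' @export
#' @examples
#' d <- tibble::tibble(per_cell_complexes = c(0, 1e-11, 2e-11),
#'                     delta_proliferation = c(2, 5, 8))
#' fit_proliferation_map(d, max_per_cell = 2.23e-11)
fit_proliferation_map <- function(data, max_per_cell = 2.23e-11) {
  d <- as.data.frame(data)
  if (!all(c("per_cell_complexes", "delta_proliferation") %in% names(d))) {
    abort("`data` needs columns `per_cell_complexes` and `delta_proliferation`.",
          class = "igfnet_data_error")
  }
  if (nrow(d) < 2) {
    abort("Need at least two points to fit a line.",
          class = "igfnet_insufficient_data")
  }
  if (!is.finite(max_per_cell) || max_per_cell <= 0) {
    abort("`max_per_cell` must be > 0 (nmol/cell).",
          class = "igfnet_data_error")
  }
  if (length(unique(d$per_cell_complexes)) < 2) {
    abort("All x values identical; the fit is degenerate.",
          class = "igfnet_degenerate_fit")
  }
  fit <- lm(delta_proliferation ~ per_cell_complexes, data = d)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         max_per_cell_complexes = max_per_cell, fit = fit),
    class = "prolif_map"
  )
}

#' Predict the proliferation increase from receptor occupancy
#'
#' Applies the fitted linear map, capping the occupancy at the receptor
#' saturation level: predictions are non-decreasing in occupancy and
#' bounded above by the value at the cap.
#'
#' @param map A `prolif_map` from [fit_proliferation_map()].
#' @param per_cell_complexes IGF1-IGF1R complexes per cell (nmol/cell),
#'   vectorized.
#' @return Predicted proliferation increase (percentage points).
#' @export
predict_proliferation <- function(map, per_cell_complexes) {
  stopifnot(inherits(map, "prolif_map"))
  if (any(per_cell_complexes < 0)) {
    abort("Occupancy must be >= 0.", class = "igfnet_data_error")
  }
  map$intercept +
    map$slope * pmin(per_cell_complexes, map$max_per_cell_complexes)
}

#' @export
print.prolif_map <- function(x, ...) {
  cat(sprintf("<prolif_map> proliferation %% = %.4g + %.4g * complexes/cell, capped at %.4g nmol/cell (max %.4g%%)\n",
              x$intercept, x$slope, x$max_per_cell_complexes,
              predict_proliferation(x, x$max_per_cell_complexes)))
  invisible(x)
}

#' @describeIn fit_proliferation_map coefficient table (broom-style), one
#'   row per model term.
#' @param x A `prolif_map`.
#' @param ... Unused.
#' @export
tidy.prolif_map <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = unname(s[, "Std. Error"]),
         statistic = unname(s[, "t value"]),
         p.value = unname(s[, "Pr(>|t|)"]))
}

#' @describeIn fit_proliferation_map one-row model summary: r.squared,
#'   sigma, the saturation cap and the capped maximum response.
#' @export
glance.prolif_map <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, sigma = s$sigma,
         nobs = length(s$residuals),
         max_per_cell_complexes = x$max_per_cell_complexes,
         max_response = predict_proliferation(x, x$max_per_cell_complexes))
}

#' @export
predict.prolif_map <- function(object, per_cell_complexes, ...) {
  predict_proliferation(object, per_cell_complexes)
}
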