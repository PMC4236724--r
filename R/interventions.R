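#' Quasi-steady state under an antibody intervention
#'
#' Runs the extended network -- base system plus the ligand-neutralizing or
#' receptor-blocking antibody reactions -- to the quasi-steady-state
#' readout.
#'
#' @inheritParams steady_state
#' @param ab An [antibody()] spec.
#' @return An `igf_steady_state` object.
#' @export
simulate_antibody_scenario <- function(trt, context, ab,
                                       rates = rate_coefficients(), ...) {
  stopifnot(inherits(ab, "igf_antibody"))
  steady_state(trt, context, rates = rates, antibody = ab, ...)
}

#' Fractional inhibition of receptor occupancy
#'
#' `(baseline - treated) / baseline`, clipped into `[0, 1]` at numerical
#' tolerance. Operationalizes the predicted reduction in proliferative
#' signal caused by an antibody, on the steady-state IGF1-IGF1R complex
#' scale.
#'
#' @param complexes_baseline Steady-state complexes without antibody (nM),
#'   > 0.
#' @param complexes_treated Steady-state complexes with antibody (nM).
#' @return Fractional inhibition in `[0, 1]`.
#' @export
#' @examples
#' inhibition(2, 1)  # 0.5
inhibition <- function(complexes_baseline, complexes_treated) {
  if (any(complexes_baseline <= 0)) {
    abort("Baseline complexes must be > 0 for inhibition to be defined.",
          class = "igfnet_undefined_inhibition")
  }
  pmin(pmax((complexes_baseline - complexes_treated) / complexes_baseline,
            0), 1)
}

#' Antibody scenario grid
#'
#' The Cartesian test matrix over which both antibody types are compared.
#' Defaults reproduce the published design: antibody Kd in {0.1, 1, 10} nM
#' crossed with four doses, low (0.1 nM) and high (2.5 nM) IGF1, IGFBP
#' totals at 0.1x, 1x and 10x the measured level, on the 67,000 cells/well
#' baseline. The four antibody doses are not printed in the source design;
#' {0.1, 1, 10, 100} nM is a log-spaced default bracketing the ligand and
#' IGFBP concentration scales.
#'
#' @param antibody_kds Antibody dissociation constants (nM).
#' @param antibody_doses Initial antibody concentrations (nM).
#' @param igf1_levels Applied IGF1 concentrations (nM).
#' @param igfbp_multipliers Scale factors on the measured IGFBP total.
#' @param igf1r_multipliers Scale factors on the measured IGF1R total.
#' @param base_context Baseline [cellular_context()].
#' @return An object of class `igf_scenario_grid`.
#' @export
scenario_grid <- function(antibody_kds = c(0.1, 1, 10),
                          antibody_doses = c(0.1, 1, 10, 100),
                          igf1_levels = c(0.1, 2.5),
                          igfbp_multipliers = c(0.1, 1, 10),
                          igf1r_multipliers = 1,
                          base_context = cellular_context(n_cells = 67000)) {
  axes <- list(antibody_kds = antibody_kds, antibody_doses = antibody_doses,
               igf1_levels = igf1_levels,
               igfbp_multipliers = igfbp_multipliers,
               igf1r_multipliers = igf1r_multipliers)
  for (nm in names(axes)) {
    ax <- axes[[nm]]
    if (length(ax) == 0 || any(!is.finite(ax)) || any(ax < 0)) {
      abort(sprintf("Grid axis `%s` must be non-empty, finite and >= 0.", nm),
            class = "igfnet_invalid_grid")
    }
  }
  stopifnot(inherits(base_context, "igf_context"))
  structure(c(axes, list(base_context = base_context)),
            class = "igf_scenario_grid")
}

scaled_context <- function(context, bp_mult, r_mult) {
  cellular_context(n_cells = context$n_cells, n_ref = context$n_ref,
                   volume = context$volume,
                   igfbp_per_cell = context$igfbp_per_cell * bp_mult,
                   igf1r_per_cell = context$igf1r_per_cell * r_mult)
}

#' Run the full antibody test matrix
#'
#' Evaluates every cell of the scenario grid: for each combination of
#' antibody Kd, dose, IGF1 level and IGFBP/IGF1R multiplier, computes the
#' quasi-steady-state IGF1-IGF1R complex level without antibody, with the
#' IGF1-neutralizing antibody and with the IGF1R-blocking antibody, the
#' fractional inhibition achieved by each, and the neutralizing-to-blocking
#' inhibition ratio. A ratio below 1 means the receptor-blocking antibody
#' suppresses receptor occupancy more strongly. Rows where the blocking
#' inhibition is numerically zero report the ratio as `NA` rather than
#' dividing by ~0; a failed scenario is recorded in its row's `error`
#' column without aborting the sweep.
#'
#' @param grid An [scenario_grid()].
#' @param rates An [rate_coefficients()] object.
#' @param ... Passed to [integrate_to_steady_state()] (e.g. `horizon`).
#' @return A tibble, one row per grid cell, in deterministic
#'   (column-major over the axes as listed) order, with the scenario
#'   descriptors, `complexes_baseline`, `complexes_ligand_ab`,
#'   `complexes_receptor_ab` (nM), `inhibition_ligand`,
#'   `inhibition_receptor`, `inhibition_ratio`, the common readout
#'   `horizon` (hours) and `error`.
#' @export
#' @examples
#' \donttest{
#' res <- run_test_matrix(scenario_grid())
#' max(res$inhibition_ratio, na.rm = TRUE)  # < 1: blocking antibody wins
#' }
run_test_matrix <- function(grid, rates = rate_coefficients(), ...) {
  stopifnot(inherits(grid, "igf_scenario_grid"))
  cells <- tidyr::expand_grid(
    igf1r_multiplier = grid$igf1r_multipliers,
    igfbp_multiplier = grid$igfbp_multipliers,
    igf1_nM = grid$igf1_levels,
    antibody_dose_nM = grid$antibody_doses,
    antibody_kd_nM = grid$antibody_kds
  )

  # baselines depend only on (igf1, bp multiplier, r multiplier)
  base_key <- function(igf1, bp, r) paste(igf1, bp, r, sep = "|")

  run_row_at <- function(baselines, fixed_h,
                         antibody_kd_nM, antibody_dose_nM, igf1_nM,
                         igfbp_multiplier, igf1r_multiplier) {
    ctx <- scaled_context(grid$base_context, igfbp_multiplier,
                          igf1r_multiplier)
    trt <- treatment(concentration = igf1_nM)
    dots <- list(...)
    extra <- if (is.null(fixed_h)) dots else {
      c(list(horizon = fixed_h, max_horizon = fixed_h),
        dots[setdiff(names(dots), c("horizon", "max_horizon"))])
    }
    key <- base_key(igf1_nM, igfbp_multiplier, igf1r_multiplier)
    if (is.null(baselines[[key]])) {
      baselines[[key]] <- do.call(
        steady_state, c(list(trt, ctx, rates = rates), extra))
    }
    ab_l <- antibody("ligand", kd = antibody_kd_nM, dose = antibody_dose_nM)
    ab_r <- antibody("receptor", kd = antibody_kd_nM,
                     dose = antibody_dose_nM)
    runs <- list(
      base = baselines[[key]],
      lig = do.call(steady_state,
                    c(list(trt, ctx, rates = rates, antibody = ab_l),
                      extra)),
      rec = do.call(steady_state,
                    c(list(trt, ctx, rates = rates, antibody = ab_r),
                      extra))
    )
    base <- runs$base$state[["c1_1r"]]
    inh_l <- inhibition(base, runs$lig$state[["c1_1r"]])
    inh_r <- inhibition(base, runs$rec$state[["c1_1r"]])
    tibble(
      complexes_baseline = base,
      complexes_ligand_ab = runs$lig$state[["c1_1r"]],
      complexes_receptor_ab = runs$rec$state[["c1_1r"]],
      inhibition_ligand = inh_l, inhibition_receptor = inh_r,
      inhibition_ratio = if (inh_r > 1e-12) inh_l / inh_r else NA_real_,
      horizon = max(purrr::map_dbl(runs, "horizon")),
      error = NA_character_
    )
  }
  run_pass <- function(fixed_h) {
    baselines <- new.env(parent = emptyenv())
    safe_row <- function(...) {
      tryCatch(run_row_at(baselines, fixed_h, ...), error = function(e) {
        tibble(complexes_baseline = NA_real_,
               complexes_ligand_ab = NA_real_,
               complexes_receptor_ab = NA_real_,
               inhibition_ligand = NA_real_, inhibition_receptor = NA_real_,
               inhibition_ratio = NA_real_, horizon = NA_real_,
               error = conditionMessage(e))
      })
    }
    purrr::pmap_dfr(cells, safe_row)
  }

  # depletion erodes complexes over time, so every scenario in the matrix
  # must be read out at a common time: first find the horizon the slowest
  # scenario needs, then recompute the whole sweep at that horizon
  first <- run_pass(NULL)
  h_common <- max(first$horizon, na.rm = TRUE)
  out <- if (all(first$horizon == h_common, na.rm = TRUE)) {
    first
  } else {
    run_pass(h_common)
  }
  dplyr::bind_cols(cells, out)
}

#' Predicted proliferation in conditioned versus fresh media
#'
#' Solves the model for the same IGF1 treatment under the IGFBP-positive
#' (conditioned media) and IGFBP-negative (fresh serum-free media)
#' scenarios. With no IGFBPs to sequester the ligand, more IGF1 is free to
#' occupy the receptor, so the fresh-media complex level -- and the
#' predicted proliferation, when a [fit_proliferation_map()] is supplied --
#' is at least as large as the conditioned-media one.
#'
#' @param concentration Applied IGF1 concentration (nM).
#' @param context An [cellular_context()].
#' @param map Optional `prolif_map`; adds a `predicted_proliferation`
#'   column.
#' @param rates An [rate_coefficients()] object.
#' @param ... Passed to [integrate_to_steady_state()].
#' @return A two-row tibble (`media` = "conditioned", "fresh") with
#'   `complexes_nM`, `per_cell_complexes` and optionally
#'   `predicted_proliferation`.
#' @export
#' @examples
#' \donttest{
#' compare_media_scenarios(0.25, cellular_context())
#' }
compare_media_scenarios <- function(concentration, context, map = NULL,
                                    rates = rate_coefficients(), ...) {
  run <- function(media) {
    steady_state(treatment(concentration = concentration, media = media),
                 context, rates = rates, ...)
  }
  res <- purrr::map(c(conditioned = "conditioned", fresh = "fresh"), run)
  # both scenarios are read out at the same time point for a fair contrast
  h <- max(purrr::map_dbl(res, "horizon"))
  res <- purrr::map(names(res), function(m) {
    if (res[[m]]$horizon == h) res[[m]] else
      steady_state(treatment(concentration = concentration, media = m),
                   context, rates = rates, horizon = h, max_horizon = h, ...)
  })
  out <- tibble(
    media = c("conditioned", "fresh"),
    complexes_nM = purrr::map_dbl(res, function(r) unname(r$state[["c1_1r"]])),
    per_cell_complexes = unname(purrr::map_dbl(res, "per_cell_complexes"))
  )
  if (!is.null(map)) {
    out$predicted_proliferation <-
      predict_proliferation(map, out$per_cell_complexes)
  }
  out
}
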