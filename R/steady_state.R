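#' Initial conditions for a scenario
#'
#' Complexes start at zero; free IGF1 comes from the treatment (converting
#' a pmol dose through the media volume if needed); free IGF1R and IGFBP
#' start at their total concentrations, converted from the per-cell
#' endowments of the context. Fresh serum-free media has no accumulated
#' cell-secreted IGFBPs, so `media = "fresh"` zeroes the IGFBP pool. A
#' supplied antibody starts entirely free, at its dose.
#'
#' @param trt An [treatment()] object.
#' @param context An [cellular_context()] object.
#' @param antibody Optional [antibody()] spec.
#' @return A named concentration vector (nM), see [species_state()].
#' @export
#' @examples
#' build_initial_state(treatment(concentration = 0.25), cellular_context())
build_initial_state <- function(trt, context, antibody = NULL) {
  c1 <- treatment_concentration(trt, context)
  cbp <- if (trt$media == "fresh") 0 else igfbp_total_nM(context)
  args <- list(c1 = c1, c1r = igf1r_total_nM(context), cbp = cbp)
  if (!is.null(antibody)) {
    args$c_ab <- antibody$dose
    if (antibody$target == "ligand") args$c1_ab <- 0 else args$c1r_ab <- 0
  }
  do.call(species_state, args)
}

desolve_rhs <- function(t, y, parms) {
  list(igf_derivatives(y, parms$rates, parms$k3, parms$antibody))
}

#' Simulate a time course of the binding network
#'
#' Integrates the mass-action system with the stiff implicit Runge-Kutta
#' method (RADAU5, via [deSolve::radau()]). Species concentrations span
#' roughly six orders of magnitude (receptor ~2.6e-3 nM against IGFBP
#' ~1.4 nM at reference density), hence the tight default tolerances.
#'
#' @param initial Named initial state from [build_initial_state()] or
#'   [species_state()].
#' @param rates An [rate_coefficients()] object.
#' @param context An [cellular_context()]; sets the depletion rate via
#'   [scale_depletion_rate()].
#' @param antibody Optional [antibody()] spec, consistent with `initial`.
#' @param times Output time grid (hours).
#' @param rtol,atol Relative / absolute integrator tolerances.
#' @return A tibble with a `time` column (hours) and one column per
#'   species (nM).
#' @export
#' @examples
#' ini <- build_initial_state(treatment(concentration = 0.25),
#'                            cellular_context())
#' tc <- simulate_timecourse(ini, rate_coefficients(), cellular_context(),
#'                           times = seq(0, 2, by = 0.25))
simulate_timecourse <- function(initial, rates, context, antibody = NULL,
                                times = seq(0, 2, by = 0.05),
                                rtol = 1e-8, atol = 1e-12) {
  check_state_antibody(initial, antibody)
  if (length(times) < 2 || any(diff(times) <= 0)) {
    abort("`times` must be an increasing grid with at least two points.",
          class = "igfnet_invalid_times")
  }
  k3 <- scale_depletion_rate(rates$k3_0, context$n_cells, context$n_ref)
  parms <- list(rates = rates, k3 = k3, antibody = antibody)
  sol <- deSolve::radau(y = initial, times = times, func = desolve_rhs,
                        parms = parms, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    abort("Stiff integration failed; see deSolve diagnostics.",
          class = "igfnet_integration_failure")
  }
  as_tibble(as.data.frame(unclass(sol)))
}

#' Integrate to the quasi-steady-state readout
#'
#' Runs the network until the binding reactions have equilibrated and
#' reports the state there. With the slow depletion drain active the
#' literal system only reaches steady state at full ligand exhaustion, so
#' "quasi-steady state" here means: the binding-reaction residual -- each
#' species' |dC/dt| computed with the depletion term switched off -- is
#' either below `residual_tol` or attributable to the slow drain itself.
#' Once the binding reactions ride the slow manifold, every species'
#' fractional drift rate is bounded by the fractional drain rate k3 (each
#' complex tracks the slowly shrinking free-ligand pool no faster than the
#' pool itself shrinks), so the per-species convergence test is
#' `|dCi/dt| <= max(residual_tol, 2 * k3 * Ci)`, with the factor 2 as a
#' safety margin.
#'
#' Integration starts at the `horizon` readout time (default 2 hours, the
#' timescale on which the binding reactions largely equilibrate at the
#' reference parameters) and, if the test fails there, continues in
#' horizon-doubling stages up to `max_horizon`. Setting
#' `max_horizon = horizon` pins a fixed-horizon readout. Tiny negative
#' excursions from the integrator are clipped to zero when no larger in
#' magnitude than `10 * atol`; in strict mode, or beyond that bound, they
#' raise an error.
#'
#' @inheritParams simulate_timecourse
#' @param horizon First readout time checked (hours), > 0.
#' @param max_horizon Upper limit on the adaptive extension (hours).
#' @param residual_tol Convergence threshold on the binding-reaction
#'   residual (nM/hr).
#' @param strict Error on any negative concentration instead of clipping.
#' @return An object of class `igf_steady_state` with fields `state`
#'   (named nM vector), `horizon` (hours actually used),
#'   `per_cell_complexes` (nmol/cell), `residual` (nM/hr), `converged`,
#'   `clipped`, and the `context` used.
#' @export
integrate_to_steady_state <- function(initial, rates, context,
                                      antibody = NULL, horizon = 2,
                                      max_horizon = 1e4,
                                      rtol = 1e-8, atol = 1e-12,
                                      residual_tol = 1e-9, strict = FALSE) {
  if (!is.finite(horizon) || horizon <= 0) {
    abort("`horizon` must be > 0 (hours).", class = "igfnet_invalid_times")
  }
  max_horizon <- max(max_horizon, horizon)
  k3 <- scale_depletion_rate(rates$k3_0, context$n_cells, context$n_ref)

  binding_rates <- function(st) {
    abs(igf_derivatives(st, rates, k3 = 0, antibody))
  }
  is_converged <- function(st) {
    all(binding_rates(st) <= pmax(residual_tol, 2 * k3 * st))
  }

  state <- initial
  t_now <- 0
  t_next <- horizon
  repeat {
    tc <- simulate_timecourse(state, rates, context, antibody,
                              times = c(t_now, t_next),
                              rtol = rtol, atol = atol)
    state <- unlist(tc[nrow(tc), names(initial)])
    t_now <- t_next
    if (is_converged(pmax(state, 0)) || t_now >= max_horizon) break
    t_next <- min(2 * t_now, max_horizon)
  }

  clipped <- FALSE
  neg <- state < 0
  if (any(neg)) {
    if (strict || any(state < -10 * atol)) {
      abort(sprintf("Negative concentration at horizon (min %.3g nM).",
                    min(state)),
            class = "igfnet_negative_concentration")
    }
    state[neg] <- 0
    clipped <- TRUE
  }

  structure(
    list(state = state, horizon = t_now,
         per_cell_complexes = concentration_to_per_cell(
           state[["c1_1r"]], context$n_cells, context$volume),
         residual = max(binding_rates(state)),
         converged = is_converged(state),
         clipped = clipped, context = context),
    class = "igf_steady_state"
  )
}

#' One-call quasi-steady-state for a treatment
#'
#' Convenience wrapper: builds the initial state for a treatment, context
#' and optional antibody, then calls [integrate_to_steady_state()].
#'
#' @inheritParams build_initial_state
#' @inheritParams integrate_to_steady_state
#' @param rates An [rate_coefficients()] object.
#' @param ... Passed on to [integrate_to_steady_state()].
#' @return An `igf_steady_state` object.
#' @export
#' @examples
#' ss <- steady_state(treatment(concentration = 0.25), cellular_context())
#' ss$state[["c1_bp"]] / 0.25   # fraction of applied IGF1 sequestered
steady_state <- function(trt, context, rates = rate_coefficients(),
                         antibody = NULL, ...) {
  ini <- build_initial_state(trt, context, antibody)
  integrate_to_steady_state(ini, rates, context, antibody, ...)
}

#' @export
print.igf_steady_state <- function(x, ...) {
  cat(sprintf("<igf_steady_state> at %g h (residual %.3g nM/hr, %s)\n",
              x$horizon, x$residual,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$state, 6))
  cat(sprintf("  IGF1-IGF1R complexes per cell: %.4g nmol/cell\n",
              x$per_cell_complexes))
  invisible(x)
}

#' @describeIn integrate_to_steady_state one-row tibble of species
#'   concentrations plus the per-cell complex level, residual and
#'   convergence flag.
#' @param x An `igf_steady_state` object.
#' @export
tidy.igf_steady_state <- function(x, ...) {
  dplyr::bind_cols(
    as_tibble(as.list(x$state)),
    tibble(per_cell_complexes = x$per_cell_complexes,
           horizon = x$horizon, residual = x$residual,
           converged = x$converged)
  )
}

#' Closed-form binding equilibrium (independent oracle)
#'
#' Solves the binding equilibrium of the network without depletion
#' (k3 = 0) directly from the conservation relations, independent of any
#' ODE integration. Free IGF1 `C` is the unique root of
#' `C * (1 + TR/(KdR + C) + TBP/(KdBP + C) [+ TAb/(KdAb + C)]) = T1`,
#' a strictly increasing function of `C` bracketed by `[0, T1]`; the bound
#' pools follow from the Kd balances. With a single binder this reduces to
#' the usual quadratic for the complex. Serves as the verification oracle
#' for the integrator and as the model behind equilibrium free-IGF1
#' measurements in conditioned media.
#'
#' Only a ligand-binding (IGF1-neutralizing) antibody fits this
#' one-dimensional reduction; a receptor-blocking antibody couples two
#' conservation equations and is handled by the ODE route instead.
#'
#' @param total_igf1,total_igf1r,total_igfbp Total moiety concentrations
#'   (nM), >= 0.
#' @param kd_receptor,kd_bp Dissociation constants (nM), > 0.
#' @param antibody Optional ligand-targeting [antibody()]; its `dose` is
#'   the total antibody concentration.
#' @return A named species concentration vector (nM).
#' @export
#' @examples
#' eq <- equilibrium_oracle(0.25, 0, 1.4036, 1, 0.1)
#' eq[["c1_bp"]] / 0.25   # ~0.9215: fraction sequestered by IGFBPs
equilibrium_oracle <- function(total_igf1, total_igf1r, total_igfbp,
                               kd_receptor, kd_bp, antibody = NULL) {
  if (total_igf1 < 0 || total_igf1r < 0 || total_igfbp < 0) {
    abort("Totals must be >= 0.", class = "igfnet_invalid_state")
  }
  if (kd_receptor <= 0 || kd_bp <= 0) {
    abort("Kd values must be > 0.", class = "igfnet_invalid_rates")
  }
  if (!is.null(antibody) && antibody$target != "ligand") {
    abort("The closed-form oracle supports only a ligand-targeting antibody.",
          class = "igfnet_inconsistent_scenario")
  }
  t_ab <- if (is.null(antibody)) 0 else antibody$dose
  kd_ab <- if (is.null(antibody)) 1 else antibody$kd

  bound_factor <- function(c1) {
    1 + total_igf1r / (kd_receptor + c1) + total_igfbp / (kd_bp + c1) +
      if (t_ab > 0) t_ab / (kd_ab + c1) else 0
  }
  c1 <- if (total_igf1 == 0) 0 else {
    f <- function(x) x * bound_factor(x) - total_igf1
    uniroot(f, c(0, total_igf1), tol = .Machine$double.eps^0.75)$root
  }

  c1_1r <- total_igf1r * c1 / (kd_receptor + c1)
  c1_bp <- total_igfbp * c1 / (kd_bp + c1)
  out <- c(c1 = c1, c1r = total_igf1r - c1_1r, c1_1r = c1_1r,
           cbp = total_igfbp - c1_bp, c1_bp = c1_bp)
  if (!is.null(antibody)) {
    c1_ab <- t_ab * c1 / (kd_ab + c1)
    out <- c(out, c_ab = t_ab - c1_ab, c1_ab = c1_ab)
  }
  out
}
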