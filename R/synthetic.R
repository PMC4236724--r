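#' Measurement noise model for synthetic data
#'
#' Concentration assays (ELISA-type) have positive, roughly
#' multiplicative error, modelled as mean-preserving lognormal noise with a
#' given coefficient of variation; proliferation readouts (flow-cytometry
#' percentages) have symmetric error, modelled as additive gaussian noise
#' with a given standard deviation in percentage points.
#'
#' @param kind `"lognormal"` (multiplicative, `scale` = CV) or
#'   `"gaussian"` (additive, `scale` = sd in output units).
#' @param scale Noise scale, >= 0. Defaults to CV 0.05 for lognormal.
#' @param seed Optional integer; when set, generators using this model are
#'   reproducible.
#' @return An object of class `igf_noise`.
#' @export
noise_model <- function(kind = c("lognormal", "gaussian"), scale = NULL,
                        seed = NULL) {
  kind <- match.arg(kind)
  scale <- scale %||% if (kind == "lognormal") 0.05 else 0.5
  if (!is.finite(scale) || scale < 0) {
    abort("Noise `scale` must be >= 0.", class = "igfnet_invalid_noise")
  }
  structure(list(kind = kind, scale = scale, seed = seed),
            class = "igf_noise")
}

apply_noise <- function(x, noise) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  if (noise$scale == 0) return(x)
  n <- length(x)
  if (noise$kind == "lognormal") {
    sdlog <- sqrt(log(1 + noise$scale^2))
    x * rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    x + rnorm(n, sd = noise$scale)
  }
}

#' Synthetic IGF1 depletion time course
#'
#' Emulates measuring free IGF1 over time in fresh serum-free media (no
#' IGFBPs): an exponential decay at the cell-number-scaled depletion rate,
#' with assay noise. The noise-free output round-trips exactly through
#' [estimate_k3_0()].
#'
#' @param k3_0 True depletion rate at the reference cell number (hr^-1).
#' @param n_cells,n_ref Cell numbers, as in [scale_depletion_rate()].
#' @param initial_igf1 Spiked IGF1 concentration (nM).
#' @param times Sampling times (hours), non-empty.
#' @param noise A [noise_model()].
#' @return A tibble with columns `time` (hours) and `free_igf1` (nM).
#' @export
#' @examples
#' sim_depletion_timecourse(0.017, 116000, 116000, 0.25, times = 0:8,
#'                          noise = noise_model(scale = 0, seed = 1))
sim_depletion_timecourse <- function(k3_0, n_cells, n_ref, initial_igf1,
                                     times = seq(0, 24, by = 2),
                                     noise = noise_model()) {
  if (length(times) == 0) {
    abort("`times` must be non-empty.", class = "igfnet_invalid_times")
  }
  k3 <- scale_depletion_rate(k3_0, n_cells, n_ref)
  clean <- initial_igf1 * exp(-k3 * times)
  tibble(time = times, free_igf1 = apply_noise(clean, noise))
}

#' Synthetic free-IGF1 equilibrium measurements in conditioned media
#'
#' Emulates the free-IGF1 ELISA in conditioned media: replicate
#' measurements scattered around the binding-equilibrium free-ligand value
#' for the given IGF1 and IGFBP totals (no receptor, whose pool is
#' negligible on this scale), computed by [equilibrium_oracle()].
#'
#' @param total_igf1 Spiked IGF1 (nM).
#' @param total_igfbp True total IGFBP (nM).
#' @param kd_bp IGF1-IGFBP dissociation constant (nM).
#' @param noise A [noise_model()].
#' @param n_replicates Number of replicate wells.
#' @return A tibble with columns `replicate` and `free_igf1` (nM).
#' @export
sim_free_igf1_measurements <- function(total_igf1, total_igfbp,
                                       kd_bp = 0.1,
                                       noise = noise_model(),
                                       n_replicates = 3) {
  if (n_replicates < 1) {
    abort("`n_replicates` must be >= 1.", class = "igfnet_invalid_grid")
  }
  eq <- equilibrium_oracle(total_igf1, 0, total_igfbp, 1, kd_bp)
  tibble(replicate = seq_len(n_replicates),
         free_igf1 = apply_noise(rep(eq[["c1"]], n_replicates), noise))
}

#' Synthetic dose-response proliferation dataset
#'
#' Emulates the proliferation experiments behind the occupancy map: for
#' each (cell density, IGF1 concentration) pair the full model is run to
#' its quasi-steady state in conditioned media, the per-cell IGF1-IGF1R
#' complex level is passed through the capped linear proliferation map, and
#' additive gaussian noise is applied to the resulting percentage.
#'
#' @param map A `prolif_map` (true generating map).
#' @param densities Cell densities (cells/well).
#' @param igf1_concentrations Applied IGF1 levels (nM).
#' @param context Template [cellular_context()]; each density replaces
#'   `n_cells`.
#' @param rates An [rate_coefficients()] object.
#' @param noise A [noise_model()] (gaussian recommended; scale in
#'   percentage points).
#' @param ... Passed to [integrate_to_steady_state()].
#' @return A tibble with columns `density`, `igf1_nM`,
#'   `per_cell_complexes` (nmol/cell, noise-free) and
#'   `delta_proliferation` (%, noisy).
#' @export
sim_proliferation_dataset <- function(map,
                                      densities = c(31000, 67000, 126000),
                                      igf1_concentrations = c(0.125, 0.25,
                                                              0.5, 1.3),
                                      context = cellular_context(),
                                      rates = rate_coefficients(),
                                      noise = noise_model("gaussian"),
                                      ...) {
  stopifnot(inherits(map, "prolif_map"))
  if (length(densities) == 0 || length(igf1_concentrations) == 0) {
    abort("Density and concentration grids must be non-empty.",
          class = "igfnet_invalid_grid")
  }
  cells <- tidyr::expand_grid(density = densities,
                              igf1_nM = igf1_concentrations)
  occ <- purrr::pmap_dbl(cells, function(density, igf1_nM) {
    ctx <- cellular_context(n_cells = density, n_ref = context$n_ref,
                            volume = context$volume,
                            igfbp_per_cell = context$igfbp_per_cell,
                            igf1r_per_cell = context$igf1r_per_cell)
    steady_state(treatment(concentration = igf1_nM), ctx,
                 rates = rates, ...)$per_cell_complexes
  })
  clean <- predict_proliferation(map, occ)
  dplyr::mutate(cells, per_cell_complexes = occ,
                delta_proliferation = apply_noise(clean, noise))
}
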