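#' Scale the depletion rate coefficient to a cell number
#'
#' Cell-mediated IGF1 depletion (receptor-mediated endocytosis, lumped into
#' a single first-order drain on free ligand) is proportional to the number
#' of cells: `k3 = k3_0 * n_cells / n_ref`.
#'
#' @param k3_0 Depletion rate at the reference cell number (hr^-1).
#' @param n_cells Cell number of the condition being simulated.
#' @param n_ref Reference cell number at which `k3_0` was measured.
#' @return The scaled depletion rate coefficient k3 (hr^-1).
#' @export
#' @examples
#' scale_depletion_rate(0.017, 58000, 116000)  # 0.0085
scale_depletion_rate <- function(k3_0, n_cells, n_ref) {
  if (!is.finite(n_ref) || n_ref <= 0) {
    abort("`n_ref` must be > 0.", class = "igfnet_invalid_context")
  }
  if (k3_0 < 0 || n_cells < 0) {
    abort("`k3_0` and `n_cells` must be >= 0.",
          class = "igfnet_invalid_context")
  }
  k3_0 * n_cells / n_ref
}

#' Convert between IGF1 dose and concentration
#'
#' An applied amount in pmol dissolved in `volume` mL gives
#' pmol/mL = nmol/L = nM, so the two conversions are a division and a
#' multiplication by the media volume.
#'
#' @param amount Applied amount (pmol).
#' @param concentration Concentration (nM).
#' @param volume Media volume (mL).
#' @return `dose_to_concentration()` returns nM; `concentration_to_dose()`
#'   returns pmol.
#' @export
#' @examples
#' dose_to_concentration(0.25, 2)  # 0.125 nM
#' concentration_to_dose(0.125, 2) # 0.25 pmol
dose_to_concentration <- function(amount, volume) {
  check_volume(volume)
  amount / volume
}

#' @rdname dose_to_concentration
#' @export
concentration_to_dose <- function(concentration, volume) {
  check_volume(volume)
  concentration * volume
}

#' Convert per-cell amounts to bulk concentrations and back
#'
#' Per-cell endowments are reported in nmol/cell; a well with `n_cells`
#' cells in `volume` mL therefore holds
#' `amount_per_cell * n_cells / volume` nmol/mL, i.e. 1000 times that in
#' nM. `concentration_to_per_cell()` is the exact inverse and is how
#' steady-state complex concentrations become the per-cell receptor
#' occupancy that predicts proliferation.
#'
#' @param amount_per_cell Per-cell amount (nmol/cell).
#' @param concentration Bulk concentration (nM).
#' @param n_cells Number of cells in the well.
#' @param volume Media volume (mL).
#' @return nM, or nmol/cell for the inverse.
#' @export
#' @examples
#' per_cell_to_concentration(1.21e-8, 116000, 1)   # 1.4036 nM
#' concentration_to_per_cell(1.4036, 116000, 1)    # 1.21e-8 nmol/cell
per_cell_to_concentration <- function(amount_per_cell, n_cells, volume) {
  check_volume(volume)
  amount_per_cell * n_cells / volume * .NM_PER_NMOL_PER_ML
}

#' @rdname per_cell_to_concentration
#' @export
concentration_to_per_cell <- function(concentration, n_cells, volume) {
  check_volume(volume)
  if (any(n_cells <= 0)) {
    abort("`n_cells` must be > 0 to express a concentration per cell.",
          class = "igfnet_invalid_context")
  }
  concentration * volume / n_cells / .NM_PER_NMOL_PER_ML
}

check_volume <- function(volume) {
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    abort("`volume` must be > 0 (mL).", class = "igfnet_invalid_context")
  }
  invisible(volume)
}
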