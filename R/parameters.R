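#' Kinetic rate coefficients of the IGF1 binding network
#'
#' Bundles the five rate coefficients of the mass-action model. The defaults
#' are the published parameter set for OVCAR5 ovarian cancer cells: both
#' association rate coefficients are 1 nM^-1 hr^-1, so the dissociation rate
#' coefficients equal the dissociation constants measured in intact cells
#' (Kd = 1 nM for IGF1-IGF1R, Kd = 0.1 nM for IGF1-IGFBP), and the
#' cell-mediated depletion rate at the reference cell density is
#' 0.017 hr^-1.
#'
#' @param k1 Association rate coefficient of the IGF1-IGF1R complex
#'   (nM^-1 hr^-1).
#' @param k_neg1 Dissociation rate coefficient of IGF1 and IGF1R (hr^-1).
#' @param k2 Association rate coefficient of the IGF1-IGFBP complex
#'   (nM^-1 hr^-1).
#' @param k_neg2 Dissociation rate coefficient of IGF1 and IGFBP (hr^-1).
#' @param k3_0 Cell-mediated IGF1 depletion rate coefficient at the
#'   reference cell number (hr^-1).
#'
#' @return An object of class `igf_rates`: a named list of the five
#'   coefficients plus the derived dissociation constants `kd_receptor`
#'   (= k_neg1/k1) and `kd_bp` (= k_neg2/k2), both in nM.
#' @export
#' @examples
#' rates <- rate_coefficients()
#' rates$kd_receptor  # 1 nM
#' rates$kd_bp        # 0.1 nM
rate_coefficients <- function(k1 = 1, k_neg1 = 1, k2 = 1, k_neg2 = 0.1,
                              k3_0 = 0.017) {
  vals <- c(k1 = k1, k_neg1 = k_neg1, k2 = k2, k_neg2 = k_neg2, k3_0 = k3_0)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("All rate coefficients must be finite and >= 0.",
          class = "igfnet_invalid_rates")
  }
  if (k1 <= 0 || k2 <= 0) {
    abort("Association rate coefficients k1 and k2 must be > 0 (Kd values must be finite).",
          class = "igfnet_invalid_rates")
  }
  structure(
    list(k1 = k1, k_neg1 = k_neg1, k2 = k2, k_neg2 = k_neg2, k3_0 = k3_0,
         kd_receptor = k_neg1 / k1, kd_bp = k_neg2 / k2),
    class = "igf_rates"
  )
}

#' Cellular context of an experiment
#'
#' Describes one culture condition: how many cells are in the well, the
#' media volume, and the per-cell endowments of IGFBP and IGF1R. All unit
#' conversions between per-cell amounts (nmol/cell) and bulk concentrations
#' (nM) go through this object. Defaults are the measured OVCAR5 values at
#' the reference density of 116,000 cells/well in 1 mL of media.
#'
#' @param n_cells Number of cells in the well.
#' @param n_ref Reference cell number at which `k3_0` was measured.
#' @param volume Media volume (mL).
#' @param igfbp_per_cell Total IGFBP endowment (nmol/cell).
#' @param igf1r_per_cell Total IGF1R endowment (nmol/cell).
#'
#' @return An object of class `igf_context`.
#' @export
#' @examples
#' ctx <- cellular_context(n_cells = 67000)
#' igfbp_total_nM(ctx)  # ~0.81 nM
cellular_context <- function(n_cells = 116000, n_ref = 116000, volume = 1,
                             igfbp_per_cell = 1.21e-8,
                             igf1r_per_cell = 2.23e-11) {
  if (!is.finite(n_ref) || n_ref <= 0) {
    abort("`n_ref` must be > 0.", class = "igfnet_invalid_context")
  }
  if (!is.finite(volume) || volume <= 0) {
    abort("`volume` must be > 0 (mL).", class = "igfnet_invalid_context")
  }
  if (n_cells < 0 || igfbp_per_cell < 0 || igf1r_per_cell < 0) {
    abort("Cell number and per-cell endowments must be >= 0.",
          class = "igfnet_invalid_context")
  }
  structure(
    list(n_cells = n_cells, n_ref = n_ref, volume = volume,
         igfbp_per_cell = igfbp_per_cell, igf1r_per_cell = igf1r_per_cell),
    class = "igf_context"
  )
}

#' Total IGFBP and IGF1R concentrations implied by a context
#'
#' Convert the per-cell endowments of a [cellular_context()] into the bulk
#' media concentrations used as initial conditions.
#'
#' @param context An `igf_context`.
#' @return Concentration in nM.
#' @export
igfbp_total_nM <- function(context) {
  per_cell_to_concentration(context$igfbp_per_cell, context$n_cells,
                            context$volume)
}

#' @rdname igfbp_total_nM
#' @export
igf1r_total_nM <- function(context) {
  per_cell_to_concentration(context$igf1r_per_cell, context$n_cells,
                            context$volume)
}

#' IGF1 treatment specification
#'
#' A treatment is defined either by an applied amount (pmol) or by a bulk
#' concentration (nM) -- exactly one of the two -- together with the media
#' condition. `media = "conditioned"` means IGF1 is spiked into media that
#' cells have conditioned, so the accumulated cell-secreted IGFBP pool is
#' present; `media = "fresh"` means the media was replaced just before
#' treatment, so the initial IGFBP total is zero (secretion during the short
#' simulation window is not modelled).
#'
#' @param concentration Applied IGF1 concentration (nM).
#' @param amount Applied IGF1 amount (pmol).
#' @param media `"conditioned"` or `"fresh"`.
#'
#' @return An object of class `igf_treatment`.
#' @export
#' @examples
#' treatment(concentration = 0.25)
#' treatment(amount = 0.5, media = "fresh")
treatment <- function(concentration = NULL, amount = NULL,
                      media = c("conditioned", "fresh")) {
  media <- match.arg(media)
  if (is.null(concentration) == is.null(amount)) {
    abort("Give exactly one of `concentration` (nM) or `amount` (pmol).",
          class = "igfnet_ambiguous_treatment")
  }
  given <- concentration %||% amount
  if (!is.finite(given) || given < 0) {
    abort("IGF1 treatment must be finite and >= 0.",
          class = "igfnet_invalid_treatment")
  }
  structure(list(concentration = concentration, amount = amount,
                 media = media),
            class = "igf_treatment")
}

#' Resolve a treatment to a concentration in a given context
#'
#' @param trt An `igf_treatment`.
#' @param context An `igf_context` supplying the media volume when the
#'   treatment is given as an amount.
#' @return Applied IGF1 concentration (nM).
#' @export
treatment_concentration <- function(trt, context) {
  if (!is.null(trt$concentration)) return(trt$concentration)
  dose_to_concentration(trt$amount, context$volume)
}

#' Antibody specification
#'
#' Describes a single therapeutic antibody: either an IGF1-neutralizing
#' antibody (`target = "ligand"`, binds free IGF1) or an IGF1R-blocking
#' antibody (`target = "receptor"`, binds free receptor). Only the
#' dissociation constant and dose are biologically specified; the
#' association rate coefficient defaults to 1 nM^-1 hr^-1, the same on-rate
#' convention as the network's own binding reactions, so that scenario
#' comparisons isolate affinity effects. The off-rate is `kd * k_on`.
#'
#' @param target `"ligand"` (IGF1-neutralizing) or `"receptor"`
#'   (IGF1R-blocking).
#' @param kd Dissociation constant (nM), > 0.
#' @param dose Initial free antibody concentration (nM), >= 0.
#' @param k_on Association rate coefficient (nM^-1 hr^-1), > 0.
#'
#' @return An object of class `igf_antibody` with fields `target`, `kd`,
#'   `dose`, `k_on`, and derived `k_off` (hr^-1).
#' @export
#' @examples
#' antibody("receptor", kd = 0.1, dose = 10)
antibody <- function(target = c("ligand", "receptor"), kd, dose, k_on = 1) {
  target <- match.arg(target)
  if (!is.finite(kd) || kd <= 0) {
    abort("Antibody `kd` must be > 0 (nM).", class = "igfnet_invalid_antibody")
  }
  if (!is.finite(k_on) || k_on <= 0) {
    abort("Antibody `k_on` must be > 0.", class = "igfnet_invalid_antibody")
  }
  if (!is.finite(dose) || dose < 0) {
    abort("Antibody `dose` must be >= 0 (nM).",
          class = "igfnet_invalid_antibody")
  }
  structure(list(target = target, kd = kd, dose = dose, k_on = k_on,
                 k_off = kd * k_on),
            class = "igf_antibody")
}

#' @export
print.igf_rates <- function(x, ...) {
  cat("<igf_rates>\n")
  cat(sprintf("  k1   = %g nM^-1 hr^-1   k-1  = %g hr^-1   (Kd receptor = %g nM)\n",
              x$k1, x$k_neg1, x$kd_receptor))
  cat(sprintf("  k2   = %g nM^-1 hr^-1   k-2  = %g hr^-1   (Kd IGFBP    = %g nM)\n",
              x$k2, x$k_neg2, x$kd_bp))
  cat(sprintf("  k3,0 = %g hr^-1 (cell-mediated depletion at reference density)\n",
              x$k3_0))
  invisible(x)
}

#' @export
print.igf_context <- function(x, ...) {
  cat("<igf_context>\n")
  cat(sprintf("  %g cells (reference %g) in %g mL\n", x$n_cells, x$n_ref,
              x$volume))
  cat(sprintf("  IGFBP %.4g nmol/cell (%.4g nM); IGF1R %.4g nmol/cell (%.4g nM)\n",
              x$igfbp_per_cell, igfbp_total_nM(x),
              x$igf1r_per_cell, igf1r_total_nM(x)))
  invisible(x)
}

#' @export
print.igf_antibody <- function(x, ...) {
  kind <- if (x$target == "ligand") "IGF1-neutralizing" else "IGF1R-blocking"
  cat(sprintf("<igf_antibody> %s: Kd %g nM, dose %g nM, k_on %g nM^-1 hr^-1\n",
              kind, x$kd, x$dose, x$k_on))
  invisible(x)
}

#' @export
print.igf_treatment <- function(x, ...) {
  given <- if (!is.null(x$concentration)) {
    sprintf("%g nM", x$concentration)
  } else {
    sprintf("%g pmol", x$amount)
  }
  cat(sprintf("<igf_treatment> IGF1 %s in %s media\n", given, x$media))
  invisible(x)
}
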