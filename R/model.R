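#' Species of the binding network
#'
#' The base model tracks five species, all in nM: free IGF1 (`c1`), free
#' IGF1R (`c1r`), the IGF1-IGF1R complex (`c1_1r`), free IGFBP (`cbp`) and
#' the IGF1-IGFBP complex (`c1_bp`). An antibody scenario appends the free
#' antibody (`c_ab`) and exactly one of the antibody complexes: `c1_ab`
#' (IGF1:antibody, ligand-neutralizing) or `c1r_ab` (IGF1R:antibody,
#' receptor-blocking).
#'
#' @param c1,c1r,c1_1r,cbp,c1_bp Base species concentrations (nM).
#' @param c_ab,c1_ab,c1r_ab Antibody species (nM); supply them only for an
#'   antibody scenario, and never both complex types at once.
#' @return A named numeric vector of concentrations.
#' @export
#' @examples
#' species_state(c1 = 0.25, c1r = 2.5868e-3, cbp = 1.4036)
species_state <- function(c1 = 0, c1r = 0, c1_1r = 0, cbp = 0, c1_bp = 0,
                          c_ab = NULL, c1_ab = NULL, c1r_ab = NULL) {
  state <- c(c1 = c1, c1r = c1r, c1_1r = c1_1r, cbp = cbp, c1_bp = c1_bp)
  if (!is.null(c1_ab) && !is.null(c1r_ab)) {
    abort("At most one antibody type per scenario: supply `c1_ab` or `c1r_ab`, not both.",
          class = "igfnet_inconsistent_scenario")
  }
  if (!is.null(c1_ab)) state <- c(state, c_ab = c_ab %||% 0, c1_ab = c1_ab)
  else if (!is.null(c1r_ab)) state <- c(state, c_ab = c_ab %||% 0, c1r_ab = c1r_ab)
  else if (!is.null(c_ab)) state <- c(state, c_ab = c_ab)
  if (any(!is.finite(state)) || any(state < 0)) {
    abort("All concentrations must be finite and >= 0.",
          class = "igfnet_invalid_state")
  }
  state
}

.BASE_SPECIES <- c("c1", "c1r", "c1_1r", "cbp", "c1_bp")

state_names_for <- function(antibody = NULL) {
  if (is.null(antibody)) return(.BASE_SPECIES)
  complex <- if (antibody$target == "ligand") "c1_ab" else "c1r_ab"
  c(.BASE_SPECIES, "c_ab", complex)
}

check_state_antibody <- function(state, antibody) {
  nm <- names(state)
  has_lig <- "c1_ab" %in% nm
  has_rec <- "c1r_ab" %in% nm
  if (has_lig && has_rec) {
    abort("State carries both antibody complex types; only one antibody per scenario.",
          class = "igfnet_inconsistent_scenario")
  }
  if (is.null(antibody)) {
    if (has_lig || has_rec || "c_ab" %in% nm) {
      abort("State carries antibody species but no antibody spec was given.",
            class = "igfnet_inconsistent_scenario")
    }
  } else {
    want <- if (antibody$target == "ligand") "c1_ab" else "c1r_ab"
    if (!all(c("c_ab", want) %in% nm)) {
      abort(sprintf("Antibody spec targets the %s but the state lacks `c_ab`/`%s`.",
                    antibody$target, want),
            class = "igfnet_inconsistent_scenario")
    }
  }
  invisible(state)
}

#' Mass-action time derivatives of the network
#'
#' Right-hand sides of the ODE system. Free IGF1 exchanges with both
#' complexes by mass action and is drained by the first-order cell-mediated
#' depletion term `-k3 * c1`; only free ligand is depleted -- complexes are
#' protected and the receptor is not degraded. With a ligand-neutralizing
#' antibody, free IGF1 additionally exchanges with the IGF1:antibody
#' complex; with a receptor-blocking antibody, free IGF1R exchanges with the
#' IGF1R:antibody complex.
#'
#' @param state Named concentration vector from [species_state()].
#' @param rates An [rate_coefficients()] object.
#' @param k3 Depletion rate coefficient for this condition (hr^-1), usually
#'   from [scale_depletion_rate()].
#' @param antibody Optional [antibody()] spec; must match the antibody
#'   species present in `state`.
#' @return Named vector of dC/dt (nM/hr), same names as `state`.
#' @export
#' @examples
#' st <- species_state(c1 = 1, c1r = 1)
#' igf_derivatives(st, rate_coefficients(), k3 = 0)
igf_derivatives <- function(state, rates, k3, antibody = NULL) {
  check_state_antibody(state, antibody)
  c1 <- state[["c1"]]; c1r <- state[["c1r"]]; c1_1r <- state[["c1_1r"]]
  cbp <- state[["cbp"]]; c1_bp <- state[["c1_bp"]]

  assoc_r  <- rates$k1 * c1 * c1r
  dissoc_r <- rates$k_neg1 * c1_1r
  assoc_b  <- rates$k2 * c1 * cbp
  dissoc_b <- rates$k_neg2 * c1_bp

  d <- c(
    c1    = dissoc_r + dissoc_b - assoc_r - assoc_b - k3 * c1,
    c1r   = dissoc_r - assoc_r,
    c1_1r = assoc_r - dissoc_r,
    cbp   = dissoc_b - assoc_b,
    c1_bp = assoc_b - dissoc_b
  )

  if (!is.null(antibody)) {
    c_ab <- state[["c_ab"]]
    if (antibody$target == "ligand") {
      assoc_a  <- antibody$k_on * c1 * c_ab
      dissoc_a <- antibody$k_off * state[["c1_ab"]]
      d[["c1"]] <- d[["c1"]] + dissoc_a - assoc_a
      d <- c(d, c_ab = dissoc_a - assoc_a, c1_ab = assoc_a - dissoc_a)
    } else {
      assoc_a  <- antibody$k_on * c1r * c_ab
      dissoc_a <- antibody$k_off * state[["c1r_ab"]]
      d[["c1r"]] <- d[["c1r"]] + dissoc_a - assoc_a
      d <- c(d, c_ab = dissoc_a - assoc_a, c1r_ab = assoc_a - dissoc_a)
    }
  }
  d[names(state)]
}

#' Totals of the conserved moieties
#'
#' Sums each species pool into its conserved moiety: total receptor
#' (`c1r + c1_1r + c1r_ab`), total IGFBP (`cbp + c1_bp`), total IGF1
#' (`c1 + c1_1r + c1_bp + c1_ab`) and total antibody. Receptor, IGFBP and
#' antibody totals are exact invariants of the rate laws; the IGF1 total
#' decays only through the depletion drain on free ligand, at rate
#' `k3 * c1`.
#'
#' @param state Named concentration vector.
#' @return A one-row tibble with columns `igf1`, `igf1r`, `igfbp`,
#'   `antibody` (all nM; `antibody` is `NA` when no antibody species are
#'   present).
#' @export
mass_totals <- function(state) {
  g <- function(nm) if (nm %in% names(state)) state[[nm]] else 0
  ab_present <- "c_ab" %in% names(state)
  tibble(
    igf1  = g("c1") + g("c1_1r") + g("c1_bp") + g("c1_ab"),
    igf1r = g("c1r") + g("c1_1r") + g("c1r_ab"),
    igfbp = g("cbp") + g("c1_bp"),
    antibody = if (ab_present) g("c_ab") + g("c1_ab") + g("c1r_ab") else NA_real_
  )
}
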