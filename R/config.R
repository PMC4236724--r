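#' Load a scenario configuration file
#'
#' Reads a YAML or JSON scenario description (dispatching on the file
#' extension) into validated parameter objects. Every field is optional:
#' omitted rate coefficients, context fields and treatment settings fall
#' back to the published OVCAR5 defaults, so an empty file yields the full
#' default parameter set. Recognised top-level blocks:
#'
#' * `rates`: `k1`, `k_neg1`, `k2`, `k_neg2`, `k3_0`
#' * `context`: `n_cells`, `n_ref`, `volume`, `igfbp_per_cell`,
#'   `igf1r_per_cell`
#' * `treatment`: `concentration` (nM) or `amount` (pmol); `media`
#' * `antibody`: `target`, `kd`, `dose`, `k_on` (optional block)
#' * `grid`: the [scenario_grid()] axes (optional block)
#'
#' All concentrations are nM, times hours, volume mL, amounts pmol,
#' per-cell endowments nmol/cell. Unknown fields raise an error naming the
#' offender rather than being silently dropped.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `igf_scenario` with elements `rates`,
#'   `context`, `treatment`, and optionally `antibody` and `grid`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("No such config file: %s", path), class = "igfnet_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw <- raw %||% list()
  scenario_from_list(raw)
}

scenario_from_list <- function(raw) {
  known <- c("rates", "context", "treatment", "antibody", "grid")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(sprintf("Unknown config block(s): %s (expected %s).",
                  toString(extra), toString(known)),
          class = "igfnet_schema_error")
  }
  take <- function(block, allowed) {
    b <- raw[[block]] %||% list()
    bad <- setdiff(names(b), allowed)
    if (length(bad)) {
      abort(sprintf("Unknown field(s) in `%s`: %s (expected %s; concentrations nM, volume mL, per-cell endowments nmol/cell).",
                    block, toString(bad), toString(allowed)),
            class = "igfnet_schema_error")
    }
    b
  }
  rates <- do.call(rate_coefficients,
                   take("rates", c("k1", "k_neg1", "k2", "k_neg2", "k3_0")))
  context <- do.call(cellular_context,
                     take("context", c("n_cells", "n_ref", "volume",
                                       "igfbp_per_cell", "igf1r_per_cell")))
  trt_raw <- take("treatment", c("concentration", "amount", "media"))
  if (is.null(trt_raw$concentration) && is.null(trt_raw$amount)) {
    trt_raw$concentration <- 0.25
  }
  trt <- do.call(treatment, trt_raw)
  out <- list(rates = rates, context = context, treatment = trt)
  ab_raw <- take("antibody", c("target", "kd", "dose", "k_on"))
  if (length(ab_raw)) out$antibody <- do.call(antibody, ab_raw)
  grid_raw <- take("grid", c("antibody_kds", "antibody_doses", "igf1_levels",
                             "igfbp_multipliers", "igf1r_multipliers"))
  if (length(grid_raw)) {
    grid_raw <- lapply(grid_raw, function(x) unlist(x, use.names = FALSE))
    out$grid <- do.call(scenario_grid,
                        c(grid_raw, list(base_context = context)))
  }
  structure(out, class = "igf_scenario")
}

#' Save a scenario configuration
#'
#' Writes an `igf_scenario` back to YAML or JSON (by extension). A
#' save/load round trip reproduces the same validated objects.
#'
#' @param scenario An `igf_scenario` from [load_scenario()] or assembled
#'   manually.
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
save_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "igf_scenario"))
  r <- scenario$rates; ctx <- scenario$context; trt <- scenario$treatment
  raw <- list(
    rates = list(k1 = r$k1, k_neg1 = r$k_neg1, k2 = r$k2,
                 k_neg2 = r$k_neg2, k3_0 = r$k3_0),
    context = list(n_cells = ctx$n_cells, n_ref = ctx$n_ref,
                   volume = ctx$volume, igfbp_per_cell = ctx$igfbp_per_cell,
                   igf1r_per_cell = ctx$igf1r_per_cell),
    treatment = Filter(Negate(is.null),
                       list(concentration = trt$concentration,
                            amount = trt$amount, media = trt$media))
  )
  if (!is.null(scenario$antibody)) {
    ab <- scenario$antibody
    raw$antibody <- list(target = ab$target, kd = ab$kd, dose = ab$dose,
                         k_on = ab$k_on)
  }
  if (!is.null(scenario$grid)) {
    g <- scenario$grid
    raw$grid <- list(antibody_kds = g$antibody_kds,
                     antibody_doses = g$antibody_doses,
                     igf1_levels = g$igf1_levels,
                     igfbp_multipliers = g$igfbp_multipliers,
                     igf1r_multipliers = g$igf1r_multipliers)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(raw, path)
  }
  invisible(path)
}

#' Write a results table to disk
#'
#' CSV (RFC 4180: header row, comma separators, `.` decimal) or JSON, with
#' numbers written at full double precision so a write/read round trip
#' preserves values exactly.
#'
#' @param table A data frame.
#' @param path Destination path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, format = NULL) {
  format <- format %||%
    if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "json") {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                         na = "null")
  } else {
    readr::write_csv(table, path)
  }
  invisible(path)
}
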