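#' Plot a simulated time course
#'
#' Concentration trajectories of all species on a log10 y axis (species
#' span several orders of magnitude).
#'
#' @param timecourse Tibble from [simulate_timecourse()].
#' @return A ggplot object.
#' @export
plot_timecourse <- function(timecourse) {
  long <- tidyr::pivot_longer(timecourse, -"time",
                              names_to = "species", values_to = "nM")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$time, y = .data$nM,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "concentration (nM)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an antibody test-matrix result
#'
#' Fractional inhibition versus antibody dose, faceted by IGF1 level and
#' IGFBP multiplier, one line per antibody Kd, solid for the
#' receptor-blocking and dashed for the ligand-neutralizing antibody.
#'
#' @param results Tibble from [run_test_matrix()].
#' @return A ggplot object.
#' @export
plot_inhibition_matrix <- function(results) {
  long <- tidyr::pivot_longer(
    results,
    c("inhibition_ligand", "inhibition_receptor"),
    names_to = "antibody", names_prefix = "inhibition_",
    values_to = "inhibition"
  )
  long$antibody <- ifelse(long$antibody == "ligand",
                          "IGF1-neutralizing", "IGF1R-blocking")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$antibody_dose_nM,
                               y = .data$inhibition,
                               colour = factor(.data$antibody_kd_nM),
                               linetype = .data$antibody)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(igf1_nM ~ igfbp_multiplier,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "antibody dose (nM)",
                  y = "fractional inhibition of IGF1-IGF1R complexes",
                  colour = "antibody Kd (nM)", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_proliferation_map plot the data, the fitted line and
#'   the receptor-saturation cap.
#' @param object A `prolif_map`.
#' @export
autoplot.prolif_map <- function(object, ...) {
  d <- object$fit$model
  cap <- object$max_per_cell_complexes
  grid <- tibble(per_cell_complexes = seq(0, cap * 1.2, length.out = 200))
  grid$pred <- predict_proliferation(object, grid$per_cell_complexes)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$per_cell_complexes,
                                  y = .data$delta_proliferation)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$pred), colour = "steelblue") +
    ggplot2::geom_vline(xintercept = cap, linetype = "dotted") +
    ggplot2::annotate("point", x = cap,
                      y = predict_proliferation(object, cap), shape = 8) +
    ggplot2::labs(x = "IGF1-IGF1R complexes per cell (nmol/cell)",
                  y = "proliferation increase (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
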