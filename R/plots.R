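#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   labs scale_x_log10 theme_minimal
#' @export
ggplot2::autoplot

#' Plot a free-energy profile
#'
#' Line plot of the PMF over the reaction coordinate, with a +/- 1 sd
#' ribbon when bootstrap errors are present.
#'
#' @param object A `pmf_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pmf_profile <- function(object, ...) {
  d <- as_tibble(object)[populated(object), ]
  p <- ggplot(d, aes(x = .data$bin_center_A, y = .data$pmf_kJ_mol))
  if ("stderr_kJ_mol" %in% names(d)) {
    p <- p + geom_ribbon(aes(ymin = .data$pmf_kJ_mol - .data$stderr_kJ_mol,
                             ymax = .data$pmf_kJ_mol + .data$stderr_kJ_mol),
                         alpha = 0.25)
  }
  p + geom_line() +
    labs(x = "reaction coordinate (Å)",
         y = "free energy (kJ/mol)") +
    theme_minimal()
}

#' Plot a single-site ITC fit
#'
#' Integrated per-injection heats against the molar ratio of injected
#' titrant to cell macromolecule, with the fitted isotherm overlaid.
#'
#' @param object An `itc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.itc_fit <- function(object, ...) {
  e <- object$experiment
  cc <- cell_concentrations(e)
  d <- tibble(ratio = cc$Xt / cc$Mt,
              observed = e$injections$heat_ucal,
              fitted = object$fitted)
  ggplot(d, aes(x = .data$ratio)) +
    geom_point(aes(y = .data$observed)) +
    geom_line(aes(y = .data$fitted)) +
    labs(x = "molar ratio (titrant / macromolecule)",
         y = "heat per injection (µcal)") +
    theme_minimal()
}

#' Plot predicted displacement curves
#'
#' The fraction of remaining reporter complex against competitor
#' concentration (log axis) for the unmodified (`y1`) and phosphorylated
#' (`y2`) competitor.
#'
#' @param object Output of [predict_displacement_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_displacement_curve <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object)[as_tibble(object)$conc > 0, ],
                           c("y1", "y2"), names_to = "competitor",
                           values_to = "fraction")
  d$competitor <- ifelse(d$competitor == "y1", "unmodified", "phosphorylated")
  ggplot(d, aes(x = .data$conc, y = .data$fraction,
                colour = .data$competitor)) +
    geom_line() +
    scale_x_log10() +
    labs(x = "competitor concentration (µM)",
         y = "fraction of reporter complex") +
    theme_minimal()
}
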