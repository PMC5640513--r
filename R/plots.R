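#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_raster
#'   scale_fill_viridis_c labs theme_minimal geom_boxplot geom_jitter
#'   facet_wrap coord_equal geom_vline
NULL

#' Plot an apparent-modulus map
#'
#' @param object An `ea_map`.
#' @param ... Unused.
#' @return A ggplot heat map of E_a over the scanned area (masked pixels
#'   blank).
#' @export
autoplot.ea_map <- function(object, ...) {
  ggplot(object, aes(x = .data$x, y = .data$y, fill = .data$Ea)) +
    geom_raster() +
    scale_fill_viridis_c(option = "inferno", na.value = "grey90") +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)", fill = "E_a (MPa)") +
    theme_minimal()
}

#' Plot a stomatal transect profile
#'
#' @param object A `transect_profile`.
#' @param ... Unused.
#' @export
autoplot.transect_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$position, y = .data$Ea)) +
    geom_line(na.rm = TRUE) +
    labs(x = sprintf("distance along %s (µm)", attr(object, "mode")),
         y = "E_a (MPa)") +
    theme_minimal()
}

#' Plot aperture-pressure curves of a scenario report
#'
#' @param object A `gc_scenario_report`.
#' @param ... Unused.
#' @export
autoplot.gc_scenario_report <- function(object, ...) {
  ggplot(object$curves,
         aes(x = .data$P_gc, y = .data$aperture, colour = .data$variant)) +
    geom_line() +
    labs(x = "guard-cell turgor (MPa)", y = "aperture (µm)",
         colour = NULL) +
    theme_minimal()
}

#' Plot the aperture-pressure curve of a single solution
#'
#' @param solution A `gc_solution`.
#' @return A ggplot with the co-ramp phase marked.
#' @export
plot_aperture_curve <- function(solution) {
  cv <- aperture_curve(solution)
  co_end <- max(cv$P_epi)
  ggplot(cv, aes(x = .data$P_gc, y = .data$aperture)) +
    geom_vline(xintercept = co_end, linetype = 2, colour = "grey50") +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "guard-cell turgor (MPa)", y = "aperture (µm)") +
    theme_minimal()
}

#' Plot recovered stiffness gradients by developmental stage
#'
#' @param object A `gc_afm_study`.
#' @param ... Unused.
#' @export
autoplot.gc_afm_study <- function(object, ...) {
  d <- object$gradients[object$gradients$flag == "ok", ]
  ggplot(d, aes(x = .data$stage, y = .data$gradient)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.1, alpha = 0.6) +
    labs(x = NULL, y = "E_a gradient (MPa/µm)") +
    theme_minimal()
}
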