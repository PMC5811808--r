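#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_raster geom_contour
#'   geom_col labs scale_x_reverse scale_fill_viridis_c theme_minimal
#'   position_dodge
#' @export
ggplot2::autoplot

#' Plot a 1D spectrum
#'
#' Intensity against ppm, with the ppm axis reversed (NMR convention).
#'
#' @param object An `nmr_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nmr_spectrum <- function(object, ...) {
  nuc <- attr(object, "nucleus", exact = TRUE) %||% ""
  ggplot(as_tibble(object), aes(x = .data$ppm, y = .data$intensity)) +
    geom_line(linewidth = 0.3) +
    scale_x_reverse() +
    labs(x = sprintf("%s chemical shift [ppm]", nuc), y = "intensity") +
    theme_minimal()
}

#' Plot a 2D spectrum
#'
#' Intensity raster over the two ppm axes, both reversed.
#'
#' @param object An `nmr_spectrum2d`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nmr_spectrum2d <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$f2_ppm, y = .data$f1_ppm, fill = .data$intensity)) +
    geom_raster() +
    scale_x_reverse() +
    ggplot2::scale_y_reverse() +
    scale_fill_viridis_c() +
    labs(x = "F2 [ppm]", y = "F1 [ppm]", fill = "intensity") +
    theme_minimal()
}

#' Plot fitted isotopomer fractions
#'
#' @param object An `isotopomer_fit`.
#' @param ... Unused.
#' @return A ggplot bar chart of percent per isotopomer with 1-sigma error
#'   bars.
#' @export
autoplot.isotopomer_fit <- function(object, ...) {
  fr <- object$fractions
  ggplot(fr, aes(x = .data$name, y = .data$percent)) +
    geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(aes(ymin = .data$percent - .data$sigma,
                               ymax = .data$percent + .data$sigma),
                           width = 0.2) +
    labs(x = NULL, y = "isotopomer fraction [%]") +
    theme_minimal()
}

#' Plot recovered fractions across enhancement levels
#'
#' @param object An `enhancement_report` from [enhancement_consistency()].
#' @param ... Unused.
#' @return A ggplot of percent per species against the enhancement factor.
#' @export
autoplot.enhancement_report <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = factor(.data$enhancement), y = .data$percent,
             colour = .data$name, group = .data$name)) +
    geom_line() +
    ggplot2::geom_point() +
    labs(x = "splitting enhancement (1 + k)", y = "recovered fraction [%]",
         colour = "isotopomer") +
    theme_minimal()
}
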