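#' Plot a parent-offspring regression dataset
#'
#' Brood-mean offspring log-FID against the parental value, with the
#' fitted regression line whose slope is the (uncorrected) heritability
#' estimate, coloured by brood habitat.
#'
#' @param object A `po_dataset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.po_dataset <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$parent_value,
                                       y = .data$offspring_value)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$habitat), alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "black", linewidth = 0.4) +
    ggplot2::labs(x = sprintf("%s log-FID", object$mode[1]),
                  y = "brood-mean offspring log-FID",
                  colour = "habitat") +
    ggplot2::theme_minimal()
}

#' Plot a table of heritability estimates
#'
#' Point estimates with +/- 1 SE bars by method and habitat stratum.
#'
#' @param object An `h2_estimate` tibble (e.g. [po_heritability()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.h2_estimate <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$habitat, y = .data$h2,
                                       colour = .data$method)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$h2 - .data$se,
                                          ymax = .data$h2 + .data$se),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = expression(h^2 %+-% SE)) +
    ggplot2::theme_minimal()
}

#' Plot animal-model posterior draws
#'
#' Trace and posterior density of heritability; the density panel shades
#' the 95% highest-posterior-density interval.
#'
#' @param object An `animal_model` fit.
#' @param parameter Which draw column to show (default `"h2"`).
#' @param ... Unused.
#' @return A ggplot object (two facets: trace and density).
#' @export
autoplot.animal_model <- function(object, parameter = "h2", ...) {
  stopifnot(parameter %in% names(object$draws))
  d <- object$draws
  hpd <- hpd_interval(d[[parameter]], 0.95)
  long <- bind_rows(
    tibble(panel = "trace", x = d$iteration, y = d[[parameter]]),
    tibble(panel = "density", x = d[[parameter]], y = NA_real_)
  )
  ggplot2::ggplot() +
    ggplot2::geom_line(data = long[long$panel == "trace", ],
                       ggplot2::aes(x = .data$x, y = .data$y),
                       linewidth = 0.2) +
    ggplot2::geom_density(data = long[long$panel == "density", ],
                          ggplot2::aes(x = .data$x), fill = "grey80") +
    ggplot2::geom_vline(data = tibble(panel = "density", xint = hpd),
                        ggplot2::aes(xintercept = .data$xint),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = parameter) +
    ggplot2::theme_minimal()
}
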