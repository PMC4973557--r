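#' Plot a culture trajectory
#'
#' Faceted time courses of the five dynamic states plus the resolved growth
#' rate.
#'
#' @param object a `culture_trajectory`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.culture_trajectory <- function(object, ...) {
  vars <- c(x = "biomass (g/L)", c_no3 = "nitrate (g/L)",
            w_chl = "chlorophyll (g/gDw)", w_car = "carotene (g/gDw)",
            w_n = "N quota (g/gDw)", mu = "growth rate (1/h)")
  long <- as_tibble(object) %>%
    select(dplyr::all_of(c("time_h", names(vars)))) %>%
    tidyr::pivot_longer(-"time_h", names_to = "variable") %>%
    mutate(variable = factor(vars[.data$variable], levels = unname(vars)))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h / 24, .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (d)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
plot.culture_trajectory <- function(x, ...) print(autoplot(x, ...))

#' Plot a fed-batch design scan
#'
#' Heat maps of maximal biomass, carotene fraction and carotene
#' concentration over the design grid.
#'
#' @param object a `design_scan`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.design_scan <- function(object, ...) {
  axis1 <- if (identical(attr(object, "inoculum_axis"), "w_n"))
    "inoculum N quota (g/gDw)" else "inoculum nitrate (g/L)"
  long <- as_tibble(object) %>%
    select("inoculum", "n_d", "max_x", "max_w_car", "max_beta") %>%
    tidyr::pivot_longer(c("max_x", "max_w_car", "max_beta"),
                        names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$inoculum), factor(.data$n_d),
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = axis1, y = "nitrogen feeding factor (gN/L/h)") +
    ggplot2::theme_minimal()
}

#' @export
plot.design_scan <- function(x, ...) print(autoplot(x, ...))
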