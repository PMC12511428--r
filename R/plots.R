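#' Plot a parameter sweep
#'
#' Two-panel view of a sweep table: export production and delta-15N
#' (deep ocean and OMZ) against the swept variable, mirroring the layout
#' of the model's upwelling and phosphorus experiments.
#'
#' @param object An `"nbox_sweep"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nbox_sweep <- function(object, ...) {
  var <- attr(object, "sweep_var")
  df <- as_tibble(object) |>
    select(dplyr::all_of(var), "export_P", "d15N_deep", "d15N_omz") |>
    tidyr::pivot_longer(-dplyr::all_of(var), names_to = "quantity") |>
    mutate(panel = ifelse(.data$quantity == "export_P",
                          "export (mol P/s)", "delta15N (permil)"))
  ggplot2::ggplot(df, ggplot2::aes(.data[[var]], .data$value,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = var, y = NULL, colour = NULL,
                  title = paste0(attr(object, "setup"), "-P setup")) +
    ggplot2::theme_minimal()
}

#' Plot a composite sediment record
#'
#' delta-15N against age, coloured by source site, oldest ages to the
#' right as is conventional for geological time series.
#'
#' @param composite A composite from [splice_records()] (or any record
#'   tibble with `age`, `d15N`, `site`).
#' @return A ggplot object.
#' @export
plot_composite <- function(composite) {
  ggplot2::ggplot(composite, ggplot2::aes(.data$age, .data$d15N,
                                          colour = .data$site)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (Ma)", y = "delta15N (permil vs AIR)",
                  colour = "site") +
    ggplot2::theme_minimal()
}

#' Map the coastal upwelling flux
#'
#' Per-cell upwelling-favourable Ekman flux over the land mask.
#'
#' @param object An `"upwelling_flux"` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.upwelling_flux <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(.data$lon, .data$lat,
                               colour = .data$flux_kg_s / 1e9)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "grey90", high = "red") +
    ggplot2::labs(x = "longitude", y = "latitude",
                  colour = "flux (1e9 kg/s)") +
    ggplot2::theme_minimal()
}
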