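# ggplot2 views of the experiment results.

#' @method autoplot camo_exp1
#' @export
autoplot.camo_exp1 <- function(object, ...) {
  ggplot2::ggplot(object$by_treatment,
                  ggplot2::aes(x = .data$max_irradiance_wm2,
                               y = .data$pct_change,
                               colour = .data$band_set)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "mean daily max irradiance (W/m²)",
                  y = "reflectance change (%)",
                  colour = "band set",
                  title = "Egg reflectance change vs radiation received") +
    ggplot2::theme_minimal()
}

#' @method autoplot camo_exp2
#' @export
autoplot.camo_exp2 <- function(object, ...) {
  ggplot2::ggplot(object$day_means,
                  ggplot2::aes(x = factor(.data$day), y = .data$mean,
                               group = .data$visual_model)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.15, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~ .data$visual_model) +
    ggplot2::labs(x = "day of exposure",
                  y = expression(chi^2 ~ "camouflage score"),
                  title = "Camouflage degradation by predator visual model") +
    ggplot2::theme_minimal()
}

#' @method autoplot exp1_run
#' @export
autoplot.exp1_run <- function(object, ...) autoplot(object$report, ...)

#' @method autoplot exp2_run
#' @export
autoplot.exp2_run <- function(object, ...) autoplot(object$report, ...)

#' Plot a scene band as a raster
#'
#' Quick look at one band of a synthetic scene, with egg and standard
#' outlines overlaid.
#'
#' @param scene a [render_scene()] object.
#' @param band one of `"R"`, `"G"`, `"B"`, `"UV"`.
#' @return a ggplot.
#' @export
plot_scene_band <- function(scene, band = "R") {
  b <- match(band, BAND_NAMES)
  img <- scene$image[, , b]
  df <- tibble(x = rep(seq_len(ncol(img)) - 1, each = nrow(img)),
               y = rep(seq_len(nrow(img)) - 1, times = ncol(img)),
               value = as.vector(img))
  polys <- c(scene$regions$egg_polygons,
             list(scene$regions$standard_polygon))
  outline <- dplyr::bind_rows(lapply(seq_along(polys), function(i) {
    tibble(x = polys[[i]][, 1], y = polys[[i]][, 2], id = i)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_polygon(data = outline,
                          ggplot2::aes(group = .data$id),
                          fill = NA, colour = "red", linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("band ", band), fill = "reflectance") +
    ggplot2::theme_minimal()
}
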