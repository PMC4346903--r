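#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line labs
#'   theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a titration curve
#'
#' @param object A `titration_data` tibble.
#' @param y `"pH"` or `"emf_mV"` (defaults to whichever is present).
#' @param ... Unused.
#' @method autoplot titration_data
#' @export
autoplot.titration_data <- function(object, y = NULL, ...) {
  y <- y %||% intersect(c("pH", "emf_mV"), names(object))[1]
  ylab <- if (y == "pH") "pH" else "EMF (mV)"
  ggplot(object, aes(x = .data$volume_mL, y = .data[[y]])) +
    geom_point(size = 1) +
    labs(x = "titrant volume (mL)", y = ylab) +
    theme_minimal()
}

#' Plot observed vs fitted EMF for a protonation-model fit
#'
#' Overlays the fitted curve on the observed points and shows the
#' weighted residuals in a second panel.
#'
#' @param object An `sbo_fit`.
#' @param ... Unused.
#' @method autoplot sbo_fit
#' @export
autoplot.sbo_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- d$emf_mV - object$raw_residuals
  d$wres <- object$residuals
  long <- dplyr::bind_rows(
    tibble(volume_mL = d$volume_mL, value = d$emf_mV,
           panel = "EMF (mV)", kind = "observed"),
    tibble(volume_mL = d$volume_mL, value = d$fitted,
           panel = "EMF (mV)", kind = "fitted"),
    tibble(volume_mL = d$volume_mL, value = d$wres,
           panel = "weighted residual", kind = "residual")
  )
  ggplot(long, aes(x = .data$volume_mL, y = .data$value,
                   colour = .data$kind)) +
    geom_point(data = ~ dplyr::filter(.x, .data$kind != "fitted"),
               size = 1) +
    geom_line(data = ~ dplyr::filter(.x, .data$kind == "fitted")) +
    facet_wrap(~panel, ncol = 1, scales = "free_y") +
    labs(x = "titrant volume (mL)", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Plot protonation-state fractions across pH
#'
#' Species-distribution diagram for every site of a model: the fraction
#' of each protonation state as a function of pH.
#'
#' @param model A [protonation_model()] (or single [acid_site()]).
#' @param ph_range pH interval to draw.
#' @param n Number of grid points.
#' @export
plot_species_fractions <- function(model, ph_range = c(2, 12), n = 200) {
  if (inherits(model, "acid_site")) {
    model <- protonation_model("custom", list(model))
  }
  grid <- seq(ph_range[1], ph_range[2], length.out = n)
  d <- purrr::map_dfr(model$sites, function(s)
    dplyr::mutate(species_fractions(s, grid), site_id = s$site_id))
  ggplot(d, aes(x = .data$pH, y = .data$alpha,
                colour = factor(.data$state))) +
    geom_line() +
    facet_wrap(~site_id) +
    labs(y = "species fraction", colour = "bound protons") +
    theme_minimal()
}
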