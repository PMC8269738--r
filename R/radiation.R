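#' Radiation schedule for a shading treatment
#'
#' The five shading treatments of the sun-exposure experiment and their
#' transmittances, anchored to the recorded direct-sun peaks (730 W/m² and
#' UV index 7.5): direct sun, one/two/four white cloth layers, and one black
#' layer, whose averaged daily maxima were 730/224/160/97/7 W/m² and
#' 7.5/2.3/1.6/1.0/0.1 UV index. Sampling is every 5 minutes over a 12-hour
#' window (145 points per day).
#'
#' @param treatment one of `"direct"`, `"white1"`, `"white2"`, `"white4"`,
#'   `"black"`.
#' @param peak_irradiance_wm2 direct-sun peak irradiance, W/m².
#' @param peak_uv_index direct-sun peak UV index.
#' @param vis_transmittance,uv_transmittance optional overrides in \[0, 1\];
#'   defaults come from the treatment table.
#' @return object of class `radiation_schedule`.
#' @export
radiation_schedule <- function(treatment = c("direct", "white1", "white2",
                                             "white4", "black"),
                               peak_irradiance_wm2 = 730,
                               peak_uv_index = 7.5,
                               vis_transmittance = NULL,
                               uv_transmittance = NULL) {
  if (length(treatment) == 1 && !treatment %in% c("direct", "white1", "white2",
                                                  "white4", "black")) {
    nc_abort(paste0("unknown treatment: ", treatment), "nestcamo_config_error")
  }
  treatment <- match.arg(treatment)
  tab <- treatment_table()
  row <- tab[tab$treatment == treatment, ]
  vis_t <- vis_transmittance %||% (row$illuminance_wm2 / 730)
  uv_t <- uv_transmittance %||% (row$uv_index / 7.5)
  if (vis_t < 0 || vis_t > 1 || uv_t < 0 || uv_t > 1) {
    nc_abort("transmittances must be in [0, 1]", "nestcamo_config_error")
  }
  structure(list(treatment = treatment,
                 vis_transmittance = vis_t, uv_transmittance = uv_t,
                 peak_irradiance_wm2 = peak_irradiance_wm2,
                 peak_uv_index = peak_uv_index,
                 sampling_min = 5, window_h = 12),
            class = "radiation_schedule")
}

#' Reference radiation maxima of the five shading treatments
#'
#' Averaged daily maxima recorded per treatment (irradiance in W/m² and
#' UV index), used to anchor the schedule transmittances.
#'
#' @return tibble with columns `treatment`, `illuminance_wm2`, `uv_index`.
#' @export
treatment_table <- function() {
  tibble(
    treatment = c("direct", "white1", "white2", "white4", "black"),
    illuminance_wm2 = c(730, 224, 160, 97, 7),
    uv_index = c(7.5, 2.3, 1.6, 1.0, 0.1)
  )
}

#' Simulate a radiation record
#'
#' Produces per-day 5-minute series of irradiance, illuminance and UV index
#' with a half-cosine diurnal bell over the 12-h window starting at 10:00
#' UTC, scaled by the treatment transmittances. Day-to-day weather
#' variability is a small lognormal factor, so each daily maximum is close
#' to transmittance × direct-sun peak.
#'
#' @param schedule a [radiation_schedule()].
#' @param days vector of day indices (non-empty).
#' @param seed integer seed.
#' @param day_sd SD of the log day-to-day weather factor.
#' @param start_date base date for the timestamps.
#' @return tibble with columns `treatment`, `day`, `timestamp`,
#'   `irradiance_wm2`, `illuminance_lux`, `uv_index`.
#' @export
simulate_radiation <- function(schedule, days, seed = 1L, day_sd = 0.02,
                               start_date = as.Date("2020-05-01")) {
  stopifnot(inherits(schedule, "radiation_schedule"))
  if (length(days) == 0) nc_abort("days must be non-empty", "nestcamo_data_error")
  n_pts <- as.integer(schedule$window_h * 60 / schedule$sampling_min) + 1L
  t_min <- seq(0, schedule$window_h * 60, by = schedule$sampling_min)
  bell <- cos((t_min - schedule$window_h * 30) / (schedule$window_h * 60) * pi)
  withr::with_seed(child_seed(seed, 11), {
    purrr::map_dfr(days, function(d) {
      f_vis <- exp(rnorm(1, 0, day_sd))
      f_uv <- exp(rnorm(1, 0, day_sd))
      irr <- schedule$vis_transmittance * schedule$peak_irradiance_wm2 *
        bell * f_vis
      uvi <- schedule$uv_transmittance * schedule$peak_uv_index * bell * f_uv
      tibble(
        treatment = schedule$treatment,
        day = d,
        timestamp = format(as.POSIXct(start_date, tz = "UTC") +
                             (d * 24 * 60 + 10 * 60 + t_min) * 60,
                           "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
        irradiance_wm2 = pmax(irr, 0),
        illuminance_lux = pmax(irr * 110, 0),
        uv_index = pmax(uvi, 0)
      )
    })
  })
}

#' Summarise radiation records per treatment
#'
#' For each quantity: take the maximum within each recording day, then
#' average the daily maxima across days.
#'
#' @param records tibble as returned by [simulate_radiation()] (one or more
#'   treatments).
#' @return tibble with one row per treatment: `n_days`,
#'   `max_irradiance_wm2`, `max_illuminance_lux`, `max_uv_index` (means of
#'   daily maxima).
#' @export
summarize_radiation <- function(records) {
  if (nrow(records) == 0) nc_abort("empty radiation record",
                                   "nestcamo_data_error")
  records |>
    dplyr::group_by(.data$treatment, .data$day) |>
    dplyr::summarise(
      irr = max(.data$irradiance_wm2),
      illum = max(.data$illuminance_lux),
      uvi = max(.data$uv_index), .groups = "drop_last") |>
    dplyr::summarise(
      n_days = dplyr::n(),
      max_irradiance_wm2 = mean(.data$irr),
      max_illuminance_lux = mean(.data$illum),
      max_uv_index = mean(.data$uvi), .groups = "drop")
}
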