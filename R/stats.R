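#' Arcsine square-root transform
#'
#' Variance-stabilising transform for proportions, `asin(sqrt(x))` in
#' radians. Reflectances above 1 (possible after normalisation of specular
#' pixels) are clipped to 1 with a warning.
#'
#' @param x proportions in \[0, 1\]; values > 1 clipped.
#' @return transformed values in \[0, pi/2\].
#' @export
arcsine_sqrt <- function(x) {
  if (any(x < 0)) nc_abort("proportions must be >= 0", "nestcamo_domain_error")
  if (any(x > 1)) {
    warn(sprintf("%d value(s) > 1 clipped to 1 before arcsine-sqrt",
                 sum(x > 1)))
    x <- pmin(x, 1)
  }
  asin(sqrt(x))
}

#' Pearson correlation with test
#'
#' Product-moment correlation with the two-sided p-value from the t
#' transform on n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3, each with non-zero
#'   variance.
#' @return tibble with columns `r`, `n`, `p`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    nc_abort("need equal-length vectors with n >= 3", "nestcamo_data_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    nc_abort("zero variance in one of the variables",
             "nestcamo_degenerate_error")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), n = length(x), p = ct$p.value)
}

#' Sun-exposure experiment summary
#'
#' Per treatment and band set: mean day-0 and final-day reflectance and the
#' percent change computed from the unrounded means; plus the Pearson
#' correlations of percent change against the per-treatment radiation
#' summaries (VIS change vs mean daily maximum irradiance, UV change vs
#' mean daily maximum UV index).
#'
#' @param table reflectance table: one row per egg x day x band_set with
#'   columns `treatment`, `egg_id`, `day`, `band_set`, `mean_reflectance`.
#' @param summaries per-treatment radiation summary from
#'   [summarize_radiation()].
#' @return object of class `camo_exp1`: list with `by_treatment` (tibble:
#'   `treatment`, `band_set`, `mean_day0`, `mean_final`, `pct_change`,
#'   radiation column) and `correlations` (tibble: `band_set`,
#'   `radiation_var`, `r`, `n`, `p`; rows marked missing when fewer than 3
#'   treatments are available).
#' @export
exp1_summary <- function(table, summaries) {
  days <- sort(unique(table$day))
  need <- tidyr::expand_grid(treatment = unique(table$treatment),
                             day = days,
                             band_set = c("VIS", "UV"))
  have <- dplyr::distinct(table, .data$treatment, .data$day, .data$band_set)
  gaps <- dplyr::anti_join(need, have,
                           by = c("treatment", "day", "band_set"))
  if (nrow(gaps) > 0) {
    nc_abort(paste0("incomplete reflectance table; missing ",
                    paste(gaps$treatment, gaps$day, gaps$band_set,
                          sep = "/", collapse = ", ")),
             "nestcamo_completeness_error")
  }
  d0 <- min(days); d1 <- max(days)
  by_tr <- table |>
    dplyr::filter(.data$day %in% c(d0, d1)) |>
    dplyr::group_by(.data$treatment, .data$band_set, .data$day) |>
    dplyr::summarise(m = mean(.data$mean_reflectance), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "day", values_from = "m",
                       names_prefix = "day") |>
    dplyr::rename(mean_day0 = paste0("day", d0),
                  mean_final = paste0("day", d1)) |>
    dplyr::mutate(pct_change = percent_change(.data$mean_day0,
                                              .data$mean_final)) |>
    dplyr::left_join(summaries, by = "treatment") |>
    dplyr::arrange(dplyr::desc(.data$max_irradiance_wm2), .data$band_set)

  corr_for <- function(bs, rad_col) {
    sub <- dplyr::filter(by_tr, .data$band_set == bs)
    if (nrow(sub) < 3 || sd(sub[[rad_col]]) == 0) {
      return(tibble(band_set = bs, radiation_var = rad_col,
                    r = NA_real_, n = nrow(sub), p = NA_real_,
                    note = "fewer than 3 treatments or degenerate radiation"))
    }
    res <- pearson(sub$pct_change, sub[[rad_col]])
    tibble(band_set = bs, radiation_var = rad_col,
           r = res$r, n = res$n, p = res$p, note = NA_character_)
  }
  correlations <- dplyr::bind_rows(
    corr_for("VIS", "max_irradiance_wm2"),
    corr_for("UV", "max_uv_index"))

  structure(list(by_treatment = by_tr, correlations = correlations,
                 days = c(d0, d1)), class = "camo_exp1")
}

#' @export
print.camo_exp1 <- function(x, ...) {
  cat("<camo_exp1> reflectance change summary (day ", x$days[1], " -> day ",
      x$days[2], ")\n", sep = "")
  print(x$by_treatment, ...)
  cat("\ncorrelations with radiation:\n")
  print(x$correlations, ...)
  invisible(x)
}

#' @method tidy camo_exp1
#' @export
tidy.camo_exp1 <- function(x, ...) x$by_treatment

#' @method glance camo_exp1
#' @export
glance.camo_exp1 <- function(x, ...) {
  tibble(r_vis = x$correlations$r[x$correlations$band_set == "VIS"],
         r_uv = x$correlations$r[x$correlations$band_set == "UV"],
         p_vis = x$correlations$p[x$correlations$band_set == "VIS"],
         p_uv = x$correlations$p[x$correlations$band_set == "UV"],
         n_treatments = nrow(x$by_treatment) / 2)
}

#' Camouflage experiment summary
#'
#' Per visual model: day-wise mean and standard error of the camouflage
#' scores (nest as the unit), per-nest paired differences against day 0,
#' and a flag for whether mean camouflage worsened (score increased) at the
#' last day relative to day 0. Formal inference is delegated to a linear
#' mixed model (`nlme::lme(chi2 ~ factor(day), random = ~1 | nest)`) whose
#' day-effect F-test is reported verbatim.
#'
#' @param scores tibble with columns `nest`, `day`, `visual_model`, `chi2`.
#' @param mixed_model fit the delegated mixed model (default TRUE when >= 2
#'   nests and >= 2 days).
#' @return object of class `camo_exp2`: list with `day_means`, `paired`,
#'   `degradation` (per-model flag `final_gt_day0`), `mixed` (tibble of
#'   F/p per model, when fitted).
#' @export
exp2_summary <- function(scores, mixed_model = TRUE) {
  if (dplyr::n_distinct(scores$day) < 2) {
    nc_abort("need scores on at least two days", "nestcamo_data_error")
  }
  d0 <- min(scores$day); d1 <- max(scores$day)
  n_nests <- dplyr::n_distinct(scores$nest)
  day_means <- scores |>
    dplyr::group_by(.data$visual_model, .data$day) |>
    dplyr::summarise(mean = mean(.data$chi2),
                     se = if (dplyr::n() > 1) sd(.data$chi2) / sqrt(dplyr::n())
                          else NA_real_,
                     n = dplyr::n(), .groups = "drop")
  paired <- scores |>
    tidyr::pivot_wider(id_cols = c("nest", "visual_model"),
                       names_from = "day", values_from = "chi2",
                       names_prefix = "day") |>
    dplyr::mutate(diff_final = .data[[paste0("day", d1)]] -
                    .data[[paste0("day", d0)]])
  degradation <- day_means |>
    dplyr::filter(.data$day %in% c(d0, d1)) |>
    tidyr::pivot_wider(id_cols = "visual_model", names_from = "day",
                       values_from = "mean", names_prefix = "day") |>
    dplyr::mutate(final_gt_day0 = .data[[paste0("day", d1)]] >
                    .data[[paste0("day", d0)]])
  mixed <- NULL
  if (mixed_model && n_nests >= 2) {
    mixed <- purrr::map_dfr(unique(scores$visual_model), function(vm) {
      sub <- dplyr::filter(scores, .data$visual_model == vm)
      fit <- try(nlme::lme(chi2 ~ factor(day), random = ~ 1 | nest,
                           data = sub), silent = TRUE)
      if (inherits(fit, "try-error")) {
        return(tibble(visual_model = vm, F = NA_real_, p = NA_real_,
                      num_df = NA_real_, den_df = NA_real_))
      }
      a <- stats::anova(fit)
      tibble(visual_model = vm, F = a["factor(day)", "F-value"],
             p = a["factor(day)", "p-value"],
             num_df = a["factor(day)", "numDF"],
             den_df = a["factor(day)", "denDF"])
    })
  }
  structure(list(day_means = day_means, paired = paired,
                 degradation = degradation, mixed = mixed,
                 days = c(d0, d1), n_nests = n_nests),
            class = "camo_exp2")
}

#' @export
print.camo_exp2 <- function(x, ...) {
  cat("<camo_exp2> camouflage scores, ", x$n_nests, " nests, days ",
      paste(x$days, collapse = "-"), "\n", sep = "")
  print(x$day_means, ...)
  cat("\ncamouflage degraded (final day > day 0):\n")
  print(x$degradation, ...)
  if (!is.null(x$mixed)) {
    cat("\nmixed-model day effect (nlme::lme, nest random intercept):\n")
    print(x$mixed, ...)
  }
  invisible(x)
}

#' @method tidy camo_exp2
#' @export
tidy.camo_exp2 <- function(x, ...) x$day_means

#' @method glance camo_exp2
#' @export
glance.camo_exp2 <- function(x, ...) {
  tibble(n_nests = x$n_nests,
         n_models = nrow(x$degradation),
         all_models_degraded = all(x$degradation$final_gt_day0))
}
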