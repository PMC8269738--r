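# End-to-end desk-scale replications of the two field experiments.

# normalised per-band dose for a treatment after `day` days of exposure
# (dose 1 = 7 days at direct sun); VIS bands scale with the visible
# transmittance, the UV band with the UV transmittance
treatment_dose <- function(schedule, day) {
  c(rep(schedule$vis_transmittance, 3), schedule$uv_transmittance) * day / 7
}

#' Replicate the sun-exposure experiment on synthetic scenes
#'
#' Synthesises one ten-egg scene per shading treatment, photographs it
#' (camera encode), recovers reflectances through the grey-standard
#' calibration chain on each recording day, simulates the per-treatment
#' radiation records, and summarises reflectance changes and their Pearson
#' correlation with radiation via [exp1_summary()].
#'
#' @param seed integer master seed; every stage derives its own seed from it.
#' @param days recording/photography days (default 0, 3, 7).
#' @param n_eggs eggs per treatment scene (default 10).
#' @param px_per_cm pixel scale of the synthetic scenes (default 5).
#' @param image_size scene size in pixels (default `c(140, 140)`).
#' @param fading a [fading_params()] object.
#' @param crp a [camera_params()] object.
#' @return object of class `exp1_run`: list with `report` (a `camo_exp1`),
#'   `reflectance_table`, `radiation_summary`, `seed`.
#' @export
run_experiment1 <- function(seed = 1L, days = c(0, 3, 7), n_eggs = 10L,
                            px_per_cm = 5, image_size = c(140L, 140L),
                            fading = fading_params(), crp = camera_params()) {
  treatments <- treatment_table()$treatment
  tabs <- list(); recs <- list()
  for (ti in seq_along(treatments)) {
    sched <- radiation_schedule(treatments[ti])
    recs[[ti]] <- simulate_radiation(sched, days = days,
                                     seed = child_seed(seed, 500 + ti))
    params <- scene_params(image_size = image_size, px_per_cm = px_per_cm,
                           n_eggs = n_eggs,
                           rng_seed = child_seed(seed, 1000 + ti))
    for (d in days) {
      scene <- render_scene(params, day = d,
                            dose = treatment_dose(sched, d), fading = fading)
      raw <- encode_camera(scene$image, crp,
                           seed = child_seed(seed, 3000 + 17 * ti + d))
      lin <- linearize(raw)
      refl <- normalize_to_reflectance(lin, scene$regions$standard_polygon)
      attr(refl, "saturation") <- attr(lin, "saturation")
      tabs[[length(tabs) + 1L]] <-
        egg_reflectance_table(refl, scene$regions,
                              treatment = treatments[ti], day = d)
    }
  }
  table <- dplyr::bind_rows(tabs)
  rad <- summarize_radiation(dplyr::bind_rows(recs))
  report <- exp1_summary(table, rad)
  structure(list(report = report, reflectance_table = table,
                 radiation_summary = rad, seed = as.integer(seed)),
            class = "exp1_run")
}

#' @export
print.exp1_run <- function(x, ...) {
  print(x$report, ...)
  invisible(x)
}

#' Replicate the camouflage experiment on synthetic nests
#'
#' Synthesises `n_nests` three-egg nests under direct sun exposure,
#' photographs and calibrates each on every day, maps the reflectance
#' images into the cone-catch spaces of the four predator visual models,
#' scores camouflage with [camouflage_distance()], and summarises day-wise
#' changes via [exp2_summary()].
#'
#' @param seed integer master seed.
#' @param n_nests number of nests (default 7).
#' @param days photography days (default 0 and 7; add 14 for the full
#'   design).
#' @param models visual model names (default all four).
#' @param px_per_cm pixel scale (default 5; the 45-cm microhabitat circle
#'   is then 225 px across).
#' @param image_size scene size (default `c(300, 300)`, large enough for
#'   the quarter-scale filter bank).
#' @param scale_factor filter-bank rescaling (default 0.25, i.e.
#'   \eqn{\sigma = \{4, 8, 16, 32\}} px).
#' @param k texture centres (default 20).
#' @param fading a [fading_params()] object.
#' @param crp a [camera_params()] object.
#' @param mixed_model fit the delegated mixed model in the summary.
#' @param ... passed to [fit_texture_model()] via [camouflage_distance()].
#' @return object of class `exp2_run`: list with `report` (a `camo_exp2`),
#'   `scores` (nest x day x model tibble), `seed`.
#' @export
run_experiment2 <- function(seed = 1L, n_nests = 7L, days = c(0, 7),
                            models = names(visual_model_registry()),
                            px_per_cm = 5, image_size = c(300L, 300L),
                            scale_factor = 0.25, k = 20L,
                            fading = fading_params(), crp = camera_params(),
                            mixed_model = TRUE, ...) {
  bank <- build_filter_bank(scale_factor = scale_factor)
  sched <- radiation_schedule("direct")
  rows <- list()
  for (nest in seq_len(n_nests)) {
    params <- scene_params(image_size = image_size, px_per_cm = px_per_cm,
                           n_eggs = 3L,
                           rng_seed = child_seed(seed, 2000 + nest))
    for (d in days) {
      scene <- render_scene(params, day = d,
                            dose = treatment_dose(sched, d), fading = fading)
      raw <- encode_camera(scene$image, crp,
                           seed = child_seed(seed, 4000 + 31 * nest + d))
      lin <- linearize(raw)
      refl <- normalize_to_reflectance(lin, scene$regions$standard_polygon)
      sc <- camouflage_multimodel(
        refl, scene$regions, models, bank, k = k,
        seed_for = function(mn) {
          child_seed(seed, 6000 + 97 * nest + 13 * d + match(mn, models))
        }, ...)
      rows[[length(rows) + 1L]] <-
        dplyr::mutate(
          dplyr::select(sc, "visual_model", "chi2", "n_egg_px",
                        "n_microhabitat_px"),
          nest = nest, day = d, .before = 1)
    }
  }
  scores <- dplyr::bind_rows(rows)
  report <- exp2_summary(scores, mixed_model = mixed_model)
  structure(list(report = report, scores = scores, seed = as.integer(seed)),
            class = "exp2_run")
}

#' @export
print.exp2_run <- function(x, ...) {
  print(x$report, ...)
  invisible(x)
}

#' Synthesise and write a set of nest scenes
#'
#' Desk-scale stand-in for a field campaign: renders `n_nests` nests on
#' each day under direct-sun fading and writes per-scene VIS/UV TIFFs,
#' region JSON and one radiation CSV into `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed.
#' @param n_nests number of nests (default 15, the full design).
#' @param days photography days (default 0, 7, 14).
#' @param px_per_cm,image_size scene geometry.
#' @param fading a [fading_params()] object.
#' @return (invisibly) tibble manifest of the files written.
#' @export
synthesize_nest_scenes <- function(out_dir, seed = 1L, n_nests = 15L,
                                   days = c(0, 7, 14), px_per_cm = 5,
                                   image_size = c(300L, 300L),
                                   fading = fading_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sched <- radiation_schedule("direct")
  rad <- simulate_radiation(sched, days = days, seed = child_seed(seed, 900))
  write_radiation_csv(rad, file.path(out_dir, "radiation.csv"))
  manifest <- list()
  for (nest in seq_len(n_nests)) {
    params <- scene_params(image_size = image_size, px_per_cm = px_per_cm,
                           n_eggs = 3L,
                           rng_seed = child_seed(seed, 2000 + nest))
    for (d in days) {
      scene <- render_scene(params, day = d,
                            dose = treatment_dose(sched, d), fading = fading)
      id <- sprintf("nest%02d_day%02d", nest, d)
      files <- write_scene(scene, out_dir, id)
      manifest[[length(manifest) + 1L]] <-
        tibble(nest = nest, day = d, id = id,
               vis = files$vis, uv = files$uv, regions = files$regions)
    }
  }
  invisible(dplyr::bind_rows(manifest))
}
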