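# Grey-standard calibration, ROI extraction, radiation summaries.

test_that("rasterisation matches the brute-force point-in-polygon oracle", {
  # concave (star-like) polygon plus a rotated ellipse
  star <- cbind(c(10, 14, 24, 16, 19, 10, 2, 5, -3, 6),
                c(0, 8, 9, 14, 24, 18, 24, 14, 9, 8)) + 3
  ell <- ellipse_polygon(15, 14, 9, 5, pi / 7)
  for (poly in list(star, ell)) {
    expect_identical(rasterize_polygon(poly, c(30, 32)),
                     oracle_rasterize(poly, c(30, 32)))
  }
})

test_that("normalisation anchors the standard at 0.25 and is idempotent and exposure-invariant", {
  set.seed(42)
  lin <- array(runif(40 * 40 * 4, 0.1, 2), c(40, 40, 4))
  std <- rect_polygon(2, 2, 14, 14)
  refl <- normalize_to_reflectance(lin, std)
  m <- rasterize_polygon(std, c(40, 40))
  for (b in 1:4) expect_equal(mean(refl[, , b][m]), 0.25)
  # uniform image at the standard level -> constant 0.25; 2x -> 0.5
  u <- array(rep(c(3, 6), each = 40 * 20), c(40, 40, 1))
  ur <- normalize_to_reflectance(u, rect_polygon(1, 1, 15, 30))
  expect_true(all(abs(ur[, 1:20, 1] - 0.25) < 1e-12))
  expect_true(all(abs(ur[, 21:40, 1] - 0.5) < 1e-12))
  # idempotence
  expect_equal(normalize_to_reflectance(refl, std), refl,
               ignore_attr = TRUE)
  # global exposure invariance
  expect_equal(normalize_to_reflectance(lin * 3.7, std), refl,
               ignore_attr = TRUE)
  expect_error(normalize_to_reflectance(lin, rect_polygon(2, 2, 5, 5)),
               class = "nestcamo_calibration_error")
})

test_that("ROI means follow the band-set definition", {
  img <- array(0, c(4, 4, 4))
  img[, , 1] <- 0.1; img[, , 2] <- 0.2; img[, , 3] <- 0.3; img[, , 4] <- 0.7
  whole <- rect_polygon(-0.5, -0.5, 4, 4)
  expect_equal(roi_mean_reflectance(img, whole, "VIS"), 0.2)
  expect_equal(roi_mean_reflectance(img, whole, "UV"), 0.7)
  # 2-pixel region with VIS means 0.1 and 0.3 -> 0.2
  img2 <- array(0, c(1, 2, 4))
  img2[1, 1, 1:3] <- 0.1; img2[1, 2, 1:3] <- 0.3
  expect_equal(roi_mean_reflectance(img2, rect_polygon(-0.5, -0.5, 2, 1),
                                    "VIS"), 0.2)
  expect_error(roi_mean_reflectance(img, rect_polygon(10, 10, 2, 2), "VIS"),
               class = "nestcamo_geometry_error")
})

test_that("full calibration chain recovers known egg reflectances", {
  p <- small_scene_params(seed = 21L, noise_sd = 0, jitter = 0.008)
  s <- render_scene(p)
  raw <- encode_camera(s$image, camera_params(shot_noise_sd = 0), seed = 1)
  refl <- normalize_to_reflectance(linearize(raw),
                                   s$regions$standard_polygon)
  for (e in seq_along(s$regions$egg_polygons)) {
    for (bs in c("VIS", "UV")) {
      truth <- roi_mean_reflectance(s$image, s$regions$egg_polygons[[e]], bs)
      got <- roi_mean_reflectance(refl, s$regions$egg_polygons[[e]], bs)
      expect_equal(got, truth, tolerance = 0.01)
    }
  }
})

test_that("percent change is plain relative change", {
  expect_equal(percent_change(0.2, 0.4), 100)
  expect_equal(percent_change(0.5, 0.5), 0)
  expect_equal(percent_change(0.175, 0.361), 106.2857, tolerance = 1e-6)
  expect_error(percent_change(0, 0.5), class = "nestcamo_domain_error")
})

test_that("radiation summaries are means of within-day maxima", {
  # hand-built record: daily maxima 700, 730, 760 -> 730
  rec <- tibble::tibble(
    treatment = "direct",
    day = rep(1:3, each = 4),
    timestamp = as.character(1:12),
    irradiance_wm2 = c(1, 700, 5, 2, 730, 1, 2, 3, 4, 5, 760, 6),
    illuminance_lux = 0, uv_index = 0)
  out <- summarize_radiation(rec)
  expect_equal(out$max_irradiance_wm2, 730)
  # one day, constant series -> the constant
  rec1 <- dplyr::mutate(rec[1:4, ], irradiance_wm2 = 5, uv_index = 2)
  out1 <- summarize_radiation(rec1)
  expect_equal(out1$max_irradiance_wm2, 5)
  expect_equal(out1$max_uv_index, 2)
  expect_error(summarize_radiation(rec[0, ]), class = "nestcamo_data_error")
})

test_that("simulated radiation matches the treatment peaks and scan oracle", {
  recs <- dplyr::bind_rows(lapply(treatment_table()$treatment, function(tr) {
    simulate_radiation(radiation_schedule(tr), days = c(0, 3, 7), seed = 5)
  }))
  expect_equal(sum(recs$treatment == "direct"), 3 * 145) # 145 points/day
  summ <- summarize_radiation(recs)
  # against a brute-force scan over the raw series
  for (tr in summ$treatment) {
    sub <- recs[recs$treatment == tr, ]
    manual <- mean(vapply(split(sub$irradiance_wm2, sub$day), max,
                          numeric(1)))
    expect_equal(summ$max_irradiance_wm2[summ$treatment == tr], manual)
  }
  # anchored near the recorded maxima, ordering preserved
  direct <- summ[summ$treatment == "direct", ]
  black <- summ[summ$treatment == "black", ]
  expect_equal(direct$max_irradiance_wm2, 730, tolerance = 0.05)
  expect_equal(direct$max_uv_index, 7.5, tolerance = 0.05)
  expect_equal(black$max_irradiance_wm2, 7, tolerance = 0.05)
  expect_equal(black$max_uv_index, 0.1, tolerance = 0.05)
  ord <- c("direct", "white1", "white2", "white4", "black")
  irr <- summ$max_irradiance_wm2[match(ord, summ$treatment)]
  uvi <- summ$max_uv_index[match(ord, summ$treatment)]
  expect_true(all(diff(irr) < 0) && all(diff(uvi) < 0))
  expect_error(radiation_schedule("green"), class = "nestcamo_config_error")
})
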