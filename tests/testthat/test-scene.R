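# Synthetic scene generator: geometry, colours, fading, determinism.

test_that("scene geometry is annotated exactly and masks are disjoint", {
  s <- render_scene(small_scene_params(seed = 3L))
  dims <- dim(s$image)[1:2]
  egg_masks <- lapply(s$regions$egg_polygons, rasterize_polygon, dim = dims)
  std_mask <- rasterize_polygon(s$regions$standard_polygon, dims)
  # polygons exactly delimit the painted regions
  expect_identical(Reduce(`|`, egg_masks), s$masks$egg)
  expect_identical(std_mask, s$masks$standard)
  # pairwise disjoint, all inside the frame
  occ <- Reduce(`+`, egg_masks) + std_mask
  expect_lte(max(occ), 1)
  expect_true(all(s$image >= 0 & s$image <= 1))
})

test_that("unfaded egg ground pixels and the grey standard have their nominal reflectance", {
  p <- small_scene_params(seed = 5L, noise_sd = 0.002, jitter = 0)
  s <- render_scene(p, day = 0, dose = 0)
  ground_mask <- s$masks$egg & !s$masks$spot
  n <- sum(ground_mask)
  for (b in 1:4) {
    expect_equal(mean(s$image[, , b][ground_mask]),
                 p$band_reflectance_egg_ground[b],
                 tolerance = 4 * p$noise_sd / sqrt(n) /
                   p$band_reflectance_egg_ground[b])
  }
  n_std <- sum(s$masks$standard)
  for (b in 1:4) {
    expect_equal(mean(s$image[, , b][s$masks$standard]), 0.25,
                 tolerance = 4 * p$noise_sd / sqrt(n_std) / 0.25)
  }
})

test_that("scenes are bit-identical under a fixed seed and vary with it", {
  p <- small_scene_params(seed = 11L)
  s1 <- render_scene(p, day = 7, dose = 1)
  s2 <- render_scene(p, day = 7, dose = 1)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$regions, s2$regions)
  s3 <- render_scene(small_scene_params(seed = 12L), day = 7, dose = 1)
  expect_false(identical(s1$image, s3$image))
})

test_that("geometry that cannot fit raises a geometry error", {
  p <- scene_params(image_size = c(40L, 40L), px_per_cm = 10, n_eggs = 5L)
  expect_error(render_scene(p), class = "nestcamo_geometry_error")
})

test_that("fading is identity at dose zero, monotone, capped, per-band", {
  fp <- fading_params()
  x <- c(0.28, 0.20, 0.13, 0.145)
  expect_identical(apply_fading(x, 0, fp), x)
  d <- sort(runif(10, 0, 6))
  prev <- apply_fading(x, d[1], fp)
  for (i in 2:10) {
    cur <- apply_fading(x, d[i], fp)
    expect_true(all(cur >= prev - 1e-12))
    expect_true(all(cur <= fp$cap + 1e-12))
    prev <- cur
  }
  # separate VIS and UV doses act on their own bands
  out <- apply_fading(x, c(1, 1, 1, 0), fp)
  expect_equal(out[4], x[4])
  expect_equal(out[1:3], x[1:3] + fp$slope_per_band[1:3])
  expect_error(apply_fading(x, -1, fp), class = "nestcamo_domain_error")
})

test_that("default fading reproduces the observed direct-sun reflectance change", {
  # egg-mean VIS 0.175 -> ~0.361 (+106%) and UV 0.124 -> 0.213 (+71%) after
  # one unit of dose (a week of direct sun)
  p <- scene_params()
  f <- p$spot_fraction
  vis0 <- mean((1 - f) * p$band_reflectance_egg_ground[1:3] +
                 f * p$band_reflectance_egg_spot[1:3])
  uv0 <- (1 - f) * p$band_reflectance_egg_ground[4] +
    f * p$band_reflectance_egg_spot[4]
  expect_equal(vis0, 0.175, tolerance = 1e-3)
  expect_equal(uv0, 0.124, tolerance = 1e-3)
  fp <- fading_params()
  vis7 <- vis0 + fp$slope_per_band[1] # same slope on ground and spots
  uv7 <- uv0 + fp$slope_per_band[4]
  expect_equal(vis7, 0.361, tolerance = 0.01)
  expect_equal(percent_change(vis0, vis7), 106.3, tolerance = 0.01)
  expect_equal(uv7, 0.213, tolerance = 0.01)
})

test_that("camera encoding hits the documented anchor points", {
  crp <- camera_params(gamma = 1, gain = 2^12 - 1 - 100, black_level = 100,
                       bit_depth = 12L, shot_noise_sd = 0)
  img <- array(c(0, 1), c(1, 2, 1))
  raw <- encode_camera(img, crp)
  expect_equal(raw$dn[1, 1, 1], 100)       # reflectance 0 -> black level
  expect_equal(raw$dn[1, 2, 1], 2^12 - 1)  # reflectance 1 -> full scale
  expect_error(camera_params(bit_depth = 6L), class = "nestcamo_config_error")
  expect_error(encode_camera(array(1.5, c(1, 1, 1)), crp),
               class = "nestcamo_domain_error")
})

test_that("encode then linearize inverts the transfer function", {
  ramp <- array(seq(0.01, 0.99, length.out = 64), c(8, 8, 1))
  crp <- camera_params(gamma = 2.2, shot_noise_sd = 0)
  lin <- linearize(encode_camera(ramp, crp, quantize = FALSE))
  expect_lt(max(abs(lin - ramp) / ramp), 1e-6)
  # quantised path: within a DN of rounding
  lin_q <- linearize(encode_camera(ramp, crp, quantize = TRUE))
  expect_lt(max(abs(lin_q - ramp) / ramp), 1e-2)
  # linear camera inverts exactly as (DN - black)/gain
  crp1 <- camera_params(gamma = 1, gain = 1000, black_level = 64,
                        shot_noise_sd = 0)
  raw <- encode_camera(ramp, crp1, quantize = FALSE)
  expect_equal(as.vector(linearize(raw)),
               as.vector((raw$dn - 64) / 1000))
  expect_equal(linearize(encode_camera(array(0, c(2, 2, 1)), crp1))[1, 1, 1], 0)
})
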