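# Texture vocabulary, labelling, signatures and the chi-square score.

test_that("chi-square distance has its analytic properties and hand value", {
  expect_equal(chi_square_distance(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(chi_square_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(chi_square_distance(c(0.5, 0.5), c(0.25, 0.75)), 0.0666667,
               tolerance = 1e-6)
  # symmetry, bounds and zero-iff-equal over random normalised histograms
  set.seed(31)
  for (i in 1:50) {
    h1 <- runif(20); h1[sample(20, 5)] <- 0; h1 <- h1 / sum(h1)
    h2 <- runif(20); h2[sample(20, 5)] <- 0; h2 <- h2 / sum(h2)
    d <- chi_square_distance(h1, h2)
    expect_equal(d, chi_square_distance(h2, h1))
    expect_gte(d, 0); expect_lte(d, 1)
    if (d == 0) expect_equal(h1, h2)
  }
  expect_error(chi_square_distance(c(1, 0), c(0.5, 0.5, 0)),
               class = "nestcamo_shape_error")
  expect_error(chi_square_distance(c(0.7, 0.7), c(0.5, 0.5)),
               class = "nestcamo_domain_error")
})

test_that("labelling agrees with the exhaustive nearest-centre oracle", {
  set.seed(13)
  x <- matrix(rnorm(100 * 6), 100, 6)
  model <- fit_texture_model(x, k = 7, seed = 2)
  labs <- assign_labels(x, model)
  xs <- sweep(sweep(x, 2, model$mean), 2, model$sd, "/")
  expect_identical(labs, oracle_labels(xs, model$centers))
  # a pixel sitting exactly on a centre gets that centre's label
  x7 <- matrix(model$centers[5, ] * model$sd + model$mean, 1)
  expect_equal(assign_labels(x7, model), 5L)
  expect_error(assign_labels(matrix(0, 3, 4), model),
               class = "nestcamo_shape_error")
})

test_that("equidistant pixels take the lowest centre index", {
  model <- structure(list(
    centers = rbind(c(5, 5), c(-1, 0), c(9, 9), c(-3, 3), c(1, 0)),
    mean = c(0, 0), sd = c(1, 1), k = 5L, seed = 1L,
    tot_withinss = 0, iterations = 0L), class = "texture_model")
  # (0, 0) is exactly equidistant from centres 2 and 5
  expect_equal(assign_labels(matrix(c(0, 0), 1), model), 2L)
})

test_that("region signatures are normalised label histograms", {
  expect_equal(region_signature(c(1, 1, 2, 4), 4), c(0.5, 0.25, 0, 0.25))
  expect_equal(region_signature(rep(3, 10), 5), c(0, 0, 1, 0, 0))
  set.seed(3)
  for (i in 1:10) {
    labs <- sample(1:20, 200, replace = TRUE)
    expect_equal(sum(region_signature(labs, 20)), 1)
  }
  expect_error(region_signature(integer(0), 4), class = "nestcamo_data_error")
})

test_that("K-means vocabulary recovers a planted two-texture partition", {
  # left half: fine grain on a dark tone; right half: coarse blobs on a
  # light tone, with shared pixel noise. The model is fitted on interior
  # windows of the two textures (the pipeline never clusters frame borders
  # or region seams), and the two-centre assignment must recover the halves.
  set.seed(17)
  H <- 60; W <- 80
  fine <- matrix(rnorm(H * W), H, W)
  smooth <- function(m, s) {
    k <- dnorm(-15:15, sd = s); k <- k / sum(k)
    a <- apply(m, 2, function(col) as.numeric(stats::filter(col, k,
                                                            circular = TRUE)))
    t(apply(a, 1, function(row) as.numeric(stats::filter(row, k,
                                                         circular = TRUE))))
  }
  coarse <- smooth(matrix(rnorm(H * W), H, W), 4)
  coarse <- coarse / sd(coarse)
  img <- cbind(0.35 + 0.02 * fine[, 1:(W / 2)],
               0.65 + 0.02 * coarse[, (W / 2 + 1):W]) +
    0.04 * matrix(rnorm(H * W), H, W)
  bank <- tiny_bank(scales = c(2, 4))
  mask <- matrix(FALSE, H, W)
  mask[15:45, 10:30] <- TRUE
  mask[15:45, 50:70] <- TRUE
  feats <- apply_filter_bank(img, bank, mask = mask)
  model <- fit_texture_model(feats, k = 2, seed = 5)
  labs <- matrix(NA_integer_, H, W)
  labs[attr(feats, "pixels")] <- assign_labels(feats, model)
  left <- labs[15:45, 10:30]; right <- labs[15:45, 50:70]
  maj_left <- as.integer(names(which.max(table(left))))
  maj_right <- as.integer(names(which.max(table(right))))
  expect_true(maj_left != maj_right)
  agree <- (sum(left == maj_left) + sum(right == maj_right)) /
    (length(left) + length(right))
  expect_gte(agree, 0.95)
})

test_that("texture model fitting is deterministic, duplication-invariant, and sized k", {
  set.seed(23)
  x <- matrix(rnorm(300 * 8), 300, 8)
  m1 <- fit_texture_model(x, k = 20, seed = 9)
  m2 <- fit_texture_model(x, k = 20, seed = 9)
  expect_identical(m1$centers, m2$centers)
  expect_equal(nrow(m1$centers), 20)
  # duplicating every pixel leaves well-separated centres unchanged
  blobs <- matrix(rnorm(200 * 2, sd = 0.05), 200, 2) +
    matrix(c(0, 10, 0, 10, 0, 0, 10, 10), 4, 2)[rep(1:4, each = 50), ]
  m3 <- fit_texture_model(rbind(blobs, blobs), k = 4, seed = 9)
  m4 <- fit_texture_model(blobs, k = 4, seed = 9)
  # compare in raw feature space: duplication leaves cluster means exactly
  # unchanged, while the standardisation SD shifts at O(1/n)
  raw <- function(m) {
    cm <- sweep(sweep(m$centers, 2, m$sd, "*"), 2, m$mean, "+")
    cm[order(cm[, 1], cm[, 2]), ]
  }
  expect_equal(raw(m3), raw(m4), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(fit_texture_model(x[1:5, ], k = 20),
               class = "nestcamo_data_error")
})

test_that("camouflage scoring hits the perfect and broken-camouflage limits", {
  # regions: two large square "eggs" inside the microhabitat circle
  ppc <- 5
  H <- 200; W <- 200
  regions <- region_set(
    egg_polygons = list(rect_polygon(55, 70, 30, 30),
                        rect_polygon(115, 70, 30, 30)),
    standard_polygon = rect_polygon(2, 2, 12, 12),
    nest_centre = c(100, 100), px_per_cm = ppc)
  bank <- tiny_bank(scales = c(2, 4))
  smooth_field <- function(seed) {
    set.seed(seed)
    k <- exp(-(-9:9)^2 / 8); k <- k / sum(k)
    f <- apply(matrix(rnorm(H * W), H, W), 2,
               function(col) stats::filter(col, k, circular = TRUE))
    f <- t(apply(f, 1, function(row) stats::filter(row, k, circular = TRUE)))
    0.3 + 0.05 * f / sd(f)
  }
  # eggs carry the background's own texture -> near-zero distance
  img_same <- smooth_field(41)
  sc_same <- camouflage_distance(img_same, regions, bank = bank, k = 8,
                                 seed = 3, microhabitat_diameter_cm = 36)
  expect_lte(sc_same$chi2, 0.05)
  # uniform bright eggs on dark clutter -> strong separation
  img_diff <- smooth_field(42) * 0.3
  emask <- rasterize_polygon(regions$egg_polygons[[1]], c(H, W)) |
    rasterize_polygon(regions$egg_polygons[[2]], c(H, W))
  img_diff[emask] <- 0.9
  sc_diff <- camouflage_distance(img_diff, regions, bank = bank, k = 8,
                                 seed = 3, microhabitat_diameter_cm = 36)
  expect_gte(sc_diff$chi2, 0.5)
  # determinism under a fixed seed
  sc_rep <- camouflage_distance(img_diff, regions, bank = bank, k = 8,
                                seed = 3, microhabitat_diameter_cm = 36)
  expect_identical(sc_diff$chi2, sc_rep$chi2)
  # circle fully outside the frame is a geometry error
  bad <- region_set(regions$egg_polygons, regions$standard_polygon,
                    nest_centre = c(5000, 5000), px_per_cm = ppc)
  expect_error(camouflage_distance(img_same, bad, bank = bank),
               class = "nestcamo_geometry_error")
})

test_that("multi-model scoring equals the per-model reference path", {
  p <- scene_params(image_size = c(160L, 160L), px_per_cm = 2.5, n_eggs = 3L,
                    rng_seed = 19L)
  s <- render_scene(p, day = 7, dose = 1)
  bank <- tiny_bank(scales = c(2, 4))
  multimodel <- getFromNamespace("camouflage_multimodel", "nestcamo")
  mm <- multimodel(s$image, s$regions, c("ferret", "bluetit"), bank, k = 6,
                   seed_for = function(m) 5L)
  for (mn in c("ferret", "bluetit")) {
    cc <- map_to_visual_model(s$image, mn)
    ref <- camouflage_distance(cc, s$regions, bank = bank, k = 6, seed = 5)
    expect_equal(mm$chi2[mm$visual_model == mn], ref$chi2, tolerance = 1e-6)
  }
})
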