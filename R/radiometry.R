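#' Camera response parameters
#'
#' Idealised per-channel power-law camera: digital numbers are
#' `DN = black_level + gain * reflectance^(1/gamma) + noise`, clipped to the
#' sensor range. The contract that matters downstream is that
#' [linearize()] inverts this encoding.
#'
#' @param gamma encoding exponent (> 0); 1 gives a linear camera.
#' @param gain DN per unit (gamma-encoded) reflectance.
#' @param black_level sensor black level in DN.
#' @param bit_depth bits per sample (>= 8).
#' @param shot_noise_sd Gaussian noise SD in DN.
#' @return object of class `camera_params`.
#' @export
camera_params <- function(gamma = 2.2, gain = 60000, black_level = 512,
                          bit_depth = 16L, shot_noise_sd = 2) {
  if (bit_depth < 8) nc_abort("bit_depth must be >= 8", "nestcamo_config_error")
  if (gamma <= 0 || gain <= 0) {
    nc_abort("gamma and gain must be > 0", "nestcamo_config_error")
  }
  structure(list(gamma = gamma, gain = gain, black_level = black_level,
                 bit_depth = as.integer(bit_depth),
                 shot_noise_sd = shot_noise_sd), class = "camera_params")
}

#' Encode a reflectance image to camera digital numbers
#'
#' @param image reflectance array (values in \[0, 1\]).
#' @param crp a [camera_params()] object.
#' @param seed integer seed for the shot noise.
#' @param quantize round DN to integers (the camera contract). Set `FALSE`
#'   to study the pure transfer function without quantisation error.
#' @return object of class `raw_image`: list with `dn` (same shape as
#'   `image`) and `crp`.
#' @export
encode_camera <- function(image, crp = camera_params(), seed = 1L,
                          quantize = TRUE) {
  if (min(image) < 0 || max(image) > 1) {
    nc_abort("reflectance must be in [0, 1] before encoding",
             "nestcamo_domain_error")
  }
  full <- 2^crp$bit_depth - 1
  dn <- crp$black_level + crp$gain * image^(1 / crp$gamma)
  if (crp$shot_noise_sd > 0) {
    dn <- withr::with_seed(seed, {
      dn + array(rnorm(length(dn), 0, crp$shot_noise_sd), dim(dn))
    })
  }
  if (quantize) dn <- round(dn)
  dn <- pmin(pmax(dn, 0), full)
  dimnames(dn) <- dimnames(image)
  structure(list(dn = dn, crp = crp), class = "raw_image")
}

#' Invert the camera encoding
#'
#' Subtracts the black level, undoes the power-law encoding and clips
#' negative excursions to zero. The output is proportional to scene radiance
#' (equal to reflectance for a noiseless encode). Saturated pixels
#' (DN at full scale) are flagged in a `saturation` attribute and excluded
#' from later calibration/ROI means.
#'
#' @param raw a [encode_camera()] object, or a DN array.
#' @param crp a [camera_params()] object (defaults to the one stored in `raw`).
#' @return linear image array with logical attribute `saturation`.
#' @export
linearize <- function(raw, crp = NULL) {
  if (inherits(raw, "raw_image")) {
    crp <- crp %||% raw$crp
    dn <- raw$dn
  } else {
    if (is.null(crp)) nc_abort("crp required for a bare DN array",
                               "nestcamo_config_error")
    dn <- raw
  }
  full <- 2^crp$bit_depth - 1
  sat <- dn >= full
  lin <- pmax(dn - crp$black_level, 0) / crp$gain
  lin <- lin^crp$gamma
  attr(lin, "saturation") <- sat
  lin
}

#' Normalise a linear image to reflectance via the grey standard
#'
#' Per channel, `R(p) = standard_reflectance * L(p) / mean(L over standard)`,
#' so the standard patch averages exactly `standard_reflectance` by
#' construction. Saturated pixels (from [linearize()]) are excluded from the
#' standard mean.
#'
#' @param linear linear image (H x W x C array), typically from [linearize()].
#' @param standard_polygon vertex matrix of the grey-standard region.
#' @param standard_reflectance known reflectance of the standard (default 0.25).
#' @param min_pixels minimum number of usable standard pixels (default 100).
#' @return reflectance image (same shape), `saturation` attribute carried
#'   forward. Values above 1 are retained (specular pixels can exceed the
#'   standard).
#' @export
normalize_to_reflectance <- function(linear, standard_polygon,
                                     standard_reflectance = 0.25,
                                     min_pixels = 100L) {
  if (is.matrix(linear)) linear <- array(linear, c(dim(linear), 1L))
  H <- dim(linear)[1]; W <- dim(linear)[2]; C <- dim(linear)[3]
  mask <- rasterize_polygon(standard_polygon, c(H, W))
  sat <- attr(linear, "saturation")
  out <- linear
  for (b in seq_len(C)) {
    ok <- mask
    if (!is.null(sat)) ok <- ok & !sat[, , b]
    if (sum(ok) < min_pixels) {
      nc_abort(sprintf("only %d usable standard pixels (need >= %d)",
                       sum(ok), min_pixels), "nestcamo_calibration_error")
    }
    m <- mean(linear[, , b][ok])
    if (m <= 0) nc_abort("standard mean is not positive",
                         "nestcamo_calibration_error")
    out[, , b] <- standard_reflectance * linear[, , b] / m
  }
  attr(out, "saturation") <- sat
  out
}

#' Mean reflectance over a region of interest
#'
#' `band_set = "VIS"` averages the per-pixel mean of the R, G and B channels
#' over the polygon; `"UV"` averages the UV channel. Rasterisation uses the
#' pixel-centre rule; saturated pixels are excluded.
#'
#' @param image 4-band reflectance image (R, G, B, UV).
#' @param polygon region-of-interest vertex matrix.
#' @param band_set `"VIS"` or `"UV"`.
#' @return scalar mean reflectance.
#' @export
roi_mean_reflectance <- function(image, polygon, band_set = c("VIS", "UV")) {
  band_set <- match.arg(band_set)
  H <- dim(image)[1]; W <- dim(image)[2]
  mask <- rasterize_polygon(polygon, c(H, W))
  if (!any(mask)) nc_abort("polygon rasterises to an empty pixel set",
                           "nestcamo_geometry_error")
  bands <- if (band_set == "VIS") 1:3 else 4L
  sat <- attr(image, "saturation")
  if (!is.null(sat)) {
    bad <- Reduce(`|`, lapply(bands, function(b) sat[, , b]))
    mask <- mask & !bad
    if (!any(mask)) nc_abort("all ROI pixels saturated",
                             "nestcamo_geometry_error")
  }
  mean(vapply(bands, function(b) mean(image[, , b][mask]), numeric(1)))
}

#' Percent change of reflectance
#'
#' @param r0 initial value(s), must be > 0.
#' @param rt final value(s).
#' @return `100 * (rt - r0) / r0`.
#' @export
percent_change <- function(r0, rt) {
  if (any(r0 <= 0)) nc_abort("initial reflectance must be > 0",
                             "nestcamo_domain_error")
  100 * (rt - r0) / r0
}

#' Per-egg reflectance table for a scene
#'
#' Runs [roi_mean_reflectance()] for every egg polygon in both band sets and
#' returns a tidy table.
#'
#' @param image 4-band reflectance image.
#' @param regions a [region_set()].
#' @param ... constant columns prepended to the table (e.g. `scene_id`,
#'   `treatment`, `day`).
#' @return tibble with columns `...`, `egg_id`, `band_set`,
#'   `mean_reflectance`.
#' @export
egg_reflectance_table <- function(image, regions, ...) {
  meta <- tibble(...)
  rows <- purrr::map_dfr(seq_along(regions$egg_polygons), function(e) {
    purrr::map_dfr(c("VIS", "UV"), function(bs) {
      tibble(egg_id = e, band_set = bs,
             mean_reflectance = roi_mean_reflectance(
               image, regions$egg_polygons[[e]], bs))
    })
  })
  if (ncol(meta)) dplyr::bind_cols(meta[rep(1, nrow(rows)), ], rows) else rows
}
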