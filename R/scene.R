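#' Parameters of a synthetic nest scene
#'
#' Describes a ground-nest scene: a heterogeneous background, `n_eggs`
#' spotted egg ellipses around the nest centre, and an in-frame grey
#' standard of exactly 25% reflectance. Reflectances are 4-vectors over the
#' bands VIS-R, VIS-G, VIS-B, UV, all in \[0, 1\].
#'
#' Default egg colours put the day-0 egg-mean reflectance at 0.175 in VIS
#' (mean of R, G, B) and 0.124 in UV — the starting values of sun-exposed
#' quail eggs — split between a lighter ground colour and darker maculation
#' covering `spot_fraction` of the egg area.
#'
#' @param image_size `c(H, W)` in pixels.
#' @param px_per_cm pixels per centimetre (> 0).
#' @param n_eggs number of eggs (>= 1).
#' @param egg_axes_cm major and minor egg axes in cm.
#' @param spot_fraction target fraction of egg area covered by maculation,
#'   in \[0, 1).
#' @param band_reflectance_egg_ground,band_reflectance_egg_spot,band_reflectance_background_base
#'   4-vectors of reflectance (R, G, B, UV) in \[0, 1\].
#' @param background_texture list with `grain_cm` (clutter grain size, cm),
#'   `contrast` (reflectance SD of the clutter field) and `band_correlation`
#'   (share of clutter variance common to all bands, in \[0, 1\]).
#' @param egg_reflectance_jitter SD of the per-egg brightness offset
#'   (reflectance units), emulating between-female variation.
#' @param standard_side_cm side of the square grey standard, cm.
#' @param noise_sd pixel noise SD in reflectance units.
#' @param rng_seed integer seed; scenes are bit-reproducible given the seed.
#' @return object of class `scene_params` (a validated list).
#' @export
scene_params <- function(image_size = c(512L, 512L),
                         px_per_cm = 10,
                         n_eggs = 3L,
                         egg_axes_cm = c(3.3, 2.5),
                         spot_fraction = 0.25,
                         band_reflectance_egg_ground = c(0.28, 0.20, 0.13, 0.145333),
                         band_reflectance_egg_spot = c(0.12, 0.09, 0.06, 0.06),
                         band_reflectance_background_base = c(0.26, 0.20, 0.14, 0.12),
                         background_texture = list(grain_cm = 1.2,
                                                   contrast = 0.05,
                                                   band_correlation = 0.7),
                         egg_reflectance_jitter = 0.008,
                         standard_side_cm = 4,
                         noise_sd = 0.004,
                         rng_seed = 1L) {
  p <- list(image_size = as.integer(image_size), px_per_cm = px_per_cm,
            n_eggs = as.integer(n_eggs), egg_axes_cm = egg_axes_cm,
            spot_fraction = spot_fraction,
            band_reflectance_egg_ground = band_reflectance_egg_ground,
            band_reflectance_egg_spot = band_reflectance_egg_spot,
            band_reflectance_background_base = band_reflectance_background_base,
            background_texture = background_texture,
            egg_reflectance_jitter = egg_reflectance_jitter,
            standard_side_cm = standard_side_cm,
            noise_sd = noise_sd, rng_seed = as.integer(rng_seed))
  refl <- c(p$band_reflectance_egg_ground, p$band_reflectance_egg_spot,
            p$band_reflectance_background_base)
  if (length(refl) != 12 || any(refl < 0) || any(refl > 1)) {
    nc_abort("band reflectances must be 4-vectors in [0, 1]",
             "nestcamo_config_error")
  }
  if (p$px_per_cm <= 0) nc_abort("px_per_cm must be > 0", "nestcamo_config_error")
  if (p$n_eggs < 1) nc_abort("n_eggs must be >= 1", "nestcamo_config_error")
  if (p$spot_fraction < 0 || p$spot_fraction >= 1) {
    nc_abort("spot_fraction must be in [0, 1)", "nestcamo_config_error")
  }
  if (p$noise_sd < 0) nc_abort("noise_sd must be >= 0", "nestcamo_config_error")
  structure(p, class = "scene_params")
}

#' Egg-fading model parameters
#'
#' Fading is linear-with-cap in cumulative normalised radiation dose:
#' `out = min(in + slope * dose, cap)` per band, where dose 1 corresponds to
#' seven days under direct sun. Default slopes are calibrated so that one
#' unit of dose takes the egg-mean reflectance from 0.175 to 0.361 in VIS
#' and from 0.124 to 0.213 in UV, the observed week of direct exposure.
#'
#' @param slope_per_band 4-vector of reflectance increase per unit dose
#'   (R, G, B, UV), all >= 0.
#' @param cap maximum reflectance after fading (<= 1).
#' @param dose_unit documentation string for the dose normalisation.
#' @return object of class `fading_params`.
#' @export
fading_params <- function(slope_per_band = c(0.186, 0.186, 0.186, 0.089),
                          cap = 0.95,
                          dose_unit = "1 = 7 days at direct-sun irradiance") {
  if (length(slope_per_band) != 4 || any(slope_per_band < 0)) {
    nc_abort("slope_per_band must be a non-negative 4-vector",
             "nestcamo_config_error")
  }
  if (cap > 1 || cap <= 0) nc_abort("cap must be in (0, 1]", "nestcamo_config_error")
  structure(list(slope_per_band = slope_per_band, cap = cap,
                 dose_unit = dose_unit), class = "fading_params")
}

#' Apply radiation-driven fading to reflectances
#'
#' @param x a reflectance 4-vector or an H x W x 4 reflectance array.
#' @param dose normalised dose: a scalar, or a 4-vector giving a separate
#'   dose per band (VIS and UV doses scale with different radiation
#'   quantities, so pipelines pass `c(d_vis, d_vis, d_vis, d_uv)`).
#' @param fp a [fading_params()] object.
#' @return same shape as `x`; identity at dose 0, monotone non-decreasing in
#'   dose, never exceeding `fp$cap` (nor decreasing values already above it).
#' @export
apply_fading <- function(x, dose, fp = fading_params()) {
  if (any(dose < 0)) nc_abort("dose must be >= 0", "nestcamo_domain_error")
  if (!length(dose) %in% c(1L, 4L)) {
    nc_abort("dose must be a scalar or a 4-vector", "nestcamo_domain_error")
  }
  add <- fp$slope_per_band * dose   # length 4
  if (is.array(x) && length(dim(x)) == 3) {
    if (dim(x)[3] != 4) nc_abort("expected 4 bands", "nestcamo_shape_error")
    out <- x
    for (b in 1:4) out[, , b] <- pmax(pmin(x[, , b] + add[b], fp$cap), x[, , b])
    out
  } else {
    if (length(x) != 4) nc_abort("expected a reflectance 4-vector",
                                 "nestcamo_shape_error")
    pmax(pmin(x + add, fp$cap), x)
  }
}

# derive a bounded child seed; keeps all derived seeds below 2^31
child_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + salt) %% 2147483629)
}

# row layout for n eggs: at most 4 per row, larger rows in the middle
# (10 eggs -> 3, 4, 3 as in the sun-exposure design)
egg_row_sizes <- function(n) {
  nrows <- ceiling(n / 4)
  base <- n %/% nrows
  sizes <- rep(base, nrows)
  extra <- n - sum(sizes)
  if (extra > 0) {
    mid <- order(abs(seq_len(nrows) - (nrows + 1) / 2))
    sizes[mid[seq_len(extra)]] <- sizes[mid[seq_len(extra)]] + 1
  }
  sizes
}

#' Render a synthetic nest scene
#'
#' Draws the background clutter, the (possibly faded) spotted eggs and the
#' 25%-reflectance grey standard, and returns the 4-band reflectance image
#' together with the region annotations that exactly delimit eggs and
#' standard (egg masks are the pixel-centre rasterisations of the returned
#' polygons). Egg layout, maculation and clutter depend only on
#' `params$rng_seed`, so the same nest keeps its eggs across days; pixel
#' noise additionally varies with `day`.
#'
#' @param params a [scene_params()] object.
#' @param day integer day index (metadata; also salts the pixel noise).
#' @param dose normalised radiation dose applied to the eggs via
#'   [apply_fading()]; scalar or per-band 4-vector.
#' @param fading a [fading_params()] object.
#' @return object of class `nest_scene`: list with `image` (H x W x 4 array,
#'   reflectance in \[0, 1\]), `regions` (a `region_set`), `truth` (the faded
#'   per-egg ground/spot reflectances actually painted), `params`, `day`,
#'   `dose`.
#' @export
render_scene <- function(params, day = 0L, dose = 0, fading = fading_params()) {
  stopifnot(inherits(params, "scene_params"))
  if (any(dose < 0)) nc_abort("dose must be >= 0", "nestcamo_domain_error")
  H <- params$image_size[1]; W <- params$image_size[2]
  ppc <- params$px_per_cm
  a_px <- params$egg_axes_cm[1] / 2 * ppc
  b_px <- params$egg_axes_cm[2] / 2 * ppc

  withr::with_seed(params$rng_seed, {
    # --- layout -----------------------------------------------------------
    s_px <- round(params$standard_side_cm * ppc)
    std_poly <- rect_polygon(round(0.03 * W), round(0.03 * H), s_px, s_px)
    centre <- c((W - 1) / 2, (H - 1) / 2)
    sizes <- egg_row_sizes(params$n_eggs)
    pitch <- (params$egg_axes_cm[1] + 0.6) * ppc
    egg_centres <- NULL
    for (ri in seq_along(sizes)) {
      yy <- centre[2] + (ri - (length(sizes) + 1) / 2) * pitch
      xs <- centre[1] + (seq_len(sizes[ri]) - (sizes[ri] + 1) / 2) * pitch
      egg_centres <- rbind(egg_centres, cbind(xs, yy))
    }
    egg_centres <- egg_centres +
      matrix(runif(2 * params$n_eggs, -0.15 * ppc, 0.15 * ppc), ncol = 2)
    angles <- runif(params$n_eggs, -25, 25) * pi / 180

    egg_polys <- lapply(seq_len(params$n_eggs), function(e) {
      ellipse_polygon(egg_centres[e, 1], egg_centres[e, 2], a_px, b_px,
                      angles[e])
    })
    all_pts <- do.call(rbind, c(egg_polys, list(std_poly)))
    if (min(all_pts) < 0 || max(all_pts[, 1]) > W - 1 || max(all_pts[, 2]) > H - 1) {
      nc_abort("egg or standard geometry does not fit inside the frame",
               "nestcamo_geometry_error")
    }
    egg_masks <- lapply(egg_polys, rasterize_polygon, dim = c(H, W))
    std_mask <- rasterize_polygon(std_poly, c(H, W))
    occ <- Reduce(`+`, egg_masks) + std_mask
    if (any(occ > 1)) {
      nc_abort("egg/standard regions overlap; enlarge the frame or reduce n_eggs",
               "nestcamo_geometry_error")
    }

    # --- faded egg colours ------------------------------------------------
    jit <- rnorm(params$n_eggs, 0, params$egg_reflectance_jitter)
    ground <- lapply(seq_len(params$n_eggs), function(e) {
      apply_fading(pmin(pmax(params$band_reflectance_egg_ground + jit[e], 0), 1),
                   dose, fading)
    })
    spot <- lapply(seq_len(params$n_eggs), function(e) {
      apply_fading(pmin(pmax(params$band_reflectance_egg_spot + jit[e], 0), 1),
                   dose, fading)
    })

    # --- maculation -------------------------------------------------------
    spot_masks <- lapply(seq_len(params$n_eggs), function(e) {
      m <- matrix(FALSE, H, W)
      target <- params$spot_fraction * sum(egg_masks[[e]])
      tries <- 0L; rejects <- 0L
      while (sum(m) < target && tries < 500L && rejects < 50L) {
        tries <- tries + 1L
        t <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1))
        ex <- rr * cos(t) * a_px * 0.9; ey <- rr * sin(t) * b_px * 0.9
        cx <- egg_centres[e, 1] + ex * cos(angles[e]) - ey * sin(angles[e])
        cy <- egg_centres[e, 2] + ex * sin(angles[e]) + ey * cos(angles[e])
        rad <- max(0.15, rnorm(1, 0.35, 0.1)) * ppc
        cand <- m | (disk_mask(cx, cy, rad, c(H, W)) & egg_masks[[e]])
        # accept a disk only if it brings coverage closer to the target,
        # so the realised spot fraction tracks spot_fraction closely
        if (abs(sum(cand) - target) <= abs(sum(m) - target)) {
          m <- cand; rejects <- 0L
        } else rejects <- rejects + 1L
      }
      m
    })

    # --- background clutter ----------------------------------------------
    grain_sigma <- max(params$background_texture$grain_cm * ppc / 2, 0.5)
    gk <- gauss_kernels_1d(grain_sigma)$g
    smooth_unit <- function() {
      f <- conv2_sep(matrix(rnorm(H * W), H, W), gk, gk)
      f / sd(f)
    }
    shared <- smooth_unit()
    rho <- params$background_texture$band_correlation
    img <- array(0, c(H, W, 4))
    for (b in 1:4) {
      fb <- smooth_unit()
      clutter <- sqrt(rho) * shared + sqrt(1 - rho) * fb
      img[, , b] <- params$band_reflectance_background_base[b] +
        params$background_texture$contrast * clutter
    }

    # --- paint eggs and standard -----------------------------------------
    for (b in 1:4) {
      ch <- img[, , b]
      for (e in seq_len(params$n_eggs)) {
        ch[egg_masks[[e]]] <- ground[[e]][b]
        ch[spot_masks[[e]]] <- spot[[e]][b]
      }
      ch[std_mask] <- 0.25
      img[, , b] <- ch
    }
  })

  if (params$noise_sd > 0) {
    withr::with_seed(child_seed(params$rng_seed, 7 + 9973 * day), {
      img <- img + array(rnorm(length(img), 0, params$noise_sd), dim(img))
    })
  }
  img <- pmin(pmax(img, 0), 1)
  dimnames(img) <- list(NULL, NULL, BAND_NAMES)

  regions <- region_set(egg_polygons = egg_polys, standard_polygon = std_poly,
                        nest_centre = centre, px_per_cm = ppc)
  structure(list(image = img, regions = regions,
                 truth = list(ground = ground, spot = spot,
                              spot_fraction = params$spot_fraction),
                 masks = list(egg = Reduce(`|`, egg_masks),
                              spot = Reduce(`|`, spot_masks),
                              standard = std_mask),
                 params = params, day = day, dose = dose),
            class = "nest_scene")
}

#' Region annotations of a scene
#'
#' @param egg_polygons list of n x 2 vertex matrices (0-based pixel
#'   coordinates, x right / y down, implicitly closed).
#' @param standard_polygon vertex matrix of the grey-standard patch.
#' @param nest_centre `c(x, y)` pixel coordinate of the nest centre.
#' @param px_per_cm pixel scale (> 0).
#' @return object of class `region_set`.
#' @export
region_set <- function(egg_polygons, standard_polygon, nest_centre, px_per_cm) {
  if (px_per_cm <= 0) nc_abort("px_per_cm must be > 0", "nestcamo_config_error")
  egg_polygons <- lapply(egg_polygons, as_polygon)
  structure(list(egg_polygons = egg_polygons,
                 standard_polygon = as_polygon(standard_polygon),
                 nest_centre = as.numeric(nest_centre),
                 px_per_cm = px_per_cm),
            class = "region_set")
}

#' @export
print.nest_scene <- function(x, ...) {
  cat("<nest_scene> ", paste(dim(x$image)[1:2], collapse = " x "),
      " px, ", length(x$regions$egg_polygons), " eggs, day ", x$day,
      ", dose ", paste(signif(x$dose, 3), collapse = "/"), "\n", sep = "")
  invisible(x)
}
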