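# K-means texture vocabulary, label maps, signatures, and the chi-square
# camouflage score.

# k-means++ seeding (stats::kmeans has none); deterministic under the
# caller's RNG state
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centres <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centres[1, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2, centres[1, ])^2)
  for (j in 2:k) {
    if (all(d2 == 0)) {
      idx <- sample.int(n, 1)
    } else {
      idx <- sample.int(n, 1, prob = d2)
    }
    centres[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centres[j, ])^2))
  }
  centres
}

#' Fit a K-means texture vocabulary
#'
#' Standardises the filter-response features over the analysis region
#' (zero mean, unit variance per feature; constant features left at zero)
#' and clusters the pixels with K-means (Lloyd, k-means++ seeding, multiple
#' restarts, best within-SS kept). For large regions the restarts run on a
#' seeded subsample and the winner is refined on a larger fit sample; the
#' returned centres live in the standardised space together with the
#' standardisation parameters, so any pixel can be labelled later.
#'
#' @param stack feature matrix (pixels x features), e.g. the masked output
#'   of [apply_filter_bank()].
#' @param k number of texture centres (default 20).
#' @param seed integer seed; fits are deterministic given the seed.
#' @param restarts k-means++ restarts (default 10).
#' @param max_fit_pixels pixels used for the refinement fit (seeded
#'   subsample; default 6000).
#' @param restart_pixels pixels used during the restart search (default 1500).
#' @param iter_max Lloyd iteration cap per run.
#' @return object of class `texture_model`: `centers` (k x d, standardised
#'   space), `mean`, `sd`, `k`, `seed`, `tot_withinss`, `iterations`.
#' @export
fit_texture_model <- function(stack, k = 20L, seed = 1L, restarts = 10L,
                              max_fit_pixels = 6000L, restart_pixels = 1500L,
                              iter_max = 100L) {
  x <- as.matrix(stack)
  if (nrow(x) < k) {
    nc_abort(sprintf("need at least k = %d pixels, got %d", k, nrow(x)),
             "nestcamo_data_error")
  }
  mu <- colMeans(x)
  sg <- apply(x, 2, sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
  withr::with_seed(child_seed(seed, 211), {
    fit_idx <- if (nrow(xs) > max_fit_pixels) {
      sort(sample.int(nrow(xs), max_fit_pixels))
    } else seq_len(nrow(xs))
    xf <- xs[fit_idx, , drop = FALSE]
    rs_idx <- if (nrow(xf) > restart_pixels) {
      sort(sample.int(nrow(xf), restart_pixels))
    } else seq_len(nrow(xf))
    xr <- xf[rs_idx, , drop = FALSE]
    best <- NULL
    for (r in seq_len(restarts)) {
      init <- kmeanspp_init(xr, k)
      km <- suppressWarnings(
        kmeans(xr, centers = init, iter.max = iter_max, algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    fit <- suppressWarnings(
      kmeans(xf, centers = best$centers, iter.max = iter_max,
             algorithm = "Lloyd"))
  })
  structure(list(centers = fit$centers, mean = mu, sd = sg, k = as.integer(k),
                 seed = as.integer(seed), tot_withinss = fit$tot.withinss,
                 iterations = fit$iter),
            class = "texture_model")
}

#' @export
print.texture_model <- function(x, ...) {
  cat("<texture_model> k = ", x$k, ", d = ", ncol(x$centers),
      ", within-SS = ", signif(x$tot_withinss, 5), "\n", sep = "")
  invisible(x)
}

#' Label pixels by their nearest texture centre
#'
#' Each pixel is assigned to the centre minimising the Euclidean distance in
#' the model's standardised feature space; ties go to the lowest centre
#' index.
#'
#' @param stack feature matrix (pixels x features) on the raw scale.
#' @param model a [fit_texture_model()] object.
#' @return integer vector of labels in `1..k`.
#' @export
assign_labels <- function(stack, model) {
  x <- as.matrix(stack)
  if (ncol(x) != ncol(model$centers)) {
    nc_abort(sprintf("feature length %d does not match model (%d)",
                     ncol(x), ncol(model$centers)), "nestcamo_shape_error")
  }
  xs <- sweep(sweep(x, 2, model$mean), 2, model$sd, "/")
  labels <- integer(nrow(xs))
  cc <- rowSums(model$centers^2)
  block <- 50000L
  for (start in seq(1L, nrow(xs), by = block)) {
    idx <- start:min(start + block - 1L, nrow(xs))
    # argmin_c ||x - c||^2 = argmax_c (2 x.c - ||c||^2); ties -> lowest index
    score <- sweep(2 * xs[idx, , drop = FALSE] %*% t(model$centers), 2, cc, "-")
    labels[idx] <- max.col(score, ties.method = "first")
  }
  labels
}

#' Texture signature of a region
#'
#' Normalised histogram of texture labels: bin t is the fraction of the
#' region's pixels labelled t.
#'
#' @param labels integer labels in `1..k`.
#' @param k number of bins.
#' @return numeric length-k vector summing to 1.
#' @export
region_signature <- function(labels, k) {
  if (length(labels) == 0) nc_abort("empty region", "nestcamo_data_error")
  tabulate(labels, nbins = k) / length(labels)
}

#' Chi-square distance between two texture signatures
#'
#' \eqn{\chi^2(h_1, h_2) = \frac{1}{2}\sum_t (h_{1t} - h_{2t})^2 /
#' (h_{1t} + h_{2t})}, skipping empty bins. Symmetric, zero iff the
#' histograms are equal, and bounded by 1 for normalised histograms
#' (attained at disjoint supports). Lower values mean more similar texture
#' distributions, i.e. better camouflage.
#'
#' @param h1,h2 normalised histograms of equal length.
#' @return scalar in \[0, 1\].
#' @export
chi_square_distance <- function(h1, h2) {
  if (length(h1) != length(h2)) {
    nc_abort("histograms must have equal length", "nestcamo_shape_error")
  }
  if (any(h1 < 0) || any(h2 < 0) ||
        abs(sum(h1) - 1) > 1e-6 || abs(sum(h2) - 1) > 1e-6) {
    nc_abort("histograms must be normalised (non-negative, sum 1)",
             "nestcamo_domain_error")
  }
  s <- h1 + h2
  keep <- s > 0
  0.5 * sum((h1[keep] - h2[keep])^2 / s[keep])
}

# union of egg masks and the microhabitat annulus used for the comparison
camouflage_masks <- function(regions, dim, microhabitat_diameter_cm = 45) {
  egg <- Reduce(`|`, lapply(regions$egg_polygons, rasterize_polygon, dim = dim))
  r_px <- microhabitat_diameter_cm / 2 * regions$px_per_cm
  disk <- disk_mask(regions$nest_centre[1], regions$nest_centre[2], r_px, dim)
  if (!any(disk)) {
    nc_abort("microhabitat circle lies entirely outside the frame",
             "nestcamo_geometry_error")
  }
  if (!any(egg)) nc_abort("no egg pixels inside the frame",
                          "nestcamo_geometry_error")
  list(egg = egg, microhabitat = disk & !egg)
}

# signature comparison from a masked feature matrix (shared by the
# reference path and the multi-model fast path)
score_from_features <- function(feats, pix, masks, k, seed, ...) {
  model <- fit_texture_model(feats, k = k, seed = seed, ...)
  labels <- assign_labels(feats, model)
  h_egg <- region_signature(labels[pix %in% which(masks$egg)], k)
  h_hab <- region_signature(labels[pix %in% which(masks$microhabitat)], k)
  out <- tibble(chi2 = chi_square_distance(h_egg, h_hab),
                k = as.integer(k), seed = as.integer(seed),
                n_egg_px = sum(masks$egg),
                n_microhabitat_px = sum(masks$microhabitat),
                signatures = list(list(egg = h_egg, microhabitat = h_hab)))
  class(out) <- c("camo_score", class(out))
  out
}

# Score one reflectance scene under several visual models while convolving
# the four bands only once: cone-catch channels are linear in the bands and
# convolution is linear, so each model's masked feature matrix is an exact
# linear recombination of the band feature matrix.
camouflage_multimodel <- function(image, regions, models, bank, k = 20L,
                                  seed_for = function(model) 1L,
                                  illuminant = illuminant_flat(),
                                  microhabitat_diameter_cm = 45, ...) {
  dims <- dim(image)[1:2]
  masks <- camouflage_masks(regions, dims, microhabitat_diameter_cm)
  both <- masks$egg | masks$microhabitat
  feats <- apply_filter_bank(image, bank, mask = both)
  pix <- attr(feats, "pixels")
  nk <- length(bank$kernels)
  purrr::map_dfr(models, function(mn) {
    model <- receptor_set(mn)
    W <- band_catch_matrix(model, illuminant)
    q_std <- as.numeric(rep(0.25, 4) %*% W)
    A <- sweep(W, 2, q_std, "/")        # 4 x chromacy von Kries weights
    fm <- matrix(0, nrow(feats), model$chromacy * nk)
    for (ci in seq_len(model$chromacy)) {
      cols <- (ci - 1L) * nk + seq_len(nk)
      for (b in 1:4) {
        fm[, cols] <- fm[, cols] +
          A[b, ci] * feats[, (b - 1L) * nk + seq_len(nk)]
      }
    }
    sc <- score_from_features(fm, pix, masks, k, seed_for(mn), ...)
    dplyr::mutate(sc, visual_model = mn, .before = 1)
  })
}

#' Camouflage score of eggs against their microhabitat
#'
#' End-to-end texture comparison for one (cone-catch) image: convolve with
#' the filter bank, fit the K-means texture vocabulary on the pixels of the
#' egg union and of the 45-cm microhabitat disk (minus the eggs), label
#' those pixels, build the two region signatures and return their
#' chi-square distance. Higher scores mean the eggs stand out more from the
#' background.
#'
#' @param image cone-catch (or reflectance) image: H x W matrix or
#'   H x W x C array.
#' @param regions a [region_set()]; supplies egg polygons, nest centre and
#'   pixel scale.
#' @param bank a [build_filter_bank()]; defaults to the standard bank at
#'   `scale_factor`.
#' @param k number of texture centres (default 20).
#' @param seed integer seed for the K-means fit.
#' @param scale_factor filter-bank rescaling used when `bank` is NULL.
#' @param microhabitat_diameter_cm diameter of the comparison disk (45 cm).
#' @param ... passed on to [fit_texture_model()].
#' @return tibble (class `camo_score`) with columns `chi2`, `k`, `seed`,
#'   `n_egg_px`, `n_microhabitat_px`, and the two signatures as a nested
#'   list column `signatures`.
#' @export
camouflage_distance <- function(image, regions, bank = NULL, k = 20L,
                                seed = 1L, scale_factor = 1,
                                microhabitat_diameter_cm = 45, ...) {
  if (is.null(bank)) bank <- build_filter_bank(scale_factor = scale_factor)
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  dims <- dim(image)[1:2]
  masks <- camouflage_masks(regions, dims, microhabitat_diameter_cm)
  both <- masks$egg | masks$microhabitat
  feats <- apply_filter_bank(image, bank, mask = both)
  score_from_features(feats, attr(feats, "pixels"), masks, k, seed, ...)
}
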