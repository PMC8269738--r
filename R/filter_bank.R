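#' Build the texture filter bank
#'
#' Constructs the 56-kernel bank used for texture signatures: at each scale
#' \eqn{\sigma}, five odd-symmetric (first-derivative-of-Gaussian) and five
#' even-symmetric (second-derivative-of-Gaussian) oriented kernels at
#' orientations evenly spaced over \[0, 180) degrees, plus four
#' rotation-invariant kernels — Gaussians at \eqn{\sigma} and
#' \eqn{\sqrt{2}\sigma} and Laplacians of Gaussian at \eqn{\sigma} and
#' \eqn{\sqrt{2}\sigma} — giving 14 kernels per scale.
#'
#' Oriented kernels are isotropic directional derivatives in steerable form
#' (e.g. \eqn{\cos\theta\,G_x + \sin\theta\,G_y}), so every kernel is a short
#' sum of separable terms; [apply_filter_bank()] exploits this for fast exact
#' convolution. Kernel support is truncated at three times the largest
#' constituent \eqn{\sigma}. First-derivative and LoG kernels sum to zero;
#' Gaussian kernels sum to one.
#'
#' @param scales numeric vector of scales \eqn{\sigma} in pixels
#'   (default `c(16, 32, 64, 128)`).
#' @param n_orientations number of orientations over \[0, 180) degrees
#'   (default 5, giving 0, 36, 72, 108, 144).
#' @param scale_factor single multiplier applied to `scales`, so a
#'   geometrically similar bank can be run on smaller images
#'   (e.g. `scale_factor = 0.25` gives \eqn{\sigma = \{4, 8, 16, 32\}}).
#' @return an object of class `filter_bank`: a list with `kernels` (each a
#'   list holding the 2-D `weights` matrix, `scale`, `sigma`, `type`,
#'   `orientation`, and its separable decomposition), plus the scale ladder
#'   and 1-D bases.
#' @export
build_filter_bank <- function(scales = c(16, 32, 64, 128), n_orientations = 5L,
                              scale_factor = 1) {
  if (any(scales <= 0) || scale_factor <= 0) {
    nc_abort("filter-bank scales must be positive", "nestcamo_domain_error")
  }
  if (n_orientations < 1) {
    nc_abort("need at least one orientation", "nestcamo_domain_error")
  }
  sigmas <- scales * scale_factor
  thetas <- (seq_len(n_orientations) - 1L) * 180 / n_orientations
  bases <- lapply(sigmas, function(s) {
    list(k1 = gauss_kernels_1d(s), k2 = gauss_kernels_1d(sqrt(2) * s))
  })
  kernels <- list()
  for (si in seq_along(sigmas)) {
    k1 <- bases[[si]]$k1; k2 <- bases[[si]]$k2
    sc <- scales[si]; sg <- sigmas[si]
    mk <- function(type, orientation, sigma, sep) {
      w <- Reduce(`+`, lapply(sep, function(t) {
        t$coef * outer(bases[[si]][[t$base]][[t$ky]],
                       bases[[si]][[t$base]][[t$kx]])
      }))
      list(weights = w, scale = sc, sigma = sigma, type = type,
           orientation = orientation, sep = sep, scale_index = si)
    }
    for (th in thetas) {
      a <- th * pi / 180
      kernels[[length(kernels) + 1L]] <- mk(
        "odd", th, sg,
        list(list(coef = cos(a), kx = "g1", ky = "g", base = "k1"),
             list(coef = sin(a), kx = "g", ky = "g1", base = "k1")))
    }
    for (th in thetas) {
      a <- th * pi / 180
      kernels[[length(kernels) + 1L]] <- mk(
        "even", th, sg,
        list(list(coef = cos(a)^2, kx = "g2", ky = "g", base = "k1"),
             list(coef = 2 * sin(a) * cos(a), kx = "g1", ky = "g1", base = "k1"),
             list(coef = sin(a)^2, kx = "g", ky = "g2", base = "k1")))
    }
    kernels[[length(kernels) + 1L]] <- mk(
      "gaussian", NA_real_, sg,
      list(list(coef = 1, kx = "g", ky = "g", base = "k1")))
    kernels[[length(kernels) + 1L]] <- mk(
      "gaussian", NA_real_, sqrt(2) * sg,
      list(list(coef = 1, kx = "g", ky = "g", base = "k2")))
    kernels[[length(kernels) + 1L]] <- mk(
      "log", NA_real_, sg,
      list(list(coef = 1, kx = "g2", ky = "g", base = "k1"),
           list(coef = 1, kx = "g", ky = "g2", base = "k1")))
    kernels[[length(kernels) + 1L]] <- mk(
      "log", NA_real_, sqrt(2) * sg,
      list(list(coef = 1, kx = "g2", ky = "g", base = "k2"),
           list(coef = 1, kx = "g", ky = "g2", base = "k2")))
  }
  structure(list(kernels = kernels, scales = scales, sigmas = sigmas,
                 n_orientations = n_orientations, scale_factor = scale_factor,
                 bases = bases),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat("<filter_bank> ", length(x$kernels), " kernels; sigma = {",
      paste(signif(x$sigmas, 4), collapse = ", "), "} px; ",
      x$n_orientations, " orientations\n", sep = "")
  invisible(x)
}

#' Feature metadata for a bank
#'
#' One row per kernel, in the deterministic order used by
#' [apply_filter_bank()] within each channel.
#'
#' @param bank a [build_filter_bank()] object.
#' @return tibble with columns `kernel`, `scale`, `sigma`, `type`,
#'   `orientation`.
#' @export
filter_bank_info <- function(bank) {
  tibble(
    kernel = seq_along(bank$kernels),
    scale = vapply(bank$kernels, `[[`, numeric(1), "scale"),
    sigma = vapply(bank$kernels, `[[`, numeric(1), "sigma"),
    type = vapply(bank$kernels, `[[`, character(1), "type"),
    orientation = vapply(bank$kernels, `[[`, numeric(1), "orientation")
  )
}

#' Convolve an image with the whole filter bank
#'
#' Every channel is convolved (true convolution, mirror boundary) with every
#' kernel. The separable decomposition of the kernels is used, so only a few
#' base convolutions per scale are computed and recombined; the result equals
#' direct 2-D convolution with the kernel weight matrices to floating-point
#' rounding. Feature order is channel-major, then scale, then kernel index
#' within scale.
#'
#' @param image numeric H x W matrix or H x W x C array.
#' @param bank a [build_filter_bank()] object.
#' @param mask optional logical H x W matrix; when supplied, responses are
#'   returned only at masked pixels as an `npix x (C * nkernel)` matrix
#'   (pixel order: column-major over `which(mask)`), which avoids
#'   materialising the full response stack on large scenes.
#' @return with `mask = NULL`, an H x W x (C * nkernel) array; otherwise the
#'   masked feature matrix. Both carry a `feature_info` attribute (tibble
#'   with `feature`, `channel`, `kernel`, `scale`, `type`, `orientation`).
#' @export
apply_filter_bank <- function(image, bank, mask = NULL) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  H <- dim(image)[1]; W <- dim(image)[2]; C <- dim(image)[3]
  max_side <- max(vapply(bank$kernels, function(k) nrow(k$weights), integer(1)))
  if (min(H, W) < max_side) {
    nc_abort(sprintf("image (%d x %d) smaller than largest kernel (%d px)",
                     H, W, max_side), "nestcamo_size_error")
  }
  nk <- length(bank$kernels)
  cache <- conv_cache()
  pix <- if (!is.null(mask)) which(mask) else NULL
  out <- if (is.null(mask)) array(NA_real_, c(H, W, C * nk)) else
    matrix(NA_real_, length(pix), C * nk)
  per_scale <- split(seq_len(nk),
                     vapply(bank$kernels, `[[`, integer(1), "scale_index"))
  for (ci in seq_len(C)) {
    ch <- image[, , ci]
    for (si in seq_along(bank$bases)) {
      b <- bank$bases[[si]]
      base_resp <- new.env(parent = emptyenv())
      get_base <- function(base, ky, kx) {
        id <- paste(base, ky, kx, sep = ".")
        if (is.null(base_resp[[id]])) {
          kb <- b[[base]]
          base_resp[[id]] <- conv2_sep(ch, kb[[ky]], kb[[kx]], cache,
                                       key_y = paste(si, base, ky),
                                       key_x = paste(si, base, kx))
        }
        base_resp[[id]]
      }
      for (ki in per_scale[[si]]) {
        kern <- bank$kernels[[ki]]
        resp <- Reduce(`+`, lapply(kern$sep, function(t) {
          t$coef * get_base(t$base, t$ky, t$kx)
        }))
        fi <- (ci - 1L) * nk + ki
        if (is.null(mask)) out[, , fi] <- resp else out[, fi] <- resp[pix]
      }
    }
  }
  info <- filter_bank_info(bank)
  finfo <- dplyr::bind_rows(lapply(seq_len(C), function(ci) {
    dplyr::mutate(info, channel = ci, feature = (ci - 1L) * nk + info$kernel)
  }))
  attr(out, "feature_info") <- finfo[, c("feature", "channel", "kernel",
                                         "scale", "sigma", "type",
                                         "orientation")]
  if (!is.null(mask)) attr(out, "pixels") <- pix
  out
}
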