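# Shared wavelength grid: 350-700 nm at 1 nm, covering the UV band
# (350-400 nm) and the visible range (400-700 nm).
WL_GRID <- 350:700

#' Wavelength grid used by the visual-model module
#' @return integer vector, 350 to 700 nm in 1-nm steps.
#' @export
wavelength_grid <- function() WL_GRID

#' Visual pigment sensitivity template
#'
#' A1 visual-pigment alpha-band template (Govardovskii-type nomogram)
#' evaluated on the module grid and peak-normalised to 1 at its maximum.
#'
#' @param lambda_max peak wavelength in nm, within \[300, 700\].
#' @return numeric vector over [wavelength_grid()].
#' @export
receptor_sensitivity <- function(lambda_max) {
  if (lambda_max < 300 || lambda_max > 700) {
    nc_abort("lambda_max must be in [300, 700] nm", "nestcamo_domain_error")
  }
  x <- lambda_max / WL_GRID
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  s <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
              exp(-14.9 * (1.104 - x)) + 0.674)
  s / max(s)
}

#' Built-in predator receptor sets
#'
#' The four observer models: dichromatic ferret (peaks 430, 538 nm),
#' trichromatic human (420, 533, 562 nm), violet-sensitive tetrachromatic
#' peafowl (421, 457, 505, 566 nm) and ultraviolet-sensitive tetrachromatic
#' blue tit (371, 448, 503, 563 nm).
#'
#' @param name one of `"ferret"`, `"human"`, `"peafowl"`, `"bluetit"`.
#' @return object of class `receptor_set`: list with `name`, `lambda_max`,
#'   `chromacy`.
#' @export
receptor_set <- function(name = c("ferret", "human", "peafowl", "bluetit")) {
  if (length(name) == 1 && !name %in% names(visual_model_registry())) {
    nc_abort(paste0("unknown visual model: ", name), "nestcamo_config_error")
  }
  name <- match.arg(name)
  peaks <- visual_model_registry()[[name]]
  structure(list(name = name, lambda_max = peaks,
                 chromacy = length(peaks)), class = "receptor_set")
}

#' @rdname receptor_set
#' @return `visual_model_registry()`: named list of peak-wavelength vectors.
#' @export
visual_model_registry <- function() {
  list(ferret = c(430, 538),
       human = c(420, 533, 562),
       peafowl = c(421, 457, 505, 566),
       bluetit = c(371, 448, 503, 563))
}

# nominal band supports (nm): UV [350,400), B [400,500), G [500,600), R [600,700]
BAND_EDGES <- c(350, 400, 500, 600, 700)

#' Reconstruct a spectrum from four band reflectances
#'
#' Piecewise-constant bridge from the camera bands to a continuous curve:
#' the UV value on \[350, 400), blue on \[400, 500), green on \[500, 600)
#' and red on \[600, 700\]. At the three interior band edges the curve takes
#' the mean of the adjacent bands, which makes trapezoid integration of the
#' curve exact for step spectra.
#'
#' @param band_reflectances 4-vector (R, G, B, UV order, matching the image
#'   bands), all >= 0.
#' @return numeric vector over [wavelength_grid()].
#' @export
reconstruct_spectrum <- function(band_reflectances) {
  if (length(band_reflectances) != 4 || any(band_reflectances < 0)) {
    nc_abort("band reflectances must be a non-negative 4-vector",
             "nestcamo_domain_error")
  }
  # spectral order: UV, B, G, R
  v <- band_reflectances[c(4, 3, 2, 1)]
  out <- numeric(length(WL_GRID))
  for (b in 1:4) {
    out[WL_GRID >= BAND_EDGES[b] & WL_GRID < BAND_EDGES[b + 1]] <- v[b]
  }
  out[WL_GRID == 700] <- v[4]
  for (e in 2:4) out[WL_GRID == BAND_EDGES[e]] <- (v[e - 1] + v[e]) / 2
  out
}

#' Illuminants
#'
#' `illuminant_flat()` is the equal-energy illuminant (default throughout);
#' `illuminant_daylight()` is a Planckian radiator at 6504 K normalised to
#' mean 1 over the grid, as a smooth daylight-like alternative.
#'
#' @return numeric vector over [wavelength_grid()].
#' @export
illuminant_flat <- function() rep(1, length(WL_GRID))

#' @rdname illuminant_flat
#' @export
illuminant_daylight <- function() {
  lam <- WL_GRID * 1e-9
  h <- 6.62607015e-34; c0 <- 299792458; kb <- 1.380649e-23
  b <- 1 / (lam^5 * (exp(h * c0 / (lam * kb * 6504)) - 1))
  b / mean(b)
}

# trapezoid rule on the unit-spaced grid
trapz_grid <- function(y) sum((y[-1] + y[-length(y)]) / 2)

#' Quantum catch of a receptor for a stimulus
#'
#' \eqn{Q = \int R(\lambda) S(\lambda) I(\lambda) d\lambda}, trapezoid rule
#' on the 1-nm grid.
#'
#' @param reflectance_spectrum,receptor,illuminant numeric vectors over
#'   [wavelength_grid()].
#' @return scalar catch.
#' @export
cone_catch <- function(reflectance_spectrum, receptor,
                       illuminant = illuminant_flat()) {
  n <- length(WL_GRID)
  if (length(reflectance_spectrum) != n || length(receptor) != n ||
        length(illuminant) != n) {
    nc_abort("spectra must share the module wavelength grid",
             "nestcamo_shape_error")
  }
  trapz_grid(reflectance_spectrum * receptor * illuminant)
}

# 4 x chromacy matrix of band catches: entry [b, r] is the catch of receptor
# r for the unit indicator spectrum of image band b (R, G, B, UV order).
# Because the reconstructed spectrum is linear in the band values, mapping an
# image through this matrix equals the per-pixel reconstruct-then-integrate
# route exactly.
band_catch_matrix <- function(model, illuminant = illuminant_flat()) {
  sens <- lapply(model$lambda_max, receptor_sensitivity)
  W <- matrix(0, 4, model$chromacy)
  for (b in 1:4) {
    e <- numeric(4); e[b] <- 1
    spec <- reconstruct_spectrum(e)
    for (r in seq_len(model$chromacy)) {
      W[b, r] <- cone_catch(spec, sens[[r]], illuminant)
    }
  }
  W
}

#' Map a reflectance image into a predator's cone-catch space
#'
#' Per pixel: reconstruct the spectrum from the four bands, integrate it
#' against each receptor sensitivity under the illuminant, then divide each
#' channel by the catch of the flat 25% grey standard under the same
#' illuminant (von Kries normalisation). A spectrally flat 0.25 stimulus
#' therefore maps to 1.0 in every channel of every model.
#'
#' @param image 4-band reflectance image (H x W x 4, bands R, G, B, UV).
#' @param model a [receptor_set()] or a model name.
#' @param illuminant illuminant spectrum (default [illuminant_flat()]).
#' @return H x W x chromacy cone-catch array with attribute `model`.
#' @export
map_to_visual_model <- function(image, model, illuminant = illuminant_flat()) {
  if (is.character(model)) model <- receptor_set(model)
  stopifnot(inherits(model, "receptor_set"))
  if (length(dim(image)) != 3 || dim(image)[3] != 4) {
    nc_abort("expected an H x W x 4 reflectance image", "nestcamo_shape_error")
  }
  W <- band_catch_matrix(model, illuminant)
  q_std <- as.numeric(rep(0.25, 4) %*% W)   # flat grey standard catches
  H <- dim(image)[1]; Wd <- dim(image)[2]
  flat <- matrix(image, H * Wd, 4)
  catches <- flat %*% W
  catches <- sweep(catches, 2, q_std, "/")
  out <- array(catches, c(H, Wd, model$chromacy))
  attr(out, "model") <- model$name
  out
}
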