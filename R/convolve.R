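# Separable 2-D convolution via banded convolution matrices.
#
# True convolution: out(i) = sum_u k(u) * in(i - u), u in -r..r, with mirror
# boundary handling (reflection about edge pixel centres). Building the n x n
# convolution matrix once per (length, kernel) pair turns each separable pass
# into a dense matrix product, which is what makes the large-sigma filter bank
# affordable in R.

# reflect an out-of-range 1-based index back into 1..n (mirror about pixel
# centres: ... 3 2 1 | 1' is 2, 0 -> 2, -1 -> 3, n+1 -> n-1 ...)
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  p <- 2L * (n - 1L)
  m <- (idx - 1L) %% p
  m <- ifelse(m < 0, m + p, m)
  ifelse(m >= n, p - m, m) + 1L
}

# n x n matrix M with (M %*% v)[i] = sum_u k[u] v(reflect(i - u))
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (u in -r:r) {
    w <- kernel[u + r + 1L]
    if (w == 0) next
    src <- reflect_index(seq_len(n) - u, n)
    M[cbind(seq_len(n), src)] <- M[cbind(seq_len(n), src)] + w
  }
  M
}

# cache of conv matrices keyed by (n, kernel id) within one apply pass
conv_cache <- function() {
  env <- new.env(parent = emptyenv())
  function(n, key, kernel) {
    id <- paste0(n, ":", key)
    if (is.null(env[[id]])) env[[id]] <- conv_matrix(n, kernel)
    env[[id]]
  }
}

# separable true convolution: rows filtered with ky (vertical), cols with kx
conv2_sep <- function(img, ky, kx, cache = NULL, key_y = NULL, key_x = NULL) {
  H <- nrow(img); W <- ncol(img)
  My <- if (is.null(cache)) conv_matrix(H, ky) else cache(H, key_y, ky)
  Mx <- if (is.null(cache)) conv_matrix(W, kx) else cache(W, key_x, kx)
  My %*% img %*% t(Mx)
}

# 1-D Gaussian and its derivatives on a symmetric support of +/- ceil(3*sigma).
# The Gaussian is normalised to unit sum; the first derivative is exactly
# antisymmetric (zero sum); the second derivative is de-meaned so that kernels
# built from it (LoG, oriented even) have zero DC response.
gauss_kernels_1d <- function(sigma) {
  r <- ceiling(3 * sigma)
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  g1 <- (-x / sigma^2) * g
  g2 <- ((x^2 - sigma^2) / sigma^4) * g
  g2 <- g2 - mean(g2)
  list(g = g, g1 = g1, g2 = g2, radius = r)
}
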