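# Independent oracles used across tests. These deliberately use naive,
# loop-based implementations so they share no code with the package paths
# they check.

# brute-force per-pixel even-odd ray cast (scalar loop)
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(poly, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  for (i in seq_len(dim[1])) {
    for (j in seq_len(dim[2])) {
      m[i, j] <- oracle_point_in_polygon(j - 1, i - 1, poly)
    }
  }
  m
}

# mirror an index about the edge pixel centres by explicit folding
oracle_reflect <- function(m, n) {
  if (n == 1) return(1)
  while (m < 1 || m > n) {
    if (m < 1) m <- 2 - m
    if (m > n) m <- 2 * n - m
  }
  m
}

# direct 2-D true convolution with mirror boundary, quadruple loop
oracle_conv2 <- function(img, K) {
  H <- nrow(img); W <- ncol(img)
  r <- (nrow(K) - 1) / 2; s <- (ncol(K) - 1) / 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      acc <- 0
      for (u in -r:r) {
        for (v in -s:s) {
          acc <- acc + K[u + r + 1, v + s + 1] *
            img[oracle_reflect(i - u, H), oracle_reflect(j - v, W)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# nearest-centre labels by exhaustive scalar loops
oracle_labels <- function(x, centres) {
  labs <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    best <- Inf; lab <- NA_integer_
    for (c in seq_len(nrow(centres))) {
      d <- sum((x[i, ] - centres[c, ])^2)
      if (d < best) { best <- d; lab <- c }
    }
    labs[i] <- lab
  }
  labs
}

# small scene used by several tests: one row of eggs, modest resolution
small_scene_params <- function(seed = 1L, n_eggs = 3L, noise_sd = 0.004,
                               jitter = 0.008) {
  scene_params(image_size = c(120L, 120L), px_per_cm = 4, n_eggs = n_eggs,
               noise_sd = noise_sd, egg_reflectance_jitter = jitter,
               rng_seed = seed)
}

# compact two-scale bank for unit tests
tiny_bank <- function(scales = c(2, 4)) build_filter_bank(scales = scales)
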