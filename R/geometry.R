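#' Polygon and mask utilities
#'
#' Pixel geometry uses 0-based image coordinates, x to the right and y down,
#' so the centre of the pixel stored at `img[i, j]` is `(x = j - 1, y = i - 1)`.
#' A polygon is an n x 2 matrix of `(x, y)` vertices, implicitly closed
#' (last vertex joined back to the first).
#'
#' @name geometry
NULL

#' Test points against a polygon (even-odd rule)
#'
#' Vectorised even-odd (ray crossing) test. Points exactly on an edge follow
#' the half-open crossing convention, which keeps adjacent polygons disjoint.
#'
#' @param px,py numeric vectors of point coordinates.
#' @param poly n x 2 matrix of polygon vertices `(x, y)`.
#' @return logical vector, `TRUE` where the point is inside.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  inside <- logical(length(px))
  xi <- poly[, 1]; yi <- poly[, 2]
  xj <- poly[c(n, seq_len(n - 1)), 1]
  yj <- poly[c(n, seq_len(n - 1)), 2]
  for (e in seq_len(n)) {
    crosses <- (yi[e] > py) != (yj[e] > py)
    if (any(crosses)) {
      xint <- (xj[e] - xi[e]) * (py[crosses] - yi[e]) / (yj[e] - yi[e]) + xi[e]
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
  }
  inside
}

as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2 || nrow(poly) < 3 || !is.numeric(poly)) {
    nc_abort("a polygon must be a numeric matrix with >= 3 rows and 2 columns",
             "nestcamo_geometry_error")
  }
  poly
}

#' Rasterise a polygon to a pixel mask
#'
#' A pixel belongs to the mask when its centre falls inside the polygon
#' (pixel-centre rule), making the rasterisation deterministic and directly
#' checkable against a brute-force point-in-polygon scan.
#'
#' @param poly n x 2 vertex matrix (`(x, y)`, 0-based pixel coordinates).
#' @param dim image dimensions `c(H, W)`.
#' @return logical H x W matrix.
#' @export
rasterize_polygon <- function(poly, dim) {
  poly <- as_polygon(poly)
  H <- dim[1]; W <- dim[2]
  mask <- matrix(FALSE, H, W)
  # restrict to the polygon's bounding box
  j0 <- max(1L, floor(min(poly[, 1])) + 1L)
  j1 <- min(W, ceiling(max(poly[, 1])) + 1L)
  i0 <- max(1L, floor(min(poly[, 2])) + 1L)
  i1 <- min(H, ceiling(max(poly[, 2])) + 1L)
  if (j0 > j1 || i0 > i1) return(mask)
  jj <- rep(j0:j1, each = i1 - i0 + 1L)
  ii <- rep(i0:i1, times = j1 - j0 + 1L)
  ins <- point_in_polygon(jj - 1, ii - 1, poly)
  mask[cbind(ii[ins], jj[ins])] <- TRUE
  mask
}

#' Regular polygon approximating an ellipse
#'
#' @param cx,cy centre (0-based pixel coordinates).
#' @param a,b semi-axes in pixels (major, minor).
#' @param angle rotation of the major axis, radians, measured from +x.
#' @param n number of vertices.
#' @return n x 2 vertex matrix.
#' @export
ellipse_polygon <- function(cx, cy, a, b, angle = 0, n = 48L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- a * cos(t); y <- b * sin(t)
  cbind(cx + x * cos(angle) - y * sin(angle),
        cy + x * sin(angle) + y * cos(angle))
}

#' Disk mask by the pixel-centre rule
#'
#' @param cx,cy centre (0-based); @param r radius in pixels; @param dim `c(H, W)`.
#' @return logical H x W matrix.
#' @export
disk_mask <- function(cx, cy, r, dim) {
  H <- dim[1]; W <- dim[2]
  x <- matrix(rep(0:(W - 1), each = H), H)
  y <- matrix(rep(0:(H - 1), times = W), H)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

#' Axis-aligned rectangle polygon
#'
#' @param x0,y0 top-left corner (0-based pixel coordinates).
#' @param w,h width and height in pixels.
#' @return 4 x 2 vertex matrix.
#' @export
rect_polygon <- function(x0, y0, w, h) {
  cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
}
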