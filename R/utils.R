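# Internal helpers shared across modules.
#
# Pixel coordinate convention: 0-based, x to the right (first matrix
# index), y downwards (second matrix index).  Angles are degrees,
# 0 deg = +x axis, counter-clockwise as displayed (i.e. towards -y).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
ray_direction <- function(angle_deg) {
  a <- angle_deg * pi / 180
  cbind(dx = cos(a), dy = -sin(a))
}

#' @noRd
pixel_angle_deg <- function(dx, dy) {
  (atan2(-dy, dx) * 180 / pi) %% 360
}

# Membership of angles (deg) in a set of arcs given as a 2-column
# matrix of [start, end) intervals; end may exceed 360 for arcs that
# wrap through 0.
#' @noRd
angle_in_arcs <- function(angle_deg, arcs) {
  if (is.null(arcs) || nrow(arcs) == 0L) {
    return(rep(FALSE, length(angle_deg)))
  }
  a <- angle_deg %% 360
  hit <- rep(FALSE, length(a))
  for (i in seq_len(nrow(arcs))) {
    s <- arcs[i, 1] %% 360
    e <- s + (arcs[i, 2] - arcs[i, 1])
    hit <- hit | (a >= s & a < e) | (a + 360 >= s & a + 360 < e)
  }
  hit
}

# Bilinear interpolation of an image matrix (dim = c(nx, ny), 0-based
# pixel centers) at arbitrary positions.  Outside the raster -> NA.
#' @noRd
bilinear_sample <- function(img, x, y) {
  nx <- nrow(img)
  ny <- ncol(img)
  x0 <- floor(x)
  y0 <- floor(y)
  fx <- x - x0
  fy <- y - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= nx - 1 & y0 <= ny - 1
  # clamp the upper neighbour so edge pixels interpolate against themselves
  x1 <- pmin(x0 + 1, nx - 1)
  y1 <- pmin(y0 + 1, ny - 1)
  out <- rep(NA_real_, length(x))
  if (any(ok)) {
    i0 <- x0[ok] + 1L
    j0 <- y0[ok] + 1L
    i1 <- x1[ok] + 1L
    j1 <- y1[ok] + 1L
    v00 <- img[cbind(i0, j0)]
    v10 <- img[cbind(i1, j0)]
    v01 <- img[cbind(i0, j1)]
    v11 <- img[cbind(i1, j1)]
    out[ok] <- v00 * (1 - fx[ok]) * (1 - fy[ok]) +
      v10 * fx[ok] * (1 - fy[ok]) +
      v01 * (1 - fx[ok]) * fy[ok] +
      v11 * fx[ok] * fy[ok]
  }
  out
}

# Signed shoelace area of a closed polygon (vertices as n x 2 matrix,
# not repeated at the end).
#' @noRd
polygon_area_signed <- function(v) {
  x <- v[, 1]
  y <- v[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' @noRd
polygon_centroid <- function(v) {
  x <- v[, 1]
  y <- v[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100) {
    stop("degenerate polygon: zero area", call. = FALSE)
  }
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# Circular extent (deg) of a set of angles: the smallest arc containing
# them all, computed from the largest gap between sorted angles.
#' @noRd
angular_extent_deg <- function(angles_deg) {
  if (length(angles_deg) == 0L) return(0)
  if (length(angles_deg) == 1L) return(0)
  a <- sort(angles_deg %% 360)
  gaps <- diff(c(a, a[1] + 360))
  360 - max(gaps)
}

#' @noRd
stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("guvactin_validation_error", "error")))
}

#' @noRd
stop_geometry <- function(msg) {
  stop(errorCondition(msg, class = c("guvactin_geometry_error", "error")))
}

#' @noRd
stop_segmentation <- function(msg) {
  stop(errorCondition(msg, class = c("guvactin_segmentation_error", "error")))
}
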