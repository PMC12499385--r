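# Small renders shared across tests.  All fixtures are generated in
# code; nothing is read from disk.

quick_spec <- function(...) {
  args <- list(...)
  defaults <- list(guv_diameter_um = 20, pixel_size_um = 0.2)
  do.call(synth_spec, utils::modifyList(defaults, args))
}

render1 <- function(...) {
  lp <- render_guv_frame(quick_spec(...))
  lp$frames[[1]]
}

# circle contour in pixel coordinates (analytic, independent of the
# segmentation code)
circle_contour <- function(r_px = 50, n = 720, center = c(60, 60),
                           pixel_size_um = 0.2) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  guv_contour(cbind(center[1] + r_px * cos(a), center[2] + r_px * sin(a)),
              pixel_size_um)
}

ellipse_contour <- function(a_px, b_px, n = 1440, center = c(0, 0),
                            pixel_size_um = 0.2, rot_deg = 0) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a_px * cos(t); y <- b_px * sin(t)
  th <- rot_deg * pi / 180
  guv_contour(cbind(center[1] + x * cos(th) - y * sin(th),
                    center[2] + x * sin(th) + y * cos(th)),
              pixel_size_um)
}

# manual radial_profile_set for tests that bypass image sampling
manual_profiles <- function(lipid, actin = rep(1, length(lipid))) {
  structure(
    list(center_px = c(0, 0),
         angles_deg = (seq_along(lipid) - 1) * 360 / length(lipid),
         lipid_peak_mean = lipid, actin_peak_mean = actin,
         background = c(lipid = 0, actin = 0),
         sigma = c(lipid = 0, actin = 0),
         guv_radius_px = 50, truncated = rep(FALSE, length(lipid))),
    class = "radial_profile_set")
}

# independent oracle: Feret by all vertex pairs; perpendicular chord by
# scanning offsets along the Feret axis and clipping the polygon with a
# dense family of perpendicular lines
brute_force_ellipticity <- function(v) {
  n <- nrow(v)
  best <- 0; pair <- c(1, 2)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((v[i, ] - v[j, ])^2))
    if (d > best) { best <- d; pair <- c(i, j) }
  }
  u <- (v[pair[2], ] - v[pair[1], ]) / best
  proj <- as.numeric(v %*% u)            # positions along the axis
  perp <- as.numeric(v %*% c(-u[2], u[1]))
  lmax <- 0
  for (s in seq(min(proj), max(proj), length.out = 2000)) {
    # intersect polygon edges with the line proj = s
    ys <- c()
    for (i in 1:n) {
      j <- if (i == n) 1 else i + 1
      p1 <- proj[i]; p2 <- proj[j]
      if ((p1 - s) * (p2 - s) <= 0 && p1 != p2) {
        t <- (s - p1) / (p2 - p1)
        ys <- c(ys, perp[i] + t * (perp[j] - perp[i]))
      }
    }
    if (length(ys) >= 2) lmax <- max(lmax, max(ys) - min(ys))
  }
  list(max_feret = best, l_max_perp = lmax)
}
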