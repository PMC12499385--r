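# GUV contour segmentation and shape/actin-shell descriptors.
#
# The experimental workflow these functions automate delineates each GUV
# on the lipid channel, then derives: the equivalent-area diameter
# d_GUV = 2*sqrt(Area/pi); the ellipticity
# 100 * L_max_perp / max_Feret (max Feret = largest caliper distance of
# the 2D contour, L_max_perp = largest chord perpendicular to it); the
# actin shell thickness as the longest radial distance between the
# membrane and the outer edge of the actin network, with the angle of
# that longest ray as the symmetry-breaking orientation.

#' GUV contour
#'
#' Closed polygon (pixel coordinates, 0-based, x right / y down) around
#' one GUV, with the enclosed pixel area.
#'
#' @param vertices n x 2 numeric matrix of polygon vertices (not
#'   repeated at the end).
#' @param pixel_size_um Pixel size, um/px.
#' @param area_px2 Enclosed area in px^2; defaults to the shoelace area
#'   of the polygon.
#' @return Object of class `guv_contour`.
#' @export
guv_contour <- function(vertices, pixel_size_um, area_px2 = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 2)
  if (nrow(vertices) < 3L) stop_validation("contour needs >= 3 vertices")
  if (is.null(area_px2)) area_px2 <- abs(polygon_area_signed(vertices))
  if (area_px2 <= 0) stop_validation("contour area must be > 0")
  structure(list(vertices = vertices, pixel_size_um = pixel_size_um,
                 area_px2 = area_px2),
            class = "guv_contour")
}

#' Segment the GUV contour on one channel
#'
#' Automated stand-in for interactive wand-tool delineation: the
#' channel is thresholded at background + 3 x MAD (background = image
#' median, with a small relative floor so noise-free images threshold
#' just above background), the bright ring is hole-filled, connected
#' components are labelled, and the outer contour of either the largest
#' component or the one enclosing `seed_point` is traced.  A
#' background-anchored threshold keeps phase-separated rings -- whose
#' Ld arcs are many times brighter than the Lo stretches -- in one
#' connected component, which a histogram split such as Otsu does not.
#'
#' @param frame One frame of an [image_lapse()] (a list with `lipid`
#'   and `actin` matrices) or an `image_lapse` (first frame is used).
#' @param channel `"lipid"` (default) or `"actin"`.
#' @param seed_point Optional `c(x, y)` pixel (0-based) that the
#'   returned contour must enclose.
#' @param pixel_size_um Pixel size; taken from the lapse when a lapse is
#'   passed.
#' @param threshold Optional absolute intensity threshold overriding
#'   Otsu.
#' @param refine Refine the contour to the sub-pixel radial peak of the
#'   ring on each of 360 rays from the component centroid (default
#'   `TRUE`).  With `refine = FALSE` the raw mask contour is returned
#'   and `area_px2` is the pixel count of the filled component.
#' @return A [guv_contour()].
#' @export
segment_guv_contour <- function(frame, channel = c("lipid", "actin"),
                                seed_point = NULL, pixel_size_um = NULL,
                                threshold = NULL, refine = TRUE) {
  channel <- match.arg(channel)
  if (inherits(frame, "image_lapse")) {
    pixel_size_um <- pixel_size_um %||% frame$pixel_size_um
    frame <- frame$frames[[1]]
  }
  if (is.null(pixel_size_um)) stop_validation("pixel_size_um required")
  img <- frame[[channel]]
  rng <- range(img)
  if (rng[2] <= rng[1]) stop_segmentation("channel is flat; nothing to segment")
  if (is.null(threshold)) {
    med <- stats::median(img)
    spread <- stats::mad(img)
    threshold <- med + max(3 * spread, 1e-4 * (rng[2] - med))
  }
  mask <- img > threshold
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  lab <- EBImage::bwlabel(filled)
  labm <- EBImage::imageData(lab)
  n_obj <- max(labm)
  if (n_obj < 1L) stop_segmentation("no connected component above threshold")
  if (!is.null(seed_point)) {
    id <- labm[round(seed_point[1]) + 1L, round(seed_point[2]) + 1L]
    if (id == 0) {
      stop_segmentation("seed point is not inside any segmented component")
    }
  } else {
    sizes <- tabulate(labm[labm > 0], nbins = n_obj)
    id <- which.max(sizes)
  }
  area <- sum(labm == id)
  oc <- EBImage::ocontour(EBImage::Image(1 * (labm == id)))
  verts <- oc[[which.max(vapply(oc, nrow, 1L))]]
  if (!refine) {
    return(guv_contour(verts, pixel_size_um, area_px2 = area))
  }
  # sub-pixel refinement: the mask contour sits on the outer tail of the
  # membrane ridge; trace the radial intensity peak of the ring instead
  sel <- which(labm == id, arr.ind = TRUE)
  center <- c(mean(sel[, 1]) - 1, mean(sel[, 2]) - 1)
  rmax <- sqrt(max((verts[, 1] - center[1])^2 + (verts[, 2] - center[2])^2))
  step <- 0.5
  rs <- seq(0, 1.3 * rmax, by = step)
  angles <- 0:359
  dirs <- ray_direction(angles)
  radial <- numeric(360)
  for (i in 1:360) {
    v <- bilinear_sample(img, center[1] + rs * dirs[i, 1],
                         center[2] + rs * dirs[i, 2])
    v[is.na(v)] <- -Inf
    j <- which.max(v)
    rpk <- rs[j]
    if (j > 1L && j < length(v) && is.finite(v[j - 1]) && is.finite(v[j + 1])) {
      den <- v[j - 1] - 2 * v[j] + v[j + 1]
      if (den < 0) {
        rpk <- rpk + step * 0.5 * (v[j - 1] - v[j + 1]) / den
      }
    }
    radial[i] <- rpk
  }
  poly <- cbind(center[1] + radial * dirs[, 1],
                center[2] + radial * dirs[, 2])
  guv_contour(poly, pixel_size_um)
}

#' Equivalent-area GUV diameter
#'
#' d_GUV = 2 * sqrt(Area / pi), with the area taken from the contour.
#'
#' @param contour A [guv_contour()].
#' @return Diameter in micrometers.
#' @export
guv_diameter <- function(contour) {
  stopifnot(inherits(contour, "guv_contour"))
  area_um2 <- contour$area_px2 * contour$pixel_size_um^2
  if (area_um2 <= 0) stop_validation("contour area must be > 0")
  2 * sqrt(area_um2 / pi)
}

#' Feret-based ellipticity of a contour
#'
#' The maximum Feret diameter is the largest pairwise distance between
#' contour points; `l_max_perp` is the largest chord measured
#' perpendicular to the Feret direction; ellipticity is their ratio in
#' percent (100 for a circle).  Ties in the Feret direction are broken
#' towards the smallest angle to the +x axis.
#'
#' @param contour A [guv_contour()].
#' @return List with `max_feret_um`, `l_max_perp_um`, `ellipticity_pct`
#'   and `feret_angle_deg`.
#' @export
ellipticity <- function(contour) {
  stopifnot(inherits(contour, "guv_contour"))
  v <- contour$vertices * contour$pixel_size_um
  h <- grDevices::chull(v)
  hv <- v[h, , drop = FALSE]
  n <- nrow(hv)
  if (n < 3L) stop_validation("degenerate (collinear) contour")
  # max Feret over hull vertex pairs
  best <- 0
  best_pair <- NULL
  best_angle <- Inf
  for (i in seq_len(n - 1L)) {
    d2 <- (hv[(i + 1):n, 1] - hv[i, 1])^2 + (hv[(i + 1):n, 2] - hv[i, 2])^2
    j <- which(d2 >= best^2 - 1e-12)
    for (jj in j) {
      k <- i + jj
      len <- sqrt(d2[jj])
      ang <- (atan2(-(hv[k, 2] - hv[i, 2]), hv[k, 1] - hv[i, 1]) * 180 / pi) %% 180
      if (len > best + 1e-12 || (abs(len - best) <= 1e-12 && ang < best_angle)) {
        best <- len
        best_pair <- c(i, k)
        best_angle <- ang
      }
    }
  }
  if (best <= 0) stop_validation("degenerate contour")
  # rotate so the Feret axis is the x axis; perpendicular chords are
  # vertical segments.  For a convex polygon, chord length vs offset is
  # concave piecewise-linear: the maximum is attained at a vertex offset.
  u <- (hv[best_pair[2], ] - hv[best_pair[1], ]) / best
  rot <- cbind(c(u[1], -u[2]), c(u[2], u[1]))  # rows of R: u, u_perp
  p <- hv %*% t(rot)
  lperp <- max(vapply(p[, 1], function(x0) .vertical_chord(p, x0), 1.0))
  if (lperp <= 1e-9 * best) stop_validation("degenerate (collinear) contour")
  list(max_feret_um = best,
       l_max_perp_um = lperp,
       ellipticity_pct = 100 * lperp / best,
       feret_angle_deg = best_angle)
}

# Length of the intersection of a convex polygon (vertices p, any order
# preserved from chull) with the vertical line x = x0.
#' @noRd
.vertical_chord <- function(p, x0) {
  n <- nrow(p)
  ys <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- p[i, 1]; x2 <- p[j, 1]
    if ((x1 - x0) * (x2 - x0) <= 0 && x1 != x2) {
      t <- (x0 - x1) / (x2 - x1)
      if (t >= 0 && t <= 1) ys <- c(ys, p[i, 2] + t * (p[j, 2] - p[i, 2]))
    } else if (x1 == x0 && x2 == x0) {
      ys <- c(ys, p[i, 2], p[j, 2])
    }
  }
  if (length(ys) < 2L) return(0)
  max(ys) - min(ys)
}

#' Per-ray actin thickness profile
#'
#' Casts `n_angles` rays from the GUV center; on each ray the actin
#' outer edge is the outermost sample whose intensity exceeds
#' `background + k * sigma_background`, and the thickness is the edge
#' radius minus the membrane radius (from the contour), floored at 0.
#'
#' @param frame Frame (list with `lipid`/`actin`) or [image_lapse()]
#'   (first frame used).
#' @param contour A [guv_contour()].
#' @param center Optional `c(x, y)` center (0-based px); defaults to
#'   the contour centroid.
#' @param n_angles Number of rays (default 360, one per degree).
#' @param k Threshold multiplier on the background spread (default 3).
#' @param step_px Radial sampling step (default 0.5 px).
#' @return data.frame with `angle_deg`, `membrane_r_um`, `edge_r_um`,
#'   `thickness_um`.
#' @export
actin_radial_thickness <- function(frame, contour, center = NULL,
                                   n_angles = 360, k = 3, step_px = 0.5) {
  if (inherits(frame, "image_lapse")) frame <- frame$frames[[1]]
  stopifnot(inherits(contour, "guv_contour"))
  px <- contour$pixel_size_um
  center <- center %||% estimate_center(contour)
  # threshold anchored on the frame border strip, which the rendering /
  # acquisition margin guarantees to be actin-free even for thick shells
  bg <- .border_background(frame)
  thr <- bg$background["actin"] + k * bg$sigma["actin"]
  angles <- (seq_len(n_angles) - 1) * 360 / n_angles
  mem_r_px <- .contour_radius_at(contour, center, angles)
  img <- frame$actin
  nx <- nrow(img); ny <- ncol(img)
  max_r_px <- sqrt(nx^2 + ny^2)
  rs <- seq(0, max_r_px, by = step_px)
  dirs <- ray_direction(angles)
  edge_r <- numeric(n_angles)
  for (i in seq_len(n_angles)) {
    xs <- center[1] + rs * dirs[i, 1]
    ys <- center[2] + rs * dirs[i, 2]
    v <- bilinear_sample(img, xs, ys)
    # light radial smoothing so a single noise sample cannot register as
    # the network edge; tolerance keeps a flat background below threshold
    v <- .smooth3(v)
    above <- which(!is.na(v) & v > thr + 1e-8 * (abs(thr) + 1))
    edge_r[i] <- if (length(above)) rs[max(above)] else 0
  }
  data.frame(
    angle_deg = angles,
    membrane_r_um = mem_r_px * px,
    edge_r_um = edge_r * px,
    thickness_um = pmax(edge_r - mem_r_px, 0) * px
  )
}

# Moving average over 3 samples, ends handled by shrinking the window.
#' @noRd
.smooth3 <- function(v) {
  n <- length(v)
  if (n < 3L) return(v)
  out <- v
  out[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
  out[1] <- (v[1] + v[2]) / 2
  out[n] <- (v[n - 1] + v[n]) / 2
  out
}

# Background level and spread from the frame border strip (median/MAD
# over pixels within `width_px` of any image edge).
#' @noRd
.border_background <- function(frame, width_px = 4L) {
  nx <- nrow(frame$lipid); ny <- ncol(frame$lipid)
  xm <- matrix(0:(nx - 1), nx, ny)
  ym <- matrix(0:(ny - 1), nx, ny, byrow = TRUE)
  strip <- xm < width_px | ym < width_px | xm >= nx - width_px |
    ym >= ny - width_px
  list(background = c(lipid = stats::median(frame$lipid[strip]),
                      actin = stats::median(frame$actin[strip])),
       sigma = c(lipid = stats::mad(frame$lipid[strip]),
                 actin = stats::mad(frame$actin[strip])))
}

# Radius of the contour polygon along each query angle, by linear
# interpolation of vertex radii versus vertex polar angle (adequate for
# star-shaped GUV contours).
#' @noRd
.contour_radius_at <- function(contour, center, angles_deg) {
  v <- contour$vertices
  dx <- v[, 1] - center[1]
  dy <- v[, 2] - center[2]
  ang <- pixel_angle_deg(dx, dy)
  r <- sqrt(dx^2 + dy^2)
  o <- order(ang)
  a_s <- ang[o]; r_s <- r[o]
  a_ext <- c(a_s[length(a_s)] - 360, a_s, a_s[1] + 360)
  r_ext <- c(r_s[length(r_s)], r_s, r_s[1])
  stats::approx(a_ext, r_ext, xout = angles_deg %% 360, rule = 2)$y
}

#' Actin shell thickness and symmetry-breaking angle
#'
#' The thickness is the maximum over rays of the radial distance between
#' the membrane and the outer edge of the actin network; the angle of
#' the maximal ray is the symmetry-breaking orientation (0 deg = +x,
#' counter-clockwise).
#'
#' @inheritParams actin_radial_thickness
#' @param profile Optional precomputed [actin_radial_thickness()]
#'   profile.
#' @return List with `thickness_um`, `break_angle_deg` (`NA` when no
#'   actin is detected), `flagged` and the per-ray `profile`.
#' @export
actin_thickness <- function(frame, contour, center = NULL, n_angles = 360,
                            k = 3, profile = NULL) {
  if (is.null(profile)) {
    profile <- actin_radial_thickness(frame, contour, center = center,
                                      n_angles = n_angles, k = k)
  }
  if (all(profile$thickness_um <= 0)) {
    return(list(thickness_um = 0, break_angle_deg = NA_real_,
                flagged = TRUE, profile = profile))
  }
  i <- which.max(profile$thickness_um)
  list(thickness_um = profile$thickness_um[i],
       break_angle_deg = profile$angle_deg[i],
       flagged = FALSE, profile = profile)
}

#' Classify the actin structure from a per-ray thickness profile
#'
#' A shell is symmetric when its thickness modulation
#' `(max - min) / max` stays below `a_sym`; a comet is called when actin
#' reaches beyond `r_comet` times the GUV radius within a sector
#' narrower than 90 degrees; anything else is an asymmetric shell.
#' Thresholds are configurable and echoed in pipeline outputs.
#'
#' @param profile data.frame from [actin_radial_thickness()].
#' @param guv_radius_um GUV radius in um (e.g. `guv_diameter(contour)/2`).
#' @param a_sym Symmetry threshold on the relative thickness modulation
#'   (default 0.3).
#' @param r_comet Comet reach threshold as a multiple of the GUV radius
#'   (default 1.5).
#' @return One of `"symmetric_shell"`, `"asymmetric_shell"`, `"comet"`,
#'   or `"none"` when no actin is present.
#' @export
classify_actin_structure <- function(profile, guv_radius_um,
                                     a_sym = 0.3, r_comet = 1.5) {
  th <- profile$thickness_um
  if (all(th <= 0)) return("none")
  mod <- (max(th) - min(th)) / max(th)
  if (mod < a_sym) return("symmetric_shell")
  far <- profile$angle_deg[profile$edge_r_um > r_comet * guv_radius_um]
  if (length(far) > 0 && angular_extent_deg(far) < 90) return("comet")
  "asymmetric_shell"
}

#' Actin thickness growth rate
#'
#' Ordinary least-squares slope of shell thickness versus time; the gel
#' thickens quasilinearly at 0.1--0.3 um/min in the regime emulated by
#' the generator.
#'
#' @param times_min Acquisition times, minutes (>= 3 points).
#' @param thickness_um Thickness at each time, um.
#' @return Slope in um/min.
#' @export
fit_growth_rate <- function(times_min, thickness_um) {
  if (length(times_min) != length(thickness_um)) {
    stop_validation("times and thicknesses must have equal length")
  }
  if (length(times_min) < 3L) stop_validation("need >= 3 time points")
  unname(stats::coef(stats::lm(thickness_um ~ times_min))[2])
}

#' Full morphometry of one frame
#'
#' Convenience wrapper running segmentation, diameter, ellipticity,
#' actin thickness and structure classification on a single frame.
#'
#' @param frame Frame or single-frame [image_lapse()].
#' @param pixel_size_um Pixel size (taken from the lapse if given one).
#' @param a_sym,r_comet Classification thresholds, see
#'   [classify_actin_structure()].
#' @param k Actin edge threshold multiplier.
#' @return A one-row data.frame (`d_guv_um`, `max_feret_um`,
#'   `l_max_perp_um`, `ellipticity_pct`, `actin_thickness_um`,
#'   `break_angle_deg`, `structure_class`).
#' @export
morphometry_record <- function(frame, pixel_size_um = NULL,
                               a_sym = 0.3, r_comet = 1.5, k = 3) {
  if (inherits(frame, "image_lapse")) {
    pixel_size_um <- pixel_size_um %||% frame$pixel_size_um
    frame <- frame$frames[[1]]
  }
  contour <- segment_guv_contour(frame, pixel_size_um = pixel_size_um)
  d <- guv_diameter(contour)
  el <- ellipticity(contour)
  prof <- actin_radial_thickness(frame, contour, k = k)
  th <- actin_thickness(frame, contour, profile = prof)
  cls <- classify_actin_structure(prof, d / 2, a_sym = a_sym,
                                  r_comet = r_comet)
  data.frame(
    d_guv_um = d,
    max_feret_um = el$max_feret_um,
    l_max_perp_um = el$l_max_perp_um,
    ellipticity_pct = el$ellipticity_pct,
    actin_thickness_um = th$thickness_um,
    break_angle_deg = th$break_angle_deg,
    structure_class = cls,
    stringsAsFactors = FALSE
  )
}
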