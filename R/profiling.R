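# Per-degree radial fluorescence profiling along the GUV perimeter,
# normalization, Ld-domain calling at the 0.2 threshold, and scoring of
# the actin fluorescence on Ld domains.

#' Area centroid of a GUV contour
#'
#' @param contour A [guv_contour()].
#' @return `c(x, y)` in 0-based pixel coordinates.
#' @export
estimate_center <- function(contour) {
  stopifnot(inherits(contour, "guv_contour"))
  polygon_centroid(contour$vertices)
}

#' Background intensity outside the GUV
#'
#' Median (and MAD spread) of the pixels farther than `factor` times the
#' maximal contour radius from the center, per channel.  Robust to the
#' GUV, its actin corona and moderate noise.
#'
#' @param frame Frame (list with `lipid`/`actin`) or [image_lapse()]
#'   (first frame used).
#' @param contour A [guv_contour()].
#' @param factor Exclusion radius as a multiple of the maximal contour
#'   radius (default 1.2).
#' @param center Optional center override.
#' @return List with `background` and `sigma`, each a named vector over
#'   channels, and `n_pixels`.
#' @export
estimate_background <- function(frame, contour, factor = 1.2,
                                center = NULL) {
  if (inherits(frame, "image_lapse")) frame <- frame$frames[[1]]
  stopifnot(inherits(contour, "guv_contour"))
  center <- center %||% estimate_center(contour)
  v <- contour$vertices
  rmax <- sqrt(max((v[, 1] - center[1])^2 + (v[, 2] - center[2])^2))
  nx <- nrow(frame$lipid); ny <- ncol(frame$lipid)
  xm <- matrix(0:(nx - 1), nx, ny)
  ym <- matrix(0:(ny - 1), nx, ny, byrow = TRUE)
  far <- ((xm - center[1])^2 + (ym - center[2])^2) > (factor * rmax)^2
  if (!any(far)) {
    stop_validation("frame too tight: no pixels beyond the exclusion radius")
  }
  bg <- c(lipid = stats::median(frame$lipid[far]),
          actin = stats::median(frame$actin[far]))
  sg <- c(lipid = stats::mad(frame$lipid[far]),
          actin = stats::mad(frame$actin[far]))
  list(background = bg, sigma = sg, n_pixels = sum(far))
}

#' Per-degree radial peak-intensity profiles
#'
#' For each of `n_angles` rays from the center, intensities are sampled
#' by bilinear interpolation every `step_px` out to `reach` times the
#' GUV radius.  On each ray the membrane (or actin) peak is the
#' contiguous run of samples around the global maximum whose
#' background-subtracted intensity is at least half the
#' background-subtracted maximum; the reported value is the mean over
#' that run, background-subtracted and floored at 0.
#'
#' @param frame Frame or [image_lapse()] (first frame used).
#' @param center `c(x, y)` center in 0-based px.
#' @param contour Optional [guv_contour()] used to derive the GUV
#'   radius and background; required unless both `guv_radius_px` and
#'   `background` are given.
#' @param n_angles Number of rays (default 360, one per degree).
#' @param step_px Radial sampling step (default 0.5).
#' @param reach Profile extent as a multiple of the GUV radius
#'   (default 1.5).
#' @param guv_radius_px Optional GUV radius override (px).
#' @param background Optional list as returned by
#'   [estimate_background()].
#' @return An object of class `radial_profile_set` with per-angle
#'   `lipid_peak_mean` and `actin_peak_mean`, the background used, and
#'   a `truncated` flag per ray.
#' @export
radial_profiles <- function(frame, center = NULL, contour = NULL,
                            n_angles = 360, step_px = 0.5, reach = 1.5,
                            guv_radius_px = NULL, background = NULL) {
  if (inherits(frame, "image_lapse")) frame <- frame$frames[[1]]
  if (is.null(center)) {
    if (is.null(contour)) stop_validation("need a center or a contour")
    center <- estimate_center(contour)
  }
  if (is.null(guv_radius_px)) {
    if (is.null(contour)) stop_validation("need guv_radius_px or a contour")
    v <- contour$vertices
    guv_radius_px <- sqrt(mean((v[, 1] - center[1])^2 +
                                 (v[, 2] - center[2])^2))
  }
  if (is.null(background)) {
    if (is.null(contour)) stop_validation("need background or a contour")
    background <- estimate_background(frame, contour, center = center)
  }
  nx <- nrow(frame$lipid); ny <- ncol(frame$lipid)
  if (center[1] < 0 || center[1] > nx - 1 || center[2] < 0 ||
      center[2] > ny - 1) {
    stop_validation("center outside the frame")
  }
  angles <- (seq_len(n_angles) - 1) * 360 / n_angles
  rs <- seq(0, reach * guv_radius_px, by = step_px)
  dirs <- ray_direction(angles)
  out <- list(lipid = numeric(n_angles), actin = numeric(n_angles))
  truncated <- logical(n_angles)
  for (i in seq_len(n_angles)) {
    xs <- center[1] + rs * dirs[i, 1]
    ys <- center[2] + rs * dirs[i, 2]
    for (ch in c("lipid", "actin")) {
      v <- bilinear_sample(frame[[ch]], xs, ys)
      if (anyNA(v)) {
        truncated[i] <- TRUE
        v <- v[!is.na(v)]
      }
      out[[ch]][i] <- .peak_mean(v - background$background[[ch]])
    }
  }
  # floor interpolation round-off so a flat background reads as zero
  for (ch in c("lipid", "actin")) {
    eps <- 1e-9 * (abs(background$background[[ch]]) + 1)
    out[[ch]][out[[ch]] < eps] <- 0
  }
  structure(
    list(center_px = center, angles_deg = angles,
         lipid_peak_mean = out$lipid, actin_peak_mean = out$actin,
         background = background$background, sigma = background$sigma,
         guv_radius_px = guv_radius_px, truncated = truncated),
    class = "radial_profile_set"
  )
}

# Mean of the contiguous half-max run around the global maximum of a
# background-subtracted radial intensity trace; 0 if nothing positive.
#' @noRd
.peak_mean <- function(v) {
  if (length(v) == 0L) return(0)
  m <- max(v)
  if (m <= 0) return(0)
  i <- which.max(v)
  lo <- i
  while (lo > 1L && v[lo - 1L] >= m / 2) lo <- lo - 1L
  hi <- i
  while (hi < length(v) && v[hi + 1L] >= m / 2) hi <- hi + 1L
  max(mean(v[lo:hi]), 0)
}

#' Normalize radial profiles per channel
#'
#' Each (already background-subtracted) channel is divided by its own
#' per-GUV maximum, so 1 corresponds to the channel maximum and 0 to the
#' background.  An all-zero channel stays all-zero and is flagged.
#'
#' @param profiles A `radial_profile_set` from [radial_profiles()].
#' @return The same object with `lipid_norm` and `actin_norm` in
#'   `[0, 1]` and a `zero_channels` character vector.
#' @export
normalize_profiles <- function(profiles) {
  stopifnot(inherits(profiles, "radial_profile_set"))
  if (any(profiles$lipid_peak_mean < 0) || any(profiles$actin_peak_mean < 0)) {
    stop_validation("peak means must be non-negative")
  }
  zero <- character(0)
  for (ch in c("lipid", "actin")) {
    v <- profiles[[paste0(ch, "_peak_mean")]]
    m <- max(v)
    if (m > 0) {
      profiles[[paste0(ch, "_norm")]] <- v / m
    } else {
      profiles[[paste0(ch, "_norm")]] <- v
      zero <- c(zero, ch)
    }
  }
  profiles$zero_channels <- zero
  profiles
}

#' Call Ld domains on the normalized lipid profile
#'
#' Ld domains are the contiguous angular runs where the normalized lipid
#' signal strictly exceeds `threshold` (default 0.2).  Runs touching
#' across the 0/360 wrap are merged; runs narrower than `min_width_deg`
#' are discarded.  The default minimum width is the angle subtended by
#' 1 um at the GUV radius, the smallest domain resolvable on
#' diffraction-limited optical images; pass `min_width_deg = 0` to
#' disable the filter.
#'
#' @param profiles A normalized `radial_profile_set` (see
#'   [normalize_profiles()]).
#' @param threshold Ld calling threshold on the normalized lipid signal
#'   (default 0.2, strict inequality).
#' @param min_width_deg Minimum angular width of a domain (deg).
#' @param guv_radius_um GUV radius used for the default minimum width;
#'   derived from `guv_radius_px` and `pixel_size_um` if supplied.
#' @param pixel_size_um Pixel size, um/px.
#' @return Object of class `domain_set`: `intervals_deg` (2-column
#'   matrix of `[start, end)`, end may exceed 360 for the wrap
#'   interval), `n_d`, `angle_index` (list of member angle indices) and
#'   the parameters used.
#' @export
segment_ld_domains <- function(profiles, threshold = 0.2,
                               min_width_deg = NULL, guv_radius_um = NULL,
                               pixel_size_um = NULL) {
  stopifnot(inherits(profiles, "radial_profile_set"))
  if (is.null(profiles$lipid_norm)) {
    stop_validation("profiles must be normalized first")
  }
  if (is.null(min_width_deg)) {
    if (is.null(guv_radius_um) && !is.null(pixel_size_um)) {
      guv_radius_um <- profiles$guv_radius_px * pixel_size_um
    }
    min_width_deg <- if (is.null(guv_radius_um)) 0 else {
      (1 / guv_radius_um) * 180 / pi
    }
  }
  n <- length(profiles$angles_deg)
  step <- 360 / n
  above <- profiles$lipid_norm > threshold
  runs <- .circular_runs(above)
  keep <- list()
  idx <- list()
  for (r in runs) {
    width <- length(r) * step
    if (width >= min_width_deg) {
      start <- profiles$angles_deg[r[1]]
      keep[[length(keep) + 1L]] <- c(start, start + width)
      idx[[length(idx) + 1L]] <- r
    }
  }
  intervals <- if (length(keep)) do.call(rbind, keep) else
    matrix(numeric(0), ncol = 2)
  colnames(intervals) <- c("start_deg", "end_deg")
  structure(
    list(intervals_deg = intervals, n_d = length(keep), angle_index = idx,
         threshold = threshold, min_width_deg = min_width_deg),
    class = "domain_set"
  )
}

# Runs of TRUE on a circular logical vector, each run as the ordered
# vector of member indices (wrap runs keep their circular order).
#' @noRd
.circular_runs <- function(x) {
  n <- length(x)
  if (!any(x)) return(list())
  if (all(x)) return(list(seq_len(n)))
  # rotate so position 1 is FALSE, find linear runs, rotate back
  first_false <- which(!x)[1]
  rot <- c(first_false:n, seq_len(first_false - 1L))
  xr <- x[rot]
  r <- rle(xr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$values)) {
    if (r$values[i]) out[[length(out) + 1L]] <- rot[starts[i]:ends[i]]
  }
  out
}

#' Average normalized actin fluorescence on Ld domains
#'
#' Mean of the normalized actin profile over all angles inside Ld
#' intervals, divided by the maximal actin value inside those intervals,
#' so 1 corresponds to the maximal actin fluorescence on the Ld domains
#' of this GUV and 0 to the background.  Returns 0 when there are no
#' domains.
#'
#' @param profiles A normalized `radial_profile_set`.
#' @param domains A `domain_set` from [segment_ld_domains()] on the same
#'   GUV.
#' @return Scalar in `[0, 1]`.
#' @export
actin_on_ld <- function(profiles, domains) {
  stopifnot(inherits(profiles, "radial_profile_set"),
            inherits(domains, "domain_set"))
  if (domains$n_d == 0L) return(0)
  idx <- unlist(domains$angle_index)
  v <- profiles$actin_norm[idx]
  m <- max(v)
  if (m <= 0) return(0)
  mean(v) / m
}
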