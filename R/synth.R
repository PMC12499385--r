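#' Specification of a synthetic two-channel GUV scene
#'
#' Describes one equatorial cross-section of a giant unilamellar vesicle
#' (GUV) as seen in two-channel epifluorescence: a lipid channel carrying
#' a bright membrane ring (optionally with brighter liquid-disordered, Ld,
#' arcs) and an actin channel carrying a shell, asymmetric shell or comet
#' outside the membrane.  All downstream measurement operations can be
#' validated against the ground truth embedded in rendered frames.
#'
#' Geometry defaults mirror the experimental regime this generator
#' emulates: microfluidic traps retain GUVs of 10--60 um diameter, actin
#' shells grow at roughly 0.1--0.3 um/min and break symmetry once
#' 5--10 um thick.
#'
#' @param guv_diameter_um GUV diameter in micrometers (default 20).
#' @param pixel_size_um Physical pixel size, um/px (default 0.2,
#'   a 63x-objective scale).
#' @param image_shape Integer vector `c(nx, ny)`.  Default: the smallest
#'   square that holds the GUV, its actin structure and a >= 2 um margin,
#'   with extra room for background estimation.
#' @param membrane_intensity Peak membrane ring intensity (arbitrary
#'   fluorescence units, default 100).
#' @param membrane_ring_sigma_um Gaussian ridge width of the membrane
#'   ring (default 0.3 um, diffraction-limited scale).
#' @param actin_structure One of `"none"`, `"symmetric_shell"`,
#'   `"asymmetric_shell"`, `"comet"`.
#' @param actin_intensity Actin plateau intensity (default 80).
#' @param actin_thickness_um Maximal actin shell thickness in um.
#' @param break_angle_deg Symmetry-breaking direction in degrees
#'   (0 = +x, counter-clockwise); peak of the asymmetric shell or comet
#'   tail direction.
#' @param asym_min_frac For asymmetric shells, thickness on the side
#'   opposite the break angle as a fraction of the maximum (default 0.2).
#' @param comet_length_factor Comet tail length beyond the membrane, as a
#'   multiple of the GUV radius (default 2.5).
#' @param n_domains Number of Ld arcs on the ring (0 = homogeneous GUV).
#' @param domain_arc_bounds_deg Optional 2-column matrix of `[start, end)`
#'   angular intervals (deg); default: `n_domains` equally spaced arcs,
#'   each covering half its period.
#' @param ld_lipid_gain Multiplier of the lipid intensity on Ld arcs
#'   relative to the Lo background ring (default 8: the fluorescent
#'   lipid partitions strongly into the Ld phase, leaving the Lo ring
#'   well below the 0.2 domain-calling level after normalization).
#' @param actin_on_ld_only If `TRUE` (default whenever `n_domains > 0`)
#'   the actin structure is restricted to the Ld arcs, emulating
#'   nucleation on Ld domains.
#' @param background_level Additive background (default 10).
#' @param shot_noise Apply Poisson noise to the signal?
#' @param gaussian_noise_sigma Standard deviation of additive Gaussian
#'   read noise (0 = none).
#' @param seed Integer seed making noisy renders reproducible.
#'
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(guv_diameter_um = 20,
                       pixel_size_um = 0.2,
                       image_shape = NULL,
                       membrane_intensity = 100,
                       membrane_ring_sigma_um = 0.3,
                       actin_structure = c("none", "symmetric_shell",
                                           "asymmetric_shell", "comet"),
                       actin_intensity = 80,
                       actin_thickness_um = 0,
                       break_angle_deg = 0,
                       asym_min_frac = 0.2,
                       comet_length_factor = 2.5,
                       n_domains = 0,
                       domain_arc_bounds_deg = NULL,
                       ld_lipid_gain = 8,
                       actin_on_ld_only = n_domains > 0,
                       background_level = 10,
                       shot_noise = FALSE,
                       gaussian_noise_sigma = 0,
                       seed = NULL) {
  actin_structure <- match.arg(actin_structure)
  if (pixel_size_um <= 0) stop_validation("pixel_size_um must be > 0")
  if (guv_diameter_um <= 0) stop_validation("guv_diameter_um must be > 0")
  if (actin_thickness_um < 0) stop_validation("actin_thickness_um must be >= 0")
  if (membrane_intensity < 0 || actin_intensity < 0 || background_level < 0) {
    stop_validation("intensities must be non-negative")
  }
  if (n_domains > 0 && is.null(domain_arc_bounds_deg)) {
    period <- 360 / n_domains
    starts <- (seq_len(n_domains) - 1) * period
    domain_arc_bounds_deg <- cbind(starts, starts + period / 2)
  }
  if (!is.null(domain_arc_bounds_deg)) {
    domain_arc_bounds_deg <- matrix(as.numeric(domain_arc_bounds_deg),
                                    ncol = 2)
    if (any(domain_arc_bounds_deg[, 2] <= domain_arc_bounds_deg[, 1])) {
      stop_validation("domain arcs must have end > start")
    }
    .check_arcs_disjoint(domain_arc_bounds_deg)
    n_domains <- nrow(domain_arc_bounds_deg)
  }
  r_um <- guv_diameter_um / 2
  reach_um <- r_um + switch(actin_structure,
    none = 0,
    symmetric_shell = actin_thickness_um,
    asymmetric_shell = actin_thickness_um,
    comet = comet_length_factor * r_um
  )
  if (is.null(image_shape)) {
    # room for the structure, the 2 um margin and the background annulus
    # (media beyond 1.2x the membrane radius) used by profiling
    half_um <- max(reach_um, 1.3 * r_um) + 3
    side <- 2L * as.integer(ceiling(half_um / pixel_size_um)) + 1L
    image_shape <- c(side, side)
  }
  image_shape <- as.integer(image_shape)
  half_x_um <- (image_shape[1] - 1) / 2 * pixel_size_um
  half_y_um <- (image_shape[2] - 1) / 2 * pixel_size_um
  if (r_um + 2 > min(half_x_um, half_y_um)) {
    stop_geometry("GUV does not fit in the image with a 2 um margin")
  }
  structure(
    list(
      guv_diameter_um = guv_diameter_um,
      pixel_size_um = pixel_size_um,
      image_shape = image_shape,
      membrane_intensity = membrane_intensity,
      membrane_ring_sigma_um = membrane_ring_sigma_um,
      actin_structure = actin_structure,
      actin_intensity = actin_intensity,
      actin_thickness_um = actin_thickness_um,
      break_angle_deg = break_angle_deg %% 360,
      asym_min_frac = asym_min_frac,
      comet_length_factor = comet_length_factor,
      n_domains = n_domains,
      domain_arc_bounds_deg = domain_arc_bounds_deg,
      ld_lipid_gain = ld_lipid_gain,
      actin_on_ld_only = actin_on_ld_only,
      background_level = background_level,
      shot_noise = shot_noise,
      gaussian_noise_sigma = gaussian_noise_sigma,
      seed = seed
    ),
    class = "synth_spec"
  )
}

#' @noRd
.check_arcs_disjoint <- function(arcs) {
  n <- nrow(arcs)
  if (n < 2L) return(invisible(TRUE))
  # unroll to [0, 720) and check pairwise overlap modulo 360
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      si <- arcs[i, 1] %% 360; ei <- si + (arcs[i, 2] - arcs[i, 1])
      sj <- arcs[j, 1] %% 360; ej <- sj + (arcs[j, 2] - arcs[j, 1])
      for (shift in c(-360, 0, 360)) {
        if (si < ej + shift && sj + shift < ei) {
          stop_validation("domain arcs overlap modulo 360 degrees")
        }
      }
    }
  }
  invisible(TRUE)
}

#' Two-channel image time series with physical calibration
#'
#' @param frames List of frames; each frame is a list with numeric
#'   matrices `lipid` and `actin` of identical dimensions
#'   (dim = `c(nx, ny)`; x = first index, y = second, 0-based pixel
#'   coordinates).
#' @param times_min Strictly increasing frame timestamps in minutes.
#' @param pixel_size_um Pixel size in um/px.
#' @param ground_truth Optional list of per-frame `synth_spec` objects.
#'
#' @return An object of class `image_lapse`.
#' @export
image_lapse <- function(frames, times_min, pixel_size_um,
                        ground_truth = NULL) {
  if (length(frames) != length(times_min)) {
    stop_validation("frames and times_min must have equal length")
  }
  if (length(times_min) > 1 && any(diff(times_min) <= 0)) {
    stop_validation("times_min must be strictly increasing")
  }
  dims <- lapply(frames, function(f) dim(f$lipid))
  if (length(unique(lapply(dims, paste, collapse = "x"))) > 1L) {
    stop_validation("all frames must share the same shape")
  }
  for (f in frames) {
    if (any(f$lipid < 0) || any(f$actin < 0)) {
      stop_validation("intensities must be non-negative")
    }
  }
  structure(
    list(frames = frames, times_min = as.numeric(times_min),
         pixel_size_um = pixel_size_um, ground_truth = ground_truth),
    class = "image_lapse"
  )
}

#' @export
print.image_lapse <- function(x, ...) {
  d <- dim(x$frames[[1]]$lipid)
  cat(sprintf(
    "image_lapse: %d frame(s), %d x %d px at %.3g um/px, t = %s min\n",
    length(x$frames), d[1], d[2], x$pixel_size_um,
    paste(signif(range(x$times_min), 3), collapse = "..")))
  invisible(x)
}

# Per-angle actin thickness profile of a spec (um), on the rendering
# grid's angular convention.  Used both by the renderer and by
# round-trip tests through the embedded ground truth.
#' @noRd
.spec_thickness_profile <- function(spec, angle_deg) {
  t_max <- spec$actin_thickness_um
  switch(spec$actin_structure,
    none = rep(0, length(angle_deg)),
    symmetric_shell = rep(t_max, length(angle_deg)),
    asymmetric_shell = {
      d <- (angle_deg - spec$break_angle_deg) * pi / 180
      f <- spec$asym_min_frac
      t_max * (f + (1 - f) * ((1 + cos(d)) / 2)^2)
    },
    comet = rep(t_max, length(angle_deg))
  )
}

#' Render a single synthetic GUV frame
#'
#' Draws the lipid membrane as a Gaussian ridge of radius d/2, multiplies
#' the lipid intensity on Ld arcs by `ld_lipid_gain`, draws the requested
#' actin structure outside the membrane (asymmetric shells have their
#' thickness modulated by a smooth unimodal angular profile peaking at
#' `break_angle_deg`; comets add a tapered tail polygon in that
#' direction), then applies noise last.  The generating `synth_spec` is
#' embedded as ground truth.
#'
#' @param spec A [synth_spec()].
#' @return An [image_lapse()] with a single frame at t = 0.
#' @export
render_guv_frame <- function(spec) {
  lp <- render_time_lapse(spec, times_min = 0, growth_rate_um_per_min = 0)
  lp
}

#' Render a synthetic time lapse with a growing actin structure
#'
#' All parameters are frozen across frames except the actin thickness,
#' which follows `thickness0 + rate * t`; `thickness0` is taken from
#' `spec$actin_thickness_um`.
#'
#' @param spec A [synth_spec()].
#' @param times_min Strictly increasing acquisition times (minutes).
#' @param growth_rate_um_per_min Actin thickness growth rate, um/min
#'   (typical experimental range 0.1--0.3).
#' @return An [image_lapse()].
#' @export
render_time_lapse <- function(spec, times_min, growth_rate_um_per_min = 0) {
  stopifnot(inherits(spec, "synth_spec"))
  if (length(times_min) > 1 && any(diff(times_min) <= 0)) {
    stop_validation("times_min must be strictly increasing")
  }
  if (growth_rate_um_per_min < 0) stop_validation("growth rate must be >= 0")
  # make sure the final-frame structure still fits; enlarge if needed
  final_thick <- spec$actin_thickness_um +
    growth_rate_um_per_min * max(times_min)
  r_um <- spec$guv_diameter_um / 2
  reach_um <- r_um + switch(spec$actin_structure,
    none = 0, symmetric_shell = final_thick, asymmetric_shell = final_thick,
    comet = spec$comet_length_factor * r_um)
  need <- 2L * as.integer(ceiling((reach_um + 2) / spec$pixel_size_um)) + 1L
  if (need > min(spec$image_shape)) {
    message(sprintf("enlarging image to %d px to fit the final actin extent",
                    need))
    spec$image_shape <- c(need, need)
  }
  frames <- vector("list", length(times_min))
  truth <- vector("list", length(times_min))
  for (k in seq_along(times_min)) {
    sp <- spec
    sp$actin_thickness_um <- spec$actin_thickness_um +
      growth_rate_um_per_min * times_min[k]
    # image_shape fixed by the t = 0 spec; re-validate reach at final frame
    frames[[k]] <- .render_channels(sp, frame_index = k)
    truth[[k]] <- sp
  }
  image_lapse(frames, times_min, spec$pixel_size_um, ground_truth = truth)
}

#' @noRd
.render_channels <- function(spec, frame_index = 1L) {
  nx <- spec$image_shape[1]
  ny <- spec$image_shape[2]
  px <- spec$pixel_size_um
  cx <- (nx - 1) / 2
  cy <- (ny - 1) / 2
  xs <- ((0:(nx - 1)) - cx) * px
  ys <- ((0:(ny - 1)) - cy) * px
  xm <- matrix(xs, nx, ny)
  ym <- matrix(ys, nx, ny, byrow = TRUE)
  rho <- sqrt(xm^2 + ym^2)
  theta <- pixel_angle_deg(xm, ym)
  r_mem <- spec$guv_diameter_um / 2

  lipid <- spec$membrane_intensity *
    exp(-(rho - r_mem)^2 / (2 * spec$membrane_ring_sigma_um^2))
  if (spec$n_domains > 0 && spec$ld_lipid_gain != 1) {
    on_ld <- angle_in_arcs(theta, spec$domain_arc_bounds_deg)
    lipid[on_ld] <- lipid[on_ld] * spec$ld_lipid_gain
  }

  actin <- matrix(0, nx, ny)
  if (spec$actin_structure != "none" && spec$actin_thickness_um > 0) {
    thick <- .spec_thickness_profile(spec, theta)
    in_shell <- rho > r_mem & rho <= r_mem + thick
    actin[in_shell] <- spec$actin_intensity
    if (spec$actin_structure == "comet") {
      # tapered tail: angular half-width shrinking from 25 to 5 deg
      # between the membrane and the tail tip
      tail_len <- spec$comet_length_factor * r_mem
      frac <- pmin(pmax((rho - r_mem) / tail_len, 0), 1)
      half_w <- 25 - 20 * frac
      dang <- abs(((theta - spec$break_angle_deg + 180) %% 360) - 180)
      in_tail <- rho > r_mem & rho <= r_mem + tail_len & dang <= half_w
      actin[in_tail] <- spec$actin_intensity
    }
    if (spec$actin_on_ld_only && spec$n_domains > 0) {
      off_ld <- !angle_in_arcs(theta, spec$domain_arc_bounds_deg)
      actin[off_ld] <- 0
    }
  }

  if (spec$shot_noise || spec$gaussian_noise_sigma > 0) {
    if (!is.null(spec$seed)) {
      set.seed(as.integer((spec$seed + 7919 * frame_index) %% .Machine$integer.max))
    }
    if (spec$shot_noise) {
      lipid <- matrix(stats::rpois(length(lipid), lambda = lipid), nx, ny)
      actin <- matrix(stats::rpois(length(actin), lambda = actin), nx, ny)
    }
    lipid <- lipid + spec$background_level
    actin <- actin + spec$background_level
    if (spec$gaussian_noise_sigma > 0) {
      lipid <- lipid + matrix(
        stats::rnorm(length(lipid), 0, spec$gaussian_noise_sigma), nx, ny)
      actin <- actin + matrix(
        stats::rnorm(length(actin), 0, spec$gaussian_noise_sigma), nx, ny)
    }
    lipid[lipid < 0] <- 0
    actin[actin < 0] <- 0
  } else {
    lipid <- lipid + spec$background_level
    actin <- actin + spec$background_level
  }
  list(lipid = lipid, actin = actin)
}

#' Render a time lapse driven by a diffusion--coalescence simulation
#'
#' Takes the equatorial arc projection recorded in a simulation trace
#' (see [simulate_domains()]) and renders one frame per recorded sample
#' time, with the Ld arcs (and the actin on them) taken from the
#' simulated domain positions.  Arcs that overlap after projection are
#' merged (and a message is emitted), so the per-frame ground-truth
#' domain count equals the simulator's equatorial count.
#'
#' @param sim_trace A `sim_trace` from [simulate_domains()] run with
#'   `record_arcs = TRUE`.
#' @param spec Template [synth_spec()]; its diameter should match
#'   `2 * sim_trace$R_guv`.
#' @param times_min Optional subset of trace sample times to render
#'   (minutes); defaults to all recorded samples.
#' @return An [image_lapse()].
#' @export
lapse_from_simulation <- function(sim_trace, spec, times_min = NULL) {
  stopifnot(inherits(sim_trace, "sim_trace"))
  if (is.null(sim_trace$arcs)) {
    stop_validation("sim_trace has no recorded arcs; rerun with record_arcs = TRUE")
  }
  tr_min <- sim_trace$times_s / 60
  if (is.null(times_min)) {
    times_min <- tr_min
    idx <- seq_along(tr_min)
  } else {
    idx <- vapply(times_min, function(t) which.min(abs(tr_min - t)), 1L)
  }
  frames <- vector("list", length(idx))
  truth <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    arcs <- sim_trace$arcs[[idx[k]]]
    arcs <- merge_wrapped_arcs(arcs)
    sp <- spec
    sp$n_domains <- if (is.null(arcs)) 0L else nrow(arcs)
    sp$domain_arc_bounds_deg <- arcs
    sp$actin_on_ld_only <- TRUE
    frames[[k]] <- .render_channels(sp, frame_index = k)
    truth[[k]] <- sp
  }
  image_lapse(frames, times_min, spec$pixel_size_um, ground_truth = truth)
}

#' Merge overlapping angular arcs modulo 360 degrees
#'
#' @param arcs 2-column matrix of `[start, end)` intervals in degrees
#'   (end may exceed 360 for wrapped arcs), or `NULL`.
#' @param quiet Suppress the message emitted when arcs are merged.
#' @return A 2-column matrix of disjoint arcs, or `NULL`.
#' @export
merge_wrapped_arcs <- function(arcs, quiet = FALSE) {
  if (is.null(arcs) || nrow(arcs) == 0L) return(NULL)
  w <- arcs[, 2] - arcs[, 1]
  if (any(w <= 0)) stop_validation("arcs must have positive width")
  if (sum(w) >= 360) {
    if (!quiet) message("arcs cover the full circle; merged into one")
    return(matrix(c(0, 360), ncol = 2))
  }
  s <- arcs[, 1] %% 360
  e <- s + w
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]
  out <- NULL
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) {
      me <- max(me, e[i])
    } else {
      out <- rbind(out, c(ms, me))
      ms <- s[i]; me <- e[i]
    }
  }
  out <- rbind(out, c(ms, me))
  # wrap: last arc may reach past 360 into the first
  if (nrow(out) > 1L && out[nrow(out), 2] >= 360 &&
      (out[nrow(out), 2] - 360) >= out[1, 1]) {
    out[1, 1] <- out[nrow(out), 1] - 360
    out[1, 2] <- max(out[1, 2], out[nrow(out), 2] - 360)
    out <- out[-nrow(out), , drop = FALSE]
    out[1, ] <- out[1, ] + 360
  }
  if (nrow(out) < nrow(arcs) && !quiet) {
    message(sprintf("merged %d overlapping arc(s)", nrow(arcs) - nrow(out)))
  }
  out
}

#' Synthesize a cohort of GUVs with actin structures
#'
#' Builds a population of homogeneous GUVs emulating the observed
#' structure-vs-size statistics: diameters uniform on the microtrap
#' selection band (10--60 um), symmetric shells below the 5--10 um
#' symmetry-breaking thickness band, and beyond it comets on small GUVs
#' (< 20 um) and asymmetric shells on larger ones.
#'
#' @param n Number of GUVs.
#' @param seed Integer seed.
#' @param pixel_size_um Pixel size for the rendered frames.
#' @param diameter_range_um Sampling range of GUV diameters.
#' @return A list with `specs` (list of [synth_spec()]) and `truth`
#'   (data.frame of diameter, thickness, structure class).
#' @export
synth_structure_cohort <- function(n = 12, seed = 1, pixel_size_um = 0.3,
                                   diameter_range_um = c(10, 60)) {
  set.seed(seed)
  d <- stats::runif(n, diameter_range_um[1], diameter_range_um[2])
  breaking <- stats::runif(n, 5, 10)   # symmetry-breaking onset band
  thick <- stats::runif(n, 1.5, 12)
  cls <- ifelse(thick < breaking, "symmetric_shell",
                ifelse(d < 20, "comet", "asymmetric_shell"))
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    specs[[i]] <- synth_spec(
      guv_diameter_um = d[i], pixel_size_um = pixel_size_um,
      actin_structure = cls[i],
      actin_thickness_um = if (cls[i] == "comet") 1 else thick[i],
      break_angle_deg = stats::runif(1, 0, 360),
      seed = seed + i
    )
  }
  list(specs = specs,
       truth = data.frame(guv_diameter_um = d, actin_thickness_um = thick,
                          structure_class = cls))
}
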