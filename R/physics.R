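# Physical model of lipid-domain coarsening on a GUV and its blocking
# by an actin corona: Saffman-Delbruck mobility of membrane domains,
# nearest-neighbor contact time, corona overhang growth, the mesh-size
# blocking criterion, and a stochastic diffusion-coalescence simulator
# on the sphere surface.

#' Physical parameters of the domain-coalescence model
#'
#' Defaults describe a liquid-disordered (Ld) domain diffusing in a
#' liquid-ordered (Lo) membrane in water at room temperature, with a
#' branched actin network growing on the domain.
#'
#' @param kBT Thermal energy, J (default 4.1e-21, ~298 K).
#' @param eta_m Membrane surface viscosity, Pa m s (default 1e-8, Lo
#'   membranes).
#' @param eta_f Bulk fluid viscosity, Pa s (default 1e-3, water).
#' @param xi_mesh Actin network mesh size, m (default 100e-9).
#' @param v_gel Lateral actin gel growth rate, m/s (default 2.5e-9,
#'   i.e. 0.15 um/min).
#' @param R_spacing Typical inter-domain distance, m (default 5e-6).
#' @param f_spvca Diffusion-slowing factor applied when the
#'   nucleation-promoting factor alone is bound to the domains (< 1;
#'   default 0.3).  This factor is a model assumption, not a measured
#'   quantity.
#' @return Object of class `physical_params`.
#' @export
physical_params <- function(kBT = 4.1e-21, eta_m = 1e-8, eta_f = 1e-3,
                            xi_mesh = 100e-9, v_gel = 2.5e-9,
                            R_spacing = 5e-6, f_spvca = 0.3) {
  vals <- c(kBT = kBT, eta_m = eta_m, eta_f = eta_f, xi_mesh = xi_mesh,
            v_gel = v_gel, R_spacing = R_spacing, f_spvca = f_spvca)
  if (any(vals <= 0)) stop_validation("all physical parameters must be > 0")
  structure(as.list(vals), class = "physical_params")
}

#' Saffman-Delbruck diffusion coefficient of a membrane inclusion
#'
#' D = kBT / (4 pi eta_m) * ln(eta_m / (eta_f r)).  Valid for inclusion
#' radii below the Saffman-Delbruck length eta_m / eta_f (10 um with the
#' defaults); at the length itself D = 0, beyond it the model does not
#' apply and an error is raised.
#'
#' @param r Domain radius in meters (vectorized).
#' @param params A [physical_params()].
#' @return Diffusion coefficient(s) in m^2/s.
#' @export
saffman_delbruck_D <- function(r, params = physical_params()) {
  if (any(r <= 0)) stop_validation("radius must be > 0")
  l_sd <- params$eta_m / params$eta_f
  if (any(r > l_sd)) {
    stop_validation(sprintf(
      "radius exceeds the Saffman-Delbruck length %.3g m; outside the model's validity", l_sd))
  }
  params$kBT / (4 * pi * params$eta_m) * log(l_sd / r)
}

#' Nearest-neighbor contact time of a diffusing domain
#'
#' tau = R^2 / (4 D): the time for a domain exploring a patch of linear
#' size R by 2D diffusion to reach its nearest neighbor.
#'
#' @param R Typical inter-domain distance, m.
#' @param D Diffusion coefficient, m^2/s.
#' @return Time in seconds.
#' @export
contact_time <- function(R, D) {
  if (any(R <= 0) || any(D <= 0)) stop_validation("R and D must be > 0")
  R^2 / (4 * D)
}

#' Lateral overhang of the actin corona
#'
#' The actin gel on a domain grows laterally at `v_gel`, so after time t
#' it overhangs the domain edge by `v_gel * t`.
#'
#' @param v_gel Gel growth rate, m/s.
#' @param t Time in seconds (>= 0).
#' @return Overhang length in meters.
#' @export
corona_overhang <- function(v_gel, t) {
  if (any(t < 0)) stop_validation("t must be >= 0")
  if (any(v_gel < 0)) stop_validation("v_gel must be >= 0")
  v_gel * t
}

#' Is domain coalescence sterically blocked by the corona?
#'
#' Blocking occurs when the corona overhang strictly exceeds the actin
#' mesh size: a softer, thinner fringe (overhang <= xi_mesh) can be
#' penetrated and does not prevent membrane contact.
#'
#' @param overhang Corona overhang, m (>= 0).
#' @param params A [physical_params()].
#' @return Logical (vectorized over `overhang`).
#' @export
is_coalescence_blocked <- function(overhang, params = physical_params()) {
  if (any(overhang < 0)) stop_validation("overhang must be >= 0")
  overhang > params$xi_mesh
}

#' Stochastic diffusion-coalescence simulation of lipid domains
#'
#' Simulates `n0` circular Ld domains performing Brownian motion on the
#' surface of a sphere of radius `R_guv`, each with its own
#' Saffman-Delbruck diffusion coefficient D(r_i).  Two domains coalesce
#' when their geodesic center distance drops below the sum of their
#' radii; the merged domain conserves area (r = sqrt(r_i^2 + r_j^2)) and
#' sits at the area-weighted centroid.  Modes:
#'
#' * `"bare"`: free coalescence.
#' * `"spvca"`: D multiplied by `f_spvca` (< 1), modelling diffusion
#'   slowing by membrane-bound nucleation-promoting factor.
#' * `"actin"`: an actin corona nucleates on each domain at t = 0 and
#'   grows laterally at `v_gel`; once its overhang exceeds the mesh size
#'   `xi_mesh` (on either contact partner) coalescence is sterically
#'   blocked, reproducing slight early coalescence followed by a
#'   plateau.
#'
#' The fully coarsened 2-domain state is absorbing in every mode: with
#' only two macroscopic phase patches left the system is treated as
#' completely coalesced and no further merging is attempted.
#'
#' Counts are recorded both for the whole sphere (`n_total`) and for the
#' equatorial focal band (`n_equatorial`: domains intersecting the
#' equator circle), which is what single-plane imaging sees.
#'
#' @param n0 Initial domain count (>= 2).
#' @param R_guv GUV radius in meters.
#' @param params A [physical_params()].
#' @param mode `"bare"`, `"spvca"` or `"actin"`.
#' @param t_end Simulated time, s.
#' @param dt Time step, s (default 0.05).  An error is raised when the
#'   RMS Brownian step exceeds the smallest domain radius.
#' @param seed Integer RNG seed.
#' @param r0 Initial domain radius (m, default 1e-6) or a vector of
#'   length `n0`.
#' @param sample_times Times at which to record counts (default ~121
#'   evenly spaced samples including 0 and `t_end`).
#' @param record_arcs Record the equatorial arc projection per sample
#'   (needed by [lapse_from_simulation()]).
#' @return Object of class `sim_trace`: `times_s`, `n_total`,
#'   `n_equatorial`, `events` (data.frame of merges), `arcs`
#'   (optional), the final domain state, `area_initial`, `area_final`,
#'   and the run configuration.
#' @export
simulate_domains <- function(n0, R_guv, params = physical_params(),
                             mode = c("bare", "spvca", "actin"),
                             t_end = 3600, dt = 0.05, seed = NULL,
                             r0 = 1e-6, sample_times = NULL,
                             record_arcs = FALSE) {
  mode <- match.arg(mode)
  if (n0 < 2L) stop_validation("n0 must be >= 2")
  if (R_guv <= 0 || t_end <= 0 || dt <= 0) {
    stop_validation("R_guv, t_end and dt must be > 0")
  }
  r <- rep_len(r0, n0)
  d_max <- max(saffman_delbruck_D(r, params)) *
    (if (mode == "spvca") params$f_spvca else 1)
  if (sqrt(4 * d_max * dt) > min(r)) {
    stop_validation(paste0(
      "dt too large: RMS Brownian step exceeds the smallest domain radius; ",
      "use a smaller dt"))
  }
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  if (is.null(sample_times)) {
    sample_times <- seq(0, t_end, length.out = 121)
  }
  sample_times <- sort(unique(pmin(sample_times, t_end)))

  pos <- .place_on_sphere(n0, r / R_guv)
  area0 <- sum(pi * r^2)

  n_steps <- ceiling(t_end / dt)
  events <- list()
  rec_t <- numeric(0); rec_total <- integer(0); rec_eq <- integer(0)
  arcs <- if (record_arcs) list() else NULL
  next_sample <- 1L
  t <- 0

  record <- function(t) {
    lat <- asin(pmin(pmax(pos[, 3], -1), 1))
    eq <- abs(lat) <= r / R_guv
    rec_t <<- c(rec_t, t)
    rec_total <<- c(rec_total, nrow(pos))
    rec_eq <<- c(rec_eq, sum(eq))
    if (record_arcs) {
      arcs[length(arcs) + 1L] <<- list(.equatorial_arcs(pos, r, R_guv))
    }
  }

  for (step in 0:n_steps) {
    # record any sample times reached
    while (next_sample <= length(sample_times) &&
           t >= sample_times[next_sample] - dt / 2) {
      record(sample_times[next_sample])
      next_sample <- next_sample + 1L
    }
    if (step == n_steps) break
    n <- nrow(pos)
    # Brownian step on the sphere (Euler-Maruyama in the tangent plane,
    # then projected back by moving along the great circle)
    D <- saffman_delbruck_D(r, params)
    if (mode == "spvca") D <- D * params$f_spvca
    sig <- sqrt(2 * D * dt) / R_guv        # angular step scale
    e1 <- .tangent_basis(pos)
    g1 <- stats::rnorm(n, 0, sig)
    g2 <- stats::rnorm(n, 0, sig)
    disp <- e1$u * g1 + e1$v * g2
    alpha <- sqrt(rowSums(disp^2))
    ok <- alpha > 0
    if (any(ok)) {
      dir <- disp[ok, , drop = FALSE] / alpha[ok]
      pos[ok, ] <- pos[ok, , drop = FALSE] * cos(alpha[ok]) +
        dir * sin(alpha[ok])
      pos <- pos / sqrt(rowSums(pos^2))
    }
    t <- t + dt
    # coalescence (2-domain state absorbing)
    if (nrow(pos) > 2L) {
      blocked <- mode == "actin" &&
        is_coalescence_blocked(corona_overhang(params$v_gel, t), params)
      if (!blocked) {
        res <- .merge_contacts(pos, r, R_guv, t, events)
        pos <- res$pos; r <- res$r; events <- res$events
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(time_s = numeric(0), i = integer(0), j = integer(0),
               r_new = numeric(0), n_after = integer(0))
  structure(
    list(times_s = rec_t, n_total = rec_total, n_equatorial = rec_eq,
         events = events, arcs = arcs,
         positions = pos, radii = r, R_guv = R_guv,
         corona_radii = if (mode == "actin")
           r + corona_overhang(params$v_gel, t_end) else r,
         area_initial = area0, area_final = sum(pi * r^2),
         n0 = n0, mode = mode, seed = seed, dt = dt, t_end = t_end,
         params = params),
    class = "sim_trace"
  )
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf(
    "sim_trace (%s): n0 = %d -> %d domains after %g s (%d merges)\n",
    x$mode, x$n0, length(x$radii), x$t_end, nrow(x$events)))
  invisible(x)
}

# Uniform non-overlapping placement of spherical caps (angular radii
# `ang`) on the unit sphere.
#' @noRd
.place_on_sphere <- function(n, ang) {
  pos <- matrix(NA_real_, n, 3)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 20000L) {
      stop_validation("cannot place domains without overlap; sphere too crowded")
    }
    z <- stats::runif(1, -1, 1)
    phi <- stats::runif(1, 0, 2 * pi)
    p <- c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
    if (placed > 0L) {
      d <- acos(pmin(pmax(pos[seq_len(placed), , drop = FALSE] %*% p, -1), 1))
      if (any(d < ang[placed + 1L] + ang[seq_len(placed)])) next
    }
    placed <- placed + 1L
    pos[placed, ] <- p
  }
  pos
}

# Orthonormal tangent basis at each row of a unit-vector matrix.
#' @noRd
.tangent_basis <- function(pos) {
  ref <- matrix(rep(c(0, 0, 1), each = nrow(pos)), ncol = 3)
  near_pole <- abs(pos[, 3]) > 0.9
  ref[near_pole, ] <- matrix(rep(c(1, 0, 0), each = sum(near_pole)), ncol = 3)
  u <- cbind(ref[, 2] * pos[, 3] - ref[, 3] * pos[, 2],
             ref[, 3] * pos[, 1] - ref[, 1] * pos[, 3],
             ref[, 1] * pos[, 2] - ref[, 2] * pos[, 1])
  u <- u / sqrt(rowSums(u^2))
  v <- cbind(pos[, 2] * u[, 3] - pos[, 3] * u[, 2],
             pos[, 3] * u[, 1] - pos[, 1] * u[, 3],
             pos[, 1] * u[, 2] - pos[, 2] * u[, 1])
  list(u = u, v = v)
}

# Merge all contacting pairs (closest first), conserving area; stops
# merging at the absorbing 2-domain state.
#' @noRd
.merge_contacts <- function(pos, r, R_guv, t, events) {
  repeat {
    n <- nrow(pos)
    if (n <= 2L) break
    cosd <- pmin(pmax(tcrossprod(pos), -1), 1)
    gd <- R_guv * acos(cosd)
    sumr <- outer(r, r, "+")
    diag(gd) <- Inf
    touching <- which(gd <= sumr, arr.ind = TRUE)
    if (nrow(touching) == 0L) break
    touching <- touching[touching[, 1] < touching[, 2], , drop = FALSE]
    if (nrow(touching) == 0L) break
    sep <- gd[touching] - sumr[touching]
    k <- which.min(sep)
    i <- touching[k, 1]; j <- touching[k, 2]
    wi <- r[i]^2; wj <- r[j]^2
    newp <- wi * pos[i, ] + wj * pos[j, ]
    newp <- newp / sqrt(sum(newp^2))
    newr <- sqrt(r[i]^2 + r[j]^2)
    keep <- setdiff(seq_len(n), c(i, j))
    pos <- rbind(pos[keep, , drop = FALSE], newp)
    r <- c(r[keep], newr)
    events[[length(events) + 1L]] <- data.frame(
      time_s = t, i = i, j = j, r_new = newr, n_after = n - 1L)
  }
  list(pos = pos, r = r, events = events)
}

# Longitude arcs (deg) where domains cross the equator circle.
#' @noRd
.equatorial_arcs <- function(pos, r, R_guv) {
  lat <- asin(pmin(pmax(pos[, 3], -1), 1))
  ang_r <- r / R_guv
  hit <- abs(lat) < ang_r
  if (!any(hit)) return(NULL)
  lon <- (atan2(pos[hit, 2], pos[hit, 1]) * 180 / pi) %% 360
  # half-width in longitude of the cap's intersection with the equator:
  # cos(angular radius) = cos(lat) cos(dlon)
  cl <- cos(lat[hit])
  arg <- pmin(pmax(cos(ang_r[hit]) / cl, -1), 1)
  hw <- acos(arg) * 180 / pi
  hw <- pmax(hw, 0.5)   # keep even grazing domains visible at 1 deg sampling
  cbind(lon - hw, lon + hw)
}

#' First-contact times of a tagged domain
#'
#' Runs independent bare-mode simulations and records, for the first
#' domain placed in each run, the time of its first contact (merge
#' event) with any neighbor.  Used to confront the simulator with the
#' analytic contact-time estimate tau = R^2 / (4 D).
#'
#' @param n_rep Number of replicates.
#' @param n0,R_guv,params,dt,t_end,r0 Passed to [simulate_domains()].
#' @param seed Base seed; replicate k uses `seed + k`.
#' @return Numeric vector of first-contact times (s; `NA` when the
#'   tagged domain never merged within `t_end`).
#' @export
first_contact_times <- function(n_rep = 100, n0 = 34, R_guv = 14.6e-6,
                                params = physical_params(), dt = 0.05,
                                t_end = 600, r0 = 1e-6, seed = 1) {
  vapply(seq_len(n_rep), function(k) {
    tr <- simulate_domains(n0, R_guv, params, mode = "bare", t_end = t_end,
                           dt = dt, seed = seed + k, r0 = r0,
                           sample_times = c(0, t_end))
    ev <- tr$events
    # track index 1 through re-indexing: a merge removes domains i < j
    # and appends the merged one at the end
    idx <- 1L
    n <- n0
    for (row in seq_len(nrow(ev))) {
      i <- ev$i[row]; j <- ev$j[row]
      if (idx == i || idx == j) return(ev$time_s[row])
      shift <- sum(c(i, j) < idx)
      idx <- idx - shift
      n <- n - 1L
    }
    NA_real_
  }, 1.0)
}
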