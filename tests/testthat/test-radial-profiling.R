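test_that("estimate_center matches analytic and shoelace-oracle centroids", {
  expect_equal(estimate_center(circle_contour(center = c(60, 60))),
               c(60, 60), tolerance = 1e-6)
  expect_equal(estimate_center(ellipse_contour(50, 25, center = c(80, 70))),
               c(80, 70), tolerance = 1e-6)
  # arbitrary polygon vs an independent shoelace implementation
  set.seed(7)
  pts <- cbind(runif(12, 0, 60), runif(12, 0, 60))
  hull <- pts[grDevices::chull(pts), ]
  x <- hull[, 1]; y <- hull[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  a <- sum(x * yn - xn * y) / 2
  oracle <- c(sum((x + xn) * (x * yn - xn * y)) / (6 * a),
              sum((y + yn) * (x * yn - xn * y)) / (6 * a))
  expect_equal(estimate_center(guv_contour(hull, 0.2)), oracle,
               tolerance = 1e-9)
})

test_that("background estimation is exact without noise and tight with it", {
  lp <- render_guv_frame(quick_spec())
  ct <- segment_guv_contour(lp, pixel_size_um = 0.2)
  bg <- estimate_background(lp$frames[[1]], ct)
  expect_equal(unname(bg$background["lipid"]), 10)
  expect_equal(unname(bg$background["actin"]), 10)
  # gaussian noise sigma = 2 around 10, >= 1e4 background pixels
  lpn <- render_guv_frame(quick_spec(gaussian_noise_sigma = 2, seed = 31))
  bgn <- estimate_background(lpn$frames[[1]], ct)
  expect_gt(bgn$n_pixels, 1e4)
  expect_lt(abs(bgn$background["lipid"] - 10), 0.5)
  # frame too tight -> error
  tight <- list(lipid = lp$frames[[1]]$lipid[60:120, 60:120],
                actin = lp$frames[[1]]$actin[60:120, 60:120])
  small_ct <- circle_contour(r_px = 50, center = c(30, 30))
  expect_error(estimate_background(tight, small_ct),
               class = "guvactin_validation_error")
})

test_that("per-degree peak means match the analytic Gaussian half-max integral", {
  # ideal ring amplitude A over background B: the half-max run of a
  # Gaussian ridge averages ~0.81 A (analytic: erf-weighted mean over
  # +/- sqrt(2 ln 2) sigma)
  A <- 90
  lp <- render_guv_frame(quick_spec(membrane_intensity = A))
  ct <- segment_guv_contour(lp, pixel_size_um = 0.2)
  prof <- radial_profiles(lp$frames[[1]], contour = ct)
  s <- sqrt(2 * log(2))
  analytic <- A * (stats::pnorm(s) - stats::pnorm(-s)) * sqrt(2 * pi) / (2 * s)
  expect_lt(max(abs(prof$lipid_peak_mean - analytic)) / analytic, 0.05)
  # blank channel stays all-zero
  expect_true(all(prof$actin_peak_mean == 0))
})

test_that("Ld arcs appear in the lipid profile at the programmed gain", {
  fr <- render1(guv_diameter_um = 30, n_domains = 1,
                domain_arc_bounds_deg = cbind(30, 60), ld_lipid_gain = 3)
  ct <- segment_guv_contour(fr, pixel_size_um = 0.2)
  prof <- radial_profiles(fr, contour = ct)
  inside <- prof$lipid_peak_mean[prof$angles_deg >= 33 & prof$angles_deg <= 57]
  outside <- prof$lipid_peak_mean[prof$angles_deg >= 90 & prof$angles_deg <= 350]
  expect_lt(abs(mean(inside) / mean(outside) - 3) / 3, 0.05)
})

test_that("normalization scales each channel to max 1 and is scale invariant", {
  p <- manual_profiles(lipid = c(1, 4, 2, 8), actin = c(0, 2, 1, 1))
  n1 <- normalize_profiles(p)
  expect_equal(max(n1$lipid_norm), 1)
  expect_equal(max(n1$actin_norm), 1)
  p2 <- p
  p2$lipid_peak_mean <- p$lipid_peak_mean * 7
  n2 <- normalize_profiles(p2)
  expect_equal(n2$lipid_norm, n1$lipid_norm)
  # all-zero channel stays zero and is flagged
  p3 <- manual_profiles(lipid = c(1, 2), actin = c(0, 0))
  n3 <- normalize_profiles(p3)
  expect_true(all(n3$actin_norm == 0))
  expect_identical(n3$zero_channels, "actin")
  p4 <- manual_profiles(lipid = c(-1, 2))
  expect_error(normalize_profiles(p4), class = "guvactin_validation_error")
})

test_that("domain calling applies the strict 0.2 threshold with wrap merging and width filter", {
  # a lipid-free profile has nothing above threshold
  p <- normalize_profiles(manual_profiles(rep(0, 360)))
  expect_identical(segment_ld_domains(p, min_width_deg = 0)$n_d, 0L)
  # arcs [10,40) and [350,360) U [0,5): wrap counted once
  v2 <- rep(0.05, 360)
  v2[11:40] <- 1
  v2[c(351:360, 1:5)] <- 0.9
  p2 <- normalize_profiles(manual_profiles(v2))
  d2 <- segment_ld_domains(p2, min_width_deg = 0)
  expect_identical(d2$n_d, 2L)
  widths <- d2$intervals_deg[, 2] - d2$intervals_deg[, 1]
  expect_setequal(widths, c(30, 15))
  # exactly 0.2 is NOT a domain (strict inequality)
  v3 <- rep(0.2, 360); v3[100:110] <- 1
  p3 <- normalize_profiles(manual_profiles(v3))
  expect_identical(segment_ld_domains(p3, min_width_deg = 0)$n_d, 1L)
  # min-width filter removes a 2-degree speck
  v4 <- rep(0.05, 360); v4[50:51] <- 1; v4[180:240] <- 0.8
  p4 <- normalize_profiles(manual_profiles(v4))
  expect_identical(segment_ld_domains(p4, min_width_deg = 5)$n_d, 1L)
  expect_identical(segment_ld_domains(p4, min_width_deg = 0)$n_d, 2L)
})

test_that("domain count round-trips over a sweep of rendered domain numbers", {
  for (nd in c(2, 5, 12, 24)) {
    fr <- render1(guv_diameter_um = 40, n_domains = nd,
                  actin_structure = "symmetric_shell",
                  actin_thickness_um = 2)
    ct <- segment_guv_contour(fr, pixel_size_um = 0.2)
    prof <- normalize_profiles(radial_profiles(fr, contour = ct))
    dom <- segment_ld_domains(prof, pixel_size_um = 0.2)
    expect_identical(dom$n_d, as.integer(nd))
  }
})

test_that("Fig-style two-domain render crosses 0.2 exactly on the generated arcs", {
  arcs <- cbind(c(20, 200), c(110, 290))
  fr <- render1(guv_diameter_um = 30, n_domains = 2,
                domain_arc_bounds_deg = arcs)
  ct <- segment_guv_contour(fr, pixel_size_um = 0.2)
  prof <- normalize_profiles(radial_profiles(fr, contour = ct))
  dom <- segment_ld_domains(prof, pixel_size_um = 0.2)
  expect_identical(dom$n_d, 2L)
  got <- dom$intervals_deg[order(dom$intervals_deg[, 1]), ]
  expect_true(all(abs(got - arcs) <= 2))
})

test_that("actin_on_ld follows its closed forms and rewards colocalization", {
  v <- rep(0.05, 360); v[1:60] <- 1
  p <- normalize_profiles(manual_profiles(v, actin = rep(0.5, 360)))
  d <- segment_ld_domains(p, min_width_deg = 0)
  expect_equal(actin_on_ld(p, d), 1.0)     # constant actin on the domain
  # no domains -> 0
  p0 <- normalize_profiles(manual_profiles(rep(0, 360)))
  d0 <- segment_ld_domains(p0, min_width_deg = 0)
  expect_identical(actin_on_ld(p0, d0), 0)
  # half the domain angles at actin 1, half at 0 -> 0.5
  act <- rep(0, 360); act[1:30] <- 1
  ph <- normalize_profiles(manual_profiles(v, actin = act))
  dh <- segment_ld_domains(ph, min_width_deg = 0)
  expect_equal(actin_on_ld(ph, dh), 0.5)
  # colocalized (dense) actin scores higher than the same total actin
  # spread uniformly around the ring: photon noise on the dim uniform
  # network inflates its within-domain maximum relative to its mean
  fr_loc <- render1(guv_diameter_um = 30, n_domains = 2,
                    actin_structure = "symmetric_shell",
                    actin_thickness_um = 2, actin_on_ld_only = TRUE,
                    shot_noise = TRUE, seed = 77)
  fr_uni <- render1(guv_diameter_um = 30, n_domains = 2,
                    actin_structure = "symmetric_shell",
                    actin_thickness_um = 2, actin_on_ld_only = FALSE,
                    actin_intensity = 80 * 0.25,  # same total over 4x angles
                    shot_noise = TRUE, seed = 77)
  score <- function(fr) {
    ct <- segment_guv_contour(fr, pixel_size_um = 0.2)
    p <- normalize_profiles(radial_profiles(fr, contour = ct))
    actin_on_ld(p, segment_ld_domains(p, pixel_size_um = 0.2))
  }
  expect_gt(score(fr_loc), score(fr_uni))
})

test_that("profile pipeline is invariant under global channel scaling", {
  fr <- render1(guv_diameter_um = 30, n_domains = 4, background_level = 0)
  fr2 <- list(lipid = fr$lipid * 5, actin = fr$actin)
  ct <- segment_guv_contour(fr, pixel_size_um = 0.2)
  p1 <- normalize_profiles(radial_profiles(fr, contour = ct))
  p2 <- normalize_profiles(radial_profiles(fr2, contour = ct))
  expect_equal(p1$lipid_norm, p2$lipid_norm, tolerance = 1e-8)
})
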