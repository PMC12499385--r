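test_that("segmentation recovers the membrane circle area and diameter", {
  lp <- render_guv_frame(quick_spec())
  ct <- segment_guv_contour(lp, pixel_size_um = 0.2)
  expect_lt(abs(ct$area_px2 - pi * 50^2) / (pi * 50^2), 0.03)
  expect_lt(abs(guv_diameter(ct) - 20) / 20, 0.02)
})

test_that("a blank frame is a segmentation failure", {
  blank <- list(lipid = matrix(5, 64, 64), actin = matrix(5, 64, 64))
  expect_error(segment_guv_contour(blank, pixel_size_um = 0.2),
               class = "guvactin_segmentation_error")
})

test_that("with two GUVs the seed point selects the enclosing contour", {
  # paste two renders side by side
  a <- render1(guv_diameter_um = 12, image_shape = c(101, 101))
  b <- render1(guv_diameter_um = 16, image_shape = c(101, 101))
  fr <- list(lipid = rbind(a$lipid, b$lipid) ,
             actin = rbind(a$actin, b$actin))
  ct1 <- segment_guv_contour(fr, seed_point = c(50, 50), pixel_size_um = 0.2)
  ct2 <- segment_guv_contour(fr, seed_point = c(151, 50), pixel_size_um = 0.2)
  expect_lt(max(ct1$vertices[, 1]), 101)
  expect_gt(min(ct2$vertices[, 1]), 100)
  expect_lt(abs(guv_diameter(ct1) - 12), 0.5)
  expect_lt(abs(guv_diameter(ct2) - 16), 0.5)
  # seed point on background is an error
  expect_error(segment_guv_contour(fr, seed_point = c(100, 5),
                                   pixel_size_um = 0.2),
               class = "guvactin_segmentation_error")
})

test_that("guv_diameter follows 2*sqrt(A/pi) and rejects zero area", {
  ct <- circle_contour()               # r = 50 px at 0.2 um/px
  ct$area_px2 <- 100 * pi / 0.2^2      # area 100*pi um^2
  expect_equal(guv_diameter(ct), 20)
  # pixel-count oracle on a rasterized disk
  m <- matrix(0, 121, 121)
  for (i in 1:121) for (j in 1:121) {
    if ((i - 61)^2 + (j - 61)^2 <= 50^2) m[i, j] <- 1
  }
  ct2 <- circle_contour()
  ct2$area_px2 <- sum(m)
  expect_lt(abs(guv_diameter(ct2) - 20) / 20, 0.02)
  expect_error(guv_contour(circle_contour()$vertices, 0.2, area_px2 = 0),
               class = "guvactin_validation_error")
})

test_that("ellipticity is 100% for a circle and 50% for a 2:1 ellipse", {
  el <- ellipticity(circle_contour())
  expect_equal(el$ellipticity_pct, 100, tolerance = 1e-3)
  # semi-axes 10 and 5 um = 50 and 25 px at 0.2 um/px
  el2 <- ellipticity(ellipse_contour(50, 25))
  expect_equal(el2$max_feret_um, 20, tolerance = 1e-3)
  expect_equal(el2$l_max_perp_um, 10, tolerance = 1e-3)
  expect_equal(el2$ellipticity_pct, 50, tolerance = 0.1)
})


test_that("ellipticity matches a brute-force oracle on random convex polygons", {
  set.seed(42)
  for (rep in 1:5) {
    pts <- cbind(runif(30, -40, 40), runif(30, -25, 25))
    hull <- pts[grDevices::chull(pts), ]
    ct <- guv_contour(hull, pixel_size_um = 0.2)
    el <- ellipticity(ct)
    bf <- brute_force_ellipticity(hull * 0.2)
    expect_equal(el$max_feret_um, bf$max_feret, tolerance = 1e-6)
    expect_equal(el$l_max_perp_um, bf$l_max_perp, tolerance = 0.01)
  }
})

test_that("ellipticity is invariant to rotation and translation", {
  base <- ellipticity(ellipse_contour(50, 30))$ellipticity_pct
  for (rot in c(17, 63.3, 118)) {
    rotated <- ellipticity(ellipse_contour(50, 30, rot_deg = rot,
                                           center = c(33, -12)))
    expect_lt(abs(rotated$ellipticity_pct - base) / base, 0.01)
  }
  expect_error(ellipticity(guv_contour(cbind(1:5, 2 * (1:5) + 1), 0.2,
                                       area_px2 = 1)),
               class = "guvactin_validation_error")
})

test_that("actin thickness and break angle round-trip through renders", {
  # symmetric shell, 5 um
  lp <- render_guv_frame(quick_spec(actin_structure = "symmetric_shell",
                                    actin_thickness_um = 5))
  ct <- segment_guv_contour(lp, pixel_size_um = 0.2)
  th <- actin_thickness(lp$frames[[1]], ct)
  expect_lt(abs(th$thickness_um - 5), 2 * 0.2 + 0.2)
  expect_false(th$flagged)
  # no actin: zero and flagged
  lp0 <- render_guv_frame(quick_spec(actin_structure = "none"))
  ct0 <- segment_guv_contour(lp0, pixel_size_um = 0.2)
  th0 <- actin_thickness(lp0$frames[[1]], ct0)
  expect_identical(th0$thickness_um, 0)
  expect_true(th0$flagged)
  expect_true(is.na(th0$break_angle_deg))
  # asymmetric shell: 8 um peak at 90 deg
  lpa <- render_guv_frame(quick_spec(actin_structure = "asymmetric_shell",
                                     actin_thickness_um = 8,
                                     break_angle_deg = 90))
  cta <- segment_guv_contour(lpa, pixel_size_um = 0.2)
  tha <- actin_thickness(lpa$frames[[1]], cta)
  expect_lt(abs(tha$thickness_um - 8), 2 * 0.2 + 0.2)
  expect_lt(min(abs(tha$break_angle_deg - 90),
                360 - abs(tha$break_angle_deg - 90)), 3)
})

test_that("structure classification round-trips and responds to a_sym monotonically", {
  cases <- list(
    list(spec = quick_spec(actin_structure = "symmetric_shell",
                           actin_thickness_um = 4), want = "symmetric_shell"),
    list(spec = quick_spec(actin_structure = "asymmetric_shell",
                           actin_thickness_um = 7, break_angle_deg = 220),
         want = "asymmetric_shell"),
    list(spec = quick_spec(guv_diameter_um = 16, actin_structure = "comet",
                           actin_thickness_um = 1, break_angle_deg = 40),
         want = "comet")
  )
  for (cs in cases) {
    lp <- render_guv_frame(cs$spec)
    ct <- segment_guv_contour(lp, pixel_size_um = 0.2)
    prof <- actin_radial_thickness(lp$frames[[1]], ct)
    expect_identical(
      classify_actin_structure(prof, guv_diameter(ct) / 2), cs$want)
  }
  # "none" class for bare GUVs
  lp0 <- render_guv_frame(quick_spec(actin_structure = "none"))
  ct0 <- segment_guv_contour(lp0, pixel_size_um = 0.2)
  prof0 <- actin_radial_thickness(lp0$frames[[1]], ct0)
  expect_identical(classify_actin_structure(prof0, 10), "none")
  # raising a_sym turns an asymmetric call symmetric, never the reverse
  lpa <- render_guv_frame(quick_spec(actin_structure = "asymmetric_shell",
                                     actin_thickness_um = 6,
                                     asym_min_frac = 0.6))
  cta <- segment_guv_contour(lpa, pixel_size_um = 0.2)
  pa <- actin_radial_thickness(lpa$frames[[1]], cta)
  calls <- vapply(c(0.1, 0.3, 0.5, 0.9),
                  function(a) classify_actin_structure(pa, 10, a_sym = a), "")
  sym <- calls == "symmetric_shell"
  expect_true(all(diff(as.integer(sym)) >= 0))
})

test_that("growth-rate fitting is exact on a line and robust on noisy lapses", {
  t <- seq(0, 60, by = 5)
  expect_equal(fit_growth_rate(t, 1 + 0.15 * t), 0.15)
  expect_error(fit_growth_rate(c(0, 10), c(1, 2)),
               class = "guvactin_validation_error")
  # noisy render at 0.2 um/min, 13 frames over 60 min
  sp <- quick_spec(pixel_size_um = 0.3, actin_structure = "symmetric_shell",
                   actin_thickness_um = 0.5, shot_noise = TRUE,
                   gaussian_noise_sigma = 1, seed = 99)
  lp <- suppressMessages(
    render_time_lapse(sp, seq(0, 60, length.out = 13), 0.2))
  th <- vapply(seq_along(lp$frames), function(k) {
    ct <- segment_guv_contour(lp$frames[[k]], pixel_size_um = 0.3)
    actin_thickness(lp$frames[[k]], ct)$thickness_um
  }, 1.0)
  fit <- fit_growth_rate(lp$times_min, th)
  expect_lt(abs(fit - 0.2) / 0.2, 0.1)
})

test_that("morphometry_record assembles all descriptors for one frame", {
  lp <- render_guv_frame(quick_spec(actin_structure = "symmetric_shell",
                                    actin_thickness_um = 3))
  rec <- morphometry_record(lp)
  expect_named(rec, c("d_guv_um", "max_feret_um", "l_max_perp_um",
                      "ellipticity_pct", "actin_thickness_um",
                      "break_angle_deg", "structure_class"))
  expect_lt(abs(rec$d_guv_um - 20) / 20, 0.02)
  expect_gt(rec$ellipticity_pct, 98)
  expect_identical(rec$structure_class, "symmetric_shell")
})
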