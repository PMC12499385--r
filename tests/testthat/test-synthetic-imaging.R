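test_that("noise-free render puts the lipid ridge on the membrane circle and leaves actin at background", {
  sp <- quick_spec(actin_structure = "none")
  lp <- render_guv_frame(sp)
  fr <- lp$frames[[1]]
  nx <- nrow(fr$lipid)
  cx <- (nx - 1) / 2
  i <- which(fr$lipid == max(fr$lipid), arr.ind = TRUE)
  r_px <- sqrt((i[, 1] - 1 - cx)^2 + (i[, 2] - 1 - cx)^2)
  expect_true(all(abs(r_px - 10 / 0.2) <= 1))
  expect_true(all(fr$actin == sp$background_level))
  # ground truth embedded
  expect_identical(lp$ground_truth[[1]]$guv_diameter_um, 20)
})

test_that("Ld arcs carry ld_lipid_gain times the Lo ring intensity", {
  arcs <- cbind(c(0, 90, 180, 270), c(30, 120, 210, 300))
  fr <- render1(guv_diameter_um = 30, n_domains = 4,
                domain_arc_bounds_deg = arcs, ld_lipid_gain = 3)
  nx <- nrow(fr$lipid)
  cx <- (nx - 1) / 2
  xm <- matrix(0:(nx - 1), nx, nx) - cx
  ym <- matrix(0:(nx - 1), nx, nx, byrow = TRUE) - cx
  rho <- sqrt(xm^2 + ym^2) * 0.2
  ang <- (atan2(-ym, xm) * 180 / pi) %% 360
  on_ring <- abs(rho - 15) < 0.1
  bg <- 10
  on_arc <- on_ring &
    ((ang %% 90) >= 1 & (ang %% 90) <= 29)   # 1 deg guard at arc edges
  off_arc <- on_ring & ((ang %% 90) >= 46 & (ang %% 90) <= 89)
  ratio <- mean(fr$lipid[on_arc] - bg) / mean(fr$lipid[off_arc] - bg)
  expect_lt(abs(ratio - 3) / 3, 0.05)
})

test_that("overlapping or invalid domain arcs are rejected", {
  expect_error(quick_spec(n_domains = 2,
                          domain_arc_bounds_deg = cbind(c(0, 20), c(30, 50))),
               class = "guvactin_validation_error")
  expect_error(quick_spec(n_domains = 2,
                          domain_arc_bounds_deg = cbind(c(350, 2), c(365, 10))),
               class = "guvactin_validation_error")
  # wrap-disjoint arcs are fine
  expect_silent(quick_spec(n_domains = 2,
                           domain_arc_bounds_deg = cbind(c(350, 20), c(365, 40))))
})

test_that("a GUV that cannot fit with a 2 um margin is a geometry error", {
  expect_error(synth_spec(guv_diameter_um = 30, image_shape = c(100, 100),
                          pixel_size_um = 0.2),
               class = "guvactin_geometry_error")
})

test_that("noisy renders are reproducible given the seed and differ without it", {
  a <- render1(shot_noise = TRUE, gaussian_noise_sigma = 2, seed = 5)
  b <- render1(shot_noise = TRUE, gaussian_noise_sigma = 2, seed = 5)
  c <- render1(shot_noise = TRUE, gaussian_noise_sigma = 2, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("integrated actin intensity is non-decreasing in shell thickness", {
  totals <- vapply(c(1, 2, 4, 6), function(th) {
    fr <- render1(actin_structure = "symmetric_shell", actin_thickness_um = th,
                  image_shape = c(181, 181))
    sum(fr$actin)
  }, 1.0)
  expect_true(all(diff(totals) >= 0))
})

test_that("zero growth rate renders identical frames over time", {
  sp <- quick_spec(actin_structure = "symmetric_shell", actin_thickness_um = 3)
  lp <- render_time_lapse(sp, times_min = c(0, 10, 20),
                          growth_rate_um_per_min = 0)
  expect_identical(lp$frames[[1]], lp$frames[[2]])
  expect_identical(lp$frames[[1]], lp$frames[[3]])
})

test_that("programmed growth is recorded in the ground truth (0.15 um/min over 30 min = 4.5 um)", {
  sp <- quick_spec(actin_structure = "symmetric_shell",
                   actin_thickness_um = 0)
  lp <- suppressMessages(
    render_time_lapse(sp, times_min = seq(0, 30, by = 5),
                      growth_rate_um_per_min = 0.15))
  final <- lp$ground_truth[[length(lp$ground_truth)]]$actin_thickness_um
  expect_equal(final, 4.5)
  # and the rendered final frame measures 4.5 um within 2 px
  ct <- segment_guv_contour(lp$frames[[7]], pixel_size_um = 0.2)
  th <- actin_thickness(lp$frames[[7]], ct)
  expect_lt(abs(th$thickness_um - 4.5), 2 * 0.2)
})

test_that("image lapse validates monotone times and equal shapes", {
  fr <- render1()
  expect_error(image_lapse(list(fr, fr), c(0, 0), 0.2),
               class = "guvactin_validation_error")
  fr2 <- list(lipid = fr$lipid[-1, , drop = FALSE],
              actin = fr$actin[-1, , drop = FALSE])
  expect_error(image_lapse(list(fr, fr2), c(0, 1), 0.2),
               class = "guvactin_validation_error")
})

test_that("structure cohort builds comets only beyond the breaking band on small GUVs", {
  coh <- synth_structure_cohort(n = 10, seed = 3)
  comets <- coh$truth$structure_class == "comet"
  if (any(comets)) {
    expect_true(all(coh$truth$guv_diameter_um[comets] < 20))
    expect_true(all(coh$truth$actin_thickness_um[comets] >= 5))
  }
  expect_true(all(coh$truth$structure_class[coh$truth$actin_thickness_um < 5]
                  == "symmetric_shell"))
})
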