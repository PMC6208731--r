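test_that("uniform image yields zero profiles with a warning", {
  img <- micrograph(matrix(0.8, 64, 64), pixel_size = 0.05)
  expect_warning(seg <- segment_profiles(img), "no foreground")
  expect_equal(seg$n_profiles, 0)
  mm <- measure_image(img)
  expect_equal(mm$n_profiles, 0)
  expect_equal(mm$density$fraction, 0)
})

test_that("disjoint rings are each segmented as one profile", {
  set.seed(21)
  p <- tissue_params(field_size = 20, target_areal_fraction = 0.15,
                     pixel_size = 0.02, seed = 21)
  pop <- sample_axon_population(p)
  img <- render_micrograph(pop, p)
  mm <- measure_image(img)
  # border exclusion may drop a few; all placed profiles are interior here
  expect_equal(mm$n_profiles, nrow(pop$axons))
})

test_that("regions below min_area are excluded", {
  px <- 0.05
  ell <- data.frame(x = c(2, 6), y = c(2, 2),
                    minor = c(0.2, 2), major = c(0.2, 2),
                    minor_inner = c(0.1, 1.2), major_inner = c(0.1, 1.2),
                    angle_deg = 0)
  p <- tissue_params(field_size = 8, pixel_size = px)
  img <- render_micrograph(ell, p)
  seg_all <- segment_profiles(img, segmentation_params(min_area = 0))
  expect_equal(seg_all$n_profiles, 2)
  seg_min <- segment_profiles(img,
                              segmentation_params(min_area = pi * 0.5^2))
  expect_equal(seg_min$n_profiles, 1)
})

test_that("measurement matches analytic ellipse values", {
  img <- single_ellipse_image(minor = 1.0, ar = 2, angle = 30, g = 0.6,
                              pixel = 0.02)
  m <- measure_image(img)$profiles
  expect_equal(nrow(m), 1)
  expect_equal(m$major_diameter, 2.0, tolerance = 0.02)
  expect_equal(m$outer_diameter, 1.0, tolerance = 0.02)
  expect_equal(m$inner_diameter, 0.6, tolerance = 0.02)
  expect_equal(m$ar, 2.0, tolerance = 0.05 / 2)
  expect_lt(abs(m$angle_deg - 30), 2)
})

test_that("circle with known myelin recovers inner diameter and thickness", {
  px <- 0.01
  ell <- data.frame(x = 1.5, y = 1.5, minor = 1, major = 1,
                    minor_inner = 0.6, major_inner = 0.6, angle_deg = 0)
  p <- tissue_params(field_size = 3, pixel_size = px)
  m <- measure_image(render_micrograph(ell, p))$profiles
  expect_equal(m$outer_diameter, 1.0, tolerance = 0.01)
  expect_equal(m$inner_diameter, 0.6, tolerance = 0.01)
  expect_equal(m$myelin_thickness, 0.2, tolerance = 0.02)
  expect_equal(m$g_ratio, 0.6, tolerance = 0.01)
})

test_that("moment-fit AR agrees with the caliper ratio on true ellipses", {
  set.seed(22)
  for (i in 1:10) {
    minor <- runif(1, 2, 4); ar <- runif(1, 1.2, 3)
    img <- single_ellipse_image(minor, ar, runif(1, 0, 180))
    m <- measure_image(img)$profiles
    caliper_ar <- m$major_diameter / m$minor_diameter
    expect_equal(m$ar, caliper_ar, tolerance = 0.02)
  }
})

test_that("collapsed lumens are flagged, kept, and count for density", {
  px <- 0.05
  ell <- data.frame(x = 2, y = 2, minor = 1, major = 1,
                    minor_inner = 0, major_inner = 0, angle_deg = 0)
  p <- tissue_params(field_size = 4, pixel_size = px)
  m <- measure_image(render_micrograph(ell, p))
  expect_true(m$profiles$collapsed_lumen)
  expect_equal(m$profiles$inner_diameter, 0)
  expect_gt(m$density$fraction, 0.04)
})

test_that("mask areal density matches the disk formula", {
  px <- 1
  mat <- matrix(0.85, 100, 100)
  ctr <- 50.5
  for (r in 1:100) for (cc in 1:100)
    if ((r - ctr)^2 + (cc - ctr)^2 <= 10^2) mat[r, cc] <- 0.15
  img <- micrograph(mat, pixel_size = px)
  seg <- segment_profiles(img, segmentation_params(
    border_policy = "include"))
  d <- areal_density(seg, field_area = 100 * 100)
  expect_equal(d$fraction, 0.0314, tolerance = 0.001 / 0.0314)
  expect_error(areal_density(seg, field_area = 0), "positive")
})

test_that("mask and profile-sum density variants agree on clean renders", {
  p <- tissue_preset("CTR-SWM", seed = 23)
  pop <- sample_axon_population(p)
  img <- render_micrograph(pop, p)
  mm <- measure_image(img)
  expect_lt(abs(mm$density$fraction - mm$density_profiles$fraction), 0.01)
})

test_that("measures are stable when pixel resolution doubles", {
  m1 <- measure_image(single_ellipse_image(2, 2, 40, pixel = 0.05))$profiles
  m2 <- measure_image(single_ellipse_image(2, 2, 40, pixel = 0.025))$profiles
  for (colm in c("major_diameter", "outer_diameter", "inner_diameter")) {
    expect_equal(m1[[colm]], m2[[colm]], tolerance = 0.01)
  }
})

test_that("profile tables round-trip through CSV", {
  img <- single_ellipse_image(2, 2, 40)
  m <- measure_image(img, id = "img1")$profiles
  path <- file.path(withr::local_tempdir(), "prof.csv")
  write_profiles_csv(m, path)
  back <- read_profiles_csv(path)
  expect_equal(back$outer_diameter, m$outer_diameter, tolerance = 1e-8)
})

test_that("border-touching profiles are excluded by default, kept on demand", {
  px <- 0.05
  ell <- data.frame(x = c(0.45, 3), y = c(0.45, 3),
                    minor = c(1, 1), major = c(1, 1),
                    minor_inner = c(0.6, 0.6), major_inner = c(0.6, 0.6),
                    angle_deg = 0)
  p <- tissue_params(field_size = 6, pixel_size = px)
  img <- render_micrograph(ell, p)
  expect_equal(segment_profiles(img)$n_profiles, 1)
  expect_equal(segment_profiles(img, segmentation_params(
    border_policy = "include"))$n_profiles, 2)
})

test_that("an LM-scale field with ~2000 profiles round-trips the count", {
  p <- tissue_preset("CTR-SWM", modality = "LM-like", seed = 24)
  pop <- sample_axon_population(p)
  mm <- measure_image(render_micrograph(pop, p))
  expect_gt(nrow(pop$axons), 1000)
  expect_lt(abs(mm$n_profiles - nrow(pop$axons)) / nrow(pop$axons), 0.1)
  # and mean caliber survives the pipeline within a few percent
  expect_equal(mean(mm$profiles$outer_diameter),
               mean(pop$axons$outer_diameter), tolerance = 0.05)
})
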