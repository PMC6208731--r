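test_that("degenerate concentration about the normal gives circular profiles", {
  set.seed(1)
  p <- tissue_params(orientation_law = list(list(weight = 1, tilt_deg = 0,
                                                 azimuth_deg = 0,
                                                 kappa = 1e7)))
  pop <- sample_axon_population(p, n = 500, place = FALSE)
  expect_lt(max(pop$ellipses$ar), 1.001)
  expect_lt(max(pop$axons$theta_deg), 2)
})

test_that("isotropic axes reproduce the closed-form elongated fractions", {
  set.seed(2)
  iso <- list(list(weight = 1, tilt_deg = 0, azimuth_deg = 0, kappa = 0))
  p_off <- tissue_params(orientation_law = iso, flux_weighting = FALSE)
  pop <- sample_axon_population(p_off, n = 3e4, place = FALSE)
  expect_equal(mean(pop$ellipses$ar >= 3), 1 / 3, tolerance = 0.02)
  # cross-check against a direct Monte-Carlo oracle
  expect_equal(mean(oracle_isotropic_ar(3e4) >= 3), 1 / 3, tolerance = 0.02)

  p_on <- tissue_params(orientation_law = iso, flux_weighting = TRUE)
  pop2 <- sample_axon_population(p_on, n = 3e4, place = FALSE)
  expect_equal(mean(pop2$ellipses$ar >= 3), 1 / 9, tolerance = 0.03)
})

test_that("cylinder-plane intersection matches the analytic geometry", {
  ax <- data.frame(axis_x = sin(pi / 3), axis_y = 0, axis_z = cos(pi / 3),
                   outer_diameter = 1, inner_diameter = 0.6)
  e <- intersect_with_plane(ax)
  expect_equal(e$minor, 1)
  expect_equal(e$major, 2)
  expect_equal(e$ar, 2)

  ax0 <- data.frame(axis_x = 0, axis_y = 0, axis_z = 1,
                    outer_diameter = 0.8, inner_diameter = 0.5)
  e0 <- intersect_with_plane(ax0)
  expect_equal(e0$ar, 1)
  expect_equal(e0$major, 0.8)

  th <- 70.52878 * pi / 180  # cos(theta) = 1/3
  ax3 <- data.frame(axis_x = sin(th), axis_y = 0, axis_z = cos(th),
                    outer_diameter = 1, inner_diameter = 0.6)
  expect_equal(intersect_with_plane(ax3)$ar, 3, tolerance = 1e-4)

  # in-plane axis has no bounded intersection
  axp <- data.frame(axis_x = 1, axis_y = 0, axis_z = 0,
                    outer_diameter = 1, inner_diameter = 0.6)
  expect_error(intersect_with_plane(axp), "section plane")

  # aspect-ratio cap
  th2 <- 89.9 * pi / 180
  axc <- data.frame(axis_x = sin(th2), axis_y = 0, axis_z = cos(th2),
                    outer_diameter = 1, inner_diameter = 0.6)
  expect_equal(intersect_with_plane(axc, cap_ar = 10)$ar, 10)
})

test_that("profile angle is the in-plane projection of the axis", {
  phi <- c(0, 30, 100, 170)
  th <- 60 * pi / 180
  ax <- data.frame(axis_x = sin(th) * cos(phi * pi / 180),
                   axis_y = sin(th) * sin(phi * pi / 180),
                   axis_z = cos(th),
                   outer_diameter = 1, inner_diameter = 0.6)
  expect_equal(intersect_with_plane(ax)$angle_deg, phi)
})

test_that("rendering an annulus recovers its analytic area", {
  # one circle: outer radius 10 px, inner radius 6 px at 0.05 um/px
  px <- 0.05
  ell <- data.frame(x = 2, y = 2, minor = 20 * px, major = 20 * px,
                    minor_inner = 12 * px, major_inner = 12 * px,
                    angle_deg = 0)
  p <- tissue_params(field_size = 4, pixel_size = px)
  img <- render_micrograph(ell, p)
  n_myelin <- sum(img$pixels < 0.5)
  expect_equal(n_myelin, pi * (10^2 - 6^2), tolerance = 0.02)
})

test_that("empty population renders a uniform background", {
  p <- tissue_params(field_size = 5, pixel_size = 0.05)
  img <- render_micrograph(data.frame(), p, background = 0.85)
  expect_true(all(img$pixels == 0.85))
})

test_that("placement reaches the target fraction or fails loudly", {
  p <- tissue_params(field_size = 10, target_areal_fraction = 0.25,
                     pixel_size = 0.02, seed = 7)
  pop <- sample_axon_population(p)
  expect_lt(abs(pop$ground_truth$achieved_areal_fraction - 0.25), 0.05)
  # an infeasible dense target within a tiny attempt budget names the
  # achieved fraction
  p2 <- tissue_params(field_size = 6, target_areal_fraction = 0.55,
                      pixel_size = 0.02, seed = 8)
  expect_error(sample_axon_population(p2, max_attempts_per = 3),
               "achieved areal fraction")
})

test_that("generation is deterministic under a fixed seed", {
  p <- tissue_params(field_size = 8, target_areal_fraction = 0.2,
                     pixel_size = 0.02, seed = 33)
  img1 <- render_micrograph(sample_axon_population(p), p)
  img2 <- render_micrograph(sample_axon_population(p), p)
  expect_identical(img1$pixels, img2$pixels)
})

test_that("micrograph TIFF + sidecar round-trips", {
  p <- tissue_params(field_size = 5, target_areal_fraction = 0.15,
                     pixel_size = 0.02, seed = 5)
  img <- render_micrograph(sample_axon_population(p), p, id = "rt")
  path <- file.path(withr::local_tempdir(), "rt.tif")
  write_micrograph(img, path)
  back <- read_micrograph(path)
  expect_equal(back$pixel_size, img$pixel_size)
  expect_equal(back$pixels, img$pixels, tolerance = 1 / 65535 * 2)
})

test_that("cell populations are homogeneous Poisson with correct mix", {
  pop0 <- generate_cell_population(c(100, 100, 10), c(neuron = 0))
  expect_equal(nrow(pop0$cells), 0)

  set.seed(9)
  pop <- generate_cell_population(c(1000, 1000, 100),
                                  c(a = 30000, b = 10000), seed = 10)
  # volume 0.1 mm^3: expect 3000 a and 1000 b
  tab <- table(pop$cells$label)
  expect_equal(unname(tab["a"] / tab["b"]), 3, tolerance = 0.15)
  expect_equal(nrow(pop$cells), 4000, tolerance = 0.1)
  expect_true(all(pop$cells$x >= 0 & pop$cells$x <= 1000))
})

test_that("cohort generator validates its inputs", {
  expect_error(cohort_spec(n_children = 1, n_teens = 0, n_adults = 0),
               "at least 2 cases")
  expect_error(cohort_spec(groups = "CTR"), "two groups")
})

test_that("identical group laws give no average slope difference", {
  laws <- default_cohort_laws()
  laws$ASD <- laws$CTR
  set.seed(11)
  ests <- replicate(30, {
    co <- generate_cohort(cohort_spec(laws = laws, n_children = 4,
                                      n_teens = 0, n_adults = 4),
                          mode = "table")
    gt <- co$ground_truth[co$ground_truth$compartment == "SWM", ]
    tr <- trajectory_ancova(gt, "mean_outer")
    tr$interaction$estimate
  })
  expect_lt(abs(mean(ests)), 3 * sd(ests) / sqrt(length(ests)) + 1e-4)
})
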