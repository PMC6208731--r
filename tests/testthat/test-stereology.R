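test_that("density arithmetic converts disector volume exactly", {
  fp <- fractionator_params(55, 5, 2, 150, 12)
  fc <- structure(list(frames = data.frame(x0 = 1:50, y0 = 0,
                                           count = rep(2, 50)),
                       sum_q = 100, n_frames = 50, offset = c(0, 0),
                       params = fp),
                  class = "fractionator_counts")
  est <- density_from_counts(fc)
  expect_equal(est$density, 100 / (50 * 55^2 * 5) * 1e9, tolerance = 1e-12)
  expect_equal(round(est$density), 132231)
})

test_that("parameter invariants are enforced", {
  expect_error(fractionator_params(55, 10, 2, 150, section_thickness = 12),
               "exceed")
  expect_error(fractionator_params(160, 5, 2, 150, 12), "grid_spacing")
})

test_that("counting-frame rule excludes exclusion edges and tiles exactly", {
  fp <- fractionator_params(frame_side = 10, disector_height = 6,
                            guard_zone = 2, grid_spacing = 10,
                            section_thickness = 10, offset = c(0, 0))
  # cell exactly on the right (exclusion) edge of the frame at (10, 10)
  cells <- data.frame(x = 20, y = 15, z = 5)
  roi <- data.frame(x = c(-1, 41, 41, -1), y = c(-1, -1, 41, 41))
  fc <- fractionator_counts(cells, fp, roi = roi)
  frame_r <- fc$frames[fc$frames$x0 == 10 & fc$frames$y0 == 10, ]
  expect_equal(frame_r$count, 0)
  # ... it belongs to the next frame's inclusion (left) edge
  frame_l <- fc$frames[fc$frames$x0 == 20 & fc$frames$y0 == 10, ]
  expect_equal(frame_l$count, 1)

  # adjacent frames tiling the ROI count every interior cell exactly once
  set.seed(51)
  cells2 <- data.frame(x = runif(300, 0, 40), y = runif(300, 0, 40),
                       z = runif(300, 0, 10))
  fc2 <- fractionator_counts(cells2, fp, roi = roi)
  in_z <- sum(cells2$z >= 2 & cells2$z < 8)
  expect_equal(fc2$sum_q, in_z)
})

test_that("a disector covering the whole ROI counts all guarded cells", {
  set.seed(52)
  pop <- generate_cell_population(c(60, 60, 12), c(neuron = 2e5), seed = 52)
  fp <- fractionator_params(frame_side = 50, disector_height = 8,
                            guard_zone = 2, grid_spacing = 50,
                            section_thickness = 12, offset = c(5, 5))
  roi <- data.frame(x = c(4, 56, 56, 4), y = c(4, 4, 56, 56))
  fc <- fractionator_counts(pop, fp, roi = roi)
  expect_equal(fc$n_frames, 1)
  cc <- pop$cells
  manual <- sum(cc$x >= 5 & cc$x < 55 & cc$y > 5 & cc$y <= 55 &
                  cc$z >= 2 & cc$z < 10)
  expect_equal(fc$sum_q, manual)
})

test_that("ROI smaller than one grid cell is refused", {
  fp <- fractionator_params(55, 5, 2, 150, 12)
  roi <- data.frame(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100))
  expect_error(fractionator_counts(data.frame(x = 1, y = 1, z = 5), fp,
                                   roi = roi), "smaller than one grid cell")
})

test_that("CE follows 1/sqrt(sum Q) on homogeneous counts", {
  expect_equal(gundersen_ce(rep(2, 50))$ce_noise, 0.10)
  expect_equal(gundersen_ce(rep(8, 50))$ce_noise, 0.05)
  expect_warning(ce0 <- gundersen_ce(rep(0, 10)), "zero")
  expect_true(is.na(ce0$ce_noise))
  expect_error(gundersen_ce(5), "at least 2")
  # scaling: quadrupling counts halves the noise CE
  set.seed(53)
  q <- rpois(100, 2)
  expect_equal(gundersen_ce(q * 4)$ce_noise,
               gundersen_ce(q)$ce_noise / 2, tolerance = 1e-12)
})

test_that("fractionator is unbiased over random offsets", {
  set.seed(54)
  pop <- generate_cell_population(c(3000, 3000, 12), c(neuron = 40000),
                                  seed = 54)
  realized <- nrow(pop$cells) / (prod(pop$slab) / 1e9)
  fp <- fractionator_params(55, 5, 2, 150, 12)
  d <- replicate(60, density_from_counts(fractionator_counts(pop, fp))$density)
  expect_equal(mean(d), realized, tolerance = 0.04)
})

test_that("coarser grids keep the mean but inflate per-frame variance", {
  set.seed(55)
  pop <- generate_cell_population(c(1200, 1200, 12), c(neuron = 80000),
                                  seed = 55)
  est_at <- function(spacing) {
    replicate(40, {
      fp <- fractionator_params(55, 5, 2, spacing, 12)
      density_from_counts(fractionator_counts(pop, fp))$density
    })
  }
  fine <- est_at(120)
  coarse <- est_at(240)
  expect_equal(mean(fine), mean(coarse), tolerance = 0.08)
  expect_gt(var(coarse), var(fine))
})

test_that("label filters restrict counting to the requested population", {
  set.seed(56)
  pop <- generate_cell_population(c(800, 800, 12),
                                  c(neuron = 40000, microglia = 40000),
                                  seed = 56)
  fp <- fractionator_params(55, 5, 2, 150, 12, offset = c(10, 10))
  all_q <- fractionator_counts(pop, fp)$sum_q
  neu_q <- fractionator_counts(pop, fp, label = "neuron")$sum_q
  expect_lt(neu_q, all_q)
  expect_equal(neu_q / all_q, 0.5, tolerance = 0.3)
})
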