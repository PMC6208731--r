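test_that("elongation filter keeps AR >= threshold and records the weight", {
  s <- filter_elongated(data.frame(angle_deg = c(10, 20, 30, 40),
                                   ar = c(1, 2, 3, 4)))
  expect_equal(s$n_elongated, 2)
  expect_equal(s$weight, 0.5)
  expect_equal(s$angles, c(30, 40))

  s0 <- filter_elongated(data.frame(angle_deg = c(10, 20),
                                    ar = c(1.2, 2.9)))
  expect_equal(s0$n_elongated, 0)
  expect_equal(s0$flag, "empty")
})

test_that("peak alignment shifts the modal bin to 90 degrees", {
  expect_equal(as.numeric(align_peak_to_90(c(40, 45, 50), min_n = 1)),
               c(85, 90, 95))
  # the modal bin of the input is mapped onto the window centred at 90
  a <- c(rep(86, 6), rep(93, 6), 10, 170)
  once <- as.numeric(align_peak_to_90(a))
  expect_true(all(once >= 0 & once < 180))
  expect_equal(sum(once >= 85 & once < 95), 6)  # the modal-bin angles
  # alignment is a pure axial shift: pairwise axial distances preserved
  d0 <- abs(outer(a, a, "-")) %% 180
  d1 <- abs(outer(once, once, "-")) %% 180
  expect_equal(pmin(d1, 180 - d1), pmin(d0, 180 - d0))
  # and below the minimum count, alignment is skipped with a flag
  few <- align_peak_to_90(c(10, 20, 30))
  expect_false(attr(few, "aligned"))
  expect_equal(as.numeric(few), c(10, 20, 30))
})

test_that("wraparound clusters align to 90 with spread preserved", {
  a <- c(170, 175, 5, 10, 174, 176, 3, 177, 175, 4)
  al <- align_peak_to_90(a)
  orc <- oracle_align(a)
  expect_equal(orientation_sd(al), orientation_sd(orc), tolerance = 0.15)
  expect_lt(abs(mean(al) - 90), 15)
})

test_that("orientation SD matches direct formulas", {
  expect_equal(orientation_sd(c(80, 90, 100)), 10)
  expect_equal(orientation_sd(rep(45, 5)), 0)
  expect_warning(expect_true(is.na(orientation_sd(42))), "fewer than 2")
  set.seed(41)
  u <- runif(1e4, 0, 180)
  expect_equal(orientation_sd(align_peak_to_90(u)), 180 / sqrt(12),
               tolerance = 1 / 51.96)
})

test_that("SD is invariant to global axial rotation of the input", {
  set.seed(42)
  base <- c(rnorm(300, 90, 12)) %% 180
  sd0 <- orientation_sd(align_peak_to_90(base))
  for (rot in runif(5, 0, 180)) {
    sdr <- orientation_sd(align_peak_to_90((base + rot) %% 180))
    expect_equal(sdr, sd0, tolerance = 0.1)
  }
})

test_that("case weighted SD is the weight-averaged per-image SD", {
  w <- weighted_case_sd(c(10, 20), c(0.25, 0.75))
  expect_equal(w$case_weighted_sd_deg, 17.5)
  expect_equal(w$case_sd_deg, 15)
  # equal weights reduce to the plain mean
  expect_equal(weighted_case_sd(c(10, 20), c(0.3, 0.3))$case_weighted_sd_deg,
               15)
  # single image: its own SD regardless of weight
  expect_equal(weighted_case_sd(12, 0.05)$case_weighted_sd_deg, 12)
  # weighted SD always lies between the per-image extremes
  set.seed(43)
  for (i in 1:20) {
    sds <- runif(3, 5, 50); ws <- runif(3)
    wc <- weighted_case_sd(sds, ws)$case_weighted_sd_deg
    expect_gte(wc, min(sds)); expect_lte(wc, max(sds))
  }
  expect_warning(weighted_case_sd(c(10, 20), c(0, 0)), "weights")
})

test_that("paired compartment test behaves at its symmetry points", {
  ct <- data.frame(case = rep(sprintf("c%d", 1:6), 2),
                   compartment = rep(c("SWM", "DWM"), each = 6),
                   sd_deg = c(1:6 + 10, 1:6 + 10),
                   weighted_sd_deg = c(1:6 + 9, 1:6 + 9))
  r <- compare_compartments_paired(ct)
  expect_equal(r$sd$t, 0)
  expect_equal(r$sd$p_two_tailed, 1)

  set.seed(44)
  ct2 <- ct
  ct2$sd_deg <- ct$sd_deg + rep(c(3, 0), each = 6) + rnorm(12, 0, 0.5)
  ct2$weighted_sd_deg <- ct2$sd_deg
  r2 <- compare_compartments_paired(ct2)
  ct3 <- ct2
  # swapping compartment labels flips the sign of t exactly
  ct3$compartment <- rep(c("DWM", "SWM"), each = 6)
  r3 <- compare_compartments_paired(ct3)
  expect_equal(r2$sd$t, -r3$sd$t)
  expect_error(compare_compartments_paired(ct[1:2, ]), "at least 2")
})

test_that("compartment presets order the dispersion SWM > DWM per case", {
  set.seed(45)
  make_case <- function(case) {
    do.call(rbind, lapply(c("SWM", "DWM"), function(comp) {
      do.call(rbind, lapply(1:2, function(im) {
        p <- tissue_params(orientation_law = orientation_preset(comp))
        pop <- sample_axon_population(p, n = 1500, place = FALSE)
        data.frame(case = case, compartment = comp,
                   image = sprintf("%s_%s_%d", case, comp, im),
                   angle_deg = pop$ellipses$angle_deg, ar = pop$ellipses$ar)
      }))
    }))
  }
  prof <- do.call(rbind, lapply(sprintf("c%d", 1:4), make_case))
  ct <- case_orientation(prof)
  sw <- ct[ct$compartment == "SWM", ]
  dw <- ct[ct$compartment == "DWM", ]
  expect_true(all(sw$sd_deg[match(dw$case, sw$case)] > dw$sd_deg))
  expect_true(all(sw$weighted_sd_deg[match(dw$case, sw$case)] >
                    dw$weighted_sd_deg))
})
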