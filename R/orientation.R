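## Axon-trajectory variability statistics -----------------------------------

#' Keep elongated profiles for orientation analysis
#'
#' Profiles nearly perpendicular to the section appear circular and their
#' fitted angle is unreliable, so orientation analysis is constrained to
#' elongated profiles with aspect ratio at or above `ar_threshold`
#' (default 3, which keeps roughly 30% of profiles in typical white
#' matter). The kept/total ratio is recorded as the image's weighting
#' factor.
#'
#' @param measures Data frame with `angle_deg` and `ar` columns (one image's
#'   profiles), or a list with numeric `angle_deg` and `ar`.
#' @param ar_threshold Elongation cutoff (default 3).
#' @return Object of class `orientation_sample`: `angles` (degrees, axial in
#'   `[0, 180)`), `n_all`, `n_elongated`, `weight = n_elongated / n_all`,
#'   and `flag` (`"empty"` when no profile passes).
#' @examples
#' s <- filter_elongated(data.frame(angle_deg = c(10, 20, 30, 40),
#'                                  ar = c(1, 2, 3, 4)))
#' s$weight  # 0.5
#' @export
filter_elongated <- function(measures, ar_threshold = 3) {
  ang <- measures$angle_deg
  ar <- measures$ar
  stopifnot(length(ang) == length(ar))
  keep <- is.finite(ar) & ar >= ar_threshold
  structure(list(angles = ang[keep] %% 180,
                 n_all = length(ang),
                 n_elongated = sum(keep),
                 weight = if (length(ang)) sum(keep) / length(ang) else 0,
                 flag = if (!sum(keep)) "empty" else NA_character_),
            class = "orientation_sample")
}

#' @export
print.orientation_sample <- function(x, ...) {
  cat("<orientation_sample>", x$n_elongated, "/", x$n_all,
      "elongated (weight", round(x$weight, 3), ")\n")
  invisible(x)
}

#' Align the modal angle of an image to 90 degrees
#'
#' To remove acquisition-dependent rotation, angle values of each image are
#' normalised by shifting the peak of the axial angle histogram to 90°.
#' The peak is the modal 10°-wide bin (ties broken toward the lowest bin);
#' every angle is shifted by `90 - peak` modulo 180, so the spread about the
#' peak is preserved, including clusters wrapping through 0°/180°.
#'
#' @param angles Axial angles in degrees.
#' @param bin_width Histogram bin width in degrees (default 10; must divide
#'   180).
#' @param min_n Below this many angles alignment is skipped (the mode is
#'   meaningless); the input is returned with attribute `aligned = FALSE`.
#' @return Aligned angles in `[0, 180)`, attribute `aligned`.
#' @examples
#' align_peak_to_90(c(40, 45, 50))  # 85, 90, 95
#' @export
align_peak_to_90 <- function(angles, bin_width = 10, min_n = 10) {
  if (180 %% bin_width != 0) stop("bin_width must divide 180")
  a <- angles %% 180
  if (length(a) < min_n) {
    out <- a
    attr(out, "aligned") <- FALSE
    return(out)
  }
  bins <- floor(a / bin_width)            # 0 .. 180/bin_width - 1
  counts <- tabulate(bins + 1L, nbins = 180 %/% bin_width)
  peak_bin <- which.max(counts)           # ties -> lowest bin
  peak <- (peak_bin - 0.5) * bin_width    # bin centre
  out <- (a + (90 - peak)) %% 180
  attr(out, "aligned") <- TRUE
  out
}

#' Per-image orientation dispersion
#'
#' Plain (linear) sample standard deviation of peak-aligned axial angles,
#' with n-1 normalisation. After alignment the angles live in `[0, 180)`
#' centred on 90°, so no further wrapping is applied. For uniformly
#' dispersed axial angles the SD approaches \eqn{180/\sqrt{12} \approx 51.96°}.
#'
#' @param angles Aligned angles in degrees (at least 2).
#' @return SD in degrees (`NA` with a warning if fewer than 2 angles).
#' @export
orientation_sd <- function(angles) {
  if (length(angles) < 2) {
    warning("fewer than 2 angles: SD undefined")
    return(NA_real_)
  }
  stats::sd(angles)
}

# Circular axial SD (optional column for users): 180/pi/2 * sqrt(-2 log R)
# on doubled angles.
axial_circular_sd <- function(angles) {
  if (length(angles) < 2) return(NA_real_)
  a2 <- angles * pi / 90  # doubled angles in radians
  R <- sqrt(mean(cos(a2))^2 + mean(sin(a2))^2)
  sqrt(pmax(-2 * log(R), 0)) * 90 / pi
}

#' Per-image orientation summary table
#'
#' Applies [filter_elongated()], [align_peak_to_90()] and [orientation_sd()]
#' image by image.
#'
#' @param profiles Per-profile data frame with `image`, `angle_deg`, `ar`
#'   (optionally `case`, `compartment`, carried through).
#' @param ar_threshold Elongation cutoff (default 3).
#' @param bin_width Peak-alignment histogram bin (default 10°).
#' @return Object of class `orientation_summary`: `per_image` data frame
#'   with `image`, `n_all`, `n_elongated`, `weight`, `sd_deg`,
#'   `sd_axial_circ_deg`.
#' @export
orientation_summary <- function(profiles, ar_threshold = 3, bin_width = 10) {
  stopifnot("image" %in% names(profiles))
  imgs <- unique(profiles$image)
  rows <- lapply(imgs, function(im) {
    p <- profiles[profiles$image == im, ]
    s <- filter_elongated(p, ar_threshold)
    al <- align_peak_to_90(s$angles, bin_width = bin_width)
    data.frame(image = im,
               case = if ("case" %in% names(p)) p$case[1] else NA,
               compartment = if ("compartment" %in% names(p))
                 p$compartment[1] else NA,
               n_all = s$n_all, n_elongated = s$n_elongated,
               weight = s$weight,
               sd_deg = if (s$n_elongated >= 2)
                 orientation_sd(al) else NA_real_,
               sd_axial_circ_deg = axial_circular_sd(al))
  })
  per_image <- do.call(rbind, rows)
  rownames(per_image) <- NULL
  structure(list(per_image = per_image,
                 ar_threshold = ar_threshold, bin_width = bin_width),
            class = "orientation_summary")
}

#' @export
print.orientation_summary <- function(x, ...) {
  cat("<orientation_summary>", nrow(x$per_image), "images; mean SD",
      round(mean(x$per_image$sd_deg, na.rm = TRUE), 2), "deg\n")
  invisible(x)
}

#' Case-level (weighted) orientation SD
#'
#' The case SD is the unweighted mean of per-image SDs; the case weighted SD
#' averages per-image SDs with the elongated-fraction weights
#' \eqn{\sum w_i SD_i / \sum w_i}.
#'
#' @param sd_deg Per-image SDs (degrees), 1–3 images per case, or an
#'   `orientation_summary` (then `weights` is taken from it).
#' @param weights Per-image elongated fractions in `[0, 1]`, not all zero.
#' @return List with `case_sd_deg` and `case_weighted_sd_deg`.
#' @examples
#' weighted_case_sd(c(10, 20), c(0.25, 0.75))$case_weighted_sd_deg  # 17.5
#' @export
weighted_case_sd <- function(sd_deg, weights = NULL) {
  if (inherits(sd_deg, "orientation_summary")) {
    weights <- sd_deg$per_image$weight
    sd_deg <- sd_deg$per_image$sd_deg
  }
  ok <- is.finite(sd_deg)
  sd_deg <- sd_deg[ok]; weights <- weights[ok]
  if (!length(sd_deg)) stop("no finite per-image SDs")
  if (all(weights <= 0)) {
    warning("all weights are zero: weighted SD undefined")
    return(list(case_sd_deg = mean(sd_deg),
                case_weighted_sd_deg = NA_real_))
  }
  list(case_sd_deg = mean(sd_deg),
       case_weighted_sd_deg = sum(weights * sd_deg) / sum(weights))
}

#' Case-by-compartment orientation table
#'
#' Aggregates a per-profile table to one row per case x compartment with
#' plain and weighted case SDs.
#'
#' @inheritParams orientation_summary
#' @return Data frame: `case`, `compartment`, `n_images`, `sd_deg`,
#'   `weighted_sd_deg`, `mean_weight`.
#' @export
case_orientation <- function(profiles, ar_threshold = 3, bin_width = 10) {
  stopifnot(all(c("case", "compartment") %in% names(profiles)))
  os <- orientation_summary(profiles, ar_threshold, bin_width)$per_image
  key <- interaction(os$case, os$compartment, drop = TRUE)
  rows <- lapply(split(os, key), function(d) {
    w <- weighted_case_sd(d$sd_deg, d$weight)
    data.frame(case = d$case[1], compartment = d$compartment[1],
               n_images = nrow(d), sd_deg = w$case_sd_deg,
               weighted_sd_deg = w$case_weighted_sd_deg,
               mean_weight = mean(d$weight))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired comparison of orientation dispersion between compartments
#'
#' Paired t-test of per-case SD (and, separately, weighted SD) between
#' superficial and deep white matter; every included case must have both
#' compartments. Both two-tailed and one-tailed p values are reported
#' (one-tailed in the direction of the observed mean difference).
#'
#' @param case_table Output of [case_orientation()] (columns `case`,
#'   `compartment`, `sd_deg`, `weighted_sd_deg`).
#' @param compartments Length-2: the pair to compare, difference taken as
#'   first minus second (default SWM - DWM).
#' @return List of class `paired_orientation_test` with elements `sd` and
#'   `weighted_sd`, each containing `t`, `df`, `p_two_tailed`,
#'   `p_one_tailed`, `mean_diff`, `n`.
#' @export
compare_compartments_paired <- function(case_table,
                                        compartments = c("SWM", "DWM")) {
  a <- case_table[case_table$compartment == compartments[1], ]
  b <- case_table[case_table$compartment == compartments[2], ]
  common <- intersect(a$case, b$case)
  if (length(common) < 2)
    stop("need at least 2 cases with both compartments; got ",
         length(common))
  a <- a[match(common, a$case), ]
  b <- b[match(common, b$case), ]
  one <- function(xa, xb) {
    d <- xa - xb
    if (stats::sd(d) == 0) {
      # degenerate paired data: identical values give t = 0, p = 1
      t0 <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      return(list(t = t0, df = length(d) - 1,
                  p_two_tailed = if (mean(d) == 0) 1 else 0,
                  p_one_tailed = if (mean(d) == 0) 0.5 else 0,
                  mean_diff = mean(d), n = length(d)))
    }
    tt <- stats::t.test(xa, xb, paired = TRUE)
    p2 <- tt$p.value
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p_two_tailed = p2, p_one_tailed = p2 / 2,
         mean_diff = unname(tt$estimate), n = length(xa))
  }
  structure(list(sd = one(a$sd_deg, b$sd_deg),
                 weighted_sd = one(a$weighted_sd_deg, b$weighted_sd_deg),
                 compartments = compartments),
            class = "paired_orientation_test")
}

#' @export
print.paired_orientation_test <- function(x, ...) {
  cat("<paired_orientation_test>", paste(x$compartments, collapse = " vs "),
      "( n =", x$sd$n, ")\n")
  cat(sprintf("  SD:          t = %.3f, two-tailed p = %.4g\n",
              x$sd$t, x$sd$p_two_tailed))
  cat(sprintf("  weighted SD: t = %.3f, two-tailed p = %.4g\n",
              x$weighted_sd$t, x$weighted_sd$p_two_tailed))
  invisible(x)
}

#' Stick plot of elongated-profile orientations
#'
#' Draws each elongated profile as a short segment at its centroid,
#' oriented at its axial angle and colour-coded by angle — a quick visual
#' check of trajectory homogeneity (parallel deep-white-matter fibers show
#' one colour; heterogeneous superficial fields show many).
#'
#' @param profiles Per-profile data frame with `centroid_x`, `centroid_y`,
#'   `angle_deg`, `ar`, `major_diameter` columns (one image).
#' @param ar_threshold Elongation cutoff (default 3).
#' @param ... Passed to [graphics::plot()].
#' @return The plotted subset, invisibly.
#' @export
plot_orientation_sticks <- function(profiles, ar_threshold = 3, ...) {
  p <- profiles[is.finite(profiles$ar) & profiles$ar >= ar_threshold, ]
  if (!nrow(p)) {
    warning("no elongated profiles to plot")
    return(invisible(p))
  }
  cols <- grDevices::hsv(h = (p$angle_deg %% 180) / 180, s = 0.9, v = 0.8)
  len <- p$major_diameter / 2
  a <- p$angle_deg * pi / 180
  graphics::plot(p$centroid_x, p$centroid_y, type = "n", asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  graphics::segments(p$centroid_x - len * cos(a), p$centroid_y - len * sin(a),
                     p$centroid_x + len * cos(a), p$centroid_y + len * sin(a),
                     col = cols, lwd = 2)
  invisible(p)
}
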