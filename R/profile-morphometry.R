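## Segmentation -------------------------------------------------------------

#' Segmentation parameters
#'
#' @param threshold_method `"otsu"` (default, computed on the inverted
#'   image) or `"fixed"`.
#' @param threshold_value Threshold on the inverted intensity in `[0, 1]`,
#'   used when `threshold_method = "fixed"` (constant-exposure protocols).
#' @param min_area Minimum profile area in μm²; smaller regions are
#'   discarded. Default = area of a 0.1 μm-diameter circle.
#' @param fill_holes Fill lumens so regions are full profiles (default
#'   `TRUE`; required for outer-area density).
#' @param border_policy `"exclude-touching"` (default, unbiased counting
#'   frame logic) or `"include"`.
#' @return Object of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                threshold_value = 0.5,
                                min_area = pi * 0.05^2,
                                fill_holes = TRUE,
                                border_policy = c("exclude-touching",
                                                  "include")) {
  threshold_method <- match.arg(threshold_method)
  border_policy <- match.arg(border_policy)
  stopifnot(min_area >= 0)
  structure(list(threshold_method = threshold_method,
                 threshold_value = threshold_value,
                 min_area = min_area,
                 fill_holes = fill_holes,
                 border_policy = border_policy),
            class = "segmentation_params")
}

#' Segment myelinated-axon profiles in a micrograph
#'
#' The image is inverted (myelin becomes bright), thresholded (Otsu or
#' fixed), lumens are filled, connected components are labelled, regions
#' below `min_area` are discarded and the border policy is applied. Each
#' retained label is one profile: its filled region is the outer profile and
#' the filled-minus-thresholded pixels are its lumen.
#'
#' @param img A [micrograph()].
#' @param params A [segmentation_params()].
#' @return Object of class `profile_segmentation`: `labels` (integer matrix
#'   of filled profile labels, 0 = background), `myelin` (logical matrix of
#'   thresholded myelin pixels), `n_profiles`, `pixel_size`, `params`.
#'   If nothing is above threshold an empty result is returned with a
#'   warning.
#' @export
segment_profiles <- function(img, params = segmentation_params()) {
  stopifnot(inherits(img, "micrograph"))
  if (length(img$pixels) == 0) stop("empty image")
  inv <- 1 - img$pixels
  thr <- if (params$threshold_method == "otsu") {
    if (max(inv) - min(inv) < 1e-8) Inf  # flat image: nothing to segment
    else EBImage::otsu(EBImage::Image(inv), range = range(inv))
  } else params$threshold_value
  fg <- inv > thr
  empty <- function() {
    warning("no foreground after thresholding: zero profiles")
    structure(list(labels = matrix(0L, nrow(inv), ncol(inv)),
                   myelin = fg & FALSE, n_profiles = 0L,
                   pixel_size = img$pixel_size, params = params),
              class = "profile_segmentation")
  }
  if (!any(fg)) return(empty())
  filled <- if (params$fill_holes) {
    as.matrix(EBImage::fillHull(EBImage::Image(fg * 1)))> 0
  } else fg
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(filled * 1)))
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (nlab == 0) return(empty())
  keep <- rep(TRUE, nlab)
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  keep[sizes * img$pixel_size^2 < params$min_area] <- FALSE
  if (params$border_policy == "exclude-touching") {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    keep[border[border > 0]] <- FALSE
  }
  remap <- integer(nlab)
  remap[keep] <- seq_len(sum(keep))
  lab[lab > 0] <- remap[lab[lab > 0]]
  structure(list(labels = lab, myelin = fg, n_profiles = sum(keep),
                 pixel_size = img$pixel_size, params = params),
            class = "profile_segmentation")
}

#' @export
print.profile_segmentation <- function(x, ...) {
  cat("<profile_segmentation>", x$n_profiles, "profiles at",
      x$pixel_size, "um/px\n")
  invisible(x)
}

## Measurement --------------------------------------------------------------

# Second-central-moment summary of a pixel set given as (row, col) indices.
# The 1/12 term restores the variance lost by collapsing unit-square pixels
# to their centres, making axis estimates subpixel-accurate on noiseless
# elliptical regions.
pixel_moments <- function(rows, cols) {
  n <- length(rows)
  mx <- mean(cols); my <- mean(rows)
  vxx <- sum((cols - mx)^2) / n + 1 / 12
  vyy <- sum((rows - my)^2) / n + 1 / 12
  vxy <- sum((cols - mx) * (rows - my)) / n
  tr <- vxx + vyy
  dt <- sqrt(((vxx - vyy) / 2)^2 + vxy^2)
  l1 <- tr / 2 + dt
  l2 <- max(tr / 2 - dt, 1e-12)
  ang <- (0.5 * atan2(2 * vxy, vxx - vyy) * 180 / pi) %% 180
  list(cx = mx, cy = my, major = 4 * sqrt(l1), minor = 4 * sqrt(l2),
       angle = ang, n = n)
}

# Maximum caliper (Feret) diameter of a pixel set, via the convex hull of
# pixel centres, + 1 px for the half-pixel extent at each end.
feret_diameter <- function(rows, cols) {
  if (length(rows) == 1) return(1)
  h <- grDevices::chull(cols, rows)
  hx <- cols[h]; hy <- rows[h]
  d2 <- outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2
  sqrt(max(d2)) + 1
}

#' Measure one segmented profile
#'
#' Computes the per-profile morphometric record: maximum-caliper (Feret)
#' major diameter; outer and inner diameters as the width of the profile and
#' of its lumen perpendicular to the major axis through its centre (equal,
#' for elliptical profiles, to the minor axes of the filled region and of
#' the lumen, estimated from second central moments with subpixel accuracy);
#' myelin thickness `(outer - inner)/2`; aspect ratio and axial orientation
#' angle from the moment ellipse fit. Angles are measured counterclockwise
#' from the image x axis, in `[0, 180)` degrees. A profile whose lumen has
#' fully collapsed gets `inner_diameter = 0` and `collapsed_lumen = TRUE`
#' (kept: it still counts for density).
#'
#' @param seg A `profile_segmentation`.
#' @param label Integer label of the profile to measure.
#' @return One-row data frame (see [measure_image()] for columns).
#' @export
measure_profile <- function(seg, label) {
  stopifnot(inherits(seg, "profile_segmentation"))
  idx <- which(seg$labels == label, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no pixels with label ", label)
  measure_profile_px(idx, seg$myelin[seg$labels == label],
                     seg$pixel_size)
}

measure_profile_px <- function(idx, is_myelin, px) {
  rows <- idx[, 1]; cols <- idx[, 2]
  m <- pixel_moments(rows, cols)
  feret <- feret_diameter(rows, cols) * px
  lum <- !is_myelin
  if (any(lum)) {
    ml <- pixel_moments(rows[lum], cols[lum])
    inner <- ml$minor * px
    collapsed <- FALSE
  } else {
    inner <- 0
    collapsed <- TRUE
  }
  outer <- m$minor * px
  data.frame(centroid_x = m$cx * px, centroid_y = m$cy * px,
             area = m$n * px^2,
             major_diameter = feret,
             minor_diameter = outer,
             outer_diameter = outer,
             inner_diameter = min(inner, outer),
             myelin_thickness = max(outer - min(inner, outer), 0) / 2,
             ar = m$major / m$minor,
             angle_deg = m$angle,
             collapsed_lumen = collapsed)
}

#' Measure all profiles in a micrograph
#'
#' Composition of [segment_profiles()] and [measure_profile()], plus the two
#' areal-density variants. One row per profile.
#'
#' @param img A [micrograph()].
#' @param params A [segmentation_params()].
#' @param id Image identifier recorded in the `image` column.
#' @return Object of class `morphometry`: list with `profiles` (data frame:
#'   `image`, `centroid_x`, `centroid_y`, `area`, `major_diameter`,
#'   `minor_diameter`, `outer_diameter`, `inner_diameter`,
#'   `myelin_thickness`, `g_ratio`, `ar`, `angle_deg`, `collapsed_lumen`),
#'   `density` (mask variant [areal_density()]), `density_profiles`
#'   (profile-sum variant), `field_area` (μm²), `n_profiles`.
#' @export
measure_image <- function(img, params = segmentation_params(), id = NULL) {
  seg <- suppressWarnings(segment_profiles(img, params))
  field_area <- length(img$pixels) * img$pixel_size^2
  if (seg$n_profiles == 0) {
    prof <- empty_profile_table()
  } else {
    labv <- seg$labels
    ord <- which(labv > 0)
    sp <- split(ord, labv[ord])
    nr <- nrow(labv)
    rowsL <- lapply(sp, function(li) {
      idx <- cbind((li - 1L) %% nr + 1L, (li - 1L) %/% nr + 1L)
      measure_profile_px(idx, seg$myelin[li], seg$pixel_size)
    })
    prof <- do.call(rbind, rowsL)
    rownames(prof) <- NULL
    prof$g_ratio <- ifelse(prof$outer_diameter > 0,
                           prof$inner_diameter / prof$outer_diameter, NA_real_)
  }
  img_id <- if (is.null(id)) img$id %||% "image" else id
  prof <- cbind(image = rep(img_id, nrow(prof)), prof)
  dens <- areal_density(seg, field_area = field_area)
  densp <- areal_density(prof, field_area = field_area, variant = "profiles")
  structure(list(profiles = prof, density = dens, density_profiles = densp,
                 field_area = field_area, n_profiles = nrow(prof)),
            class = "morphometry")
}

empty_profile_table <- function() {
  data.frame(centroid_x = numeric(0), centroid_y = numeric(0),
             area = numeric(0), major_diameter = numeric(0),
             minor_diameter = numeric(0), outer_diameter = numeric(0),
             inner_diameter = numeric(0), myelin_thickness = numeric(0),
             ar = numeric(0), angle_deg = numeric(0),
             collapsed_lumen = logical(0), g_ratio = numeric(0))
}

#' @export
print.morphometry <- function(x, ...) {
  cat("<morphometry>", x$n_profiles, "profiles; areal fraction",
      round(x$density$fraction, 4), "(mask),",
      round(x$density_profiles$fraction, 4), "(profile sum)\n")
  invisible(x)
}

#' Areal-fraction density of myelinated axons
#'
#' Fraction of the field covered by axon profiles, myelin sheath included
#' (both light- and electron-microscopic densities are myelin-defined).
#' Two variants:
#' * `"mask"` — pixels of the retained (filled) profile regions divided by
#'   the field; takes a `profile_segmentation`.
#' * `"profiles"` — sum of per-profile outer ellipse areas
#'   \eqn{\pi/4 \cdot major \cdot minor} divided by the field; takes a
#'   profile table.
#'
#' @param x A `profile_segmentation` (mask variant) or a profile data frame
#'   (profile-sum variant).
#' @param field_area Field area in μm² (> 0).
#' @param variant `"mask"` or `"profiles"` (chosen automatically from `x`
#'   when omitted).
#' @return Object of class `density_estimate`: `fraction` in `[0, 1]`,
#'   `n_profiles`, `field_area`, `variant`.
#' @export
areal_density <- function(x, field_area, variant = NULL) {
  if (field_area <= 0) stop("field_area must be positive")
  if (is.null(variant))
    variant <- if (inherits(x, "profile_segmentation")) "mask" else "profiles"
  if (variant == "mask") {
    stopifnot(inherits(x, "profile_segmentation"))
    covered <- sum(x$labels > 0) * x$pixel_size^2
    n <- x$n_profiles
  } else {
    prof <- if (inherits(x, "morphometry")) x$profiles else x
    covered <- sum(pi / 4 * prof$major_diameter * prof$minor_diameter)
    n <- nrow(prof)
  }
  structure(list(fraction = min(covered / field_area, 1),
                 n_profiles = n, field_area = field_area, variant = variant),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat("<density_estimate>", round(x$fraction, 4), "(", x$variant, "variant,",
      x$n_profiles, "profiles )\n")
  invisible(x)
}
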