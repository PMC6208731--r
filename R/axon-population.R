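## Watson-type axial sampler ------------------------------------------------

# Sample u = cos(angle from mean axis) in [0, 1] with density
# proportional to exp(kappa * u^2) (axial Watson concentration), via a
# dense-grid inverse CDF. kappa = 0 gives the isotropic axial law
# (u uniform on [0, 1], i.e. directions uniform on the hemisphere).
sample_watson_u <- function(n, kappa, grid_n = 4096) {
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(stats::runif(n))
  # restrict the grid to where the density is non-negligible (relative
  # mass below exp(-21) excluded), so huge concentrations keep resolution
  u_lo <- sqrt(max(0, 1 - 21 / kappa))
  u <- seq(u_lo, 1, length.out = grid_n)
  # log-density, stabilised; trapezoid cumulative
  f <- exp(kappa * (u^2 - 1))
  cdf <- c(0, cumsum((f[-1] + f[-grid_n]) / 2)) * (u[2] - u[1])
  cdf <- cdf / cdf[grid_n]
  stats::approx(cdf, u, xout = stats::runif(n), ties = "ordered")$y
}

# Rotation matrix taking the z axis onto the unit axis with polar tilt
# (degrees from +z) and azimuth (degrees CCW from +x in the plane).
rotation_to_axis <- function(tilt_deg, azimuth_deg) {
  th <- tilt_deg * pi / 180
  ph <- azimuth_deg * pi / 180
  # R_z(ph) %*% R_y(th): maps (0,0,1) to (sin th cos ph, sin th sin ph, cos th)
  matrix(c(cos(ph) * cos(th), sin(ph) * cos(th), -sin(th),
           -sin(ph),          cos(ph),            0,
           cos(ph) * sin(th), sin(ph) * sin(th),  cos(th)),
         nrow = 3, byrow = FALSE)
}

# Draw n undirected unit axes from a mixture of Watson components.
# Returns a matrix with columns x, y, z; z >= 0 by axial convention.
sample_axial_directions <- function(n, orientation_law) {
  w <- vapply(orientation_law, function(co) co$weight, numeric(1))
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  out <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (k in seq_along(orientation_law)) {
    idx <- which(comp == k)
    if (!length(idx)) next
    co <- orientation_law[[k]]
    u <- sample_watson_u(length(idx), co$kappa)
    psi <- stats::runif(length(idx), 0, 2 * pi)
    s <- sqrt(pmax(0, 1 - u^2))
    d <- cbind(s * cos(psi), s * sin(psi), u)
    R <- rotation_to_axis(co$tilt_deg, co$azimuth_deg)
    out[idx, ] <- d %*% t(R)
  }
  # axial convention: flip to the upper hemisphere
  flip <- out[, 3] < 0
  out[flip, ] <- -out[flip, ]
  out
}

## Diameter and g-ratio laws ------------------------------------------------

sample_outer_diameters <- function(n, law) {
  thick <- stats::runif(n) < law$weight_thick
  d <- numeric(n)
  nt <- sum(!thick)
  if (nt) {
    meanlog <- log(law$mean_thin) - law$sd_log_thin^2 / 2
    x <- stats::rlnorm(nt, meanlog, law$sd_log_thin)
    # truncate by resampling
    bad <- x < law$min_diameter | x > law$thick_shift
    while (any(bad)) {
      x[bad] <- stats::rlnorm(sum(bad), meanlog, law$sd_log_thin)
      bad <- x < law$min_diameter | x > law$thick_shift
    }
    d[!thick] <- x
  }
  nk <- sum(thick)
  if (nk) {
    x <- law$thick_shift + stats::rweibull(nk, law$thick_shape, law$thick_scale)
    bad <- x > law$max_diameter
    while (any(bad)) {
      x[bad] <- law$thick_shift +
        stats::rweibull(sum(bad), law$thick_shape, law$thick_scale)
      bad <- x > law$max_diameter
    }
    d[thick] <- x
  }
  d
}

sample_g_ratios <- function(outer, law) {
  mu <- law$mean + law$size_slope * (outer - law$ref_diameter)
  pmin(pmax(stats::rnorm(length(outer), mu, law$sd), law$lo), law$hi)
}

## Population sampling ------------------------------------------------------

#' Sample a ground-truth 3D axon population
#'
#' Draws straight-cylinder axons crossing the section plane: axial
#' orientations from the Watson mixture in `params$orientation_law`
#' (optionally flux-weighted by \eqn{|\cos\theta|}), outer diameters from the
#' two-population diameter law, and per-axon g-ratios (inner/outer) from a
#' size-dependent normal law. With `place = TRUE` the elliptical
#' cross-sections are positioned in the field by random sequential
#' (dart-throwing) placement without overlap until the target areal fraction
#' is reached.
#'
#' @param params A [tissue_params()] object.
#' @param n Number of axons to draw when `place = FALSE`. Ignored when
#'   placing (the number follows from the target areal fraction).
#' @param place Logical; position profiles in the field without overlap.
#' @param max_attempts_per Placement attempt budget per axon profile.
#' @return An object of class `axon_population`: list with
#'   * `axons`: data frame with one row per axon — `axis_x/y/z`, `theta_deg`
#'     (angle from the section normal), `inner_diameter`, `outer_diameter`,
#'     `myelin_thickness`, `g_ratio`, and (if placed) `x`, `y` centre in μm;
#'   * `ellipses`: the plane intersections from [intersect_with_plane()];
#'   * `ground_truth`: target and achieved areal fraction, per-axon truth,
#'     and the generating parameters.
#' @examples
#' p <- tissue_params(field_size = 10, target_areal_fraction = 0.2, seed = 1)
#' pop <- sample_axon_population(p)
#' pop$ground_truth$achieved_areal_fraction
#' @export
sample_axon_population <- function(params, n = NULL, place = TRUE,
                                   max_attempts_per = 4000) {
  stopifnot(inherits(params, "tissue_params"))
  if (!is.null(params$seed)) set.seed(params$seed)

  if (!place) {
    if (is.null(n)) stop("n must be given when place = FALSE")
    ax <- draw_axons(n, params)
    ell <- intersect_with_plane(ax, cap_ar = params$cap_ar)
    gt <- list(target_areal_fraction = NA_real_,
               achieved_areal_fraction = NA_real_,
               params = params)
    return(structure(list(axons = ax, ellipses = ell, ground_truth = gt),
                     class = "axon_population"))
  }

  field_px <- max(8L, as.integer(round(params$field_size / params$pixel_size)))
  field_area <- (field_px * params$pixel_size)^2
  target_area <- params$target_areal_fraction * field_area

  ## rounds of draw-and-place until the occupied fraction reaches the
  ## target; profiles that cannot be placed are skipped (flagged) and
  ## effectively replaced by later draws
  ax_all <- NULL; ell_all <- NULL
  mask <- NULL
  n_oversize <- 0L; n_unplaced <- 0L
  achieved <- 0
  for (round_i in 1:12) {
    short_area <- (params$target_areal_fraction - achieved) * field_area
    if (short_area <= 0) break
    ## draw a stream with summed ellipse area covering the shortfall
    ax <- draw_axons(64L, params)
    ell <- intersect_with_plane(ax, cap_ar = params$cap_ar)
    a <- pi / 4 * ell$major * ell$minor
    while (sum(a) < short_area) {
      ax2 <- draw_axons(64L, params)
      ell2 <- intersect_with_plane(ax2, cap_ar = params$cap_ar)
      ax <- rbind(ax, ax2); ell <- rbind(ell, ell2)
      a <- c(a, pi / 4 * ell2$major * ell2$minor)
    }
    cs <- cumsum(a)
    ncut <- which(cs >= short_area)[1]
    if (ncut > 1 &&
        abs(cs[ncut - 1] - short_area) < abs(cs[ncut] - short_area))
      ncut <- ncut - 1L
    ax <- ax[seq_len(ncut), , drop = FALSE]
    ell <- ell[seq_len(ncut), , drop = FALSE]
    pl <- place_ellipses(ell, field_px, params$pixel_size, mask = mask,
                         max_attempts_per = max_attempts_per)
    mask <- pl$mask
    n_oversize <- n_oversize + pl$n_oversize
    n_unplaced <- n_unplaced + pl$n_unplaced
    achieved <- pl$achieved_fraction
    if (any(pl$placed)) {
      keep <- which(pl$placed)
      ax <- ax[keep, , drop = FALSE]
      ell <- ell[keep, , drop = FALSE]
      ell$x <- pl$x[keep]; ell$y <- pl$y[keep]
      ax$x <- pl$x[keep]; ax$y <- pl$y[keep]
      ax_all <- rbind(ax_all, ax); ell_all <- rbind(ell_all, ell)
    }
    # near-jamming: progress has stalled, stop and report
    if (pl$n_unplaced > 0 && achieved < params$target_areal_fraction &&
        round_i >= 3 && pl$n_unplaced >= nrow(ell)) break
  }
  if (achieved < params$target_areal_fraction - 0.02)
    stop("placement budget exhausted: achieved areal fraction ",
         round(achieved, 4), " < target ", params$target_areal_fraction)
  rownames(ax_all) <- rownames(ell_all) <- NULL

  gt <- list(target_areal_fraction = params$target_areal_fraction,
             achieved_areal_fraction = achieved,
             occupancy = mask,
             n_oversize = n_oversize,
             n_unplaced = n_unplaced,
             field_px = field_px,
             params = params)
  structure(list(axons = ax_all, ellipses = ell_all, ground_truth = gt),
            class = "axon_population")
}

draw_axons <- function(n, params) {
  if (params$flux_weighting) {
    ## accept an axon crossing the plane with probability |cos theta|
    dirs <- matrix(numeric(0), 0, 3)
    while (nrow(dirs) < n) {
      cand <- sample_axial_directions(2L * (n - nrow(dirs)) + 8L,
                                      params$orientation_law)
      acc <- stats::runif(nrow(cand)) < abs(cand[, 3])
      dirs <- rbind(dirs, cand[acc, , drop = FALSE])
    }
    dirs <- dirs[seq_len(n), , drop = FALSE]
  } else {
    dirs <- sample_axial_directions(n, params$orientation_law)
  }
  outer <- sample_outer_diameters(n, params$diameter_law)
  g <- sample_g_ratios(outer, params$g_ratio_law)
  inner <- g * outer
  data.frame(axis_x = dirs[, 1], axis_y = dirs[, 2], axis_z = dirs[, 3],
             theta_deg = acos(pmin(1, abs(dirs[, 3]))) * 180 / pi,
             outer_diameter = outer,
             inner_diameter = inner,
             myelin_thickness = (outer - inner) / 2,
             g_ratio = g)
}

#' @export
print.axon_population <- function(x, ...) {
  cat("<axon_population>", nrow(x$axons), "axons\n")
  if (!is.na(x$ground_truth$achieved_areal_fraction))
    cat("  areal fraction: target", x$ground_truth$target_areal_fraction,
        "achieved", round(x$ground_truth$achieved_areal_fraction, 4), "\n")
  invisible(x)
}

## Plane intersection -------------------------------------------------------

#' Intersect cylinder axons with the section plane
#'
#' A straight circular cylinder of outer diameter \eqn{d} whose axis makes
#' angle \eqn{\theta} with the section normal intersects the plane in an
#' ellipse with minor axis exactly \eqn{d} and major axis
#' \eqn{d/\cos\theta}. The aspect ratio is capped at `cap_ar` (finite
#' section thickness truncates near-in-plane profiles). The in-plane profile
#' angle is the azimuth of the projected axis, axial in `[0, 180)` degrees.
#'
#' @param axons Data frame with columns `axis_x`, `axis_y`, `axis_z`,
#'   `outer_diameter`, `inner_diameter` (as produced inside
#'   [sample_axon_population()]), or a single-axon list with those fields.
#' @param cap_ar Maximum aspect ratio (default 10).
#' @return Data frame with one row per axon: `minor`, `major` (outer
#'   ellipse, μm), `minor_inner`, `major_inner` (lumen ellipse), `angle_deg`
#'   in `[0, 180)`, `ar`, `theta_deg`.
#' @examples
#' ax <- data.frame(axis_x = sin(pi / 3), axis_y = 0, axis_z = cos(pi / 3),
#'                  outer_diameter = 1, inner_diameter = 0.6)
#' intersect_with_plane(ax)  # minor 1, major 2, AR 2
#' @export
intersect_with_plane <- function(axons, cap_ar = 10) {
  if (!is.data.frame(axons)) axons <- as.data.frame(axons)
  if (cap_ar < 1) stop("cap_ar must be >= 1")
  cz <- abs(axons$axis_z)
  if (any(cz < 1e-12))
    stop(sum(cz < 1e-12), " axon(s) lie exactly in the section plane ",
         "(theta = 90 deg): no bounded intersection")
  ar <- pmin(1 / cz, cap_ar)
  inplane <- sqrt(axons$axis_x^2 + axons$axis_y^2)
  ang <- ifelse(inplane < 1e-12, 0,
                atan2(axons$axis_y, axons$axis_x) * 180 / pi) %% 180
  data.frame(minor = axons$outer_diameter,
             major = axons$outer_diameter * ar,
             minor_inner = axons$inner_diameter,
             major_inner = axons$inner_diameter * ar,
             angle_deg = ang,
             ar = ar,
             theta_deg = acos(pmin(1, cz)) * 180 / pi)
}
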