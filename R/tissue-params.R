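#' Tissue generation parameters
#'
#' Bundles everything needed to generate a ground-truth axon population and
#' render it as a cross-section micrograph: the target areal fraction, the
#' outer-diameter law, the g-ratio law, the 3D orientation law, field geometry
#' and pixel size.
#'
#' @details
#' The outer-diameter law is a two-population mixture reflecting the
#' short-range/long-range composition of subcortical white matter: a
#' truncated log-normal thin/medium component and a thick/extra-large
#' component shifted to start at the thick-class boundary
#' (`1.51 + Weibull(shape, scale)` μm). The mixture weight of the thick
#' component equals the thick-class fraction, so the mean outer diameter and
#' the thick-axon proportion can be controlled independently (see
#' [solve_diameter_law()]).
#'
#' The orientation law is a mixture of Watson-type axial concentrations.
#' Each component has a mean axis given by `tilt_deg` (polar angle from the
#' section normal) and `azimuth_deg` (in-plane direction), a concentration
#' `kappa >= 0` (0 = isotropic) and a `weight`. Deep white matter is well
#' described by a single high-concentration tilted component (parallel
#' fibers); superficial white matter by a low-concentration mixture of
#' several azimuths (heterogeneous trajectories).
#'
#' @param compartment `"SWM"` or `"DWM"`.
#' @param target_areal_fraction Fraction of the field to be covered by outer
#'   profiles, in `[0, 0.6)` (random sequential placement becomes infeasible
#'   beyond that).
#' @param diameter_law List describing the outer-diameter mixture; see
#'   [solve_diameter_law()]. Fields: `mean_thin`, `sd_log_thin`,
#'   `weight_thick`, `thick_shift`, `thick_shape`, `thick_scale`,
#'   `min_diameter`, `max_diameter`.
#' @param g_ratio_law List with `mean`, `sd`, `size_slope` (per μm of outer
#'   diameter, centered on `ref_diameter`), `ref_diameter`, and clip limits
#'   `lo`, `hi`.
#' @param orientation_law List of components, each a list with `weight`,
#'   `tilt_deg`, `azimuth_deg`, `kappa`.
#' @param field_size Side of the square field, μm.
#' @param pixel_size μm per pixel.
#' @param flux_weighting Logical; if `TRUE` (default) axons are sampled with
#'   probability proportional to \eqn{|\cos\theta|}, the physically correct
#'   plane-sampling of a line process. Switch off for closed-form tests.
#' @param cap_ar Maximum profile aspect ratio; near-in-plane axons produce
#'   finite elongated profiles (finite section thickness truncates real
#'   profiles). Default 10.
#' @param modality `"EM-like"` or `"LM-like"` (affects default pixel size and
#'   the minimum renderable diameter).
#' @param seed Optional integer seed; if given, generation is reproducible.
#'
#' @return An object of class `tissue_params` (a validated list).
#' @seealso [tissue_preset()], [sample_axon_population()],
#'   [render_micrograph()]
#' @export
tissue_params <- function(compartment = c("SWM", "DWM"),
                          target_areal_fraction = 0.34,
                          diameter_law = solve_diameter_law(0.77, 0.30),
                          g_ratio_law = list(mean = 0.6, sd = 0.05,
                                             size_slope = 0.02,
                                             ref_diameter = 1,
                                             lo = 0.3, hi = 0.95),
                          orientation_law = list(list(weight = 1,
                                                      tilt_deg = 65,
                                                      azimuth_deg = 0,
                                                      kappa = 40)),
                          field_size = 30,
                          pixel_size = 0.01,
                          flux_weighting = TRUE,
                          cap_ar = 10,
                          modality = c("EM-like", "LM-like"),
                          seed = NULL) {
  compartment <- match.arg(compartment)
  modality <- match.arg(modality)
  stopifnot(is.numeric(target_areal_fraction), length(target_areal_fraction) == 1)
  if (target_areal_fraction < 0 || target_areal_fraction >= 0.6)
    stop("target_areal_fraction must lie in [0, 0.6): dart-throwing placement ",
         "cannot reach denser packings")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (pixel_size > diameter_law$min_diameter / 2)
    stop("pixel_size must not exceed half the thinnest outer diameter (",
         diameter_law$min_diameter / 2, " um); thin profiles would vanish")
  if (cap_ar < 1) stop("cap_ar must be >= 1")
  w <- vapply(orientation_law, function(co) co$weight, numeric(1))
  if (any(w < 0) || sum(w) <= 0) stop("orientation component weights invalid")
  if (any(vapply(orientation_law, function(co) co$kappa, numeric(1)) < 0))
    stop("orientation kappa must be >= 0")
  structure(list(compartment = compartment,
                 target_areal_fraction = target_areal_fraction,
                 diameter_law = diameter_law,
                 g_ratio_law = g_ratio_law,
                 orientation_law = orientation_law,
                 field_size = field_size,
                 pixel_size = pixel_size,
                 flux_weighting = isTRUE(flux_weighting),
                 cap_ar = cap_ar,
                 modality = modality,
                 seed = seed),
            class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat("<tissue_params>", x$compartment, "/", x$modality, "\n")
  cat("  target areal fraction:", x$target_areal_fraction, "\n")
  cat("  field:", x$field_size, "x", x$field_size, "um at",
      x$pixel_size, "um/px\n")
  cat("  flux weighting:", x$flux_weighting, "; AR cap:", x$cap_ar, "\n")
  invisible(x)
}

#' Solve the two-population outer-diameter law from published summaries
#'
#' White-matter axon calibers are summarised in the literature by a mean
#' outer diameter together with the fraction of thick/extra-large axons
#' (outer diameter above 1.51 μm). No unimodal log-normal can satisfy both
#' (e.g. a mean of 0.77 μm admits at most ~12% of mass above 1.51 μm), so
#' the generator uses a two-population mixture: a log-normal thin/medium
#' component and a long-range thick component `1.51 + Weibull(shape, scale)`.
#' The mixture weight equals the thick fraction exactly, and the thin
#' component mean is solved from the target mean.
#'
#' @param mean_outer Target population mean outer diameter, μm.
#' @param thick_fraction Target fraction of axons thicker than 1.51 μm,
#'   in `(0, 0.5)`.
#' @param sd_log_thin Log-scale SD of the thin/medium component.
#' @param thick_shape,thick_scale Weibull shape/scale of the thick excess
#'   over 1.51 μm.
#' @param min_diameter,max_diameter Truncation limits, μm (observed axon
#'   range 0.1–9.7 μm).
#' @return A `diameter_law` list usable in [tissue_params()].
#' @export
solve_diameter_law <- function(mean_outer, thick_fraction,
                               sd_log_thin = 0.38,
                               thick_shape = 0.9, thick_scale = 0.30,
                               min_diameter = 0.1, max_diameter = 9.7) {
  stopifnot(thick_fraction >= 0, thick_fraction < 0.5, mean_outer > min_diameter)
  thick_mean <- 1.51 + thick_scale * gamma(1 + 1 / thick_shape)
  mean_thin <- (mean_outer - thick_fraction * thick_mean) / (1 - thick_fraction)
  if (mean_thin < min_diameter * 1.2)
    stop("infeasible diameter law: mean_outer = ", mean_outer,
         " with thick_fraction = ", thick_fraction,
         " leaves thin-component mean ", round(mean_thin, 3), " um")
  list(mean_thin = mean_thin,
       sd_log_thin = sd_log_thin,
       weight_thick = thick_fraction,
       thick_shift = 1.51,
       thick_shape = thick_shape,
       thick_scale = thick_scale,
       min_diameter = min_diameter,
       max_diameter = max_diameter)
}

#' Compartment presets for synthetic white matter
#'
#' Named presets carrying the published compartment summaries: areal
#' fractions 0.34 (CTR-SWM), 0.39 (CTR-DWM), 0.28 (ASD-SWM), 0.35 (ASD-DWM);
#' mean outer diameters 0.77, 0.93, 0.73 and 0.90 μm respectively; thick
#' fraction 0.30 so that thin+medium axons make up ~70% of the population;
#' mean g-ratio 0.6 with a positive size slope. Orientation presets encode
#' parallel deep-white-matter fibers (single tilted high-concentration
#' component) versus heterogeneous superficial trajectories (low-concentration
#' mixture of azimuths); they are tuned to reproduce the ordering
#' SD(SWM) > SD(DWM) of per-image angle dispersion, not absolute values.
#'
#' @param name One of `"CTR-SWM"`, `"CTR-DWM"`, `"ASD-SWM"`, `"ASD-DWM"`.
#' @param modality `"EM-like"` (0.01 μm/px) or `"LM-like"` (0.1 μm/px,
#'   minimum renderable diameter 0.25 μm).
#' @param field_size Field side in μm (default 20 for EM-like, 45 for
#'   LM-like).
#' @param seed Optional seed stored in the params.
#' @return A [tissue_params()] object.
#' @export
tissue_preset <- function(name = c("CTR-SWM", "CTR-DWM", "ASD-SWM", "ASD-DWM"),
                          modality = c("EM-like", "LM-like"),
                          field_size = NULL, seed = NULL) {
  name <- match.arg(name)
  modality <- match.arg(modality)
  tab <- list(
    "CTR-SWM" = list(comp = "SWM", af = 0.34, mean_outer = 0.77),
    "CTR-DWM" = list(comp = "DWM", af = 0.39, mean_outer = 0.93),
    "ASD-SWM" = list(comp = "SWM", af = 0.28, mean_outer = 0.73),
    "ASD-DWM" = list(comp = "DWM", af = 0.35, mean_outer = 0.90))[[name]]
  px <- if (modality == "EM-like") 0.01 else 0.1
  min_d <- if (modality == "EM-like") 0.1 else 0.25
  if (is.null(field_size)) field_size <- if (modality == "EM-like") 20 else 120
  law <- solve_diameter_law(tab$mean_outer, 0.30, min_diameter = min_d)
  tissue_params(compartment = tab$comp,
                target_areal_fraction = tab$af,
                diameter_law = law,
                orientation_law = orientation_preset(tab$comp),
                field_size = field_size,
                pixel_size = px,
                modality = modality,
                seed = seed)
}

#' Orientation-law presets for the two white-matter compartments
#'
#' DWM: one tilted, highly concentrated Watson component (fibers traveling
#' in parallel). SWM: a balanced mixture of three azimuths with low
#' concentration (heterogeneous, branching trajectories). Both are tilted
#' away from the section normal so that a usable fraction (~30%) of profiles
#' is elongated (AR >= 3).
#'
#' @param compartment `"SWM"` or `"DWM"`.
#' @return A list of orientation components for [tissue_params()].
#' @export
orientation_preset <- function(compartment = c("SWM", "DWM")) {
  compartment <- match.arg(compartment)
  if (compartment == "DWM") {
    list(list(weight = 1, tilt_deg = 69, azimuth_deg = 0, kappa = 45))
  } else {
    list(list(weight = 0.4, tilt_deg = 73, azimuth_deg = 0,   kappa = 7),
         list(weight = 0.3, tilt_deg = 71, azimuth_deg = 55,  kappa = 7),
         list(weight = 0.3, tilt_deg = 75, azimuth_deg = 120, kappa = 7))
  }
}
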