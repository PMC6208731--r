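## Developmental cohort simulation ------------------------------------------

#' Specification of a simulated developmental cohort
#'
#' Defines two (or more) diagnostic groups sampled in three age bands —
#' children 3–10 y, teenagers 14–15 y, adults 30–67 y — with per-group
#' linear age laws for the tissue parameters that the generator controls
#' directly: areal fraction, mean outer diameter, thick-class fraction and
#' mean g-ratio, each per compartment, plus case-level residual noise.
#'
#' The default laws encode the published developmental signature: the
#' control group is flat in axon thickness and g-ratio with mildly rising
#' density and thick fraction, while the contrast group starts (in
#' childhood) with similar axon calibers but a lower superficial-white-matter
#' density, then declines with age in mean diameter, thick fraction and
#' g-ratio. Intercepts reproduce the published compartment means when pooled
#' over the cohort's age range.
#'
#' @param groups Group labels; first is the reference (default
#'   `c("CTR", "ASD")`).
#' @param n_children,n_teens,n_adults Cases per group per age band (teens
#'   are descriptive only in band analyses but enter trajectory fits).
#' @param age_bands List of band age ranges in years.
#' @param laws Named list per group; each group is a list per compartment
#'   (`SWM`, `DWM`) of lists with `areal_fraction`, `mean_outer`,
#'   `thick_fraction`, `g_mean`, each `c(intercept, slope_per_year)`.
#' @param noise Case-level residual SDs:
#'   `c(areal_fraction, mean_outer, thick_fraction, g_mean)`.
#' @param images_per_case Images per case per compartment (2–3).
#' @param profiles_per_image Expected profiles per image in table mode
#'   (about 2000 in the emulated protocol).
#' @param seed Optional seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = c("CTR", "ASD"),
                        n_children = 9, n_teens = 2, n_adults = 6,
                        age_bands = list(children = c(3, 10),
                                         teens = c(14, 15),
                                         adults = c(30, 67)),
                        laws = default_cohort_laws(),
                        noise = c(areal_fraction = 0.03,
                                  mean_outer = 0.04,
                                  thick_fraction = 0.025,
                                  g_mean = 0.008),
                        images_per_case = 2,
                        profiles_per_image = 2000,
                        seed = NULL) {
  if (length(groups) < 2) stop("need at least two groups")
  if (min(n_children + n_teens + n_adults) < 2)
    stop("need at least 2 cases per group: no statistics possible")
  if (!all(groups %in% names(laws)))
    stop("laws must be provided for every group")
  if (images_per_case < 1 || images_per_case > 3)
    stop("images_per_case must be 1-3")
  structure(list(groups = groups, n_children = n_children,
                 n_teens = n_teens, n_adults = n_adults,
                 age_bands = age_bands, laws = laws, noise = noise,
                 images_per_case = images_per_case,
                 profiles_per_image = profiles_per_image, seed = seed),
            class = "cohort_spec")
}

#' Default opposite-trajectory cohort laws
#'
#' Control group flat in caliber and g-ratio, contrast (ASD-like) group with
#' a childhood superficial density deficit and negative age slopes for mean
#' diameter, thick fraction and g-ratio. Values are
#' `c(intercept, slope_per_year)`.
#' @return Nested list usable as the `laws` argument of [cohort_spec()].
#' @export
default_cohort_laws <- function() {
  list(
    CTR = list(
      SWM = list(areal_fraction = c(0.315, 0.0008),
                 mean_outer = c(0.77, 0),
                 thick_fraction = c(0.16, 0.0012),
                 g_mean = c(0.60, 0)),
      DWM = list(areal_fraction = c(0.365, 0.0010),
                 mean_outer = c(0.93, 0),
                 thick_fraction = c(0.20, 0.0012),
                 g_mean = c(0.60, 0))),
    ASD = list(
      SWM = list(areal_fraction = c(0.245, 0.0012),
                 mean_outer = c(0.80, -0.0035),
                 thick_fraction = c(0.21, -0.0018),
                 g_mean = c(0.625, -0.0009)),
      DWM = list(areal_fraction = c(0.325, 0.0010),
                 mean_outer = c(0.97, -0.0035),
                 thick_fraction = c(0.25, -0.0018),
                 g_mean = c(0.625, -0.0009))))
}

lin <- function(cf, age) cf[1] + cf[2] * age

#' Generate a simulated developmental cohort
#'
#' Draws cases per group and age band, derives each case's per-compartment
#' tissue parameters from the group age laws plus case-level noise, and
#' produces per-profile measurement tables for 2–3 images per case per
#' compartment. In `mode = "table"` the profile tables are the generator's
#' ground-truth plane intersections (no rendering); in `mode = "render"`
#' each image is rendered as a micrograph and measured through the
#' segmentation pipeline, exercising the full image chain.
#'
#' @param spec A [cohort_spec()].
#' @param mode `"table"` (fast, ground-truth profiles) or `"render"`
#'   (render + segment + measure).
#' @param compartments Compartments to generate.
#' @param render_field,render_pixel Field size and pixel size (μm) used in
#'   render mode; the default 30 μm at 0.05 μm/px yields several hundred
#'   profiles per image with resolvable thin axons.
#' @return List of class `cohort`: `cases` (case id, group, age, sex, PMI,
#'   other diagnoses), `profiles` (per-profile table with `case`,
#'   `compartment`, `image` columns), `field_areas` (per image, μm²;
#'   `NA` in table mode where density comes from truth), `ground_truth`
#'   (per case x compartment generating values), `spec`.
#' @export
generate_cohort <- function(spec, mode = c("table", "render"),
                            compartments = c("SWM", "DWM"),
                            render_field = 30, render_pixel = 0.05) {
  stopifnot(inherits(spec, "cohort_spec"))
  mode <- match.arg(mode)
  if (!is.null(spec$seed)) set.seed(spec$seed)

  cases <- do.call(rbind, lapply(spec$groups, function(g) {
    ages <- c(stats::runif(spec$n_children, spec$age_bands$children[1],
                           spec$age_bands$children[2]),
              stats::runif(spec$n_teens, spec$age_bands$teens[1],
                           spec$age_bands$teens[2]),
              stats::runif(spec$n_adults, spec$age_bands$adults[1],
                           spec$age_bands$adults[2]))
    data.frame(case = sprintf("%s-%02d", g, seq_along(ages)),
               group = g, age = ages,
               sex = sample(c("M", "F"), length(ages), replace = TRUE,
                            prob = c(0.75, 0.25)),
               pmi = round(pmin(stats::rgamma(length(ages), shape = 4,
                                              scale = 5), 99), 1),
               other_dx = stats::rbinom(length(ages), 1, 0.15))
  }))
  rownames(cases) <- NULL

  prof_list <- list(); gt_list <- list(); fa_list <- list()
  for (i in seq_len(nrow(cases))) {
    for (comp in compartments) {
      law <- spec$laws[[cases$group[i]]][[comp]]
      af <- clamp(lin(law$areal_fraction, cases$age[i]) +
                    stats::rnorm(1, 0, spec$noise["areal_fraction"]),
                  0.05, 0.55)
      mo <- clamp(lin(law$mean_outer, cases$age[i]) +
                    stats::rnorm(1, 0, spec$noise["mean_outer"]),
                  0.35, 2.0)
      tf <- clamp(lin(law$thick_fraction, cases$age[i]) +
                    stats::rnorm(1, 0, spec$noise["thick_fraction"]),
                  0.02, 0.45)
      gm <- clamp(lin(law$g_mean, cases$age[i]) +
                    stats::rnorm(1, 0, spec$noise["g_mean"]),
                  0.40, 0.80)
      min_d <- if (mode == "render") max(0.2, 2 * render_pixel) else 0.1
      dlaw <- solve_diameter_law(mo, tf, min_diameter = min_d)
      params <- tissue_params(compartment = comp,
                              target_areal_fraction = af,
                              diameter_law = dlaw,
                              g_ratio_law = list(mean = gm, sd = 0.05,
                                                 size_slope = 0.02,
                                                 ref_diameter = mo,
                                                 lo = 0.3, hi = 0.95),
                              orientation_law = orientation_preset(comp),
                              field_size = render_field,
                              pixel_size = if (mode == "render") render_pixel
                                           else 0.05,
                              modality = "EM-like")
      gt_list[[length(gt_list) + 1]] <-
        data.frame(case = cases$case[i], compartment = comp,
                   group = cases$group[i], age = cases$age[i],
                   areal_fraction = af, mean_outer = mo,
                   thick_fraction = tf, g_mean = gm)
      for (im in seq_len(spec$images_per_case)) {
        img_id <- sprintf("%s_%s_im%d", cases$case[i], comp, im)
        if (mode == "table") {
          n <- stats::rpois(1, spec$profiles_per_image)
          pop <- sample_axon_population(params, n = n, place = FALSE)
          e <- pop$ellipses
          p <- data.frame(image = img_id,
                          outer_diameter = e$minor,
                          inner_diameter = e$minor_inner,
                          major_diameter = e$major,
                          minor_diameter = e$minor,
                          myelin_thickness = (e$minor - e$minor_inner) / 2,
                          g_ratio = e$minor_inner / e$minor,
                          ar = e$ar, angle_deg = e$angle_deg,
                          true_areal_fraction = af)
          # nominal field area consistent with the true areal fraction, so
          # density features are defined without rendering
          fa <- sum(pi / 4 * e$major * e$minor) / af
        } else {
          pop <- sample_axon_population(params)
          mg <- render_micrograph(pop, params, id = img_id)
          mm <- measure_image(mg, id = img_id)
          p <- mm$profiles
          p$true_areal_fraction <- pop$ground_truth$achieved_areal_fraction
          fa <- mm$field_area
        }
        p$case <- cases$case[i]; p$compartment <- comp
        prof_list[[length(prof_list) + 1]] <- p
        fa_list[[length(fa_list) + 1]] <-
          data.frame(image = img_id, field_area = fa)
      }
    }
  }
  profiles <- do.call(rbind, prof_list)
  structure(list(cases = cases,
                 profiles = profiles,
                 field_areas = do.call(rbind, fa_list),
                 ground_truth = do.call(rbind, gt_list),
                 spec = spec, mode = mode),
            class = "cohort")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", nrow(x$cases), "cases (",
      paste(unique(x$cases$group), collapse = ", "), ");",
      nrow(x$profiles), "profiles (", x$mode, "mode )\n")
  invisible(x)
}
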