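## g-ratio, thickness classes and the 16-dimension feature vector ----------

#' g-ratio (inner/outer diameter)
#'
#' The g-ratio is the inner (axolemma) diameter divided by the outer
#' (myelin-included) diameter; values near 0.6 are conduction-optimal.
#'
#' @param inner,outer Diameters in μm, vectorised; `0 <= inner <= outer`,
#'   `outer > 0`.
#' @return Numeric vector of ratios in `[0, 1]`.
#' @examples
#' g_ratio(0.6, 1.0)   # 0.6
#' g_ratio(0.84, 1.4)  # 0.6
#' @export
g_ratio <- function(inner, outer) {
  if (any(outer <= 0)) stop("outer diameter must be positive")
  if (any(inner < 0)) stop("inner diameter must be non-negative")
  if (any(inner > outer + 1e-12))
    stop("inner diameter exceeds outer diameter: measurement defect upstream")
  pmin(inner / outer, 1)
}

#' Reference thickness-class boundaries (μm)
#'
#' Published pooled-cohort boundaries between thin/medium, medium/thick and
#' thick/extra-large axons. Classification with these fixed boundaries is
#' reproducible across cohorts; re-clustering a new cohort is an explicit
#' choice via [kmeans_1d()].
#' @export
reference_boundaries <- c(thin_medium = 0.83, medium_thick = 1.51,
                          thick_xl = 2.65)

size_class_labels <- c("thin", "medium", "thick", "extra_large")

#' Exact one-dimensional k-means size-class model
#'
#' Clusters outer diameters into `k` thickness groups. The default method is
#' the exact dynamic program over contiguous partitions of the sorted values
#' (in 1D the globally optimal k-means clusters are contiguous), which
#' guarantees the minimum within-cluster sum of squares. `method = "lloyd"`
#' gives the classic heuristic with deterministic farthest-point (maximin)
#' initialisation, which maximises initial between-cluster distances but can
#' stall in local optima on skewed diameter data. Class boundaries are the
#' midpoints between adjacent final cluster means (published class ranges
#' are contiguous, so midpoints are the reproducible analogue of data-gap
#' boundaries).
#'
#' @param x Numeric vector of outer diameters (μm); needs at least `k`
#'   distinct values.
#' @param k Number of classes (default 4: thin, medium, thick, extra-large).
#' @param method `"dp"` (exact, default) or `"lloyd"` (maximin-initialised
#'   Lloyd's algorithm).
#' @param max_iter Iteration cap for `"lloyd"`.
#' @return Object of class `size_class_model`: `means` (ascending),
#'   `boundaries` (k-1 cut points), `labels`, `sse`, `sizes`, `method`.
#' @examples
#' m <- kmeans_1d(c(0.2, 0.25, 1.0, 1.05, 2.0, 2.05, 5.0, 5.1))
#' m$means
#' @export
kmeans_1d <- function(x, k = 4, method = c("dp", "lloyd"), max_iter = 200) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  if (length(unique(x)) < k)
    stop("need at least ", k, " distinct values for ", k, " clusters; got ",
         length(unique(x)))
  xs <- sort(x)
  n <- length(xs)
  if (method == "dp") {
    cs <- cumsum(xs); cs2 <- cumsum(xs^2)
    seg_sse <- function(i, j) {
      s <- cs[j] - if (i > 1) cs[i - 1] else 0
      s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
      max(s2 - s^2 / (j - i + 1), 0)
    }
    D <- matrix(Inf, k, n)
    B <- matrix(0L, k, n)
    for (j in 1:n) D[1, j] <- seg_sse(1, j)
    if (k > 1) for (q in 2:k) {
      for (j in q:n) {
        best <- Inf; bi <- q
        for (i in q:j) {
          v <- D[q - 1, i - 1] + seg_sse(i, j)
          if (v < best) { best <- v; bi <- i }
        }
        D[q, j] <- best; B[q, j] <- bi
      }
    }
    cuts <- integer(k + 1); cuts[k + 1] <- n
    j <- n
    if (k > 1) for (q in k:2) { cuts[q] <- B[q, j] - 1L; j <- B[q, j] - 1L }
    means <- vapply(1:k, function(q) mean(xs[(cuts[q] + 1):(cuts[q + 1])]),
                    numeric(1))
    sizes <- diff(cuts)
    sse <- D[k, n]
  } else {
    centers <- numeric(k)
    centers[1] <- xs[which.max(abs(xs - mean(xs)))]
    if (k > 1) for (q in 2:k) {
      d <- vapply(xs, function(v) min(abs(v - centers[1:(q - 1)])), numeric(1))
      centers[q] <- xs[which.max(d)]
    }
    centers <- sort(centers)
    assign <- NULL
    for (it in seq_len(max_iter)) {
      a <- max.col(-abs(outer(xs, centers, "-")), ties.method = "first")
      if (identical(a, assign)) break
      assign <- a
      centers <- sort(vapply(1:k, function(q)
        if (any(a == q)) mean(xs[a == q]) else centers[q], numeric(1)))
    }
    means <- centers
    sizes <- tabulate(assign, k)
    sse <- sum((xs - centers[assign])^2)
  }
  structure(list(means = means,
                 boundaries = (means[-k] + means[-1]) / 2,
                 labels = if (k == 4) size_class_labels
                          else paste0("class", 1:k),
                 sse = sse, sizes = sizes, n = n, method = method),
            class = "size_class_model")
}

#' @export
print.size_class_model <- function(x, ...) {
  cat("<size_class_model>", length(x$means), "classes (", x$method, ")\n")
  cat("  means (um):", paste(round(x$means, 3), collapse = ", "), "\n")
  cat("  boundaries (um):", paste(round(x$boundaries, 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Classify outer diameters into thickness classes
#'
#' Half-open, lower-exclusive intervals: thin `(0, b1]`, medium `(b1, b2]`,
#' thick `(b2, b3]`, extra-large `(b3, Inf)`. With the default
#' [reference_boundaries] (0.83 / 1.51 / 2.65 μm), 0.83 is thin and 0.84 is
#' medium, matching the published class ranges.
#'
#' @param outer Outer diameters, μm (> 0).
#' @param model A `size_class_model`, or a numeric vector of boundaries
#'   (default [reference_boundaries]).
#' @return Factor of class labels.
#' @examples
#' classify_by_boundaries(c(0.5, 0.84, 3.0))  # thin, medium, extra_large
#' @export
classify_by_boundaries <- function(outer, model = reference_boundaries) {
  if (any(outer <= 0, na.rm = TRUE)) stop("outer diameters must be positive")
  b <- if (inherits(model, "size_class_model")) model$boundaries else model
  labs <- if (inherits(model, "size_class_model")) model$labels
          else size_class_labels[seq_len(length(b) + 1)]
  cut(outer, breaks = c(0, b, Inf), labels = labs, right = TRUE)
}

#' Per-class proportions of axon thickness
#'
#' @param outer Outer diameters (μm) or a profile data frame with an
#'   `outer_diameter` column.
#' @param model Boundaries or `size_class_model` (see
#'   [classify_by_boundaries()]).
#' @return Named numeric vector of class fractions summing to 1.
#' @export
class_proportions <- function(outer, model = reference_boundaries) {
  if (is.data.frame(outer)) outer <- outer$outer_diameter
  outer <- outer[is.finite(outer) & outer > 0]
  if (!length(outer)) stop("no valid outer diameters to classify")
  tab <- table(classify_by_boundaries(outer, model))
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p
}

#' Assemble the 16-dimension morphometric feature vector
#'
#' One row per case x compartment with the 16 morphometric features of
#' myelinated axons: areal density of all profiles (`density_all`), areal
#' density of elongated profiles only (`density_elongated`, AR >= ar_threshold),
#' mean outer/inner/major diameters (μm), axon orientation dispersion
#' (`orientation_sd_deg`, the per-case mean of per-image peak-aligned angle
#' SDs), mean myelin thickness (μm), mean g-ratio, four thickness-class
#' proportions, and mean myelin thickness within each of the four classes
#' (`NA` marks an empty class). Missing compartments yield a row of `NA`
#' markers.
#'
#' @param profiles Per-profile data frame with columns `case`,
#'   `compartment`, `image`, `outer_diameter`, `inner_diameter`,
#'   `major_diameter`, `minor_diameter`, `myelin_thickness`, `g_ratio`,
#'   `ar`, `angle_deg`.
#' @param field_areas Data frame `image`, `field_area` (μm²) or a single
#'   number applying to every image.
#' @param boundaries Class boundaries (default [reference_boundaries]).
#' @param ar_threshold Elongation cutoff for the orientation-bearing subset
#'   (default 3).
#' @param compartments Compartments every case is expected to have.
#' @return Data frame, one row per case x compartment, 16 feature columns.
#' @export
feature_table <- function(profiles, field_areas,
                          boundaries = reference_boundaries,
                          ar_threshold = 3,
                          compartments = c("SWM", "DWM")) {
  stopifnot(all(c("case", "compartment", "image") %in% names(profiles)))
  if (is.numeric(field_areas) && length(field_areas) == 1) {
    field_areas <- data.frame(image = unique(profiles$image),
                              field_area = field_areas)
  }
  cases <- unique(profiles$case)
  grid <- expand.grid(case = cases, compartment = compartments,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- profiles[profiles$case == grid$case[i] &
                  profiles$compartment == grid$compartment[i], ]
    out <- data.frame(case = grid$case[i], compartment = grid$compartment[i])
    feats <- setNames(rep(NA_real_, 16), feature_names())
    if (nrow(p)) {
      imgs <- unique(p$image)
      fa <- field_areas$field_area[match(imgs, field_areas$image)]
      dens_all <- vapply(seq_along(imgs), function(j) {
        pi_ <- p[p$image == imgs[j], ]
        sum(pi / 4 * pi_$major_diameter * pi_$minor_diameter) / fa[j]
      }, numeric(1))
      dens_el <- vapply(seq_along(imgs), function(j) {
        pi_ <- p[p$image == imgs[j] & p$ar >= ar_threshold, ]
        sum(pi / 4 * pi_$major_diameter * pi_$minor_diameter) / fa[j]
      }, numeric(1))
      cls <- classify_by_boundaries(p$outer_diameter, boundaries)
      prop <- as.numeric(table(cls)) / nrow(p)
      myel_by <- tapply(p$myelin_thickness, cls, mean)
      orient <- orientation_summary(p, ar_threshold = ar_threshold)
      feats[] <- c(mean(dens_all), mean(dens_el),
                   mean(p$outer_diameter), mean(p$inner_diameter),
                   mean(p$major_diameter),
                   mean(orient$per_image$sd_deg, na.rm = TRUE),
                   mean(p$myelin_thickness), mean(p$g_ratio, na.rm = TRUE),
                   prop, as.numeric(myel_by))
    }
    cbind(out, as.data.frame(as.list(feats)))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

feature_names <- function() {
  c("density_all", "density_elongated", "outer_diameter", "inner_diameter",
    "major_diameter", "orientation_sd_deg", "myelin_thickness", "g_ratio",
    "prop_thin", "prop_medium", "prop_thick", "prop_extra_large",
    "myelin_thin", "myelin_medium", "myelin_thick", "myelin_extra_large")
}
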