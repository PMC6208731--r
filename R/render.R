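## Ellipse rasterisation and non-overlapping placement ----------------------

# Pixel index set of an ellipse on a field_px x field_px grid.
# Centre (cx, cy) in um, semi-axes (a, b) in um, angle in degrees.
# Pixel centres sit at ((col - 0.5) * px, (row - 0.5) * px); x runs along
# columns, y along rows. Returns integer vector of linear indices
# (row-major into a matrix with nrow = field_px), possibly empty.
ellipse_pixels <- function(cx, cy, a, b, angle_deg, field_px, px,
                           inflate_px = 0) {
  a <- a + inflate_px * px
  b <- b + inflate_px * px
  r <- max(a, b)
  c0 <- max(1L, floor((cx - r) / px)); c1 <- min(field_px, ceiling((cx + r) / px) + 1L)
  r0 <- max(1L, floor((cy - r) / px)); r1 <- min(field_px, ceiling((cy + r) / px) + 1L)
  if (c0 > c1 || r0 > r1) return(integer(0))
  cols <- c0:c1; rows <- r0:r1
  xs <- (cols - 0.5) * px - cx
  ys <- (rows - 0.5) * px - cy
  ca <- cos(angle_deg * pi / 180); sa <- sin(angle_deg * pi / 180)
  X <- matrix(xs, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  Y <- matrix(ys, nrow = length(rows), ncol = length(cols))
  u <- ca * X + sa * Y
  v <- -sa * X + ca * Y
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(inside)) return(integer(0))
  ij <- which(inside, arr.ind = TRUE)
  (cols[ij[, 2]] - 1L) * field_px + rows[ij[, 1]]
}

# Random sequential (dart-throwing) placement of ellipses without overlap.
# Ellipses are tried largest-first (standard packing practice; the set of
# profiles itself is i.i.d. from the tissue law). A 2-px exclusion margin
# keeps neighbouring annuli separable by connected-component labelling.
# Profiles that cannot fit the field (near-in-plane thick axons whose
# capped ellipse exceeds the field — in a real micrograph these would only
# appear clipped) or that find no free position within the attempt budget
# are skipped and reported; the caller replaces them to reach the target.
place_ellipses <- function(ellipses, field_px, px, mask = NULL,
                           max_attempts_per = 4000, margin_px = 2) {
  n <- nrow(ellipses)
  ord <- order(ellipses$major * ellipses$minor, decreasing = TRUE)
  if (is.null(mask)) mask <- matrix(FALSE, field_px, field_px)
  xs <- ys <- rep(NA_real_, n)
  placed <- logical(n)
  oversize <- 0L; unplaced <- 0L
  field_um <- field_px * px
  for (i in seq_len(n)) {
    e <- ellipses[ord[i], ]
    a <- e$major / 2; b <- e$minor / 2
    ca <- abs(cos(e$angle_deg * pi / 180)); sa <- abs(sin(e$angle_deg * pi / 180))
    # tight half-extents of the rotated ellipse bounding box
    hx <- sqrt((a * ca)^2 + (b * sa)^2) + (margin_px + 1) * px
    hy <- sqrt((a * sa)^2 + (b * ca)^2) + (margin_px + 1) * px
    if (2 * hx >= field_um || 2 * hy >= field_um) {
      oversize <- oversize + 1L
      next
    }
    for (att in seq_len(max_attempts_per)) {
      cx <- stats::runif(1, hx, field_um - hx)
      cy <- stats::runif(1, hy, field_um - hy)
      test_idx <- ellipse_pixels(cx, cy, a, b, e$angle_deg, field_px, px,
                                 inflate_px = margin_px)
      if (!any(mask[test_idx])) {
        paint <- ellipse_pixels(cx, cy, a, b, e$angle_deg, field_px, px)
        mask[paint] <- TRUE
        xs[ord[i]] <- cx; ys[ord[i]] <- cy
        placed[ord[i]] <- TRUE
        break
      }
    }
    if (!placed[ord[i]] && 2 * hx < field_um && 2 * hy < field_um)
      unplaced <- unplaced + 1L
  }
  list(placed = placed, x = xs, y = ys, mask = mask,
       n_oversize = oversize, n_unplaced = unplaced,
       achieved_fraction = sum(mask) / length(mask))
}

## Micrograph container -----------------------------------------------------

#' Construct a micrograph object
#'
#' A micrograph is a numeric matrix of grayscale intensities in `[0, 1]`
#' (rows = y, columns = x, pixel centres at `(index - 0.5) * pixel_size` μm)
#' with pixel-size and modality metadata.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`.
#' @param pixel_size μm per pixel (> 0).
#' @param modality `"EM-like"` or `"LM-like"`.
#' @param id Optional identifier string.
#' @return Object of class `micrograph`.
#' @export
micrograph <- function(pixels, pixel_size, modality = "EM-like", id = NULL) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)), pixel_size > 0)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 modality = modality, id = id),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat("<micrograph>", if (!is.null(x$id)) x$id else "", "\n")
  cat(" ", nrow(x$pixels), "x", ncol(x$pixels), "px at", x$pixel_size,
      "um/px (", x$modality, ")\n")
  invisible(x)
}

#' @export
plot.micrograph <- function(x, ...) {
  op <- graphics::par(mar = c(1, 1, 2, 1)); on.exit(graphics::par(op))
  graphics::image(t(x$pixels), col = grDevices::gray.colors(256, 0, 1), asp = 1,
                  axes = FALSE, main = if (!is.null(x$id)) x$id else "", ...)
  invisible(x)
}

#' Render a cross-section micrograph from a placed axon population
#'
#' Draws each profile as a dark myelin annulus between the outer and inner
#' (lumen) ellipses on a light background, with a lighter lumen — emulating
#' the appearance of electron-dense myelin sheaths in EM and toluidine-blue
#' myelin staining in LM. Optional Gaussian blur and additive noise.
#'
#' @param pop An `axon_population` with placed ellipses (see
#'   [sample_axon_population()]), or a data frame of ellipses with columns
#'   `x`, `y`, `minor`, `major`, `minor_inner`, `major_inner`, `angle_deg`.
#' @param params The [tissue_params()] used (field geometry, pixel size).
#' @param background,myelin,lumen Intensities in `[0, 1]`.
#' @param blur_sigma Gaussian blur SD in pixels (0 = none).
#' @param noise_sd Additive Gaussian noise SD (0 = none).
#' @param id Identifier stored in the micrograph.
#' @return A [micrograph()]; ellipses clipped by the field boundary are
#'   flagged in `attr(, "clipped")`.
#' @export
render_micrograph <- function(pop, params,
                              background = 0.85, myelin = 0.15, lumen = 0.70,
                              blur_sigma = 0, noise_sd = 0, id = NULL) {
  ell <- if (inherits(pop, "axon_population")) pop$ellipses else pop
  field_px <- max(8L, as.integer(round(params$field_size / params$pixel_size)))
  px <- params$pixel_size
  img <- matrix(background, field_px, field_px)
  clipped <- logical(NROW(ell))
  if (NROW(ell)) {
    for (i in seq_len(nrow(ell))) {
      e <- ell[i, ]
      outer_idx <- ellipse_pixels(e$x, e$y, e$major / 2, e$minor / 2,
                                  e$angle_deg, field_px, px)
      ## myelin thinner than ~1 px would break the annulus into fragments;
      ## stain/electron density saturates such sheaths to a full pixel, so
      ## the painted lumen is shrunk to keep a closed >= 1.2 px ring
      b_in <- e$minor_inner / 2
      a_in <- e$major_inner / 2
      ring_px <- (e$minor / 2 - b_in) / px
      if (ring_px < 1.2 && b_in > 0) {
        b_new <- max(e$minor / 2 - 1.2 * px, 0)
        a_in <- a_in * if (b_in > 0) b_new / b_in else 0
        b_in <- b_new
      }
      inner_idx <- if (b_in > 0.3 * px)
        ellipse_pixels(e$x, e$y, a_in, b_in, e$angle_deg, field_px, px)
      else integer(0)
      img[outer_idx] <- myelin
      img[inner_idx] <- lumen
      # flag profiles whose analytic extent leaves the field
      a <- e$major / 2; ca <- abs(cos(e$angle_deg * pi / 180))
      b <- e$minor / 2; sa <- abs(sin(e$angle_deg * pi / 180))
      hx <- sqrt((a * ca)^2 + (b * sa)^2); hy <- sqrt((a * sa)^2 + (b * ca)^2)
      clipped[i] <- (e$x - hx < 0) || (e$x + hx > field_px * px) ||
        (e$y - hy < 0) || (e$y + hy > field_px * px)
    }
  }
  if (blur_sigma > 0) {
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = blur_sigma))
  }
  if (noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                        nrow(img), ncol(img))
  }
  img <- pmin(pmax(img, 0), 1)
  out <- micrograph(img, pixel_size = px, modality = params$modality, id = id)
  attr(out, "clipped") <- clipped
  out
}

#' Simulate a 3D cell population in a tissue slab
#'
#' Homogeneous Poisson point process per cell label at the stated density,
#' for validating stereological estimators. Positions are uniform in the
#' slab; counts are Poisson with mean `density x volume`.
#'
#' @param slab Numeric length-3: width (x), depth (y) in μm and section
#'   thickness (z) in μm.
#' @param densities Named numeric vector of densities in cells/mm^3, e.g.
#'   `c(neuron = 40000, astrocyte = 20000, oligodendrocyte = 25000)`.
#' @param seed Optional seed.
#' @return Object of class `cell_population`: data frame `cells`
#'   (`x`, `y`, `z` in μm, `label`), plus `slab` and the true `densities`.
#' @export
generate_cell_population <- function(slab, densities, seed = NULL) {
  stopifnot(length(slab) == 3, all(slab > 0), all(densities >= 0))
  if (is.null(names(densities)))
    names(densities) <- paste0("label", seq_along(densities))
  if (!is.null(seed)) set.seed(seed)
  vol_mm3 <- prod(slab) / 1e9
  parts <- lapply(names(densities), function(lb) {
    n <- stats::rpois(1, densities[[lb]] * vol_mm3)
    if (n == 0) return(NULL)
    data.frame(x = stats::runif(n, 0, slab[1]),
               y = stats::runif(n, 0, slab[2]),
               z = stats::runif(n, 0, slab[3]),
               label = lb)
  })
  cells <- do.call(rbind, parts)
  if (is.null(cells))
    cells <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        label = character(0))
  structure(list(cells = cells, slab = slab, densities = densities),
            class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  cat("<cell_population>", nrow(x$cells), "cells in",
      paste(x$slab, collapse = " x "), "um slab\n")
  invisible(x)
}
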