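## Optical-fractionator cell-density estimation -----------------------------

#' Optical-fractionator sampling parameters
#'
#' @param frame_side Side of the square counting frame, μm (published range
#'   50–60, default 55).
#' @param disector_height Height of the optical disector, μm (default 5).
#' @param guard_zone Guard zone at top and bottom of the section, μm
#'   (default 2): excludes surfaces damaged by sectioning.
#' @param grid_spacing Systematic grid spacing, μm (published range 100–300,
#'   default 150). Must be at least `frame_side`.
#' @param section_thickness Mounted section thickness, μm.
#' @param offset Fixed 2D grid offset in μm, or `NULL` for a uniformly
#'   random offset in `[0, grid_spacing)^2` (unbiased systematic random
#'   sampling).
#' @param seed Optional seed for the random offset.
#' @return Object of class `fractionator_params`.
#' @export
fractionator_params <- function(frame_side = 55, disector_height = 5,
                                guard_zone = 2, grid_spacing = 150,
                                section_thickness = 12,
                                offset = NULL, seed = NULL) {
  if (2 * guard_zone + disector_height > section_thickness)
    stop("guard zones plus disector height exceed section thickness")
  if (frame_side > grid_spacing)
    stop("frame_side must not exceed grid_spacing")
  structure(list(frame_side = frame_side,
                 disector_height = disector_height,
                 guard_zone = guard_zone,
                 grid_spacing = grid_spacing,
                 section_thickness = section_thickness,
                 offset = offset, seed = seed),
            class = "fractionator_params")
}

# Even-odd (ray casting) point-in-polygon, vectorised over points.
point_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (poly_y[i] > py) != (poly_y[j] > py)
    xint <- (poly_x[j] - poly_x[i]) * (py - poly_y[i]) /
      (poly_y[j] - poly_y[i]) + poly_x[i]
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}

#' Systematic disector counts over an ROI
#'
#' Lays a systematic grid of counting frames (spacing `grid_spacing`) from a
#' uniformly random offset over the region of interest and counts cells with
#' the unbiased counting-frame rule: a cell is counted if it falls inside
#' the frame or on its inclusion edges (left and top) and not on its
#' exclusion edges (right and bottom) — implemented as the half-open square
#' `x in [x0, x0 + s)`, `y in (y0, y0 + s]` — and if its z position lies
#' within the disector, between the guard zones
#' (`z in [guard, guard + height)`). Only frames lying entirely inside the
#' ROI are used, so adjacent frames tile the plane and count every cell
#' exactly once.
#'
#' @param pop A [generate_cell_population()] result, or a data frame with
#'   `x`, `y`, `z` (μm) and optionally `label`.
#' @param params A [fractionator_params()].
#' @param roi Region of interest as a polygon data frame (`x`, `y`, μm);
#'   default = rectangle of the slab footprint (or the data's bounding box).
#' @param label Optional cell label filter (e.g. count only neurons;
#'   microglia exclusion is the same mechanism).
#' @return Object of class `fractionator_counts`: data frame `frames`
#'   (`x0`, `y0`, `count`, serpentine order), `sum_q`, `n_frames`, `offset`,
#'   `params`.
#' @export
fractionator_counts <- function(pop, params, roi = NULL, label = NULL) {
  stopifnot(inherits(params, "fractionator_params"))
  cells <- if (inherits(pop, "cell_population")) pop$cells else pop
  if (!is.null(label) && "label" %in% names(cells))
    cells <- cells[cells$label %in% label, ]
  if (is.null(roi)) {
    if (inherits(pop, "cell_population")) {
      roi <- data.frame(x = c(0, pop$slab[1], pop$slab[1], 0),
                        y = c(0, 0, pop$slab[2], pop$slab[2]))
    } else {
      roi <- data.frame(x = range(cells$x)[c(1, 2, 2, 1)],
                        y = range(cells$y)[c(1, 1, 2, 2)])
    }
  }
  sp <- params$grid_spacing
  fs <- params$frame_side
  if (!is.null(params$seed)) set.seed(params$seed)
  off <- params$offset %||% stats::runif(2, 0, sp)

  ## frame origins on the shifted grid covering the ROI bounding box
  bx <- range(roi$x); by <- range(roi$y)
  if (diff(bx) < sp || diff(by) < sp)
    stop("ROI smaller than one grid cell (", sp, " um)")
  ## frame origins at off + k * spacing in absolute coordinates
  kx <- (floor((bx[1] - off[1]) / sp) - 1):(ceiling((bx[2] - off[1]) / sp) + 1)
  ky <- (floor((by[1] - off[2]) / sp) - 1):(ceiling((by[2] - off[2]) / sp) + 1)
  gx <- off[1] + kx * sp
  gy <- off[2] + ky * sp
  grid <- expand.grid(x0 = gx, y0 = gy)
  ## keep frames entirely inside the ROI (all four corners)
  corners_in <- point_in_polygon(grid$x0, grid$y0, roi$x, roi$y) &
    point_in_polygon(grid$x0 + fs, grid$y0, roi$x, roi$y) &
    point_in_polygon(grid$x0, grid$y0 + fs, roi$x, roi$y) &
    point_in_polygon(grid$x0 + fs, grid$y0 + fs, roi$x, roi$y)
  grid <- grid[corners_in, , drop = FALSE]
  if (!nrow(grid)) stop("no counting frame fits inside the ROI")

  zmin <- params$guard_zone
  zmax <- params$guard_zone + params$disector_height
  zc <- cells[cells$z >= zmin & cells$z < zmax, , drop = FALSE]
  ## each cell can belong to at most one frame (frame_side <= spacing):
  ## x rule [x0, x0 + fs): frame index floor((x - off)/sp), residual < fs
  ## y rule (y0, y0 + fs]: frame index ceil((y - off)/sp) - 1, residual <= fs
  kx <- floor((zc$x - off[1]) / sp)
  rx <- zc$x - (off[1] + kx * sp)
  ky <- ceiling((zc$y - off[2]) / sp) - 1
  ry <- zc$y - (off[2] + ky * sp)
  inframe <- rx < fs & ry > 0 & ry <= fs
  cell_key <- paste(off[1] + kx * sp, off[2] + ky * sp)[inframe]
  grid_key <- paste(grid$x0, grid$y0)
  counts <- as.numeric(table(factor(cell_key, levels = grid_key)))
  ## serpentine ordering for the systematic CE estimator
  o <- order(grid$y0, ifelse(match(grid$y0, sort(unique(grid$y0))) %% 2 == 0,
                             -grid$x0, grid$x0))
  frames <- data.frame(x0 = grid$x0[o], y0 = grid$y0[o], count = counts[o])
  structure(list(frames = frames, sum_q = sum(counts),
                 n_frames = nrow(frames), offset = off, params = params),
            class = "fractionator_counts")
}

#' @export
print.fractionator_counts <- function(x, ...) {
  cat("<fractionator_counts> sum Q =", x$sum_q, "over", x$n_frames,
      "frames\n")
  invisible(x)
}

#' Cell density from disector counts
#'
#' Density = total count / total disector volume, converted exactly from
#' μm³ to mm³ (factor 1e9).
#'
#' @param counts A [fractionator_counts()] result.
#' @return Object of class `stereo_estimate`: `sum_q`, `n_frames`,
#'   `density` (cells/mm³), `ce_noise`, `ce_gj` (see [gundersen_ce()]).
#' @examples
#' # 100 cells over 50 frames of 55 x 55 x 5 um^3 -> 132231 cells/mm^3
#' @export
density_from_counts <- function(counts) {
  stopifnot(inherits(counts, "fractionator_counts"))
  p <- counts$params
  vol_um3 <- counts$n_frames * p$frame_side^2 * p$disector_height
  if (vol_um3 <= 0) stop("zero sampled volume")
  ce <- gundersen_ce(counts$frames$count)
  structure(list(sum_q = counts$sum_q, n_frames = counts$n_frames,
                 density = counts$sum_q / vol_um3 * 1e9,
                 ce_noise = ce$ce_noise, ce_gj = ce$ce_gj),
            class = "stereo_estimate")
}

#' @export
print.stereo_estimate <- function(x, ...) {
  cat("<stereo_estimate>", round(x$density), "cells/mm^3 ( sum Q =",
      x$sum_q, ")\n")
  cat("  CE:", round(x$ce_noise, 4), "(noise),",
      round(x$ce_gj, 4), "(Gundersen-Jensen)\n")
  invisible(x)
}

#' Coefficient of error of a systematic disector sample
#'
#' Two estimators are reported, because published protocols often name only
#' "coefficient of error":
#' * `ce_noise` — the nugget/noise CE \eqn{\sqrt{\Sigma Q}/\Sigma Q} under
#'   the Poisson counting model;
#' * `ce_gj` — the Gundersen–Jensen CE for systematic sampling,
#'   \eqn{\sqrt{\Sigma Q + Var_{SRS}}/\Sigma Q}, with the smoothness-class
#'   `m = 1` variance \eqn{(3(A - \Sigma Q) - 4B + C)/240} (or `m = 0`,
#'   \eqn{(3A - 4B + C)/12}), where \eqn{A = \sum Q_i^2},
#'   \eqn{B = \sum Q_i Q_{i+1}}, \eqn{C = \sum Q_i Q_{i+2}} along the
#'   serpentine frame order.
#'
#' @param counts Per-frame counts in systematic (serpentine) order.
#' @param m Smoothness class, 1 (default) or 0.
#' @return List with `ce_noise`, `ce_gj`, `var_srs`, `sum_q`. Both CEs are
#'   `NA` (flagged) when the total count is zero.
#' @examples
#' gundersen_ce(rep(2, 50))$ce_noise  # sqrt(100)/100 = 0.1
#' @export
gundersen_ce <- function(counts, m = 1) {
  if (length(counts) < 2) stop("need at least 2 frames")
  sq <- sum(counts)
  if (sq == 0) {
    warning("total count is zero: CE undefined")
    return(list(ce_noise = NA_real_, ce_gj = NA_real_, var_srs = NA_real_,
                sum_q = 0))
  }
  A <- sum(counts^2)
  B <- sum(counts[-length(counts)] * counts[-1])
  C <- if (length(counts) > 2)
    sum(counts[seq_len(length(counts) - 2)] * counts[-(1:2)]) else 0
  var_srs <- if (m == 1) (3 * (A - sq) - 4 * B + C) / 240
             else (3 * A - 4 * B + C) / 12
  var_srs <- max(var_srs, 0)
  list(ce_noise = sqrt(sq) / sq,
       ce_gj = sqrt(sq + var_srs) / sq,
       var_srs = var_srs, sum_q = sq)
}
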