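## File interfaces: 16-bit TIFF + JSON sidecar, YAML params, CSV tables ----

#' Write a micrograph as 16-bit grayscale TIFF with a JSON sidecar
#'
#' The sidecar (`<image>.json`) records pixel size (μm/px), modality and id,
#' so measurements on re-read images are calibrated.
#'
#' @param img A [micrograph()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(img, path) {
  stopifnot(inherits(img, "micrograph"))
  tiff::writeTIFF(img$pixels, path, bits.per.sample = 16)
  meta <- list(pixel_size = img$pixel_size, modality = img$modality,
               id = img$id, units = "um")
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a micrograph from TIFF or PNG plus its pixel-size sidecar
#'
#' @param path Image path (`.tif`, `.tiff` or `.png`).
#' @param pixel_size Pixel size in μm/px; if `NULL`, read from the JSON
#'   sidecar `<image>.json` (error if absent — uncalibrated images cannot be
#'   measured).
#' @return A [micrograph()].
#' @export
read_micrograph <- function(path, pixel_size = NULL) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("package 'png' is needed to read PNG images")
    png::readPNG(path)
  } else stop("unsupported image format: ", ext)
  if (length(dim(m)) == 3) m <- apply(m, c(1, 2), mean)  # collapse channels
  meta <- list(modality = "EM-like", id = basename(path))
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(side)) meta <- utils::modifyList(meta, jsonlite::read_json(side))
  if (is.null(pixel_size)) pixel_size <- meta$pixel_size
  if (is.null(pixel_size))
    stop("pixel_size not given and no sidecar found for ", path)
  micrograph(m, pixel_size = pixel_size,
             modality = meta$modality %||% "EM-like", id = meta$id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write/read tissue or cohort parameters as YAML
#'
#' @param x A `tissue_params` or `cohort_spec` object (or plain list).
#' @param path YAML file path.
#' @return For `write_params_yaml`, `path` invisibly; for
#'   `read_params_yaml`, the reconstructed object.
#' @export
write_params_yaml <- function(x, path) {
  lst <- unclass(x)
  lst$.class <- class(x)[1]
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  cl <- lst$.class
  lst$.class <- NULL
  if (!is.null(cl) && cl %in% c("tissue_params", "cohort_spec"))
    class(lst) <- cl
  lst
}

#' Write a per-profile measurement table to CSV
#'
#' Column set is fixed: `image`, `case`, `compartment` (when present),
#' `centroid_x`, `centroid_y`, `area`, `major_diameter`, `minor_diameter`,
#' `outer_diameter`, `inner_diameter`, `myelin_thickness`, `g_ratio`, `ar`,
#' `angle_deg`, `collapsed_lumen`. Units: μm and μm², angles in degrees.
#'
#' @param profiles Data frame of profile measures (see [measure_image()]).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
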