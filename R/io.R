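# File I/O for the three modalities and the trait table.
#
# RGB: 8-bit 3-channel PNG or TIFF. Depth: 16-bit single-channel raster,
# millimetres; written as 16-bit TIFF (PNG writing is 8-bit only), read from
# 16-bit TIFF or 16-bit PNG. Thermal: 8-bit gray PNG plus a JSON calibration
# sidecar `<basename>.calib.json` holding {"t_min": , "t_max": } in degC.
# Readers never coerce bit depth silently; mismatches raise format errors.

ext_of <- function(path) tolower(tools::file_ext(path))

#' Read an 8-bit RGB image
#'
#' @param path PNG or TIFF file with exactly 3 channels at 8 bits per sample.
#' @return An [rgb_image()].
#' @export
read_rgb <- function(path) {
  if (!file.exists(path)) stop("read_rgb: file not found: ", path)
  ext <- ext_of(path)
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    info <- attr(raw, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 8) {
      stop("read_rgb: expected an 8-bit image, got bit depth ", info$bit.depth)
    }
    scale <- 255
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    bps <- attr(raw, "bits.per.sample")
    if (!is.null(bps) && bps != 8) {
      stop("read_rgb: expected an 8-bit image, got bit depth ", bps)
    }
    scale <- 255
  } else {
    stop("read_rgb: unsupported extension '", ext, "' (png/tif expected)")
  }
  if (length(dim(raw)) != 3 || dim(raw)[3] != 3) {
    nch <- if (length(dim(raw)) == 3) dim(raw)[3] else 1L
    stop("read_rgb: expected 3 channels, got ", nch)
  }
  rgb_image(round(unclass(raw) * scale))
}

#' Write an RGB image as 8-bit PNG or TIFF
#'
#' @param img An [rgb_image()].
#' @param path Output path (`.png`, `.tif`).
#' @return `path`, invisibly.
#' @export
write_rgb <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  a <- unclass(img) / 255
  ext <- ext_of(path)
  if (ext == "png") {
    png::writePNG(a, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(a, path, bits.per.sample = 8L)
  } else {
    stop("write_rgb: unsupported extension '", ext, "'")
  }
  invisible(path)
}

#' Read a 16-bit depth image (millimetres)
#'
#' Zero pixels are preserved as the invalid/no-return sentinel.
#'
#' @param path 16-bit single-channel TIFF or PNG.
#' @return A [depth_image()].
#' @export
read_depth <- function(path) {
  if (!file.exists(path)) stop("read_depth: file not found: ", path)
  ext <- ext_of(path)
  if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE, as.is = TRUE)
    bps <- attr(raw, "bits.per.sample")
    if (!is.null(bps) && bps != 16) {
      stop("read_depth: expected a 16-bit raster, got bit depth ", bps)
    }
    vals <- raw
  } else if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    info <- attr(raw, "info")
    if (is.null(info$bit.depth) || info$bit.depth != 16) {
      stop("read_depth: expected a 16-bit raster, got bit depth ",
           if (is.null(info$bit.depth)) "unknown" else info$bit.depth)
    }
    vals <- round(unclass(raw) * 65535)
  } else {
    stop("read_depth: unsupported extension '", ext, "'")
  }
  if (length(dim(vals)) != 2) {
    stop("read_depth: expected a single-channel raster, got ",
         dim(vals)[3], " channels")
  }
  depth_image(vals)
}

#' Write a depth image as 16-bit TIFF
#'
#' @param img A [depth_image()].
#' @param path Output path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_depth <- function(img, path) {
  stopifnot(inherits(img, "depth_image"))
  if (!ext_of(path) %in% c("tif", "tiff")) {
    stop("write_depth: depth images are written as 16-bit TIFF ('.tif')")
  }
  tiff::writeTIFF(unclass(img) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Default calibration sidecar path for a thermal image file
#'
#' @param path Thermal image path; the sidecar is `<basename>.calib.json`
#'   next to it.
#' @return Sidecar path.
#' @export
thermal_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".calib.json")
}

#' Read a calibrated thermal image
#'
#' @param path 8-bit gray PNG.
#' @param sidecar_path JSON sidecar with fields `t_min`, `t_max` (degC);
#'   defaults to `<basename>.calib.json`.
#' @return A [thermal_image()].
#' @export
read_thermal <- function(path, sidecar_path = thermal_sidecar_path(path)) {
  if (!file.exists(path)) stop("read_thermal: file not found: ", path)
  if (!file.exists(sidecar_path)) {
    stop("read_thermal: calibration sidecar not found: ", sidecar_path)
  }
  raw <- png::readPNG(path, info = TRUE)
  info <- attr(raw, "info")
  if (!is.null(info$bit.depth) && info$bit.depth != 8) {
    stop("read_thermal: expected an 8-bit gray image, got bit depth ", info$bit.depth)
  }
  if (length(dim(raw)) == 3) {
    stop("read_thermal: expected a single-channel image, got ", dim(raw)[3], " channels")
  }
  calib <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(calib$t_min) || is.null(calib$t_max)) {
    stop("read_thermal: sidecar must provide t_min and t_max")
  }
  thermal_image(gray_image(round(unclass(raw) * 255)),
                temperature_calibration(calib$t_min, calib$t_max))
}

#' Write a calibrated thermal image (PNG + JSON sidecar)
#'
#' @param img A [thermal_image()].
#' @param path Output PNG path.
#' @param sidecar_path Output sidecar path; defaults to `<basename>.calib.json`.
#' @return `path`, invisibly.
#' @export
write_thermal <- function(img, path, sidecar_path = thermal_sidecar_path(path)) {
  stopifnot(inherits(img, "thermal_image"))
  png::writePNG(unclass(img$gray) / 255, path)
  jsonlite::write_json(list(t_min = img$calibration$t_min,
                            t_max = img$calibration$t_max),
                       sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

trait_columns <- c("box_id", "growth_stage", "timestamp", "leaf_area_cm2",
                   "green_index", "plant_height_cm", "canopy_t_min",
                   "canopy_t_max", "canopy_t_mean")

#' One row of extracted canopy traits
#'
#' All traits are optional (`NA` when not measured); present traits are
#' validated (green index in `[0, 1]`, temperature ordering).
#'
#' @param box_id Root-box identifier.
#' @param growth_stage Stage label, e.g. `"trefoil"`, `"pre_tillering"`,
#'   `"late_tillering"`, `"jointing"`.
#' @param timestamp Acquisition time (any printable scalar).
#' @param leaf_area_cm2,green_index,plant_height_cm Canopy traits.
#' @param canopy_t_min,canopy_t_max,canopy_t_mean Canopy temperatures, degC.
#' @return A one-row `data.frame` with the fixed trait-table columns.
#' @export
trait_record <- function(box_id, growth_stage = NA, timestamp = NA,
                         leaf_area_cm2 = NA, green_index = NA,
                         plant_height_cm = NA, canopy_t_min = NA,
                         canopy_t_max = NA, canopy_t_mean = NA) {
  if (!is.na(green_index) && (green_index < 0 || green_index > 1)) {
    stop("trait_record: green_index must lie in [0, 1]")
  }
  ts <- c(canopy_t_min, canopy_t_mean, canopy_t_max)
  if (!anyNA(ts) && !(ts[1] <= ts[2] && ts[2] <= ts[3])) {
    stop("trait_record: canopy temperatures must satisfy t_min <= t_mean <= t_max")
  }
  data.frame(box_id = as.character(box_id),
             growth_stage = as.character(growth_stage),
             timestamp = as.character(timestamp),
             leaf_area_cm2 = as.numeric(leaf_area_cm2),
             green_index = as.numeric(green_index),
             plant_height_cm = as.numeric(plant_height_cm),
             canopy_t_min = as.numeric(canopy_t_min),
             canopy_t_max = as.numeric(canopy_t_max),
             canopy_t_mean = as.numeric(canopy_t_mean),
             stringsAsFactors = FALSE)
}

#' Write a trait table as CSV
#'
#' @param records A `data.frame` of trait rows (see [trait_record()]) or a
#'   list of such rows; may be empty.
#' @param path Output CSV path. Missing traits become empty cells.
#' @return `path`, invisibly.
#' @export
write_traits <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else if (is.list(records)) {
    df <- if (length(records)) do.call(rbind, records) else
      trait_record("x")[0, , drop = FALSE]
  } else {
    stop("write_traits: records must be a data.frame or a list of records")
  }
  if (nrow(df) && !identical(names(df), trait_columns)) {
    stop("write_traits: records must have the fixed trait columns")
  }
  if (!nrow(df)) df <- trait_record("x")[0, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trait table written by [write_traits()]
#'
#' @param path CSV path.
#' @return A `data.frame` with the fixed trait columns; empty cells are `NA`.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(box_id = "character",
                                       growth_stage = "character",
                                       timestamp = "character"))
  if (!identical(names(df), trait_columns)) {
    stop("read_traits: unexpected header in ", path)
  }
  for (col in trait_columns[4:9]) df[[col]] <- as.numeric(df[[col]])
  df
}
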