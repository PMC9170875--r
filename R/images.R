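# In-memory raster containers shared by all extractors.
#
# Convention (all modules): pixel coordinates are (row, col), 1-based in R,
# origin top-left, row-major semantics. Depth is stored in millimetres with
# 0 as the invalid/no-return sentinel; heights are reported in centimetres.

#' RGB canopy image
#'
#' An 8-bit, 3-channel raster stored as an `H x W x 3` integer array with
#' channel values in `[0, 255]`.
#'
#' @param pixels Numeric array of dimension `H x W x 3`; values must be whole
#'   numbers in `[0, 255]`.
#' @return An object of class `rgb_image`.
#' @export
#' @examples
#' img <- rgb_image(array(0L, dim = c(4, 4, 3)))
#' dim(img)
rgb_image <- function(pixels) {
  pixels <- check_pixels(pixels, ndim = 3, lo = 0, hi = 255, what = "rgb_image")
  if (dim(pixels)[3] != 3L) {
    stop("rgb_image: expected 3 channels, got ", dim(pixels)[3])
  }
  structure(pixels, class = c("rgb_image", "phk_image"))
}

#' Single-channel 8-bit gray image
#'
#' @param pixels Numeric matrix with whole values in `[0, 255]`.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels) {
  pixels <- check_pixels(pixels, ndim = 2, lo = 0, hi = 255, what = "gray_image")
  structure(pixels, class = c("gray_image", "phk_image"))
}

#' Binary foreground mask
#'
#' Foreground pixels are 1, background 0. A mask always shares the pixel grid
#' of the image it was derived from.
#'
#' @param pixels Logical or 0/1 numeric matrix.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels) {
  if (is.logical(pixels)) {
    storage <- matrix(as.integer(pixels), nrow = nrow(pixels), ncol = ncol(pixels))
  } else {
    storage <- check_pixels(pixels, ndim = 2, lo = 0, hi = 1, what = "binary_mask")
  }
  if (!all(storage %in% c(0L, 1L))) {
    stop("binary_mask: values must be 0 or 1")
  }
  structure(storage, class = c("binary_mask", "phk_image"))
}

#' Depth image in millimetres
#'
#' Each pixel is the distance from the camera plane to the scene in mm;
#' the value 0 is the sensor's invalid/no-return sentinel and is excluded
#' from all statistics downstream.
#'
#' @param pixels Numeric matrix of non-negative whole values (mm).
#' @return An object of class `depth_image`.
#' @export
depth_image <- function(pixels) {
  pixels <- check_pixels(pixels, ndim = 2, lo = 0, hi = 65535, what = "depth_image")
  structure(pixels, class = c("depth_image", "phk_image"))
}

#' Temperature calibration of a thermal frame
#'
#' Maps the 8-bit gray scale to degrees Celsius: gray 0 corresponds to
#' `t_min`, gray 255 to `t_max`.
#'
#' @param t_min,t_max Frame temperature bounds in degrees Celsius;
#'   `t_min < t_max` is required.
#' @return An object of class `temperature_calibration`.
#' @export
temperature_calibration <- function(t_min, t_max) {
  if (!is.numeric(t_min) || !is.numeric(t_max) ||
      length(t_min) != 1L || length(t_max) != 1L ||
      !is.finite(t_min) || !is.finite(t_max)) {
    stop("temperature_calibration: t_min and t_max must be finite scalars")
  }
  if (t_min >= t_max) {
    stop("temperature_calibration: t_min must be strictly less than t_max (got ",
         t_min, " >= ", t_max, ")")
  }
  structure(list(t_min = as.numeric(t_min), t_max = as.numeric(t_max)),
            class = "temperature_calibration")
}

#' Calibrated thermal image
#'
#' An 8-bit gray raster whose levels encode a temperature span given by a
#' [temperature_calibration()].
#'
#' @param gray A [gray_image()] (or matrix coercible to one).
#' @param calibration A [temperature_calibration()].
#' @return An object of class `thermal_image` with elements `gray` and
#'   `calibration`.
#' @export
thermal_image <- function(gray, calibration) {
  if (!inherits(gray, "gray_image")) gray <- gray_image(gray)
  if (!inherits(calibration, "temperature_calibration")) {
    stop("thermal_image: calibration must be a temperature_calibration")
  }
  structure(list(gray = gray, calibration = calibration),
            class = "thermal_image")
}

#' Extract one colour channel of an RGB image
#'
#' @param img An [rgb_image()].
#' @param which One of `"R"`, `"G"`, `"B"`.
#' @return A [gray_image()].
#' @export
rgb_channel <- function(img, which = c("G", "R", "B")) {
  which <- match.arg(which)
  stopifnot(inherits(img, "rgb_image"))
  k <- match(which, c("R", "G", "B"))
  gray_image(unclass(img)[, , k])
}

# internal: validate + coerce pixel storage to integer
check_pixels <- function(pixels, ndim, lo, hi, what) {
  if (ndim == 2) {
    if (!is.matrix(pixels)) stop(what, ": expected a matrix")
  } else {
    if (!is.array(pixels) || length(dim(pixels)) != ndim) {
      stop(what, ": expected a ", ndim, "-dimensional array")
    }
  }
  if (any(dim(pixels)[1:2] < 1L)) stop(what, ": image must have H >= 1, W >= 1")
  v <- as.vector(pixels)
  if (anyNA(v) || !is.numeric(v)) stop(what, ": pixel values must be numeric and non-missing")
  if (any(v < lo) || any(v > hi)) {
    stop(what, ": pixel values must lie in [", lo, ", ", hi, "]")
  }
  if (any(v != round(v))) stop(what, ": pixel values must be whole numbers")
  storage.mode(pixels) <- "integer"
  attributes(pixels) <- list(dim = dim(pixels))  # drop file-format metadata
  pixels
}

#' @export
print.phk_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<%s> %d x %d", class(x)[1], d[1], d[2]))
  if (length(d) == 3) cat(" x", d[3])
  v <- range(unclass(x))
  cat(sprintf(", values in [%s, %s]\n", v[1], v[2]))
  invisible(x)
}

#' @export
print.thermal_image <- function(x, ...) {
  d <- dim(x$gray)
  cat(sprintf("<thermal_image> %d x %d, calibration [%g, %g] degC\n",
              d[1], d[2], x$calibration$t_min, x$calibration$t_max))
  invisible(x)
}
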