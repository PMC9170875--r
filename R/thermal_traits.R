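# Canopy temperature statistics from calibrated thermal images.
#
# The 8-bit gray scale encodes the frame's temperature span linearly:
# T = t_min + (g / 255) * (t_max - t_min). Histogram equalization and
# median filtering serve the segmentation only; temperature statistics are
# always computed from the ORIGINAL gray values (equalized grays no longer
# encode temperatures).

#' Convert gray level(s) to temperature
#'
#' Affine interpolation between the frame calibration bounds: gray 0 maps
#' to `t_min`, gray 255 to `t_max`.
#'
#' @param g Gray level(s) in `[0, 255]`: scalar, vector, matrix or
#'   [gray_image()].
#' @param calib A [temperature_calibration()].
#' @return Temperature(s) in degC, same shape as `g`.
#' @export
gray_to_temperature <- function(g, calib) {
  stopifnot(inherits(calib, "temperature_calibration"))
  v <- unclass(g)
  if (any(v < 0 | v > 255)) stop("gray_to_temperature: gray level outside [0, 255]")
  calib$t_min + v / 255 * (calib$t_max - calib$t_min)
}

#' Convert temperature(s) to gray level(s)
#'
#' Inverse of [gray_to_temperature()]: `round(255 * (T - t_min) / span)`,
#' clipped to `[0, 255]`. Out-of-span temperatures are clipped and flagged
#' via the `clipped` attribute.
#'
#' @param temp_c Temperature(s) in degC.
#' @param calib A [temperature_calibration()].
#' @return Integer gray level(s) with attribute `clipped`.
#' @export
temperature_to_gray <- function(temp_c, calib) {
  stopifnot(inherits(calib, "temperature_calibration"))
  raw <- 255 * (temp_c - calib$t_min) / (calib$t_max - calib$t_min)
  g <- round(raw)
  clipped <- any(g < 0 | g > 255)
  g <- clamp(g, 0, 255)
  structure(if (is.matrix(temp_c)) matrix(as.integer(g), nrow = nrow(temp_c))
            else as.integer(g),
            clipped = clipped)
}

# n-fold binary dilation / erosion (3x3 structuring element)
dilate_n <- function(m, n) {
  for (i in seq_len(n)) m <- dilate1(m)
  m
}

erode_n <- function(m, n) !dilate_n(!m, n)

# 1-px binary dilation (3x3 structuring element)
dilate1 <- function(m) {
  n <- nrow(m); w <- ncol(m)
  z <- matrix(FALSE, n + 2L, w + 2L)
  z[2:(n + 1L), 2:(w + 1L)] <- m
  out <- matrix(FALSE, n, w)
  for (di in 0:2) for (dj in 0:2) {
    out <- out | z[di + seq_len(n), dj + seq_len(w)]
  }
  out
}

# Fill holes: background components (4-connected) not touching the image
# border become foreground.
fill_holes <- function(mask) {
  comp <- connected_components(binary_mask(unclass(mask) == 0L), connectivity = 4L)
  lab <- comp$labels
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border != 0L]
  hole <- lab != 0L & !(lab %in% border)
  binary_mask(unclass(mask) == 1L | hole)
}

#' Segment the canopy region of a thermal image
#'
#' `threshold` method: histogram-valley (Otsu fallback) threshold on the
#' gray image; the canopy is the cooler side by default (vegetation is
#' usually cooler than sunlit soil), selectable via `side`. `edge` method:
#' gradient-magnitude threshold at the `edge_quantile`, 1-px dilation to
#' close the contour, hole filling, then the largest component.
#'
#' @param img A [thermal_image()] or preprocessed [gray_image()].
#' @param method `"threshold"` or `"edge"`.
#' @param side Which side of the threshold is canopy: `"cool"` (below) or
#'   `"warm"` (above). Threshold method only.
#' @param edge_quantile Gradient-magnitude quantile for the edge method
#'   (default 0.9).
#' @return A [binary_mask()] of the canopy.
#' @export
segment_canopy <- function(img, method = c("threshold", "edge"),
                           side = c("cool", "warm"), edge_quantile = 0.9) {
  method <- match.arg(method)
  side <- match.arg(side)
  g <- if (inherits(img, "thermal_image")) img$gray else img
  stopifnot(inherits(g, "gray_image"))
  if (method == "threshold") {
    thr <- valley_threshold(gray_histogram(g))
    mask <- binarize(g, thr, polarity = if (side == "cool") "below" else "above")
  } else {
    m <- unclass(g)
    n <- nrow(m); w <- ncol(m)
    if (n < 3 || w < 3) stop("segment_canopy: image too small for edge method")
    gx <- matrix(0, n, w); gy <- matrix(0, n, w)
    gy[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / 2
    gx[, 2:(w - 1)] <- (m[, 3:w] - m[, 1:(w - 2)]) / 2
    gm <- sqrt(gx^2 + gy^2)
    if (max(gm) <= 0) stop("segment_canopy: no contrast in the image")
    # flat scenes put the plain quantile at zero; floor it so that sparse but
    # strong step edges (the usual synthetic case) stay a closed contour
    gth <- max(stats::quantile(gm, edge_quantile), 0.25 * max(gm))
    edges <- dilate1(gm >= gth)
    filled <- fill_holes(binary_mask(edges))
    cc <- connected_components(filled, 8L)
    if (length(cc$sizes) == 0) stop("segment_canopy: empty canopy mask")
    mask <- binary_mask(cc$labels == which.max(cc$sizes))
  }
  if (sum(unclass(mask)) == 0) {
    stop("segment_canopy: empty canopy mask (no contrast between canopy and background?)")
  }
  mask
}

#' Canopy temperature statistics over a mask
#'
#' Converts the masked pixels of the original gray image to temperatures
#' and returns minimum, maximum, mean (sum over count), pixel count and the
#' per-pixel temperature field.
#'
#' @param img A [thermal_image()].
#' @param mask A non-empty [binary_mask()] with the image's dimensions.
#' @return A list of class `canopy_temperature` with `t_min_c`, `t_max_c`,
#'   `t_mean_c`, `n_pixels` and `field` (temperature matrix, `NA` outside
#'   the mask).
#' @export
canopy_temperature <- function(img, mask) {
  stopifnot(inherits(img, "thermal_image"), inherits(mask, "binary_mask"))
  if (!all(dim(img$gray) == dim(mask))) {
    stop("canopy_temperature: mask dimensions differ from the image")
  }
  sel <- unclass(mask) == 1L
  if (!any(sel)) stop("canopy_temperature: empty canopy mask")
  temps <- gray_to_temperature(img$gray, img$calibration)
  field <- temps
  field[!sel] <- NA_real_
  vals <- temps[sel]
  structure(list(t_min_c = min(vals),
                 t_max_c = max(vals),
                 t_mean_c = sum(vals) / length(vals),
                 n_pixels = length(vals),
                 field = field),
            class = "canopy_temperature")
}

#' @export
print.canopy_temperature <- function(x, ...) {
  cat(sprintf("Canopy temperature over %d px: min %.2f, mean %.2f, max %.2f degC\n",
              x$n_pixels, x$t_min_c, x$t_mean_c, x$t_max_c))
  invisible(x)
}

#' Full canopy-temperature extraction pipeline
#'
#' Median filtering (and, for the edge method, histogram equalization)
#' enhance the gray image for segmentation; the canopy mask found there is
#' then applied to the ORIGINAL gray values for the temperature statistics.
#' The valley/Otsu threshold is taken on the median-filtered gray without
#' equalization: equalization flattens the histogram by construction, which
#' destroys the very valley the threshold needs, and being monotone it
#' selects no different pixel classes anyway.
#'
#' @param img A [thermal_image()].
#' @param method,side,edge_quantile Passed to [segment_canopy()].
#' @param median_kernel Median-filter kernel (default 3).
#' @param mask Optional precomputed canopy [binary_mask()]; skips
#'   segmentation.
#' @return A `canopy_temperature` with an extra `mask` element.
#' @export
canopy_temperature_pipeline <- function(img, method = c("threshold", "edge"),
                                        side = c("cool", "warm"),
                                        edge_quantile = 0.9,
                                        median_kernel = 3L, mask = NULL) {
  stopifnot(inherits(img, "thermal_image"))
  method <- match.arg(method)
  if (is.null(mask)) {
    pre <- if (method == "edge") {
      median_filter(histogram_equalize(img$gray), median_kernel)
    } else {
      median_filter(img$gray, median_kernel)
    }
    mask <- segment_canopy(pre, method = method, side = side,
                           edge_quantile = edge_quantile)
  }
  out <- canopy_temperature(img, mask)
  out$mask <- mask
  out
}
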