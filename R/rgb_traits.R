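# Green index and reference-calibrated leaf area from RGB canopy images.
#
# Leaf area follows the unit-pixel-area principle: a reference disk of known
# physical area S1 imaged by the same camera yields pixel count P1, so one
# pixel covers S1/P1 cm^2 and a canopy of P leaf pixels covers
# S = (S1/P1) * P cm^2.

#' Green-segmentation parameters
#'
#' Two segmentation rules are supported. `excess_green` (default): a pixel
#' is vegetation iff `2G - R - B > tau` and `G > R` and `G > B`.
#' `channel_threshold`: the G-channel histogram is thresholded with
#' [valley_threshold()] (or an explicit `green_threshold`), foreground above
#' the threshold.
#'
#' @param method `"excess_green"` or `"channel_threshold"`.
#' @param tau Excess-green threshold (default 20; raising it makes the
#'   segmentation stricter).
#' @param green_threshold Optional explicit G-channel gray threshold for the
#'   channel method; `NULL` selects the histogram-valley threshold.
#' @return A list of class `green_params`.
#' @export
green_params <- function(method = c("excess_green", "channel_threshold"),
                         tau = 20, green_threshold = NULL) {
  method <- match.arg(method)
  if (!is.numeric(tau) || tau < -510 || tau > 510) {
    stop("green_params: tau must lie in the excess-green range [-510, 510]")
  }
  if (!is.null(green_threshold) &&
      (green_threshold < 0 || green_threshold > 255)) {
    stop("green_params: green_threshold must be a gray level in [0, 255]")
  }
  structure(list(method = method, tau = tau, green_threshold = green_threshold),
            class = "green_params")
}

#' Segment green vegetation in an RGB image
#'
#' @param img An [rgb_image()].
#' @param params A [green_params()].
#' @return A [binary_mask()] of vegetation pixels.
#' @export
segment_green <- function(img, params = green_params()) {
  stopifnot(inherits(img, "rgb_image"), inherits(params, "green_params"))
  a <- unclass(img)
  r <- a[, , 1]; g <- a[, , 2]; b <- a[, , 3]
  if (params$method == "excess_green") {
    fg <- (2 * g - r - b > params$tau) & (g > r) & (g > b)
  } else {
    gi <- gray_image(g)
    thr <- if (is.null(params$green_threshold)) {
      valley_threshold(gray_histogram(gi))
    } else {
      params$green_threshold
    }
    return(binarize(gi, thr, polarity = "above"))
  }
  binary_mask(fg)
}

#' Green index of a canopy image
#'
#' The fraction of image pixels classified as green vegetation in the
#' vertical canopy projection.
#'
#' @inheritParams segment_green
#' @return A ratio in `[0, 1]`.
#' @export
green_index <- function(img, params = green_params()) {
  mask <- segment_green(img, params)
  sum(unclass(mask)) / length(mask)
}

#' Area of the circular reference disk
#'
#' @param diameter_cm Disk diameter in cm (the chamber's round root box has
#'   inner diameter 15 cm and the reference disk matches it).
#' @param pi_value Value of pi used; the default is machine `pi`. Passing
#'   `3.14` reproduces the legacy printed S1 = 176.625 cm^2 for d = 15.
#' @return Disk area in cm^2.
#' @export
reference_area <- function(diameter_cm = 15, pi_value = pi) {
  if (!is.numeric(diameter_cm) || diameter_cm <= 0) {
    stop("reference_area: diameter_cm must be > 0")
  }
  pi_value * (diameter_cm / 2)^2
}

#' Specification of the calibration reference
#'
#' @inheritParams reference_area
#' @return A list of class `reference_spec` with `shape`, `diameter_cm`,
#'   `area_cm2`.
#' @export
reference_spec <- function(diameter_cm = 15, pi_value = pi) {
  structure(list(shape = "circle",
                 diameter_cm = diameter_cm,
                 area_cm2 = reference_area(diameter_cm, pi_value)),
            class = "reference_spec")
}

# Crofton perimeter estimate of a component: pi/4 times the number of
# foreground/background 4-adjacent edges (image border counts as background).
# Exact-in-expectation for disks; elongated blobs score well below 1 in
# circularity, which is what the reference detector needs.
crofton_perimeter <- function(cm) {
  n <- nrow(cm); w <- ncol(cm)
  z <- matrix(FALSE, n + 2L, w + 2L)
  z[2:(n + 1L), 2:(w + 1L)] <- cm
  inner <- z[2:(n + 1L), 2:(w + 1L)]
  edges <- sum(inner & !z[1:n, 2:(w + 1L)]) +
    sum(inner & !z[3:(n + 2L), 2:(w + 1L)]) +
    sum(inner & !z[2:(n + 1L), 1:w]) +
    sum(inner & !z[2:(n + 1L), 3:(w + 2L)])
  pi / 4 * edges
}

component_circularity <- function(labels, id) {
  cm <- labels == id
  area <- sum(cm)
  per <- crofton_perimeter(cm)
  4 * pi * area / per^2
}

#' Detect the calibration reference in a binary mask
#'
#' In `calibration_image` mode the image contains only the reference, and
#' P1 is the largest component's pixel count. In `in_scene` mode the disk
#' shares the frame with leaves of the same colour, so it is selected by
#' shape: the component with the highest circularity
#' (`4 * pi * area / perimeter^2`) above `circularity_min` among components
#' within `area_tol` of the expected disk pixel area implied by
#' `px_per_cm`.
#'
#' @param mask A [binary_mask()] (already cleaned of specks).
#' @param spec A [reference_spec()].
#' @param mode `"calibration_image"` or `"in_scene"`.
#' @param px_per_cm Scale hint, required for `in_scene` mode.
#' @param circularity_min Minimum circularity to accept (default 0.8).
#' @param area_tol Relative half-width of the expected-area window
#'   (default 0.3).
#' @param connectivity Component connectivity (default 8).
#' @return A list of class `phk_reference`: `reference_pixels` (P1),
#'   `component_id`, `component_mask`, `labels`, and `circularity`
#'   (in-scene mode).
#' @export
detect_reference <- function(mask, spec = reference_spec(),
                             mode = c("calibration_image", "in_scene"),
                             px_per_cm = NULL, circularity_min = 0.8,
                             area_tol = 0.3, connectivity = 8L) {
  mode <- match.arg(mode)
  cc <- connected_components(mask, connectivity)
  if (length(cc$sizes) == 0) {
    stop("detect_reference: mask contains no components")
  }
  if (mode == "calibration_image") {
    id <- which.max(cc$sizes)
    circ <- component_circularity(cc$labels, id)
  } else {
    if (is.null(px_per_cm)) {
      stop("detect_reference: in_scene mode needs a px_per_cm scale hint")
    }
    expected <- pi * (spec$diameter_cm / 2 * px_per_cm)^2
    cand <- which(abs(cc$sizes - expected) <= area_tol * expected)
    if (length(cand) == 0) {
      stop("detect_reference: no component within ", 100 * area_tol,
           "% of the expected disk area (", round(expected), " px); ",
           "component sizes: ", paste(cc$sizes, collapse = ", "))
    }
    circs <- vapply(cand, function(i) component_circularity(cc$labels, i),
                    numeric(1))
    ok <- circs > circularity_min
    if (!any(ok)) {
      stop("detect_reference: no candidate exceeds circularity ",
           circularity_min, "; best was ", round(max(circs), 3))
    }
    id <- cand[ok][which.max(circs[ok])]
    circ <- max(circs[ok])
  }
  structure(list(reference_pixels = cc$sizes[id],
                 component_id = id,
                 component_mask = binary_mask(cc$labels == id),
                 labels = cc$labels,
                 circularity = circ),
            class = "phk_reference")
}

#' Leaf area from pixel counts (unit-pixel-area rule)
#'
#' `S = (S1 / P1) * P`: the reference of known area `S1` covering `P1`
#' pixels fixes the area of one pixel; the canopy's `P` leaf pixels then
#' give the leaf area.
#'
#' @param P Leaf pixel count (>= 0).
#' @param P1 Reference pixel count (> 0).
#' @param S1 Reference area in cm^2 (> 0).
#' @return A list of class `leaf_area_result` with `leaf_area_cm2`,
#'   `leaf_pixels`, `reference_pixels`, `unit_pixel_area_cm2`.
#' @export
leaf_area <- function(P, P1, S1) {
  if (!is.numeric(P1) || P1 <= 0) stop("leaf_area: P1 must be > 0 (calibration error)")
  if (!is.numeric(S1) || S1 <= 0) stop("leaf_area: S1 must be > 0")
  if (!is.numeric(P) || P < 0) stop("leaf_area: P must be >= 0")
  structure(list(leaf_area_cm2 = S1 / P1 * P,
                 leaf_pixels = P,
                 reference_pixels = P1,
                 unit_pixel_area_cm2 = S1 / P1),
            class = "leaf_area_result")
}

#' @export
print.leaf_area_result <- function(x, ...) {
  cat(sprintf("Leaf area: %.2f cm^2 (P = %d leaf px, P1 = %d reference px, %.5f cm^2/px)\n",
              x$leaf_area_cm2, x$leaf_pixels, x$reference_pixels,
              x$unit_pixel_area_cm2))
  invisible(x)
}

#' Full leaf-area extraction pipeline
#'
#' Segment green -> median filter -> small-object removal -> reference
#' detection -> leaf pixel count -> unit-pixel-area leaf area. The reference
#' can be supplied three ways: a separate calibration image (`ref_image`),
#' an in-scene disk separated by shape (`ref_mode = "in_scene"`, needs
#' `px_per_cm`), or a precomputed pixel count (`reference_pixels`). In
#' in-scene mode the reference component's pixels are excluded from the
#' leaf count.
#'
#' @param img Canopy [rgb_image()].
#' @param spec A [reference_spec()].
#' @param params A [green_params()].
#' @param ref_mode `"calibration_image"` or `"in_scene"`.
#' @param ref_image Calibration [rgb_image()] containing only the reference.
#' @param reference_pixels Optional precomputed P1 (skips detection).
#' @param px_per_cm Scale hint for in-scene detection.
#' @param median_kernel Median-filter kernel on the mask (default 3).
#' @param min_area_px Small-object removal threshold (default 25).
#' @return A `leaf_area_result` with an extra `masks` element (raw and
#'   cleaned masks) and, when detection ran, `reference` (the
#'   `phk_reference`).
#' @export
leaf_area_pipeline <- function(img, spec = reference_spec(),
                               params = green_params(),
                               ref_mode = c("calibration_image", "in_scene"),
                               ref_image = NULL, reference_pixels = NULL,
                               px_per_cm = NULL, median_kernel = 3L,
                               min_area_px = 25L) {
  ref_mode <- match.arg(ref_mode)
  raw <- segment_green(img, params)
  clean <- remove_small_objects(median_filter(raw, median_kernel), min_area_px)
  det <- NULL
  if (!is.null(reference_pixels)) {
    P1 <- reference_pixels
    P <- sum(unclass(clean))
  } else if (ref_mode == "calibration_image") {
    if (is.null(ref_image)) {
      stop("leaf_area_pipeline: calibration_image mode needs ref_image or reference_pixels")
    }
    rraw <- segment_green(ref_image, params)
    rclean <- remove_small_objects(median_filter(rraw, median_kernel), min_area_px)
    det <- detect_reference(rclean, spec, mode = "calibration_image")
    P1 <- det$reference_pixels
    P <- sum(unclass(clean))
  } else {
    det <- detect_reference(clean, spec, mode = "in_scene", px_per_cm = px_per_cm)
    P1 <- det$reference_pixels
    P <- sum(unclass(clean)) - P1
  }
  res <- leaf_area(P, P1, spec$area_cm2)
  res$masks <- list(green = raw, clean = clean)
  res$reference <- det
  res
}
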