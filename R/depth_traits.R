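# Plant height from registered RGB + depth image pairs.
#
# Height is the difference of two camera distances: H = h2 - h3, where h2 is
# camera-to-soil-surface and h3 is camera-to-leaf, both read off the depth
# image at characteristic points (the main stem where leaves meet; the soil
# matrix next to the roots). Depths are in mm; heights are reported in cm,
# converted exactly once at the HeightMeasurement boundary.

#' A characteristic pixel location
#'
#' @param row,col 1-based pixel coordinates.
#' @param role `"leaf_center"` or `"soil_center"`.
#' @return A list of class `center_point`.
#' @export
center_point <- function(row, col, role = c("leaf_center", "soil_center")) {
  role <- match.arg(role)
  structure(list(row = as.integer(row), col = as.integer(col), role = role),
            class = "center_point")
}

#' Per-pixel RGB-to-depth correspondence
#'
#' @param map `NULL` for the identity mapping (pre-registered RGB-D pairs),
#'   or an `H x W x 2` integer array giving, for each RGB pixel, the (row,
#'   col) of the corresponding depth pixel.
#' @return A list of class `depth_alignment`.
#' @export
depth_alignment <- function(map = NULL) {
  if (!is.null(map) && (!is.array(map) || length(dim(map)) != 3 ||
                        dim(map)[3] != 2)) {
    stop("depth_alignment: map must be NULL or an H x W x 2 index array")
  }
  structure(list(map = map), class = "depth_alignment")
}

#' Resample a depth image into RGB pixel coordinates
#'
#' `out[r, c] = depth[map[r, c, 1], map[r, c, 2]]`; the identity mapping
#' returns the input unchanged.
#'
#' @param depth A [depth_image()].
#' @param alignment A [depth_alignment()].
#' @return A [depth_image()] on the RGB grid.
#' @export
align_depth_to_rgb <- function(depth, alignment = depth_alignment()) {
  stopifnot(inherits(depth, "depth_image"))
  if (!inherits(alignment, "depth_alignment")) {
    stop("align_depth_to_rgb: alignment must be a depth_alignment")
  }
  if (is.null(alignment$map)) return(depth)
  map <- alignment$map
  rr <- map[, , 1]; cc <- map[, , 2]
  if (any(rr < 1 | rr > nrow(depth) | cc < 1 | cc > ncol(depth))) {
    stop("align_depth_to_rgb: mapping lands outside the depth image")
  }
  vals <- unclass(depth)[cbind(as.vector(rr), as.vector(cc))]
  depth_image(matrix(vals, nrow = dim(map)[1], ncol = dim(map)[2]))
}

# nearest foreground pixel to a target (r, c); ties -> smallest row, then col
nearest_pixel <- function(rows, cols, r0, c0) {
  d2 <- (rows - r0)^2 + (cols - c0)^2
  ord <- order(d2, rows, cols)
  c(rows[ord[1]], cols[ord[1]])
}

#' Locate the leaf center (main stem) of a plant mask
#'
#' The area where the leaves meet is taken as the foreground pixel nearest
#' to the foreground centroid, which guarantees an on-mask point even for
#' ring-like canopies. Ties break to the smallest row, then column.
#'
#' @param plant_mask A non-empty [binary_mask()] of the plant.
#' @return A [center_point()] with role `"leaf_center"`.
#' @export
locate_leaf_center <- function(plant_mask) {
  stopifnot(inherits(plant_mask, "binary_mask"))
  idx <- which(unclass(plant_mask) == 1L)
  if (length(idx) == 0) stop("locate_leaf_center: empty plant mask")
  n <- nrow(plant_mask)
  rows <- (idx - 1L) %% n + 1L
  cols <- (idx - 1L) %/% n + 1L
  p <- nearest_pixel(rows, cols, mean(rows), mean(cols))
  center_point(p[1], p[2], "leaf_center")
}

#' Locate the soil-matrix center next to the plant
#'
#' The soil point is the non-plant pixel inside the box region nearest to
#' the leaf center (or to the box centroid when the plant mask is empty).
#'
#' @param plant_mask [binary_mask()] of the plant.
#' @param box_mask [binary_mask()] of the root-box region; `NULL` means the
#'   whole frame.
#' @return A [center_point()] with role `"soil_center"`.
#' @export
locate_soil_center <- function(plant_mask, box_mask = NULL) {
  stopifnot(inherits(plant_mask, "binary_mask"))
  n <- nrow(plant_mask); w <- ncol(plant_mask)
  box <- if (is.null(box_mask)) matrix(1L, n, w) else unclass(box_mask)
  cand <- which(box == 1L & unclass(plant_mask) == 0L)
  if (length(cand) == 0) {
    stop("locate_soil_center: no soil pixel available (plant fills the box)")
  }
  if (any(unclass(plant_mask) == 1L)) {
    lc <- locate_leaf_center(plant_mask)
    r0 <- lc$row; c0 <- lc$col
  } else {
    bidx <- which(box == 1L)
    r0 <- mean((bidx - 1L) %% n + 1L)
    c0 <- mean((bidx - 1L) %/% n + 1L)
  }
  rows <- (cand - 1L) %% n + 1L
  cols <- (cand - 1L) %/% n + 1L
  p <- nearest_pixel(rows, cols, r0, c0)
  center_point(p[1], p[2], "soil_center")
}

#' Patch-median depth at a point
#'
#' The median of valid (nonzero) depths in the `patch x patch` window
#' centred on the point (clipped at the image border). Single-pixel reads of
#' consumer depth sensors are unreliable; the patch median realizes the
#' Z1/Z2 lookups robustly. An optional include-mask restricts the window to
#' pixels of the right surface (e.g. soil-only when sampling next to a
#' leaf).
#'
#' @param depth A [depth_image()].
#' @param point A [center_point()] (or `c(row, col)`).
#' @param patch Odd window size (default 5).
#' @param include Optional logical/0-1 matrix; only `TRUE` pixels enter the
#'   median.
#' @return Depth in mm (numeric scalar).
#' @export
depth_at <- function(depth, point, patch = 5L, include = NULL) {
  stopifnot(inherits(depth, "depth_image"))
  patch <- check_kernel(patch)
  if (inherits(point, "center_point")) {
    r <- point$row; c <- point$col
  } else {
    r <- point[1]; c <- point[2]
  }
  n <- nrow(depth); w <- ncol(depth)
  if (r < 1 || r > n || c < 1 || c > w) stop("depth_at: point out of bounds")
  h <- (patch - 1L) %/% 2L
  ri <- max(1L, r - h):min(n, r + h)
  ci <- max(1L, c - h):min(w, c + h)
  vals <- unclass(depth)[ri, ci, drop = FALSE]
  ok <- vals > 0
  if (!is.null(include)) ok <- ok & (include[ri, ci, drop = FALSE] > 0)
  if (!any(ok)) {
    stop("depth_at: no valid depth in the ", patch, "x", patch,
         " window at (", r, ", ", c, ")")
  }
  stats::median(vals[ok])
}

#' Plant height from the two camera distances
#'
#' `H = h2 - h3` (camera-to-soil minus camera-to-leaf, both cm). If
#' `h3 > h2` (leaf apparently below the soil surface, a sensor-noise case)
#' the negative height is returned with attribute `below_soil = TRUE` and a
#' warning.
#'
#' @param h2_cm Camera-to-soil-surface distance, cm.
#' @param h3_cm Camera-to-leaf distance, cm.
#' @return Height in cm with attribute `below_soil`.
#' @export
plant_height <- function(h2_cm, h3_cm) {
  if (!is.numeric(h2_cm) || !is.numeric(h3_cm) ||
      !is.finite(h2_cm) || !is.finite(h3_cm) || h2_cm <= 0 || h3_cm <= 0) {
    stop("plant_height: h2_cm and h3_cm must be finite positive scalars")
  }
  below <- h3_cm > h2_cm
  if (below) {
    warning("plant_height: h3 > h2 (leaf below soil surface); ",
            "flagging as sensor noise")
  }
  structure(h2_cm - h3_cm, below_soil = below)
}

#' A complete height measurement
#'
#' @param h2_cm,h3_cm Camera-to-soil and camera-to-leaf distances (cm).
#' @param h1_cm Optional camera-to-ground distance (cm), used only for the
#'   consistency check `|h1 - h2 - b|` against the measured box height `b`.
#' @param n_repeats Number of repeated depth extractions averaged.
#' @param box_height_cm Optional measured root-box height `b` (cm).
#' @param tol_cm Consistency-residual tolerance (default 1 cm).
#' @return A list of class `height_measurement` with `height_cm`, the input
#'   distances, `n_repeats`, `below_soil`, and (when `h1_cm` and
#'   `box_height_cm` are given) `consistency_residual_cm` plus
#'   `consistency_flag`.
#' @export
height_measurement <- function(h2_cm, h3_cm, h1_cm = NULL, n_repeats = 1L,
                               box_height_cm = NULL, tol_cm = 1) {
  H <- plant_height(h2_cm, h3_cm)
  out <- list(height_cm = as.numeric(H),
              h1_cm = h1_cm, h2_cm = h2_cm, h3_cm = h3_cm,
              n_repeats = as.integer(n_repeats),
              below_soil = attr(H, "below_soil"))
  if (!is.null(h1_cm)) {
    if (h2_cm > h1_cm) {
      warning("height_measurement: h2 exceeds h1 (soil surface below ground?)")
    }
    if (!is.null(box_height_cm)) {
      res <- h1_cm - h2_cm - box_height_cm
      out$consistency_residual_cm <- res
      out$consistency_flag <- abs(res) > tol_cm
    }
  }
  structure(out, class = "height_measurement")
}

#' @export
print.height_measurement <- function(x, ...) {
  cat(sprintf("Plant height: %.2f cm (h2 = %.2f, h3 = %.2f cm, %d repeats)\n",
              x$height_cm, x$h2_cm, x$h3_cm, x$n_repeats))
  if (isTRUE(x$below_soil)) cat("  [flag] leaf below soil surface\n")
  if (!is.null(x$consistency_residual_cm)) {
    cat(sprintf("  consistency residual |h1 - h2 - b|: %.2f cm%s\n",
                abs(x$consistency_residual_cm),
                if (isTRUE(x$consistency_flag)) " [flag]" else ""))
  }
  invisible(x)
}

#' Full plant-height extraction pipeline
#'
#' Median-denoises the depth image, segments the plant in the RGB image,
#' aligns depth to RGB, locates the leaf and soil centers, then performs
#' `n_repeats` patch-median depth extractions at deterministically jittered
#' centers (jitter radius `jitter_px`, seeded) and averages Z1 and Z2
#' before applying `H = h2 - h3`. Soil patches exclude plant-labelled
#' pixels and leaf patches exclude soil, so boundary jitter cannot mix the
#' two surfaces.
#'
#' @param rgb An [rgb_image()] of the scene.
#' @param depth The co-registered [depth_image()] (mm).
#' @param alignment A [depth_alignment()] (`NULL` = identity).
#' @param params [green_params()] for plant segmentation.
#' @param box_mask Optional [binary_mask()] of the root box.
#' @param n_repeats Repeated extractions to average (default 5).
#' @param patch Patch size for [depth_at()] (default 5).
#' @param jitter_px Jitter radius in px (default 2).
#' @param depth_kernel Median-filter kernel for depth denoising (default 5).
#' @param seed Seed for the deterministic jitter (default 1).
#' @param h1_cm,box_height_cm Optional consistency-check inputs (cm).
#' @return A [height_measurement()] with extra elements `leaf_center`,
#'   `soil_center` and `plant_mask`.
#' @export
plant_height_pipeline <- function(rgb, depth, alignment = NULL,
                                  params = green_params(), box_mask = NULL,
                                  n_repeats = 5L, patch = 5L, jitter_px = 2L,
                                  depth_kernel = 5L, seed = 1L,
                                  h1_cm = NULL, box_height_cm = NULL) {
  stopifnot(inherits(rgb, "rgb_image"), inherits(depth, "depth_image"))
  d <- median_filter(depth, depth_kernel)
  if (!is.null(alignment)) d <- align_depth_to_rgb(d, alignment)
  if (!all(dim(d) == dim(rgb)[1:2])) {
    stop("plant_height_pipeline: depth and RGB grids differ after alignment")
  }
  pm <- segment_green(rgb, params)
  leaf <- locate_leaf_center(pm)
  # Depth denoising mixes values across the plant/soil boundary, so depth is
  # sampled at a safety margin from it: soil patches at least margin+1 px
  # from the plant, leaf patches on the eroded plant core where available.
  margin <- (check_kernel(depth_kernel) - 1L) %/% 2L
  plant <- unclass(pm)
  plant_dil <- dilate_n(plant == 1L, margin)
  soil <- locate_soil_center(binary_mask(plant_dil), box_mask)
  plant_core <- erode_n(plant == 1L, margin)
  if (!any(plant_core)) plant_core <- plant == 1L
  n <- nrow(d); w <- ncol(d)
  jit <- with_seed(seed, {
    matrix(sample(seq(-jitter_px, jitter_px), 4L * n_repeats, replace = TRUE),
           ncol = 4L)
  })
  soil_ok <- !plant_dil
  z1 <- z2 <- numeric(n_repeats)
  for (i in seq_len(n_repeats)) {
    lp <- c(clamp(leaf$row + jit[i, 1], 1L, n), clamp(leaf$col + jit[i, 2], 1L, w))
    sp <- c(clamp(soil$row + jit[i, 3], 1L, n), clamp(soil$col + jit[i, 4], 1L, w))
    z1[i] <- depth_at(d, lp, patch, include = plant_core)
    z2[i] <- depth_at(d, sp, patch, include = soil_ok)
  }
  out <- height_measurement(h2_cm = mean(z2) / 10, h3_cm = mean(z1) / 10,
                            h1_cm = h1_cm, n_repeats = n_repeats,
                            box_height_cm = box_height_cm)
  out$leaf_center <- leaf
  out$soil_center <- soil
  out$plant_mask <- pm
  out
}
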