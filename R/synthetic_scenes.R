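# Ground-truth synthetic scenes emulating the chamber's imaging geometry:
# a round root box (inner diameter 15 cm) seen from a camera 0.6 m above,
# containing a rosette of leaves over a soil matrix, imaged simultaneously
# in RGB, depth (mm) and calibrated thermal. Every extractor is tested
# against the generator's recorded truth.
#
# The px<->cm scale is induced by the rendered reference disk (diameter px
# versus 15 cm), so the leaf-area pipeline is exercised end to end,
# calibration included; no separate scale constant leaks into the truth.

shape_mask <- function(H, W, shape) {
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  dy <- rr - shape$center[1]
  dx <- cc - shape$center[2]
  if (shape$shape == "disk") {
    dy^2 + dx^2 <= shape$axes[1]^2
  } else {
    th <- (shape$angle %||% 0) * pi / 180
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    (u / shape$axes[1])^2 + (v / shape$axes[2])^2 <= 1
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rosette of elliptical leaves fanning out of one center
#'
#' @param n Number of leaves.
#' @param center `(row, col)` of the rosette center.
#' @param len,wid Semi-major and semi-minor axes of each leaf, px.
#' @return A list of leaf shapes for [scene_params()].
#' @export
rosette_leaves <- function(n, center, len, wid) {
  lapply(seq_len(n) - 1L, function(k) {
    list(shape = "ellipse", center = center, axes = c(len, wid),
         angle = k * 180 / n)
  })
}

#' Parameters of a synthetic chamber scene
#'
#' Defaults emulate the chamber's acquisition geometry: camera plane 0.6 m
#' (600 mm) above the root-box top, round box of inner diameter 15 cm
#' rendered at 200 px (13.33 px/cm), a same-diameter green reference disk
#' photographed as a separate calibration image, leaves as a rosette of
#' ellipses, and a thermal calibration span of 15-45 degC.
#'
#' @param width,height Image size in px.
#' @param box_center `(row, col)` of the root box.
#' @param box_diameter_px Rendered box (and reference) diameter.
#' @param ref_diameter_px Reference-disk diameter in px.
#' @param box_diameter_cm Physical box/reference diameter (15 cm).
#' @param leaves List of leaf shapes (see [rosette_leaves()]); each is a
#'   list with `shape` (`"ellipse"`/`"disk"`), `center`, `axes` (semi-axes
#'   px), `angle` (degrees).
#' @param leaf_color,soil_color,floor_color RGB triples 0-255.
#' @param camera_to_soil_mm,camera_to_leaf_mm Depths of the soil surface
#'   and the leaf plane (mm); leaves must be nearer the camera.
#' @param floor_extra_mm Extra depth of the chamber floor outside the box.
#' @param canopy_temp Canopy temperature field: `list(type = "constant",
#'   value = )` or `list(type = "gradient", from = , to = )` (linear in the
#'   row coordinate across the canopy).
#' @param soil_temp_c,floor_temp_c Background temperatures (degC).
#' @param calibration A [temperature_calibration()] (default 15-45 degC).
#' @param noise Per-modality Gaussian sigma: `list(rgb = , depth = ,
#'   thermal = )` (gray levels / mm / gray levels).
#' @param depth_dropout Fraction of depth pixels zeroed as invalid returns.
#' @param seed Seed fixing all randomness of the scene.
#' @return A validated list of class `scene_params`.
#' @export
scene_params <- function(width = 240L, height = 240L,
                         box_center = c(120.5, 120.5),
                         box_diameter_px = 200, ref_diameter_px = 200,
                         box_diameter_cm = 15,
                         leaves = rosette_leaves(3, box_center, 40, 7),
                         leaf_color = c(60, 150, 70),
                         soil_color = c(120, 85, 60),
                         floor_color = c(90, 90, 95),
                         camera_to_soil_mm = 600,
                         camera_to_leaf_mm = 494.2,
                         floor_extra_mm = 80,
                         canopy_temp = list(type = "constant", value = 28),
                         soil_temp_c = 40, floor_temp_c = 40,
                         calibration = temperature_calibration(15, 45),
                         noise = list(rgb = 0, depth = 0, thermal = 0),
                         depth_dropout = 0, seed = 1L) {
  p <- list(width = as.integer(width), height = as.integer(height),
            box_center = box_center, box_diameter_px = box_diameter_px,
            ref_diameter_px = ref_diameter_px,
            box_diameter_cm = box_diameter_cm, leaves = leaves,
            leaf_color = leaf_color, soil_color = soil_color,
            floor_color = floor_color,
            camera_to_soil_mm = camera_to_soil_mm,
            camera_to_leaf_mm = camera_to_leaf_mm,
            floor_extra_mm = floor_extra_mm, canopy_temp = canopy_temp,
            soil_temp_c = soil_temp_c, floor_temp_c = floor_temp_c,
            calibration = calibration, noise = noise,
            depth_dropout = depth_dropout, seed = as.integer(seed))
  if (p$camera_to_leaf_mm > p$camera_to_soil_mm) {
    stop("scene_params: leaves must not lie below the soil surface ",
         "(camera_to_leaf_mm <= camera_to_soil_mm)")
  }
  temps <- c(p$soil_temp_c, p$floor_temp_c,
             if (canopy_temp$type == "constant") canopy_temp$value
             else c(canopy_temp$from, canopy_temp$to))
  if (any(temps < calibration$t_min | temps > calibration$t_max)) {
    stop("scene_params: scene temperatures must lie within the calibration span")
  }
  structure(p, class = "scene_params")
}

fill_color <- function(arr, sel, color) {
  for (k in 1:3) {
    ch <- arr[, , k]
    ch[sel] <- color[k]
    arr[, , k] <- ch
  }
  arr
}

#' Render a synthetic RGB/depth/thermal scene with ground truth
#'
#' Deterministic given `params$seed`. The rasterized leaf union is recorded
#' as the truth mask; the depth image is the soil plane with a leaf-plane
#' override (noise applied before 1 mm quantization, as in real sensor
#' pipelines); the thermal gray is [temperature_to_gray()] of the truth
#' temperature field plus gray-level noise.
#'
#' @param params A [scene_params()].
#' @return A list of class `phk_scene`: `rgb`, `depth`, `thermal`,
#'   `ref_rgb` (calibration image) and `truth` (list with `green_mask`,
#'   `leaf_pixels`, `reference_pixels`, `leaf_area_cm2`, `green_index`,
#'   `px_per_cm`, `height_cm`, `t_min_c`, `t_max_c`, `t_mean_c`, `seed`).
#' @export
make_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  H <- p$height; W <- p$width
  box <- shape_mask(H, W, list(shape = "disk", center = p$box_center,
                               axes = p$box_diameter_px / 2))
  green <- matrix(FALSE, H, W)
  for (lf in p$leaves) green <- green | shape_mask(H, W, lf)
  green <- green & box

  with_seed(p$seed, {
    # --- RGB ---
    rgb <- array(0, dim = c(H, W, 3))
    rgb <- fill_color(rgb, !box, p$floor_color)
    rgb <- fill_color(rgb, box, p$soil_color)
    rgb <- fill_color(rgb, green, p$leaf_color)
    if (p$noise$rgb > 0) {
      rgb <- rgb + array(stats::rnorm(length(rgb), 0, p$noise$rgb), dim = dim(rgb))
    }
    rgb_img <- rgb_image(clamp(round(rgb), 0, 255))

    # --- depth (mm) ---
    d <- matrix(p$camera_to_soil_mm + p$floor_extra_mm, H, W)
    d[box] <- p$camera_to_soil_mm
    d[green] <- p$camera_to_leaf_mm
    if (p$noise$depth > 0) {
      d <- d + matrix(stats::rnorm(length(d), 0, p$noise$depth), H, W)
    }
    d <- clamp(round(d), 1, 65535)
    if (p$depth_dropout > 0) {
      drop <- stats::runif(length(d)) < p$depth_dropout
      d[drop] <- 0
    }
    depth_img <- depth_image(d)

    # --- thermal ---
    tf <- matrix(p$floor_temp_c, H, W)
    tf[box] <- p$soil_temp_c
    if (p$canopy_temp$type == "constant") {
      tf[green] <- p$canopy_temp$value
    } else {
      rows <- matrix(seq_len(H), H, W)[green]
      rlo <- min(rows); rhi <- max(rows)
      frac <- if (rhi > rlo) (rows - rlo) / (rhi - rlo) else 0
      tf[green] <- p$canopy_temp$from + frac * (p$canopy_temp$to - p$canopy_temp$from)
    }
    g <- unclass(temperature_to_gray(tf, p$calibration))
    if (p$noise$thermal > 0) {
      g <- g + matrix(round(stats::rnorm(length(g), 0, p$noise$thermal)), H, W)
    }
    thermal_img <- thermal_image(gray_image(clamp(g, 0, 255)), p$calibration)

    # --- calibration (reference) image ---
    ref_mask <- shape_mask(H, W, list(shape = "disk", center = c((H + 1) / 2, (W + 1) / 2),
                                      axes = p$ref_diameter_px / 2))
    ref <- array(0, dim = c(H, W, 3))
    ref <- fill_color(ref, !ref_mask, p$floor_color)
    ref <- fill_color(ref, ref_mask, p$leaf_color)
    if (p$noise$rgb > 0) {
      ref <- ref + array(stats::rnorm(length(ref), 0, p$noise$rgb), dim = dim(ref))
    }
    ref_img <- rgb_image(clamp(round(ref), 0, 255))
  })

  ref_px <- sum(ref_mask)
  leaf_px <- sum(green)
  s1 <- reference_area(p$box_diameter_cm, pi)
  canopy_vals <- tf[green]
  truth <- list(green_mask = binary_mask(green),
                leaf_pixels = leaf_px,
                reference_pixels = ref_px,
                leaf_area_cm2 = s1 / ref_px * leaf_px,
                green_index = leaf_px / (H * W),
                px_per_cm = p$box_diameter_px / p$box_diameter_cm,
                height_cm = (p$camera_to_soil_mm - p$camera_to_leaf_mm) / 10,
                t_min_c = if (leaf_px) min(canopy_vals) else NA_real_,
                t_max_c = if (leaf_px) max(canopy_vals) else NA_real_,
                t_mean_c = if (leaf_px) mean(canopy_vals) else NA_real_,
                seed = p$seed)
  structure(list(rgb = rgb_img, depth = depth_img, thermal = thermal_img,
                 ref_rgb = ref_img, truth = truth, params = p),
            class = "phk_scene")
}

#' Synthetic systematic/manual measurement pairs
#'
#' Emulates the chamber's validation protocol: each manual value is the
#' average of three noisy readings of the truth (manual measurements were
#' taken in triplicate and averaged); each systematic value is a linear
#' response `slope * truth + intercept` plus one noise draw.
#'
#' @param n Number of pairs (>= 3).
#' @param slope,intercept Systematic response line.
#' @param sigma Gaussian noise sd on the systematic readings (trait units).
#' @param sigma_manual Noise sd of a single manual reading (default
#'   `sigma`); the averaged manual noise then has sd `sigma / sqrt(3)`.
#' @param range Range the true trait values are drawn from.
#' @param trait,stage Labels carried into the result.
#' @param seed Seed fixing all randomness.
#' @return A [paired_measurements()].
#' @export
make_measurement_pairs <- function(n, slope = 1, intercept = 0, sigma = 0,
                                   sigma_manual = sigma, range = c(10, 50),
                                   trait = "trait", stage = "all", seed = 1L) {
  if (n < 3) stop("make_measurement_pairs: need n >= 3")
  with_seed(seed, {
    truth <- stats::runif(n, range[1], range[2])
    manual <- truth + rowMeans(matrix(stats::rnorm(3 * n, 0, sigma_manual), n, 3))
    systematic <- slope * truth + intercept + stats::rnorm(n, 0, sigma)
    paired_measurements(systematic, manual, trait, stage)
  })
}

#' Growth-stage scene presets
#'
#' Four presets tracking the wheat stages sampled in the chamber: trefoil,
#' pre-tillering, late tillering, jointing. Plant heights rise
#' 10.58 -> 20.0 -> 33.28 -> 49.28 cm; canopy mean temperature rises to
#' late tillering and falls to 24.39 degC at jointing; canopy cover grows
#' with leaf number and size.
#'
#' @param camera_to_soil_mm Soil-plane depth (default 600 mm, the chamber's
#'   0.6 m standoff).
#' @return Named list of stage-parameter lists (`n_leaves`, `leaf_len`,
#'   `leaf_wid`, `height_cm`, `canopy_temp_c`).
#' @export
stage_presets <- function(camera_to_soil_mm = 600) {
  list(trefoil        = list(n_leaves = 3, leaf_len = 40, leaf_wid = 7,
                             height_cm = 10.58, canopy_temp_c = 28),
       pre_tillering  = list(n_leaves = 4, leaf_len = 48, leaf_wid = 8,
                             height_cm = 20.0, canopy_temp_c = 34),
       late_tillering = list(n_leaves = 6, leaf_len = 55, leaf_wid = 9,
                             height_cm = 33.28, canopy_temp_c = 36),
       jointing       = list(n_leaves = 7, leaf_len = 60, leaf_wid = 10,
                             height_cm = 49.28, canopy_temp_c = 24.39))
}

#' Parameters for one stage preset
#'
#' @param stage Stage name from [stage_presets()].
#' @param presets Preset list.
#' @param seed Scene seed.
#' @param leaf_scale,height_scale Multiplicative plant-to-plant variation of
#'   leaf size and height (default 1).
#' @param temp_offset_c Additive canopy-temperature variation (default 0).
#' @param ... Further overrides passed to [scene_params()].
#' @return A [scene_params()].
#' @export
stage_scene_params <- function(stage, presets = stage_presets(), seed = 1L,
                               leaf_scale = 1, height_scale = 1,
                               temp_offset_c = 0, ...) {
  ps <- presets[[stage]]
  if (is.null(ps)) stop("stage_scene_params: unknown stage '", stage, "'")
  soil <- 600
  scene_params(leaves = rosette_leaves(ps$n_leaves, c(120.5, 120.5),
                                       ps$leaf_len * leaf_scale,
                                       ps$leaf_wid * leaf_scale),
               camera_to_soil_mm = soil,
               camera_to_leaf_mm = soil - ps$height_cm * height_scale * 10,
               canopy_temp = list(type = "constant",
                                  value = ps$canopy_temp_c + temp_offset_c),
               seed = seed, ...)
}

#' Render a batch of stage scenes (with optional on-disk layout)
#'
#' Renders `boxes` scenes for each stage preset. Boxes within a stage carry
#' deterministic plant-to-plant variation (leaf size, height and canopy
#' temperature spread around the preset), as real replicate boxes would.
#' With `out_dir`, images are written in the CLI-consumable layout
#' (`<stage>_<box>.rgb.png`, `.depth.tif`, `.thermal.png` + `.calib.json`,
#' `.ref.png`) together with a `manifest.json` listing every file and truth
#' value.
#'
#' @param presets From [stage_presets()].
#' @param boxes Root boxes per stage (default 3).
#' @param seed Base seed; scene seeds are derived deterministically.
#' @param out_dir Output directory, or `NULL` to keep scenes in memory.
#' @param ... Overrides passed to [scene_params()] for every scene.
#' @return A list with `manifest` (data.frame of truth values), `scenes`
#'   (list of `phk_scene`, `NULL` entries when written to disk) and `dir`.
#' @export
scene_batch <- function(presets = stage_presets(), boxes = 3L, seed = 1L,
                        out_dir = NULL, ...) {
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  rows <- list()
  scenes <- list()
  entries <- list()
  i <- 0L
  for (stage in names(presets)) {
    for (b in seq_len(boxes)) {
      i <- i + 1L
      sseed <- as.integer(seed) + 131L * i
      spread <- if (boxes > 1) (b - 1) / (boxes - 1) - 0.5 else 0
      sc <- make_scene(stage_scene_params(stage, presets, seed = sseed,
                                          leaf_scale = 1 + 0.2 * spread,
                                          height_scale = 1 + 0.1 * spread,
                                          temp_offset_c = spread, ...))
      id <- sprintf("%s_%d", stage, b)
      tr <- sc$truth
      rows[[i]] <- data.frame(box_id = id, stage = stage, seed = sseed,
                              leaf_area_cm2 = tr$leaf_area_cm2,
                              green_index = tr$green_index,
                              height_cm = tr$height_cm,
                              t_mean_c = tr$t_mean_c,
                              t_min_c = tr$t_min_c, t_max_c = tr$t_max_c,
                              stringsAsFactors = FALSE)
      if (is.null(out_dir)) {
        scenes[[id]] <- sc
      } else {
        files <- list(rgb = paste0(id, ".rgb.png"),
                      depth = paste0(id, ".depth.tif"),
                      thermal = paste0(id, ".thermal.png"),
                      ref = paste0(id, ".ref.png"))
        write_rgb(sc$rgb, file.path(out_dir, files$rgb))
        write_depth(sc$depth, file.path(out_dir, files$depth))
        write_thermal(sc$thermal, file.path(out_dir, files$thermal))
        write_rgb(sc$ref_rgb, file.path(out_dir, files$ref))
        entries[[i]] <- c(list(box_id = id, stage = stage, seed = sseed,
                               files = files),
                          rows[[i]][1, c("leaf_area_cm2", "green_index",
                                         "height_cm", "t_mean_c", "t_min_c",
                                         "t_max_c")])
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    jsonlite::write_json(list(box_diameter_cm = 15, scenes = entries),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(manifest = manifest, scenes = scenes, dir = out_dir)
}
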