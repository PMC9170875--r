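# Batch extraction over a scene directory + manifest, and the run
# configuration shared with the command-line interface.

#' Default run configuration
#'
#' Nested list of every tunable parameter, suitable for JSON round-trips.
#' Unknown keys in a supplied configuration are rejected.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(preprocess = list(median_kernel = 3, depth_kernel = 5,
                         min_area_px = 25, connectivity = 8),
       green = list(method = "excess_green", tau = 20,
                    green_threshold = NULL),
       leaf_area = list(ref_mode = "calibration_image", diameter_cm = 15,
                        pi_compat = NULL),
       height = list(n_repeats = 5, patch = 5, jitter_px = 2, seed = 1),
       thermal = list(method = "threshold", side = "cool",
                      edge_quantile = 0.9),
       validation = list(rmse_denominator = "n"),
       logging = list(level = "info"))
}

#' Merge a partial configuration over the defaults
#'
#' @param config Nested list of overrides; unknown sections or keys are
#'   rejected.
#' @return Full configuration list.
#' @export
merge_config <- function(config) {
  base <- default_config()
  if (is.null(config)) return(base)
  for (sect in names(config)) {
    if (!sect %in% names(base)) stop("config: unknown section '", sect, "'")
    for (key in names(config[[sect]])) {
      if (!key %in% names(base[[sect]])) {
        stop("config: unknown key '", sect, ".", key, "'")
      }
      base[[sect]][[key]] <- config[[sect]][[key]]
    }
  }
  base
}

#' Write the default configuration as JSON
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
init_config <- function(path = "phenokit-config.json") {
  jsonlite::write_json(default_config(), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a JSON configuration, filling defaults
#'
#' @param path JSON path, or `NULL` for pure defaults.
#' @return Full configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- if (is.null(path)) NULL else jsonlite::read_json(path, simplifyVector = TRUE)
  merge_config(cfg)
}

#' Build [green_params()] from a configuration
#' @param config A full configuration list (see [default_config()]).
#' @return A [green_params()].
#' @export
config_green_params <- function(config) {
  green_params(method = config$green$method, tau = config$green$tau,
               green_threshold = config$green$green_threshold)
}

#' Build a [reference_spec()] from a configuration
#' @param config A full configuration list (see [default_config()]).
#' @return A [reference_spec()].
#' @export
config_reference_spec <- function(config) {
  pi_value <- config$leaf_area$pi_compat
  reference_spec(diameter_cm = config$leaf_area$diameter_cm,
                 pi_value = if (is.null(pi_value)) pi else pi_value)
}

#' Extract all traits from every scene of a batch directory
#'
#' Reads the manifest written by [scene_batch()], runs the three trait
#' pipelines on every RGB/depth/thermal triplet, and joins the extracted
#' (systematic) values with the manifest truth (standing in for manual
#' measurements) into a per-stage [agreement_report()]. Per-scene failures
#' are logged as warnings; the call fails only if every scene fails.
#'
#' @param scene_dir Directory of image triplets.
#' @param manifest_path Manifest JSON (default `<scene_dir>/manifest.json`).
#' @param config Configuration list (see [default_config()]).
#' @param out_traits,out_report Optional CSV output paths.
#' @return List with `traits` (data.frame, one row per scene) and `report`
#'   (the agreement table).
#' @export
run_batch <- function(scene_dir,
                      manifest_path = file.path(scene_dir, "manifest.json"),
                      config = default_config(),
                      out_traits = NULL, out_report = NULL) {
  if (!dir.exists(scene_dir)) stop("run_batch: no such directory: ", scene_dir)
  if (!file.exists(manifest_path)) {
    stop("run_batch: manifest not found: ", manifest_path)
  }
  config <- merge_config(config)
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  if (is.null(man$scenes) || length(man$scenes) == 0) {
    stop("run_batch: manifest lists no scenes")
  }
  gp <- config_green_params(config)
  spec <- config_reference_spec(config)
  traits <- list()
  pairs <- list()
  n_fail <- 0L
  for (entry in man$scenes) {
    res <- tryCatch({
      rgb <- read_rgb(file.path(scene_dir, entry$files$rgb))
      depth <- read_depth(file.path(scene_dir, entry$files$depth))
      thermal <- read_thermal(file.path(scene_dir, entry$files$thermal))
      ref <- read_rgb(file.path(scene_dir, entry$files$ref))
      la <- leaf_area_pipeline(rgb, spec, gp, ref_mode = "calibration_image",
                               ref_image = ref,
                               median_kernel = config$preprocess$median_kernel,
                               min_area_px = config$preprocess$min_area_px)
      gi <- green_index(rgb, gp)
      hm <- plant_height_pipeline(rgb, depth, params = gp,
                                  n_repeats = config$height$n_repeats,
                                  patch = config$height$patch,
                                  jitter_px = config$height$jitter_px,
                                  depth_kernel = config$preprocess$depth_kernel,
                                  seed = config$height$seed)
      ct <- canopy_temperature_pipeline(thermal, method = config$thermal$method,
                                        side = config$thermal$side,
                                        edge_quantile = config$thermal$edge_quantile,
                                        median_kernel = config$preprocess$median_kernel)
      list(trait = trait_record(entry$box_id, entry$stage,
                                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                leaf_area_cm2 = la$leaf_area_cm2,
                                green_index = gi,
                                plant_height_cm = hm$height_cm,
                                canopy_t_min = ct$t_min_c,
                                canopy_t_max = ct$t_max_c,
                                canopy_t_mean = ct$t_mean_c),
           pair = data.frame(
             trait = c("leaf_area_cm2", "plant_height_cm", "canopy_t_mean"),
             stage = entry$stage,
             systematic = c(la$leaf_area_cm2, hm$height_cm, ct$t_mean_c),
             manual = c(entry$leaf_area_cm2, entry$height_cm, entry$t_mean_c),
             stringsAsFactors = FALSE))
    }, error = function(e) {
      warning("run_batch: scene '", entry$box_id, "' failed: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(res)) {
      n_fail <- n_fail + 1L
    } else {
      traits[[length(traits) + 1L]] <- res$trait
      pairs[[length(pairs) + 1L]] <- res$pair
    }
  }
  if (length(traits) == 0) {
    stop("run_batch: all ", n_fail, " scenes failed")
  }
  traits <- do.call(rbind, traits)
  pairs <- do.call(rbind, pairs)
  report <- agreement_report(pairs,
                             rmse_denominator = config$validation$rmse_denominator)
  if (!is.null(out_traits)) write_traits(traits, out_traits)
  if (!is.null(out_report)) utils::write.csv(report, out_report, row.names = FALSE)
  list(traits = traits, report = report)
}
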