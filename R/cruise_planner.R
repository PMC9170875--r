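# Serpentine acquisition plan for the gantry-mounted camera group.
#
# The imaging rig visits a rows x cols grid of camera sites along an
# S-shaped (boustrophedon) path, dwelling at each site to collect 3-5
# frames. Defaults follow the chamber protocol: 0.6 m camera standoff,
# 0.5 m/s travel, 50 s dwell, 6 x 3 sites within a 6000 x 2000 mm travel
# envelope.

#' Plan a serpentine cruise over the camera-site grid
#'
#' Boustrophedon order: grid row 0 left-to-right, row 1 right-to-left, and
#' so on, starting at site (0, 0). Every site is visited exactly once and
#' consecutive waypoints differ by one grid step. Total time is the sum of
#' travel (unit moves at `speed_mm_s`) and per-site dwell.
#'
#' @param rows,cols Grid dimensions (default 6 x 3).
#' @param spacing_mm Site spacing in mm: scalar or `c(x, y)`; the site grid
#'   must fit the travel envelope.
#' @param speed_mm_s Travel speed (default 500 mm/s, i.e. 0.5 m/s).
#' @param dwell_s Dwell per site (default 50 s).
#' @param frames_per_site Frames collected per site, in 3..5 (default 4).
#' @param z_offset_mm Camera standoff above the boxes (default 600 mm).
#' @param envelope_mm Travel envelope `c(x, y)` (default 6000 x 2000 mm).
#' @return A list of class `cruise_plan`: `waypoints` (data.frame with
#'   `row`, `col`, `x_mm`, `y_mm`), `z_offset_mm`, `speed_mm_s`, `dwell_s`,
#'   `frames_per_site`, `travel_time_s`, `dwell_time_s`, `total_time_s`,
#'   `total_frames`.
#' @export
s_path <- function(rows = 6L, cols = 3L, spacing_mm = 900,
                   speed_mm_s = 500, dwell_s = 50, frames_per_site = 4L,
                   z_offset_mm = 600, envelope_mm = c(6000, 2000)) {
  if (rows < 1 || cols < 1) stop("s_path: rows and cols must be >= 1")
  if (any(spacing_mm <= 0) || speed_mm_s <= 0) {
    stop("s_path: spacing and speed must be > 0")
  }
  if (frames_per_site < 3 || frames_per_site > 5) {
    stop("s_path: frames_per_site must lie in 3..5")
  }
  sp <- if (length(spacing_mm) == 1) c(spacing_mm, spacing_mm) else spacing_mm
  # grid rows run along x (the long 0-6000 mm axis), cols along y
  if ((rows - 1) * sp[1] > envelope_mm[1] || (cols - 1) * sp[2] > envelope_mm[2]) {
    stop("s_path: grid exceeds the travel envelope (",
         envelope_mm[1], " x ", envelope_mm[2], " mm)")
  }
  wp <- do.call(rbind, lapply(seq_len(rows) - 1L, function(r) {
    cs <- if (r %% 2L == 0L) seq_len(cols) - 1L else rev(seq_len(cols) - 1L)
    data.frame(row = r, col = cs)
  }))
  wp$x_mm <- wp$row * sp[1]
  wp$y_mm <- wp$col * sp[2]
  n <- nrow(wp)
  moves <- if (n > 1) {
    dx <- diff(wp$x_mm); dy <- diff(wp$y_mm)
    sum(sqrt(dx^2 + dy^2))
  } else 0
  travel <- moves / speed_mm_s
  dwell <- n * dwell_s
  structure(list(waypoints = wp, z_offset_mm = z_offset_mm,
                 speed_mm_s = speed_mm_s, dwell_s = dwell_s,
                 frames_per_site = as.integer(frames_per_site),
                 travel_time_s = travel, dwell_time_s = dwell,
                 total_time_s = travel + dwell,
                 total_frames = n * as.integer(frames_per_site)),
            class = "cruise_plan")
}

#' @export
print.cruise_plan <- function(x, ...) {
  cat(sprintf("Cruise plan: %d sites, dwell %g s each, %d frames/site\n",
              nrow(x$waypoints), x$dwell_s, x$frames_per_site))
  cat(sprintf("  travel %.1f s + dwell %.1f s = total %.1f s\n",
              x$travel_time_s, x$dwell_time_s, x$total_time_s))
  invisible(x)
}

#' @export
as.data.frame.cruise_plan <- function(x, ...) x$waypoints
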