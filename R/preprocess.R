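# Shared image-cleaning operators: median filtering, histogram tools,
# valley/Otsu thresholding, connected components, small-object removal,
# histogram equalization. Gray levels are 0-based (0..255) throughout.

check_kernel <- function(kernel) {
  if (!is.numeric(kernel) || length(kernel) != 1L || kernel != round(kernel) ||
      kernel < 3 || kernel %% 2 == 0) {
    stop("kernel must be an odd integer >= 3 (got ", kernel, ")")
  }
  as.integer(kernel)
}

# Reflect-pad a matrix by p pixels on each side (edge row/col mirrored).
reflect_pad <- function(m, p) {
  n <- nrow(m); w <- ncol(m)
  ri <- c(pmin(p:1, n), 1:n, pmax(n - seq_len(p) + 1, 1))
  ci <- c(pmin(p:1, w), 1:w, pmax(w - seq_len(p) + 1, 1))
  m[ri, ci, drop = FALSE]
}

# Row-wise median of a numeric matrix whose invalid entries are +Inf;
# `valid` gives the per-row count of finite entries. Zero-valid rows -> NA.
row_median_sorted <- function(x, valid) {
  n <- nrow(x)
  s <- matrix(x[order(row(x), x)], nrow = n, byrow = TRUE)
  lo <- pmax((valid + 1L) %/% 2L, 1L)
  hi <- pmax((valid + 2L) %/% 2L, 1L)
  out <- (s[cbind(seq_len(n), lo)] + s[cbind(seq_len(n), hi)]) / 2
  out[valid == 0L] <- NA_real_
  out
}

# Core windowed median with reflect padding; optionally exclude zeros
# (depth invalid sentinel) from the window.
window_median <- function(m, kernel, exclude_zero = FALSE) {
  k <- check_kernel(kernel)
  p <- (k - 1L) %/% 2L
  n <- nrow(m); w <- ncol(m)
  pad <- reflect_pad(m, p)
  cols <- matrix(0, nrow = n * w, ncol = k * k)
  idx <- 1L
  for (dj in 0:(k - 1L)) {
    for (di in 0:(k - 1L)) {
      cols[, idx] <- as.vector(pad[di + seq_len(n), dj + seq_len(w)])
      idx <- idx + 1L
    }
  }
  if (exclude_zero) {
    invalid <- cols == 0
    cols[invalid] <- Inf
    valid <- as.integer(rowSums(!invalid))
  } else {
    valid <- rep.int(k * k, n * w)
  }
  med <- row_median_sorted(cols, valid)
  med[is.na(med)] <- 0
  matrix(med, nrow = n, ncol = w)
}

#' Median filter
#'
#' Each output pixel is the median of its `kernel x kernel` neighbourhood,
#' with reflect padding at the edges. For depth images, invalid (0) pixels
#' are excluded from the window and a window with no valid depth yields 0.
#'
#' @param img A [gray_image()], [depth_image()], [binary_mask()] or plain
#'   numeric matrix.
#' @param kernel Odd integer window size, at least 3.
#' @return The filtered image, same class as the input.
#' @export
median_filter <- function(img, kernel = 3L) UseMethod("median_filter")

#' @export
median_filter.gray_image <- function(img, kernel = 3L) {
  gray_image(round(window_median(unclass(img), kernel)))
}

#' @export
median_filter.binary_mask <- function(img, kernel = 3L) {
  binary_mask(round(window_median(unclass(img), kernel)))
}

#' @export
median_filter.depth_image <- function(img, kernel = 5L) {
  depth_image(round(window_median(unclass(img), kernel, exclude_zero = TRUE)))
}

#' @export
median_filter.default <- function(img, kernel = 3L) {
  if (!is.matrix(img)) stop("median_filter: expected a matrix or phenokit image")
  window_median(img, kernel)
}

#' Gray-level histogram (256 bins)
#'
#' @param img A [gray_image()] (or any image with values 0..255).
#' @return Integer vector of 256 counts (class `histogram256`), bin `i`
#'   counting gray level `i - 1`; counts sum to the pixel count.
#' @export
gray_histogram <- function(img) {
  v <- as.vector(unclass(img))
  if (length(v) == 0) stop("gray_histogram: zero-pixel image")
  if (any(v < 0 | v > 255)) stop("gray_histogram: values outside [0, 255]")
  counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  structure(counts, class = "histogram256", n_pixels = length(v))
}

# local maxima of a smoothed histogram, plateau-aware:
# returns data.frame(pos = 0-based gray of plateau midpoint, height)
local_peaks <- function(s) {
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1], -Inf)
  is_peak <- r$values > left & r$values > right
  pos <- floor((starts[is_peak] + ends[is_peak]) / 2) - 1L  # 0-based
  data.frame(pos = pos, height = r$values[is_peak])
}

#' Valley threshold of a bimodal histogram
#'
#' Smooths the histogram with a centred moving average, finds the two
#' highest local maxima at least `min_peak_sep` gray levels apart, and
#' returns the gray level of the minimum of the smoothed histogram strictly
#' between them (midpoint of a flat valley plateau). If no two distinct
#' peaks exist, falls back to [otsu_threshold()] and flags it.
#'
#' @param hist A `histogram256` from [gray_histogram()].
#' @param smooth_window Odd moving-average window (default 9).
#' @param min_peak_sep Minimum peak separation in gray levels (default 10).
#' @param valley_frac The valley between the two modes must drop below this
#'   fraction of the lower peak for the peaks to count as "obvious"
#'   (default 0.8); sampling wiggles on one broad mode are thereby rejected.
#' @return A list of class `phk_threshold` with elements `threshold`
#'   (gray level, 0..255), `method` (`"valley"` or `"otsu_fallback"`) and,
#'   for valley thresholds, `peaks` (the two mode positions).
#' @export
valley_threshold <- function(hist, smooth_window = 9L, min_peak_sep = 10L,
                             valley_frac = 0.8) {
  stopifnot(inherits(hist, "histogram256"))
  smooth_window <- check_kernel(smooth_window)
  h <- (smooth_window - 1L) %/% 2L
  counts <- as.numeric(unclass(hist))
  s <- vapply(1:256, function(i) {
    mean(counts[max(1L, i - h):min(256L, i + h)])
  }, numeric(1))
  pk <- local_peaks(s)
  res <- NULL
  if (nrow(pk) >= 2) {
    pk <- pk[order(-pk$height, pk$pos), , drop = FALSE]
    p1 <- pk$pos[1]
    rest <- pk[abs(pk$pos - p1) >= min_peak_sep, , drop = FALSE]
    for (j in seq_len(nrow(rest))) {
      p2 <- rest$pos[j]
      lo <- min(p1, p2); hi <- max(p1, p2)
      between <- (lo + 2):(hi)  # 1-based indices of gray levels lo+1 .. hi-1
      between <- between[between >= 1 & between <= 256]
      if (length(between) == 0) next
      vals <- s[between]
      vmin <- min(vals)
      # the valley must be pronounced relative to the lower of the two modes,
      # otherwise this is a wiggle on one broad mode, not a second peak
      if (vmin >= valley_frac * min(s[p1 + 1L], rest$height[j])) next
      at <- between[vals == vmin]
      brk <- which(c(diff(at) != 1, TRUE))[1]    # end of first contiguous plateau
      thr <- floor((at[1] + at[brk]) / 2) - 1L   # plateau midpoint, back to 0-based
      res <- list(threshold = as.integer(thr), method = "valley",
                  peaks = c(lo, hi))
      break
    }
  }
  if (is.null(res)) {
    ot <- otsu_threshold(hist)
    res <- list(threshold = as.integer(ot), method = "otsu_fallback",
                peaks = NULL)
  }
  structure(res, class = "phk_threshold")
}

#' Otsu's threshold
#'
#' Maximizes the between-class variance over all 256 candidate thresholds;
#' pixels with gray level `<= t` form the lower class. Ties are broken by
#' the lowest gray level. A histogram with all mass at one level returns
#' that level with attribute `degenerate = TRUE`.
#'
#' @param hist A `histogram256`.
#' @return Integer gray level in 0..255, with attribute `degenerate`.
#' @export
otsu_threshold <- function(hist) {
  stopifnot(inherits(hist, "histogram256"))
  counts <- as.numeric(unclass(hist))
  n <- sum(counts)
  if (n == 0) stop("otsu_threshold: empty histogram")
  lv <- 0:255
  if (sum(counts > 0) == 1L) {
    return(structure(as.integer(lv[counts > 0]), degenerate = TRUE))
  }
  p <- counts / n
  w0 <- cumsum(p)
  mu <- cumsum(p * lv)
  mu_t <- mu[256]
  denom <- w0 * (1 - w0)
  sigma_b <- ifelse(denom > 0, (mu_t * w0 - mu)^2 / denom, -Inf)
  structure(as.integer(lv[which.max(sigma_b)]), degenerate = FALSE)
}

#' Binarize a gray image at a threshold
#'
#' @param img A [gray_image()] (or [depth_image()]).
#' @param threshold Gray level, or a `phk_threshold` from
#'   [valley_threshold()].
#' @param polarity `"above"`: foreground are pixels strictly greater than
#'   the threshold; `"below"`: strictly smaller.
#' @return A [binary_mask()].
#' @export
binarize <- function(img, threshold, polarity = c("above", "below")) {
  polarity <- match.arg(polarity)
  if (inherits(threshold, "phk_threshold")) threshold <- threshold$threshold
  m <- unclass(img)
  fg <- if (polarity == "above") m > threshold else m < threshold
  binary_mask(fg)
}

neighbour_offsets <- function(connectivity) {
  if (connectivity == 4) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else if (connectivity == 8) {
    cbind(dr = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
          dc = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  } else {
    stop("connectivity must be 4 or 8")
  }
}

#' Connected components of a binary mask
#'
#' Labels foreground components 1..K in scan order (column-major first
#' encounter); label 0 is background.
#'
#' @param mask A [binary_mask()].
#' @param connectivity 4 or 8 (default 8; thin leaves survive 8-connectivity
#'   better).
#' @return List of class `phk_components` with `labels` (integer matrix),
#'   `sizes` (pixel count per label) and `connectivity`.
#' @export
connected_components <- function(mask, connectivity = 8L) {
  stopifnot(inherits(mask, "binary_mask"))
  offs <- neighbour_offsets(connectivity)
  n <- nrow(mask); w <- ncol(mask)
  m <- unclass(mask)
  labels <- matrix(0L, n, w)
  fg <- which(m == 1L)
  sizes <- integer(0)
  k <- 0L
  for (seed in fg) {
    if (labels[seed] != 0L) next
    k <- k + 1L
    labels[seed] <- k
    frontier <- seed
    count <- 1L
    while (length(frontier)) {
      fr <- (frontier - 1L) %% n + 1L
      fc <- (frontier - 1L) %/% n + 1L
      nxt <- integer(0)
      for (o in seq_len(nrow(offs))) {
        rr <- fr + offs[o, 1L]
        cc <- fc + offs[o, 2L]
        ok <- rr >= 1L & rr <= n & cc >= 1L & cc <= w
        if (!any(ok)) next
        ni <- (cc[ok] - 1L) * n + rr[ok]
        ni <- ni[m[ni] == 1L & labels[ni] == 0L]
        if (length(ni)) {
          labels[ni] <- k
          nxt <- c(nxt, ni)
        }
      }
      nxt <- unique(nxt)
      count <- count + length(nxt)
      frontier <- nxt
    }
    sizes[k] <- count
  }
  structure(list(labels = labels, sizes = sizes,
                 connectivity = as.integer(connectivity)),
            class = "phk_components")
}

#' Remove small foreground objects
#'
#' Components with fewer than `min_area_px` pixels are set to background;
#' components with `>= min_area_px` pixels are kept intact.
#'
#' @param mask A [binary_mask()].
#' @param min_area_px Minimum component area in pixels (default 25).
#' @param connectivity 4 or 8.
#' @return A [binary_mask()].
#' @export
remove_small_objects <- function(mask, min_area_px = 25L, connectivity = 8L) {
  cc <- connected_components(mask, connectivity)
  keep <- which(cc$sizes >= min_area_px)
  binary_mask(matrix(cc$labels %in% keep, nrow = nrow(cc$labels)))
}

#' Histogram equalization
#'
#' Standard cumulative-distribution remapping to `[0, 255]`; the mapping is
#' monotone non-decreasing in input gray level, so pixel-intensity ordering
#' is preserved. Constant images are returned unchanged.
#'
#' @param img A [gray_image()].
#' @return An equalized [gray_image()].
#' @export
histogram_equalize <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  counts <- as.numeric(unclass(gray_histogram(img)))
  n <- sum(counts)
  cdf <- cumsum(counts)
  cdf_min <- min(cdf[cdf > 0])
  if (cdf_min == n) return(img)  # constant image
  map <- round((cdf - cdf_min) / (n - cdf_min) * 255)
  map <- pmin(pmax(map, 0), 255)
  m <- unclass(img)
  gray_image(matrix(map[m + 1L], nrow = nrow(m)))
}
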