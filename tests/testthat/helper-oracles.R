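# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations: plain loops, explicit
# sorting, scalar flood fill.

# per-pixel sort-and-middle median with reflect padding; optionally treat
# zeros as invalid (excluded; all-invalid window -> 0)
oracle_median <- function(m, k, exclude_zero = FALSE) {
  h <- (k - 1) / 2
  n <- nrow(m); w <- ncol(m)
  refl <- function(i, lim) {
    i <- ifelse(i < 1, 1 - i + 1 - 1, i)        # mirror below: 0 -> 1, -1 -> 2
    ifelse(i > lim, 2 * lim - i + 1, i)          # mirror above: lim+1 -> lim
  }
  out <- matrix(0, n, w)
  for (r in seq_len(n)) {
    for (c in seq_len(w)) {
      vals <- c()
      for (dr in -h:h) for (dc in -h:h) {
        vals <- c(vals, m[refl(r + dr, n), refl(c + dc, w)])
      }
      if (exclude_zero) vals <- vals[vals != 0]
      out[r, c] <- if (length(vals) == 0) 0 else {
        s <- sort(vals)
        L <- length(s)
        if (L %% 2 == 1) s[(L + 1) / 2] else (s[L / 2] + s[L / 2 + 1]) / 2
      }
    }
  }
  out
}

# exhaustive 256-way Otsu scan computing class statistics from scratch
oracle_otsu <- function(counts) {
  lv <- 0:255
  best <- -Inf; best_t <- 0
  for (t in 0:255) {
    lo <- counts[lv <= t]; hi <- counts[lv > t]
    n0 <- sum(lo); n1 <- sum(hi)
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(lv[lv <= t] * lo) / n0
    mu1 <- sum(lv[lv > t] * hi) / n1
    w0 <- n0 / (n0 + n1); w1 <- n1 / (n0 + n1)
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best + 1e-12) { best <- sb; best_t <- t }
  }
  best_t
}

# scalar BFS flood fill labelling; returns list(labels, sizes)
oracle_flood_fill <- function(m, connectivity = 8) {
  n <- nrow(m); w <- ncol(m)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  lab <- matrix(0L, n, w)
  k <- 0L; sizes <- integer(0)
  for (c0 in seq_len(w)) for (r0 in seq_len(n)) {
    if (m[r0, c0] != 1 || lab[r0, c0] != 0) next
    k <- k + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- k; sz <- 1L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        rr <- p[1] + o[1]; cc <- p[2] + o[2]
        if (rr >= 1 && rr <= n && cc >= 1 && cc <= w &&
            m[rr, cc] == 1 && lab[rr, cc] == 0) {
          lab[rr, cc] <- k; sz <- sz + 1L
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
    sizes[k] <- sz
  }
  list(labels = lab, sizes = sizes)
}

# do two labellings induce the same partition of the foreground?
same_partition <- function(lab1, lab2) {
  f1 <- lab1[lab1 > 0]; f2 <- lab2[lab2 > 0]
  if (length(f1) != length(f2)) return(FALSE)
  all(tapply(f2, f1, function(x) length(unique(x))) == 1) &&
    all(tapply(f1, f2, function(x) length(unique(x))) == 1)
}

# random small gray image
random_gray <- function(seed, n = 9, w = n, levels = 0:255) {
  set.seed(seed)
  gray_image(matrix(sample(levels, n * w, replace = TRUE), n, w))
}

# rasterized disk pixel count, computed independently of the generator
oracle_disk_count <- function(H, W, r0, c0, radius) {
  cnt <- 0L
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if ((r - r0)^2 + (c - c0)^2 <= radius^2) cnt <- cnt + 1L
  }
  cnt
}

# small scene used by several depth/thermal tests (fast to render)
small_scene <- function(seed = 1L, ...) {
  make_scene(scene_params(width = 160L, height = 160L,
                          box_center = c(80.5, 80.5), box_diameter_px = 140,
                          ref_diameter_px = 140, seed = seed, ...))
}
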