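# Agreement between systematic (image-derived) and manual measurements:
# Pearson correlation with t-based significance, ordinary least-squares
# calibration fit (manual ~ systematic), R^2 and RMSE.
#
# RMSE uses denominator n (not n - 2): it is treated as the deviation
# between the two measurement routes, a measurement-precision metric, not a
# regression standard error. Configurable via `rmse_denominator`.

#' Paired systematic/manual measurements of one trait
#'
#' @param systematic,manual Equal-length numeric vectors (n >= 3, finite).
#' @param trait Trait name.
#' @param stage Growth-stage label.
#' @return A list of class `paired_measurements`.
#' @export
paired_measurements <- function(systematic, manual, trait = "trait",
                                stage = "all") {
  if (length(systematic) != length(manual)) {
    stop("paired_measurements: systematic and manual must have equal length")
  }
  if (length(systematic) < 3) {
    stop("paired_measurements: need at least 3 pairs")
  }
  if (!all(is.finite(systematic)) || !all(is.finite(manual))) {
    stop("paired_measurements: values must be finite")
  }
  structure(list(systematic = as.numeric(systematic),
                 manual = as.numeric(manual),
                 trait = trait, stage = stage),
            class = "paired_measurements")
}

#' Pearson correlation with significance
#'
#' Sample Pearson r with a two-sided p-value from the exact t-distribution
#' with n - 2 degrees of freedom; significance is declared at p < 0.05
#' (rendered as a star in reports).
#'
#' @param pairs A [paired_measurements()].
#' @return List with `r`, `p_value`, `significant`, `n`.
#' @export
pearson_r <- function(pairs) {
  stopifnot(inherits(pairs, "paired_measurements"))
  if (stats::sd(pairs$systematic) == 0 || stats::sd(pairs$manual) == 0) {
    stop("pearson_r: correlation undefined for zero-variance input")
  }
  ct <- stats::cor.test(pairs$systematic, pairs$manual, method = "pearson",
                        alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- if (abs(r) >= 1) 0 else ct$p.value
  list(r = r, p_value = p, significant = p < 0.05, n = length(pairs$systematic))
}

#' Linear calibration fit between systematic and manual measurements
#'
#' Ordinary least squares `manual = slope * systematic + intercept` (the
#' systematic reading calibrated against the manual reference), with
#' `R^2 = 1 - SSE/SST` and `RMSE = sqrt(SSE / n)` in trait units.
#'
#' @param pairs A [paired_measurements()].
#' @param rmse_denominator `"n"` (default, measurement-precision
#'   convention) or `"n-2"` (regression residual standard error).
#' @return A list of class `regression_report`: `r`, `p_value`,
#'   `significant`, `slope`, `intercept`, `r_squared`, `rmse`, `n`, plus
#'   `trait` and `stage`.
#' @export
linear_fit <- function(pairs, rmse_denominator = c("n", "n-2")) {
  stopifnot(inherits(pairs, "paired_measurements"))
  rmse_denominator <- match.arg(rmse_denominator)
  if (stats::sd(pairs$systematic) == 0) {
    stop("linear_fit: degenerate fit (systematic values have zero variance)")
  }
  fit <- stats::lm(manual ~ systematic,
                   data = data.frame(systematic = pairs$systematic,
                                     manual = pairs$manual))
  res <- stats::residuals(fit)
  n <- length(res)
  sse <- sum(res^2)
  sst <- sum((pairs$manual - mean(pairs$manual))^2)
  r2 <- if (sst == 0) 0 else 1 - sse / sst
  denom <- if (rmse_denominator == "n") n else n - 2L
  cr <- if (stats::sd(pairs$manual) == 0) {
    list(r = NA_real_, p_value = NA_real_, significant = FALSE)
  } else {
    pearson_r(pairs)
  }
  structure(list(r = cr$r, p_value = cr$p_value, significant = cr$significant,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 rmse = sqrt(sse / denom),
                 n = n, trait = pairs$trait, stage = pairs$stage),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  star <- if (isTRUE(x$significant)) "*" else ""
  cat(sprintf("%s / %s (n = %d): r = %.3f%s, manual = %.3f x systematic %+ .3f, R2 = %.3f, RMSE = %.3f\n",
              x$trait, x$stage, x$n, x$r, star, x$slope, x$intercept,
              x$r_squared, x$rmse))
  invisible(x)
}

#' Verbal strength of a correlation
#'
#' `|r| > 0.7`: "very strong"; `0.4 < |r| <= 0.7`: "strong";
#' `0.2 <= |r| <= 0.4`: "average"; below 0.2: "weak".
#'
#' @param r Correlation coefficient in `[-1, 1]`.
#' @return Character label.
#' @export
strength_label <- function(r) {
  if (!is.numeric(r) || is.na(r) || abs(r) > 1) {
    stop("strength_label: r must lie in [-1, 1]")
  }
  a <- abs(r)
  if (a > 0.7) "very strong"
  else if (a > 0.4) "strong"
  else if (a >= 0.2) "average"
  else "weak"
}

#' Per-stage agreement report
#'
#' One [linear_fit()] row per (trait, stage) group; groups with fewer than
#' 3 pairs are skipped with a warning.
#'
#' @param records A `data.frame` with columns `trait`, `stage`,
#'   `systematic`, `manual`.
#' @param rmse_denominator Passed to [linear_fit()].
#' @return A `data.frame` with columns `trait`, `stage`, `n`, `r`,
#'   `significant`, `strength`, `slope`, `intercept`, `r_squared`, `rmse`.
#' @export
agreement_report <- function(records, rmse_denominator = c("n", "n-2")) {
  rmse_denominator <- match.arg(rmse_denominator)
  need <- c("trait", "stage", "systematic", "manual")
  if (!all(need %in% names(records))) {
    stop("agreement_report: records must have columns ",
         paste(need, collapse = ", "))
  }
  groups <- split(records, list(records$trait, records$stage), drop = TRUE)
  rows <- lapply(groups, function(g) {
    if (nrow(g) < 3) {
      warning("agreement_report: skipping ", g$trait[1], "/", g$stage[1],
              " (n = ", nrow(g), " < 3)")
      return(NULL)
    }
    rep <- linear_fit(paired_measurements(g$systematic, g$manual,
                                          g$trait[1], g$stage[1]),
                      rmse_denominator)
    data.frame(trait = rep$trait, stage = rep$stage, n = rep$n,
               r = rep$r, significant = rep$significant,
               strength = if (is.na(rep$r)) NA_character_ else strength_label(rep$r),
               slope = rep$slope, intercept = rep$intercept,
               r_squared = rep$r_squared, rmse = rep$rmse,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    stop("agreement_report: no group had at least 3 pairs")
  }
  rownames(out) <- NULL
  out[order(out$trait, out$stage), , drop = FALSE]
}
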