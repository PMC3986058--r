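#' Enumerate sub-area re-sampling methods
#'
#' A re-sampling method is a `w x h` km rectangle with integer sides up to
#' the full area's `W x H`; every combination is a method, so there are
#' `W * H` of them (40 for the 5 km x 8 km survey).
#'
#' @param W,H Full-area west-east and south-north sizes, whole km, >= 1.
#' @return Data frame with columns `w`, `h`, `area` (km^2).
#' @export
#' @examples
#' nrow(enumerate_methods(5, 8)) # 40
enumerate_methods <- function(W, H) {
  if (length(W) != 1L || length(H) != 1L || W < 1 || H < 1 ||
      W != round(W) || H != round(H)) {
    stop("W and H must be integers >= 1", call. = FALSE)
  }
  g <- expand.grid(w = seq_len(W), h = seq_len(H), KEEP.OUT.ATTRS = FALSE)
  g$area <- g$w * g$h
  g[order(g$area, g$w), , drop = FALSE]
}

#' Group re-sampling methods by distinct area
#'
#' Different rectangle shapes can cover the same area (1x8, 2x4 and 4x2 all
#' give 8 km^2); the CV-area curve pools them. The 40 methods of the
#' 5 km x 8 km design collapse to 24 distinct areas.
#'
#' @param methods Data frame from [enumerate_methods()].
#' @return Data frame with `area` (sorted ascending), `n_methods`, and
#'   `methods` (semicolon-separated `wxh` labels).
#' @export
#' @examples
#' distinct_areas(enumerate_methods(5, 8))
distinct_areas <- function(methods) {
  if (nrow(methods) == 0L) stop("empty method list", call. = FALSE)
  areas <- sort(unique(methods$area))
  out <- data.frame(area = areas, n_methods = NA_integer_,
                    methods = NA_character_)
  for (i in seq_along(areas)) {
    m <- methods[methods$area == areas[i], , drop = FALSE]
    out$n_methods[i] <- nrow(m)
    out$methods[i] <- paste(sprintf("%dx%d", m$w, m$h), collapse = "; ")
  }
  out
}

#' All placements of a sub-rectangle inside the survey area
#'
#' Origins step in whole km; a `w x h` rectangle fits at
#' `(W - w + 1) * (H - h + 1)` positions. Placements use closed boundaries,
#' so lattice points on a sub-area edge belong to every adjacent placement.
#'
#' @param w,h Sub-rectangle sides, km.
#' @param W,H Full-area sides, km.
#' @return Data frame of origins `x0`, `y0` in km.
#' @export
placements <- function(w, h, W, H) {
  if (w > W || h > H) stop("sub-rectangle exceeds the area", call. = FALSE)
  if (w < 1 || h < 1) stop("sides must be >= 1 km", call. = FALSE)
  expand.grid(x0 = 0:(W - w), y0 = 0:(H - h), KEEP.OUT.ATTRS = FALSE)
}

#' CV of SOC versus re-sampling area
#'
#' For every distinct sub-area size, computes the CV (%) of the SOC values
#' inside each placement of each method with that area, and averages with
#' equal weight per placement (all placements of all same-area shapes are
#' pooled). Placements holding fewer than 2 points are excluded with a
#' warning. At the full area (one placement) the curve equals the
#' whole-sample CV.
#'
#' @param samples Sample data frame for a single layer (or pass `layer`).
#' @param W,H Full-area sides in km (defaults 5 and 8).
#' @param layer Optional layer label to filter `samples` by.
#' @return Object of class `area_cv_curve`: data frame with `area_km2`,
#'   `n_placements`, `mean_cv`.
#' @export
cv_area_curve <- function(samples, W = 5, H = 8, layer = NULL) {
  if (!is.null(layer)) samples <- samples[samples$layer == layer, , drop = FALSE]
  keep <- !is.na(samples$soc)
  x <- samples$x[keep]; y <- samples$y[keep]; z <- samples$soc[keep]
  methods <- enumerate_methods(W, H)
  areas <- sort(unique(methods$area))
  out <- data.frame(area_km2 = areas, n_placements = 0L, mean_cv = NA_real_)
  n_skipped <- 0L
  for (i in seq_along(areas)) {
    cvs <- numeric(0)
    for (k in which(methods$area == areas[i])) {
      w <- methods$w[k]; h <- methods$h[k]
      pl <- placements(w, h, W, H)
      for (p in seq_len(nrow(pl))) {
        x0 <- pl$x0[p] * 1000; y0 <- pl$y0[p] * 1000
        inside <- x >= x0 & x <= x0 + w * 1000 & y >= y0 & y <= y0 + h * 1000
        zz <- z[inside]
        if (length(zz) < 2L) { n_skipped <- n_skipped + 1L; next }
        cvs <- c(cvs, 100 * stats::sd(zz) / mean(zz))
      }
    }
    out$n_placements[i] <- length(cvs)
    out$mean_cv[i] <- if (length(cvs) > 0L) mean(cvs) else NA_real_
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " placement(s) with < 2 points excluded", call. = FALSE)
  }
  structure(out, class = c("area_cv_curve", "data.frame"))
}

#' Fit a power law to a CV-area curve
#'
#' Ordinary least squares of `log(CV)` on `log(area)`:
#' `CV = a * area^b`, with `a` the CV at 1 km^2 and `b` the (fractal)
#' scaling exponent. `r_squared` is the coefficient of determination on the
#' log-log scale. Points with CV <= 0 are excluded.
#'
#' @param curve An [cv_area_curve()] result, or any data frame with
#'   `area_km2` and `mean_cv` columns.
#' @return Object of class `power_law_fit` with `a`, `b`, `r_squared`,
#'   `n`, and the underlying `lm` fit.
#' @export
fit_power_law <- function(curve) {
  ok <- is.finite(curve$mean_cv) & curve$mean_cv > 0 & curve$area_km2 > 0
  d <- curve[ok, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 areas with positive CV", call. = FALSE)
  fit <- stats::lm(log(mean_cv) ~ log(area_km2), data = d)
  structure(
    list(a = exp(unname(stats::coef(fit)[1])),
         b = unname(stats::coef(fit)[2]),
         r_squared = summary(fit)$r.squared,
         n = nrow(d), fit = fit),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Power-law CV-area scaling: CV = %.4g * area^%.4g  (R^2 = %.3f, n = %d)\n",
              x$a, x$b, x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) c(a = object$a, b = object$b)

#' Predict CV at a given area from a fitted power law
#'
#' @param object A [fit_power_law()] result.
#' @param area_km2 Areas (km^2) to predict at.
#' @param ... Unused.
#' @return Predicted CV values in percent.
#' @export
predict.power_law_fit <- function(object, area_km2, ...) {
  object$a * area_km2^object$b
}

#' Number of required samples for a target accuracy
#'
#' Classical sample-size formula for estimating a mean to relative accuracy
#' `delta` at a given confidence: `n = ceiling((z * CV / delta)^2)` with
#' `z` the standard-normal quantile (the large-sample t). Rounding is
#' always up, since the result is a minimum sample size.
#'
#' @param cv_percent Coefficient of variation, percent (vectorized).
#' @param delta_percent Relative accuracy, percent of the mean.
#' @param confidence Confidence level in (0, 1), default 0.95.
#' @return Integer sample sizes.
#' @export
#' @examples
#' required_samples(26.7, 5, 0.95) # 110
required_samples <- function(cv_percent, delta_percent = 5, confidence = 0.95) {
  if (any(cv_percent <= 0) || any(delta_percent <= 0)) {
    stop("cv and delta must be > 0", call. = FALSE)
  }
  if (confidence <= 0 || confidence >= 1) {
    stop("confidence must be in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  as.integer(ceiling((z * cv_percent / delta_percent)^2))
}
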