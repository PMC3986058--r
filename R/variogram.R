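#' Empirical semivariogram
#'
#' Method-of-moments estimator: half the mean squared difference between
#' value pairs, binned by separation distance. Pairs with separation in
#' `((k - 1) * lag_width, k * lag_width]` fall in bin `k`; bins are kept
#' for `k * lag_width <= max_dist`, so the defaults (500 m lags to 4700 m)
#' give nine distance classes reaching 4500 m. Empty bins are dropped. The
#' reported `lag` is the nominal bin midpoint distance `k * lag_width`;
#' `avg_dist` is the mean pair separation actually observed in the bin.
#'
#' With `direction` set, only pairs whose bearing (degrees clockwise from
#' north, modulo 180) lies within `tol_deg` of the azimuth are used; a
#' tolerance of 90 degrees reproduces the omnidirectional estimate.
#'
#' @param samples Sample data frame with `x`, `y` and the value column, or
#'   any data frame with those columns.
#' @param value Column to analyse (default `"soc"`).
#' @param scale `"ln"` (default) analyses the natural log of the values —
#'   the appropriate scale for positively skewed SOC — or `"raw"`.
#' @param lag_width Distance-class width, m.
#' @param max_dist Maximum separation considered, m.
#' @param direction Optional azimuth in degrees (0 = north, 90 = east).
#' @param tol_deg Angular tolerance around `direction`, degrees.
#' @return Object of class `semivariogram`: data frame with `lag`,
#'   `avg_dist`, `gamma`, `np`, plus attributes `scale`, `lag_width`,
#'   `max_dist`, `direction`, `n`.
#' @export
empirical_variogram <- function(samples, value = "soc",
                                scale = c("ln", "raw"),
                                lag_width = 500, max_dist = 4700,
                                direction = NULL, tol_deg = 22.5) {
  scale <- match.arg(scale)
  keep <- is.finite(samples[[value]]) & is.finite(samples$x) & is.finite(samples$y)
  x <- samples$x[keep]; y <- samples$y[keep]; z <- samples[[value]][keep]
  n <- length(z)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  if (scale == "ln") {
    if (any(z <= 0)) stop("ln scale requires positive values", call. = FALSE)
    z <- log(z)
  }
  dm <- as.matrix(stats::dist(cbind(x, y)))
  iu <- upper.tri(dm)
  d <- dm[iu]
  if (all(d < 1e-9)) stop("all points coincident: no usable pairs", call. = FALSE)
  g <- 0.5 * (outer(z, z, "-")[iu])^2
  if (!is.null(direction)) {
    dx <- outer(x, x, "-")[iu]
    dy <- outer(y, y, "-")[iu]
    bearing <- (atan2(dx, dy) * 180 / pi) %% 180
    diff <- abs(bearing - (direction %% 180))
    diff <- pmin(diff, 180 - diff)
    sel <- diff <= tol_deg + 1e-9
    if (!any(sel)) stop("no pairs within the direction cone", call. = FALSE)
    d <- d[sel]; g <- g[sel]
  }
  kmax <- floor(max_dist / lag_width + 1e-9)
  k <- ceiling(d / lag_width - 1e-9)
  sel <- k >= 1L & k <= kmax
  if (!any(sel)) stop("no pairs within max_dist", call. = FALSE)
  k <- k[sel]; d <- d[sel]; g <- g[sel]
  np <- tabulate(k, nbins = kmax)
  gamma_hat <- vapply(seq_len(kmax), function(b) {
    if (np[b] == 0L) NA_real_ else mean(g[k == b])
  }, numeric(1))
  avg_d <- vapply(seq_len(kmax), function(b) {
    if (np[b] == 0L) NA_real_ else mean(d[k == b])
  }, numeric(1))
  keep_bin <- np > 0L
  out <- data.frame(lag = (seq_len(kmax) * lag_width)[keep_bin],
                    avg_dist = avg_d[keep_bin],
                    gamma = gamma_hat[keep_bin],
                    np = np[keep_bin])
  structure(out, class = c("semivariogram", "data.frame"),
            scale = scale, lag_width = lag_width, max_dist = max_dist,
            direction = direction, n = n)
}

#' @export
print.semivariogram <- function(x, ...) {
  dir <- attr(x, "direction")
  cat(sprintf("Empirical semivariogram (%s scale, %d points%s)\n",
              attr(x, "scale"), attr(x, "n"),
              if (is.null(dir)) "" else sprintf(", azimuth %g deg", dir)))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
plot.semivariogram <- function(x, model = NULL, ...) {
  graphics::plot(x$avg_dist, x$gamma, xlab = "lag distance (m)",
                 ylab = "semivariance", ylim = c(0, max(x$gamma) * 1.1),
                 pch = 19, ...)
  if (!is.null(model)) lines(model, to = max(x$avg_dist))
  invisible(x)
}

#' Construct a variogram model
#'
#' Supported families and their semivariance at lag `h > 0`
#' (`gamma(0) = 0` exactly; the nugget is the limit from the right):
#' \itemize{
#' \item exponential: `C0 + C * (1 - exp(-3 h / A))`
#' \item spherical: `C0 + C * (1.5 (h/A) - 0.5 (h/A)^3)` for `h <= A`, else `C0 + C`
#' \item gaussian: `C0 + C * (1 - exp(-3 (h/A)^2))`
#' \item linear: `C0 + slope * h`
#' }
#' `A` is the *effective* range — the distance at which the model reaches
#' ~95% of its sill for the exponential and Gaussian (exactly the sill for
#' the spherical). The raw range parameter (`A/3` exponential, `A/sqrt(3)`
#' Gaussian) is stored alongside.
#'
#' @param family One of `"exponential"`, `"spherical"`, `"gaussian"`,
#'   `"linear"`.
#' @param nugget Nugget variance `C0 >= 0`.
#' @param psill Partial sill `C >= 0` (ignored for linear).
#' @param range Effective range `A > 0` in metres (ignored for linear).
#' @param slope Slope for the linear family, >= 0.
#' @return Object of class `variogram_model`.
#' @export
variogram_model <- function(family = c("exponential", "spherical",
                                       "gaussian", "linear"),
                            nugget, psill = NA_real_, range = NA_real_,
                            slope = NA_real_) {
  family <- match.arg(family)
  stopifnot(nugget >= 0)
  if (family == "linear") {
    stopifnot(!is.na(slope), slope >= 0)
    psill <- NA_real_; range <- NA_real_
  } else {
    stopifnot(!is.na(psill), psill >= 0, !is.na(range), range > 0)
    slope <- NA_real_
  }
  raw_range <- switch(family,
    exponential = range / 3,
    gaussian = range / sqrt(3),
    spherical = range,
    linear = NA_real_)
  structure(
    list(family = family, nugget = nugget, psill = psill,
         sill = if (family == "linear") NA_real_ else nugget + psill,
         effective_range = range, range_param = raw_range, slope = slope,
         nugget_ratio = if (family == "linear") NA_real_ else
           if (nugget + psill > 0) nugget / (nugget + psill) else 0,
         r_squared = NA_real_, rss = NA_real_),
    class = "variogram_model"
  )
}

#' Semivariance of a variogram model at given lags
#'
#' @param model A [variogram_model()] (or [fit_variogram()] result).
#' @param h Lag distances in metres, `>= 0`.
#' @return Semivariances; exactly 0 at `h = 0`.
#' @export
model_gamma <- function(model, h) {
  if (any(h < 0)) stop("lag distances must be >= 0", call. = FALSE)
  g <- switch(model$family,
    exponential = model$nugget + model$psill * (1 - exp(-3 * h / model$effective_range)),
    gaussian = model$nugget + model$psill * (1 - exp(-3 * (h / model$effective_range)^2)),
    spherical = {
      hr <- pmin(h / model$effective_range, 1)
      model$nugget + model$psill * (1.5 * hr - 0.5 * hr^3)
    },
    linear = model$nugget + model$slope * h,
    stop("unknown family: ", model$family, call. = FALSE))
  g[h == 0] <- 0
  g
}

#' @export
predict.variogram_model <- function(object, h, ...) model_gamma(object, h)

#' @export
coef.variogram_model <- function(object, ...) {
  if (object$family == "linear") {
    c(nugget = object$nugget, slope = object$slope)
  } else {
    c(nugget = object$nugget, psill = object$psill, sill = object$sill,
      effective_range = object$effective_range,
      nugget_ratio = object$nugget_ratio)
  }
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("Variogram model: %s\n", x$family))
  if (x$family == "linear") {
    cat(sprintf("  nugget %.5g, slope %.5g per m\n", x$nugget, x$slope))
  } else {
    cat(sprintf("  nugget C0 = %.5g, sill C0+C = %.5g, effective range A = %.5g m\n",
                x$nugget, x$sill, x$effective_range))
    cat(sprintf("  nugget ratio %.3f -> %s spatial dependence\n",
                x$nugget_ratio, classify_dependence(x$nugget_ratio)))
  }
  if (!is.na(x$r_squared)) {
    cat(sprintf("  fit: R^2 = %.3f, RSS = %.4g\n", x$r_squared, x$rss))
  }
  invisible(x)
}

#' @export
lines.variogram_model <- function(x, from = 0, to = 5000, n = 200, ...) {
  h <- seq(from, to, length.out = n)
  graphics::lines(h, model_gamma(x, h), ...)
  invisible(x)
}

#' @export
plot.variogram_model <- function(x, from = 0, to = 3 * max(x$effective_range, 1000, na.rm = TRUE), ...) {
  h <- seq(from, to, length.out = 200)
  graphics::plot(h, model_gamma(x, h), type = "l",
                 xlab = "lag distance (m)", ylab = "semivariance", ...)
  invisible(x)
}

# weighted least squares of gamma_hat on the family basis for a FIXED
# range: the model is linear in (C0, C) given A, so solve the 2-parameter
# weighted regression with non-negativity enforced by falling back to the
# boundary fits. Returns list(nugget, psill, rss).
.wls_given_basis <- function(gamma_hat, f, w) {
  rss_of <- function(c0, c) sum(w * (gamma_hat - c0 - c * f)^2)
  sw <- sum(w); swf <- sum(w * f); swf2 <- sum(w * f^2)
  swg <- sum(w * gamma_hat); swfg <- sum(w * f * gamma_hat)
  det <- sw * swf2 - swf^2
  cand <- list()
  if (abs(det) > 1e-12 * max(1, sw * swf2)) {
    c0 <- (swf2 * swg - swf * swfg) / det
    c1 <- (sw * swfg - swf * swg) / det
    if (c0 >= 0 && c1 >= 0) cand[[length(cand) + 1L]] <- c(c0, c1)
  }
  # boundaries: nugget = 0; partial sill = 0
  if (swf2 > 0) {
    c1 <- max(0, swfg / swf2)
    cand[[length(cand) + 1L]] <- c(0, c1)
  }
  cand[[length(cand) + 1L]] <- c(max(0, swg / sw), 0)
  best <- NULL
  for (p in cand) {
    r <- rss_of(p[1], p[2])
    if (is.null(best) || r < best$rss) best <- list(nugget = p[1], psill = p[2], rss = r)
  }
  best
}

.variogram_basis <- function(family, h, A) {
  switch(family,
    exponential = 1 - exp(-3 * h / A),
    gaussian = 1 - exp(-3 * (h / A)^2),
    spherical = {
      hr <- pmin(h / A, 1)
      1.5 * hr - 0.5 * hr^3
    })
}

#' Fit a variogram model to an empirical semivariogram
#'
#' Weighted least squares: minimizes `sum w_k (gamma_hat_k - gamma(h_k))^2`
#' with weights `w_k = N(h_k)` (pair counts, the common software default)
#' or Cressie's `N(h_k) / gamma(h_k)^2`. For the three bounded families the
#' model is linear in nugget and partial sill given the range, so the fit
#' profiles the range over a dense multi-start grid spanning
#' `(0, 2 * max_dist]` and then refines the best bracket by golden-section
#' search; non-negativity of nugget and partial sill is enforced. The
#' linear family is a constrained weighted straight-line fit.
#'
#' `R^2 = 1 - RSS / sum w_k (gamma_hat_k - weighted mean)^2` on the fitted
#' scale; `RSS` is the weighted residual sum of squares.
#'
#' @param sv A [empirical_variogram()] result (or data frame with `lag` or
#'   `avg_dist`, `gamma`, `np`).
#' @param family Model family (see [variogram_model()]).
#' @param weights `"np"` (default) or `"cressie"`.
#' @param n_starts Size of the range profile grid.
#' @return A fitted [variogram_model()] with `r_squared` and `rss` filled in.
#' @export
fit_variogram <- function(sv, family = c("exponential", "spherical",
                                         "gaussian", "linear"),
                          weights = c("np", "cressie"), n_starts = 200) {
  family <- match.arg(family)
  weights <- match.arg(weights)
  h <- if (!is.null(sv$avg_dist)) sv$avg_dist else sv$lag
  g <- sv$gamma
  np <- if (!is.null(sv$np)) sv$np else rep(1, length(g))
  ok <- is.finite(h) & is.finite(g) & np > 0
  h <- h[ok]; g <- g[ok]; np <- np[ok]
  min_bins <- if (family == "linear") 3L else 4L
  if (length(g) < min_bins) {
    stop(sprintf("need at least %d usable bins for a %s fit", min_bins, family),
         call. = FALSE)
  }
  w <- if (weights == "np") np else np / pmax(g, 1e-12)^2
  max_dist <- attr(sv, "max_dist")
  if (is.null(max_dist)) max_dist <- max(h)

  if (family == "linear") {
    sw <- sum(w); swh <- sum(w * h); swh2 <- sum(w * h^2)
    swg <- sum(w * g); swhg <- sum(w * h * g)
    det <- sw * swh2 - swh^2
    c0 <- (swh2 * swg - swh * swhg) / det
    s <- (sw * swhg - swh * swg) / det
    if (c0 < 0) { c0 <- 0; s <- max(0, swhg / swh2) }
    if (s < 0) { s <- 0; c0 <- max(0, swg / sw) }
    m <- variogram_model("linear", nugget = c0, slope = s)
  } else {
    rss_at <- function(A) .wls_given_basis(g, .variogram_basis(family, h, A), w)$rss
    A_grid <- exp(seq(log(min(h) / 4), log(2 * max_dist), length.out = n_starts))
    rss_grid <- vapply(A_grid, rss_at, numeric(1))
    if (!any(is.finite(rss_grid))) {
      stop("variogram fit failed to converge: no finite objective on the range grid",
           call. = FALSE)
    }
    i <- which.min(rss_grid)
    lo <- A_grid[max(1L, i - 1L)]; hi <- A_grid[min(length(A_grid), i + 1L)]
    opt <- stats::optimize(rss_at, interval = c(lo, hi))
    A <- if (opt$objective <= rss_grid[i]) opt$minimum else A_grid[i]
    p <- .wls_given_basis(g, .variogram_basis(family, h, A), w)
    m <- variogram_model(family, nugget = p$nugget, psill = p$psill, range = A)
  }
  res <- g - model_gamma(m, h)
  # gamma(0) = 0 convention never bites here: all bins have h > 0
  rss <- sum(w * res^2)
  tss <- sum(w * (g - sum(w * g) / sum(w))^2)
  m$rss <- rss
  m$r_squared <- if (tss > 0) 1 - rss / tss else as.numeric(rss < 1e-20)
  m$weights <- weights
  m$scale <- attr(sv, "scale") # remembered so kriging runs on the same scale
  m
}

#' Fit all variogram families and pick the best
#'
#' Fits exponential, spherical, gaussian and linear models and ranks by
#' lowest weighted RSS, ties broken by highest R^2 and then by fewest
#' parameters (linear has 2, the bounded families 3).
#'
#' @inheritParams fit_variogram
#' @param families Families to try.
#' @return The best fitted [variogram_model()]; all fits attached as
#'   attribute `fits`.
#' @export
select_variogram <- function(sv, families = c("exponential", "spherical",
                                              "gaussian", "linear"),
                             weights = "np") {
  fits <- list()
  for (f in families) {
    fit <- tryCatch(fit_variogram(sv, family = f, weights = weights),
                    error = function(e) NULL)
    if (!is.null(fit)) fits[[f]] <- fit
  }
  if (length(fits) == 0L) stop("no variogram family could be fitted", call. = FALSE)
  npar <- vapply(fits, function(m) if (m$family == "linear") 2 else 3, numeric(1))
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  r2 <- vapply(fits, `[[`, numeric(1), "r_squared")
  ord <- order(rss, -r2, npar)
  best <- fits[[ord[1]]]
  attr(best, "fits") <- fits
  best
}

#' Classify spatial dependence from the nugget ratio
#'
#' Standard classification of the nugget-to-sill ratio: below 0.25 the
#' variable is strongly spatially dependent, between 0.25 and 0.75
#' (inclusive) moderately, above 0.75 weakly.
#'
#' @param nugget_ratio Ratio `C0 / (C0 + C)` in `[0, 1]` (vectorized).
#' @return Character vector: `"strong"`, `"moderate"` or `"weak"`.
#' @export
#' @examples
#' classify_dependence(c(0.018, 0.25, 0.9))
classify_dependence <- function(nugget_ratio) {
  if (any(nugget_ratio < 0 | nugget_ratio > 1, na.rm = TRUE)) {
    stop("nugget ratio must be in [0, 1]", call. = FALSE)
  }
  ifelse(nugget_ratio < 0.25, "strong",
         ifelse(nugget_ratio <= 0.75, "moderate", "weak"))
}
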