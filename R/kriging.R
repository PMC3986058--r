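#' Ordinary kriging prediction
#'
#' Solves, for each target location, the ordinary kriging system in
#' semivariance form with a Lagrange multiplier enforcing that the weights
#' sum to one, and returns the best linear unbiased prediction
#' `Z_hat(x0) = sum_i lambda_i z(x_i)` with its kriging variance
#' `sigma^2 = sum_i lambda_i gamma(x_i, x0) + mu`. The neighbourhood is
#' global (all samples); with a few hundred points the exact solve is
#' cheap and avoids search-window artefacts. Predictions are on the
#' analysis scale: if the model was fitted to a log-scale semivariogram
#' the sample values are log-transformed first and predictions are of
#' log SOC (see [krige_map()] for back-transformed maps).
#'
#' A target that coincides with a sample gets that sample's value exactly
#' when the nugget is zero. Negative kriging variances arising from
#' round-off are clamped to zero with a warning.
#'
#' @param samples Sample data frame with `x`, `y` and the value column.
#' @param model A fitted [variogram_model()].
#' @param targets Data frame (or 2-column matrix) of prediction locations
#'   `x`, `y` in metres.
#' @param value Value column name (default `"soc"`).
#' @param scale `"ln"` or `"raw"`; defaults to the scale the model was
#'   fitted on.
#' @param keep_weights Attach the `n x m` weight matrix as attribute
#'   `weights` (and the Lagrange multipliers are always returned).
#' @return Data frame with `x`, `y`, `pred`, `var`, `se`, `lagrange`.
#' @export
krige <- function(samples, model, targets, value = "soc", scale = NULL,
                  keep_weights = FALSE) {
  if (is.null(scale)) scale <- if (!is.null(model$scale)) model$scale else "raw"
  keep <- is.finite(samples[[value]])
  x <- samples$x[keep]; y <- samples$y[keep]; z <- samples[[value]][keep]
  if (scale == "ln") {
    if (any(z <= 0)) stop("ln scale requires positive values", call. = FALSE)
    z <- log(z)
  }
  n <- length(z)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (anyDuplicated(cbind(x, y))) {
    stop("duplicate sample locations make the kriging system singular; deduplicate first",
         call. = FALSE)
  }
  targets <- as.data.frame(targets)
  if (is.null(targets$x)) names(targets)[1:2] <- c("x", "y")
  m <- nrow(targets)
  G <- model_gamma(model, as.matrix(stats::dist(cbind(x, y))))
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  d0 <- sqrt(outer(x, targets$x, "-")^2 + outer(y, targets$y, "-")^2)
  g0 <- matrix(model_gamma(model, d0), n, m)
  B <- rbind(g0, rep(1, m))
  sol <- solve(A, B)
  lambda <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1L, ]
  pred <- drop(crossprod(lambda, z))
  vr <- colSums(lambda * g0) + mu
  if (any(vr < 0)) {
    if (any(vr < -1e-6)) {
      warning("negative kriging variance clamped to 0", call. = FALSE)
    }
    vr <- pmax(vr, 0)
  }
  out <- data.frame(x = targets$x, y = targets$y, pred = pred, var = vr,
                    se = sqrt(vr), lagrange = mu)
  if (keep_weights) attr(out, "weights") <- lambda
  attr(out, "scale") <- scale
  out
}

#' Leave-one-out cross-validation of a kriging model
#'
#' Each sample in turn is removed, predicted from all the others under the
#' supplied variogram model, and replaced. Three calibration indices
#' summarize the errors: the mean error (ME, should be near zero for an
#' unbiased predictor), the root mean square error (RMSE, as small as
#' possible), and the root mean square standardized error (RMSSE, errors
#' divided by their kriging standard errors — near one when the variance
#' model is well calibrated).
#'
#' @inheritParams krige
#' @return Object of class `krige_cv`: list with `stats` (ME, RMSE,
#'   RMSSE), `pred` (per-point observed, predicted, se on the analysis
#'   scale), `n`, `scale`.
#' @export
loo_cv <- function(samples, model, value = "soc", scale = NULL) {
  if (is.null(scale)) scale <- if (!is.null(model$scale)) model$scale else "raw"
  keep <- is.finite(samples[[value]])
  x <- samples$x[keep]; y <- samples$y[keep]; z <- samples[[value]][keep]
  if (scale == "ln") z <- log(z)
  n <- length(z)
  if (n < 3L) stop("need at least 3 samples for cross-validation", call. = FALSE)
  if (anyDuplicated(cbind(x, y))) {
    stop("duplicate sample locations; deduplicate first", call. = FALSE)
  }
  G <- model_gamma(model, as.matrix(stats::dist(cbind(x, y))))
  pred <- se <- numeric(n)
  for (i in seq_len(n)) {
    Gi <- G[-i, -i, drop = FALSE]
    ni <- n - 1L
    A <- rbind(cbind(Gi, 1), c(rep(1, ni), 0))
    b <- c(G[-i, i], 1)
    sol <- solve(A, b)
    lambda <- sol[seq_len(ni)]
    pred[i] <- sum(lambda * z[-i])
    se[i] <- sqrt(max(0, sum(lambda * b[seq_len(ni)]) + sol[ni + 1L]))
  }
  err <- pred - z
  stats <- c(ME = mean(err), RMSE = sqrt(mean(err^2)),
             RMSSE = sqrt(mean((err / se)^2)))
  structure(
    list(stats = stats,
         pred = data.frame(x = x, y = y, observed = z, predicted = pred,
                           se = se),
         n = n, scale = scale),
    class = "krige_cv"
  )
}

#' @export
print.krige_cv <- function(x, ...) {
  cat(sprintf("Leave-one-out kriging cross-validation (%d points, %s scale)\n",
              x$n, x$scale))
  cat(sprintf("  ME = %.5g, RMSE = %.4g, RMSSE = %.4g\n",
              x$stats["ME"], x$stats["RMSE"], x$stats["RMSSE"]))
  invisible(x)
}

#' Kriged prediction map over the survey extent
#'
#' Predicts on a regular grid of cell centres and returns raster matrices
#' of predictions and kriging variances (row 1 = southernmost row, as in
#' [write_asc()]). When the analysis ran on the log scale the prediction
#' map can be back-transformed: the default `"lognormal"` rule applies the
#' lognormal-kriging correction `exp(pred + var/2 - lagrange)`; `"naive"`
#' is the plain exponential (biased low); `"none"` leaves log-scale values.
#' The back-transform used is recorded in the result so maps are never
#' ambiguous about their scale.
#'
#' @inheritParams krige
#' @param cell_size Cell size in metres.
#' @param extent `c(extent_x, extent_y)` in metres; default spans the
#'   samples.
#' @param back_transform `"lognormal"`, `"naive"` or `"none"`; ignored for
#'   raw-scale analyses.
#' @return Object of class `krige_raster`: list with matrices `pred` and
#'   `var`, `cell_size`, `origin`, `scale`, `back_transform`.
#' @export
krige_map <- function(samples, model, cell_size, value = "soc", scale = NULL,
                      extent = NULL,
                      back_transform = c("lognormal", "naive", "none")) {
  back_transform <- match.arg(back_transform)
  if (is.null(scale)) scale <- if (!is.null(model$scale)) model$scale else "raw"
  if (is.null(extent)) extent <- c(max(samples$x), max(samples$y))
  cx <- seq(cell_size / 2, extent[1], by = cell_size)
  cy <- seq(cell_size / 2, extent[2], by = cell_size)
  targets <- expand.grid(x = cx, y = cy, KEEP.OUT.ATTRS = FALSE)
  kr <- krige(samples, model, targets, value = value, scale = scale)
  pred <- kr$pred
  if (scale == "ln" && back_transform == "lognormal") {
    pred <- exp(kr$pred + kr$var / 2 - kr$lagrange)
  } else if (scale == "ln" && back_transform == "naive") {
    pred <- exp(kr$pred)
  } else {
    back_transform <- "none"
  }
  structure(
    list(pred = matrix(pred, nrow = length(cy), ncol = length(cx), byrow = TRUE),
         var = matrix(kr$var, nrow = length(cy), ncol = length(cx), byrow = TRUE),
         cell_size = cell_size, origin = c(0, 0), scale = scale,
         back_transform = back_transform),
    class = "krige_raster"
  )
}

#' @export
print.krige_raster <- function(x, ...) {
  cat(sprintf("Kriged raster: %d x %d cells of %g m (%s scale, back-transform: %s)\n",
              nrow(x$pred), ncol(x$pred), x$cell_size, x$scale, x$back_transform))
  cat(sprintf("  prediction range %.4g .. %.4g\n",
              min(x$pred, na.rm = TRUE), max(x$pred, na.rm = TRUE)))
  invisible(x)
}

#' Write a kriged raster's prediction and variance grids
#'
#' @param raster A [krige_map()] result.
#' @param pred_path,var_path Output `.asc` paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_krige_raster <- function(raster, pred_path = NULL, var_path = NULL) {
  if (!is.null(pred_path)) {
    write_asc(raster$pred, raster$cell_size, raster$origin, pred_path)
  }
  if (!is.null(var_path)) {
    write_asc(raster$var, raster$cell_size, raster$origin, var_path)
  }
  invisible(c(pred_path, var_path))
}
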