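# Default per-layer parameterization of the simulator: SOC marginals
# (mean g/kg, CV fraction), spatial structure (nugget ratio, effective
# range m) and covariate marginals/correlations typical of a stone-rich
# desert soil surveyed on a 500 m grid.
.default_soc_marginals <- data.frame(
  layer = c("0-10", "10-20", "20-30", "30-40"),
  mean = c(1.6, 1.5, 1.4, 1.4),
  cv = c(0.368, 0.385, 0.410, 0.421),
  nugget_ratio = c(0.018, 0.054, 0.035, 0.047),
  effective_range = c(1347, 1251, 1047, 1254),
  stringsAsFactors = FALSE
)

# covariate marginal mean, CV (fraction) and target Pearson correlation
# with raw-scale SOC, per layer
.default_covariates <- list(
  "0-10" = data.frame(
    variable = c("stones", "sand", "silt", "clay", "bd"),
    mean = c(12.1, 70.9, 7.5, 9.5, 1.4),
    cv = c(1.005, 0.201, 0.855, 0.844, 0.088),
    cor_soc = c(-0.196, -0.679, 0.676, 0.663, -0.413),
    stringsAsFactors = FALSE
  ),
  "10-20" = data.frame(
    variable = c("stones", "sand", "silt", "clay", "bd"),
    mean = c(13.3, 72.4, 6.5, 7.8, 1.4),
    cv = c(1.034, 0.197, 0.975, 1.024, 0.104),
    cor_soc = c(-0.201, -0.605, 0.606, 0.593, -0.387),
    stringsAsFactors = FALSE
  ),
  "20-30" = data.frame(
    variable = c("stones", "sand", "silt", "clay", "bd"),
    mean = c(15.2, 71.1, 6.5, 7.2, 1.4),
    cv = c(1.013, 0.210, 1.075, 1.113, 0.097),
    cor_soc = c(-0.201, -0.572, 0.572, 0.561, -0.432),
    stringsAsFactors = FALSE
  ),
  "30-40" = data.frame(
    variable = c("stones", "sand", "silt", "clay", "bd"),
    mean = c(69.1, 26.0, 2.4, 2.6, 0.5),
    cv = c(0.245, 0.221, 1.119, 1.230, 0.101),
    cor_soc = c(-0.448, -0.564, 0.567, 0.552, -0.398),
    stringsAsFactors = FALSE
  )
)

#' Moment-matched log-normal parameters
#'
#' Converts an arithmetic mean `m` and coefficient of variation `c`
#' (fraction) into the log-scale parameters of the log-normal distribution
#' with exactly that mean and CV: `sdlog^2 = log(1 + c^2)` and
#' `meanlog = log(m) - sdlog^2 / 2`.
#'
#' @param m Arithmetic mean, must be positive.
#' @param cv Coefficient of variation as a fraction (not percent), >= 0.
#' @return List with `meanlog` and `sdlog`.
#' @export
#' @examples
#' lognormal_params(1.6, 0.368)
lognormal_params <- function(m, cv) {
  if (!is.numeric(m) || any(m <= 0)) stop("mean must be > 0", call. = FALSE)
  if (any(cv < 0)) stop("cv must be >= 0", call. = FALSE)
  s2 <- log(1 + cv^2)
  list(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Parameters of one simulated depth layer
#'
#' Bundles everything [simulate_layer()] needs: the SOC marginal (mean and
#' CV), the spatial covariance structure on the log scale (nugget ratio,
#' effective exponential range, and optionally an explicit log-scale sill),
#' an optional south-to-north linear trend on the log scale, and the
#' covariate specification (marginal mean/CV and target correlation with
#' SOC for stones, sand, silt, clay and bulk density).
#'
#' When `sill_ln` is `NULL` the log-scale sill is derived from `cv` by
#' moment matching, so the marginal CV of the simulated SOC is exactly
#' `cv`. Supplying `sill_ln` overrides the log-scale variance (the marginal
#' mean is preserved); this is how a fitted variogram's sill can be fed
#' back into the generator.
#'
#' @param layer Depth-layer label (see [soc_layers()]).
#' @param mean Marginal mean SOC, g/kg.
#' @param cv Marginal CV of SOC, fraction.
#' @param nugget_ratio Nugget-to-sill ratio in `[0, 1]` of the log-scale field.
#' @param effective_range Effective range of the exponential covariance, m
#'   (distance at ~95% of the sill; correlation `exp(-3 h / A)`).
#' @param sill_ln Optional log-scale total sill (variance of log SOC).
#' @param trend Linear south-to-north slope on the log scale, per metre of
#'   `y` (negative = decreasing northward). Default 0.
#' @param covariates Data frame with columns `variable`, `mean`, `cv`,
#'   `cor_soc`; defaults to the layer's built-in specification.
#' @return Object of class `field_params`.
#' @export
field_params <- function(layer = "0-10",
                         mean = NULL, cv = NULL,
                         nugget_ratio = NULL, effective_range = NULL,
                         sill_ln = NULL, trend = 0,
                         covariates = NULL) {
  row <- .default_soc_marginals[.default_soc_marginals$layer == layer, ]
  if (nrow(row) == 0L) stop("unknown layer: ", layer, call. = FALSE)
  if (is.null(mean)) mean <- row$mean
  if (is.null(cv)) cv <- row$cv
  if (is.null(nugget_ratio)) nugget_ratio <- row$nugget_ratio
  if (is.null(effective_range)) effective_range <- row$effective_range
  if (is.null(covariates)) {
    covariates <- .default_covariates[[layer]]
  } else if (isFALSE(covariates)) {
    covariates <- NULL # SOC only; covariate columns stay NA
  }
  stopifnot(mean > 0, cv >= 0, nugget_ratio >= 0, nugget_ratio <= 1,
            effective_range > 0)
  if (!is.null(covariates)) {
    stopifnot(all(c("variable", "mean", "cv", "cor_soc") %in% names(covariates)),
              all(abs(covariates$cor_soc) < 1))
  }
  structure(
    list(layer = layer, mean = mean, cv = cv, nugget_ratio = nugget_ratio,
         effective_range = effective_range, sill_ln = sill_ln, trend = trend,
         covariates = covariates),
    class = "field_params"
  )
}

#' @export
print.field_params <- function(x, ...) {
  cat(sprintf(
    "Field parameters [%s cm]: mean %.3g g/kg, CV %.1f%%, nugget ratio %.3f, range %g m\n",
    x$layer, x$mean, 100 * x$cv, x$nugget_ratio, x$effective_range))
  if (!is.null(x$sill_ln)) cat(sprintf("  log-scale sill fixed at %.4f\n", x$sill_ln))
  if (x$trend != 0) cat(sprintf("  log-scale N-S trend %.3g per m\n", x$trend))
  invisible(x)
}

#' Default parameter sets for the four survey layers
#'
#' @return Named list of [field_params()] objects, one per layer.
#' @export
default_field_params <- function() {
  out <- lapply(soc_layers(), field_params)
  names(out) <- soc_layers()
  out
}

# Cholesky factor of the exponential correlation over grid nodes; a small
# escalating diagonal jitter absorbs round-off. Returns upper-triangular U
# with t(U) %*% U = R.
.chol_expcor <- function(nodes, effective_range) {
  D <- as.matrix(stats::dist(nodes[, c("x", "y")]))
  R <- exp(-3 * D / effective_range)
  for (jit in c(0, 1e-10, 1e-8, 1e-6)) {
    U <- tryCatch(chol(R + diag(jit, nrow(R))), error = function(e) NULL)
    if (!is.null(U)) return(U)
  }
  stop("covariance matrix is not positive definite after jitter", call. = FALSE)
}

# Pearson correlation between a unit-Gaussian blend of the structural field
# and the log-normal SOC is damped by this factor; the blend weight is
# inflated to compensate so raw-scale correlation targets are achieved.
.lognormal_attenuation <- function(sdlog, nugget_ratio) {
  if (sdlog == 0) return(1)
  sqrt(1 - nugget_ratio) * sdlog / sqrt(expm1(sdlog^2))
}

#' Simulate one depth layer on a sampling lattice
#'
#' Draws SOC as a log-normal random field
#' `SOC(x) = exp(meanlog + trend * (y - mean(y)) + sdlog * (sqrt(1 - nu) * S(x) + sqrt(nu) * eps(x)))`
#' where `S` is a zero-mean unit-variance Gaussian field with exponential
#' correlation `exp(-3 h / A)` (so `A` is the effective range), generated by
#' exact Cholesky factorization of the node covariance, and `eps` is unit
#' white noise carrying the nugget fraction `nu`. Covariates are unit-
#' Gaussian blends of `S` (sign per target) with independent noise, the
#' blend weight calibrated so the achieved raw-scale Pearson correlation
#' with SOC matches the target, then affinely mapped to their marginal mean
#' and CV and clipped to physical ranges (percentages to `[0, 100]`, bulk
#' density positive, texture triples rescaled to sum 100 when they
#' overshoot). The fraction of clipped covariate values is attached as
#' attribute `clip_fraction` and reported with a message when it exceeds 1%.
#'
#' Identical `seed` gives bit-identical output.
#'
#' @param grid A [location_grid()].
#' @param params A [field_params()] object.
#' @param seed Integer seed (required; the function seeds R's RNG).
#' @return Sample data frame (one row per location) with attribute
#'   `clip_fraction`.
#' @export
simulate_layer <- function(grid, params, seed) {
  stopifnot(inherits(grid, "location_grid"), inherits(params, "field_params"))
  nodes <- grid$nodes
  n <- nrow(nodes)
  if (n < 2L) stop("grid must have at least 2 nodes", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))

  sigma2 <- if (is.null(params$sill_ln)) log(1 + params$cv^2) else params$sill_ln
  sdlog <- sqrt(sigma2)
  meanlog <- log(params$mean) - sigma2 / 2
  nu <- params$nugget_ratio

  U <- .chol_expcor(nodes, params$effective_range)
  S <- drop(crossprod(U, stats::rnorm(n)))
  eps <- stats::rnorm(n)
  zln <- meanlog + params$trend * (nodes$y - mean(nodes$y)) +
    sdlog * (sqrt(1 - nu) * S + sqrt(nu) * eps)
  soc <- exp(zln)

  out <- data.frame(
    location_id = nodes$location_id, x = nodes$x, y = nodes$y,
    layer = params$layer, soc = soc,
    stones = NA_real_, sand = NA_real_, silt = NA_real_, clay = NA_real_,
    bd = NA_real_, stringsAsFactors = FALSE
  )

  n_clipped <- 0L
  n_values <- 0L
  if (!is.null(params$covariates)) {
    atten <- .lognormal_attenuation(sdlog, nu)
    cov_spec <- params$covariates
    for (k in seq_len(nrow(cov_spec))) {
      v <- cov_spec$variable[k]
      w <- max(-0.99, min(0.99, cov_spec$cor_soc[k] / atten))
      z <- w * S + sqrt(1 - w^2) * stats::rnorm(n)
      raw <- cov_spec$mean[k] * (1 + cov_spec$cv[k] * z)
      lo <- if (v == "bd") 0.01 else 0
      hi <- if (v == "bd") Inf else 100
      clipped <- raw < lo | raw > hi
      n_clipped <- n_clipped + sum(clipped)
      n_values <- n_values + n
      out[[v]] <- pmin(pmax(raw, lo), hi)
    }
    # texture triple must not exceed 100%; rescale overshooting rows
    tex_sum <- out$sand + out$silt + out$clay
    over <- which(tex_sum > 100)
    if (length(over) > 0L) {
      f <- 100 / tex_sum[over]
      for (v in c("sand", "silt", "clay")) out[[v]][over] <- out[[v]][over] * f
      n_clipped <- n_clipped + length(over)
    }
  }
  clip_fraction <- if (n_values > 0L) n_clipped / n_values else 0
  if (clip_fraction > 0.01) {
    message(sprintf(
      "simulate_layer [%s]: %.1f%% of covariate values clipped to physical range",
      params$layer, 100 * clip_fraction))
  }
  attr(out, "clip_fraction") <- clip_fraction
  out
}

#' Simulate a full multi-layer survey
#'
#' Runs [simulate_layer()] for each parameter set on a shared lattice;
#' layers share location coordinates and are statistically independent of
#' one another. The default design is the 187-location 500 m grid over
#' 5 km x 8 km with four depth layers, i.e. 748 records.
#'
#' @param params Named list of [field_params()], one per layer (default
#'   [default_field_params()]).
#' @param grid A [location_grid()] (default the 187-node survey lattice).
#' @param seed Integer master seed; layer `i` uses `seed + i - 1`.
#' @return Sample data frame of `nrow(grid$nodes) * length(params)` rows
#'   with attribute `clip_fraction` (pooled over layers).
#' @export
#' @examples
#' s <- simulate_survey(seed = 1)
#' nrow(s) # 748
simulate_survey <- function(params = default_field_params(),
                            grid = location_grid(), seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  pieces <- vector("list", length(params))
  clip <- numeric(length(params))
  for (i in seq_along(params)) {
    pieces[[i]] <- simulate_layer(grid, params[[i]], seed = seed + i - 1L)
    clip[i] <- attr(pieces[[i]], "clip_fraction")
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "clip_fraction") <- mean(clip)
  out
}
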