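# tiny FNV-1a hash over a string; stable across platforms and sessions,
# used only to fingerprint the configuration in run reports
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s) %% 256
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte; multiply mod 2^32 split to stay exact
    h <- h - h %% 256 + bitwXor(h %% 256, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Build a pipeline run configuration
#'
#' Returns the default configuration as a plain named list; any element
#' can be overridden by name. The configuration round-trips losslessly
#' through YAML ([read_run_config()] / [write_run_config()]).
#'
#' @param ... Named overrides merged over the defaults (one level deep).
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    input = NULL,                       # CSV path; NULL = simulate
    seed = 1L,
    grid = list(extent_x = 5000, extent_y = 8000, spacing = 500),
    layers = soc_layers(),
    scaling = list(W = 5, H = 8, layer = "0-10",
                   delta_percent = 5, confidence = 0.95,
                   plan_areas_km2 = c(1, 100, 1000)),
    variogram = list(scale = "ln", lag_width = 500, max_dist = 4700,
                     weights = "np"),
    kriging = list(cell_size = 250, back_transform = "lognormal",
                   crossval = TRUE),
    relationships = list(alpha_in = 0.05, alpha_out = 0.10),
    stocks = list(area_km2 = 40, thickness_cm = 10)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      for (k in names(over[[nm]])) cfg[[nm]][[k]] <- over[[nm]][[k]]
    } else {
      cfg[nm] <- list(over[[nm]]) # preserves explicit NULLs
    }
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.validate_config <- function(config) {
  bad <- setdiff(config$layers, soc_layers())
  if (length(bad) > 0L) {
    stop("malformed layer name(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1L) {
    stop("config$seed must be a single integer", call. = FALSE)
  }
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: data acquisition (simulation on the
#' configured lattice, or reading a CSV), layer descriptives, the CV-area
#' re-sampling curve with power-law fit and sample-size planning,
#' semivariogram estimation and model selection per layer with
#' nugget-ratio classification, a kriged map and leave-one-out
#' cross-validation for each layer, correlation and stepwise regression,
#' and SOC density/stock accounting. Stochastic stages draw only from the
#' master seed (the simulator derives one substream per layer), so a
#' given configuration and seed always produces an identical report.
#'
#' A failing stage is recorded with its error message; stages that depend
#' on it are skipped and the report's `status` becomes `"failed"`.
#'
#' @param config A [run_config()] (or list accepted by it).
#' @param out_dir Optional directory for artifacts: `samples.csv`,
#'   `describe.csv`, `cv_curve.csv`, `report.json`, and prediction /
#'   variance rasters for the first configured layer.
#' @return Object of class `run_report`: nested list of per-stage summary
#'   numbers, the seed and a configuration fingerprint.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  .validate_config(config)
  report <- list(
    config_hash = .fnv1a(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                          null = "null")),
    seed = config$seed,
    status = "ok",
    stages = list()
  )
  failed <- character(0)
  run_stage <- function(name, deps, fun) {
    if (length(intersect(deps, failed)) > 0L) {
      report$stages[[name]] <<- list(status = "skipped",
                                     reason = paste("dependency failed:",
                                                    paste(intersect(deps, failed),
                                                          collapse = ", ")))
      failed <<- c(failed, name)
      return(NULL)
    }
    res <- tryCatch(
      withCallingHandlers(
        list(value = fun(), warnings = character(0)),
        warning = function(w) invokeRestart("muffleWarning"),
        message = function(m) invokeRestart("muffleMessage")
      ),
      error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(res))
      failed <<- c(failed, name)
      return(NULL)
    }
    report$stages[[name]] <<- c(list(status = "ok"), res$value)
    invisible(TRUE)
  }

  samples <- NULL
  run_stage("data", character(0), function() {
    if (!is.null(config$input)) {
      samples <<- read_samples(config$input)
    } else {
      grid <- location_grid(config$grid$extent_x, config$grid$extent_y,
                            config$grid$spacing)
      params <- lapply(config$layers, field_params)
      names(params) <- config$layers
      samples <<- simulate_survey(params, grid, seed = config$seed)
    }
    list(n_records = nrow(samples),
         n_locations = length(unique(samples$location_id)),
         layers = unique(samples$layer),
         clip_fraction = attr(samples, "clip_fraction"))
  })

  run_stage("descriptives", "data", function() {
    tab <- describe_survey(samples)
    soc_rows <- tab[tab$variable == "soc", ]
    list(soc = lapply(seq_len(nrow(soc_rows)), function(i) {
      r <- soc_rows[i, ]
      list(layer = r$layer, mean = r$mean, cv = r$cv, sd = r$sd,
           skewness = r$skewness, ks_p = r$ks_p,
           log_transform = r$log_transform, lsd_letters = r$lsd_letters)
    }), table = tab)
  })

  run_stage("scaling", "data", function() {
    sc <- config$scaling
    curve <- cv_area_curve(samples, W = sc$W, H = sc$H, layer = sc$layer)
    pl <- fit_power_law(curve)
    cv_at <- predict(pl, sc$plan_areas_km2)
    nrs <- required_samples(cv_at, sc$delta_percent, sc$confidence)
    list(curve = as.data.frame(curve),
         power_law = list(a = pl$a, b = pl$b, r_squared = pl$r_squared),
         plan = data.frame(area_km2 = sc$plan_areas_km2, cv = cv_at,
                           required_samples = nrs))
  })

  models <- list()
  run_stage("variogram", "data", function() {
    vg <- config$variogram
    out <- list()
    for (l in config$layers) {
      s <- samples[samples$layer == l, ]
      sv <- empirical_variogram(s, scale = vg$scale, lag_width = vg$lag_width,
                                max_dist = vg$max_dist)
      m <- select_variogram(sv, weights = vg$weights)
      models[[l]] <<- m
      out[[l]] <- list(family = m$family, nugget = m$nugget, sill = m$sill,
                       effective_range = m$effective_range,
                       nugget_ratio = m$nugget_ratio,
                       dependence = classify_dependence(m$nugget_ratio),
                       r_squared = m$r_squared, rss = m$rss)
    }
    out
  })

  rasters <- list()
  run_stage("kriging", "variogram", function() {
    kg <- config$kriging
    out <- list()
    for (l in config$layers) {
      s <- samples[samples$layer == l, ]
      r <- krige_map(s, models[[l]], cell_size = kg$cell_size,
                     back_transform = kg$back_transform)
      rasters[[l]] <<- r
      out[[l]] <- list(cells = length(r$pred),
                       pred_mean = mean(r$pred), pred_min = min(r$pred),
                       pred_max = max(r$pred),
                       back_transform = r$back_transform)
    }
    out
  })

  run_stage("crossval", "variogram", function() {
    if (!isTRUE(config$kriging$crossval)) return(list(skipped = TRUE))
    out <- list()
    for (l in config$layers) {
      s <- samples[samples$layer == l, ]
      cv <- loo_cv(s, models[[l]])
      out[[l]] <- as.list(cv$stats)
    }
    out
  })

  run_stage("relationships", "data", function() {
    rl <- config$relationships
    out <- list()
    for (l in config$layers) {
      s <- samples[samples$layer == l, ]
      pm <- pearson_matrix(s, c("soc", "stones", "sand", "silt", "clay", "bd"))
      sw <- stepwise_soc(s, alpha_in = rl$alpha_in, alpha_out = rl$alpha_out)
      out[[l]] <- list(
        cor_soc = as.list(pm$r["soc", -1]),
        stepwise = list(variables = sw$variables,
                        explained_variance = as.list(sw$explained_variance),
                        adj_r_squared = sw$adj_r_squared, mse = sw$mse))
    }
    out
  })

  run_stage("stocks", "data", function() {
    st <- config$stocks
    est <- soc_stocks(samples, thickness_cm = st$thickness_cm,
                      area_m2 = st$area_km2 * 1e6)
    list(layers = est$layers,
         total_density = as.list(est$total_density),
         total_stock_t = list(cf = est$total_stock$cf$t,
                              no_cf = est$total_stock$no_cf$t))
  })

  if (length(failed) > 0L) report$status <- "failed"
  class(report) <- c("run_report", "list")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(samples)) {
      write_samples(samples, file.path(out_dir, "samples.csv"))
      utils::write.csv(describe_survey(samples),
                       file.path(out_dir, "describe.csv"), row.names = FALSE)
    }
    if (!is.null(report$stages$scaling$curve)) {
      utils::write.csv(report$stages$scaling$curve,
                       file.path(out_dir, "cv_curve.csv"), row.names = FALSE)
    }
    if (length(rasters) > 0L) {
      l1 <- config$layers[1]
      write_krige_raster(rasters[[l1]],
                         file.path(out_dir, "pred.asc"),
                         file.path(out_dir, "var.asc"))
    }
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", null = "null", force = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %s, config %s): %s\n",
              x$seed, x$config_hash, x$status))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-13s %s%s\n", nm, st$status,
                if (!is.null(st$error)) paste0(" (", st$error, ")") else ""))
  }
  invisible(x)
}
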