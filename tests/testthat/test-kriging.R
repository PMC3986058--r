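test_that("ordinary kriging interpolates exactly when the nugget is zero", {
  s <- small_layer()
  m <- variogram_model("exponential", nugget = 0, psill = 0.12, range = 1200)
  kr <- krige(s, m, s[3, c("x", "y")], scale = "raw")
  expect_equal(kr$pred, s$soc[3], tolerance = 1e-8)
  expect_equal(kr$var, 0, tolerance = 1e-8)
})

test_that("kriging weights sum to one for arbitrary configurations", {
  set.seed(20)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    s <- data.frame(x = runif(n, 0, 5000), y = runif(n, 0, 8000),
                    soc = rlnorm(n, 0.4, 0.4))
    m <- variogram_model("exponential", nugget = runif(1, 0, 0.05),
                         psill = runif(1, 0.05, 0.2),
                         range = runif(1, 500, 3000))
    targets <- data.frame(x = runif(5, 0, 5000), y = runif(5, 0, 8000))
    kr <- krige(s, m, targets, scale = "raw", keep_weights = TRUE)
    w <- attr(kr, "weights")
    expect_true(all(abs(colSums(w) - 1) < 1e-8))
    expect_true(all(kr$var >= 0))
  }
})

test_that("a pure-nugget model predicts the neighbourhood mean with equal weights", {
  s <- small_layer()
  m <- variogram_model("exponential", nugget = 0.1, psill = 0, range = 1000)
  target <- data.frame(x = 123.4, y = 567.8)
  kr <- krige(s, m, target, scale = "raw", keep_weights = TRUE)
  expect_equal(kr$pred, mean(s$soc), tolerance = 1e-10)
  w <- attr(kr, "weights")
  expect_true(all(abs(w - 1 / nrow(s)) < 1e-10))
})

test_that("kriging is translation invariant in the data values", {
  s <- small_layer()
  m <- variogram_model("spherical", nugget = 0.01, psill = 0.1, range = 1500)
  targets <- data.frame(x = c(250, 1100), y = c(250, 900))
  base <- krige(s, m, targets, scale = "raw")
  s2 <- s; s2$soc <- s2$soc + 7
  shifted <- krige(s2, m, targets, scale = "raw")
  expect_equal(shifted$pred, base$pred + 7, tolerance = 1e-9)
  expect_equal(shifted$var, base$var, tolerance = 1e-12)
})

test_that("duplicate sample locations are rejected, not silently inverted", {
  s <- small_layer()
  s <- rbind(s, s[1, ])
  m <- variogram_model("exponential", nugget = 0.01, psill = 0.1, range = 1000)
  expect_error(krige(s, m, data.frame(x = 10, y = 10), scale = "raw"),
               "duplicate")
})

test_that("cross-validation of a constant field has zero errors", {
  g <- location_grid(2000, 2000, 500)
  s <- data.frame(x = g$nodes$x, y = g$nodes$y, soc = 3)
  m <- variogram_model("exponential", nugget = 0.05, psill = 0.1, range = 1000)
  cv <- loo_cv(s, m, scale = "raw")
  expect_equal(unname(cv$stats["ME"]), 0)
  expect_equal(unname(cv$stats["RMSE"]), 0)
  expect_error(loo_cv(s[1:2, ], m, scale = "raw"), "at least 3")
})

test_that("RMSSE is calibrated and ME unbiased under the generating model", {
  g <- location_grid(3000, 3000, 500) # 49 nodes
  p <- field_params("0-10", nugget_ratio = 0.2, effective_range = 1000,
                    covariates = FALSE)
  s2 <- log(1 + 0.368^2)
  truth <- variogram_model("exponential", nugget = 0.2 * s2,
                           psill = 0.8 * s2, range = 1000)
  stats <- sapply(1:100, function(i) {
    s <- simulate_layer(g, p, seed = 700 + i)
    loo_cv(s, truth, scale = "ln")$stats
  })
  expect_gt(mean(stats["RMSSE", ]), 0.9)
  expect_lt(mean(stats["RMSSE", ]), 1.1)
  expect_lt(abs(mean(stats["ME", ])), 0.02)
})

test_that("kriged maps honour constants, exact nodes and the configured trend", {
  g <- location_grid(2000, 2000, 500)
  s <- data.frame(x = g$nodes$x, y = g$nodes$y, soc = 2.2)
  m <- variogram_model("exponential", nugget = 0, psill = 0.1, range = 1000)
  r <- krige_map(s, m, cell_size = 250, scale = "raw")
  expect_true(all(abs(r$pred - 2.2) < 1e-8))

  # a map cell whose centre coincides with a sample reproduces it (C0 = 0)
  set.seed(30)
  s$soc <- rlnorm(nrow(s), 0.4, 0.3)
  r <- krige_map(s, m, cell_size = 200, scale = "raw")
  # cell centres at 100, 300, 500, ... -> (500, 500) is centre (3, 3)
  i <- which(s$x == 500 & s$y == 500)
  expect_equal(r$pred[3, 3], s$soc[i], tolerance = 1e-8)

  # negative northward log-scale trend shows up as decreasing row means
  gg <- location_grid(5000, 8000, 500)
  p <- field_params("0-10", trend = -1e-4, covariates = FALSE)
  down <- sapply(1:12, function(i) {
    sim <- simulate_layer(gg, p, seed = 800 + i)
    mfit <- fit_variogram(empirical_variogram(sim), "exponential")
    rr <- krige_map(sim, mfit, cell_size = 500)
    cor(seq_len(nrow(rr$pred)), rowMeans(rr$pred), method = "spearman")
  })
  expect_gte(mean(down < 0), 0.95)
})

test_that("kriged rasters export to ESRI ASCII and read back", {
  s <- small_layer()
  m <- variogram_model("exponential", nugget = 0.01, psill = 0.1, range = 1000)
  r <- krige_map(s, m, cell_size = 500, scale = "raw")
  pred_path <- withr::local_tempfile(fileext = ".asc")
  var_path <- withr::local_tempfile(fileext = ".asc")
  write_krige_raster(r, pred_path, var_path)
  back <- read_asc(pred_path)
  expect_equal(back$values, r$pred, tolerance = 1e-6)
  expect_equal(dim(read_asc(var_path)$values), dim(r$var))
})
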