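test_that("two points 400 m apart with values 1 and 3 give one bin with gamma 2", {
  s <- data.frame(x = c(0, 400), y = c(0, 0), soc = c(1, 3))
  sv <- empirical_variogram(s, scale = "raw")
  expect_equal(nrow(sv), 1)
  expect_equal(sv$np, 1)
  expect_equal(sv$gamma, 2)
  expect_equal(sv$avg_dist, 400)
})

test_that("binned estimates equal the all-pairs brute-force oracle", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 30
    s <- data.frame(x = runif(n, 0, 5000), y = runif(n, 0, 8000),
                    soc = rlnorm(n, 0.4, 0.4))
    lw <- sample(c(300, 500, 800), 1)
    sv <- empirical_variogram(s, scale = "raw", lag_width = lw, max_dist = 4700)
    o <- brute_semivariogram(s$x, s$y, s$soc, lw, 4700)
    expect_equal(sv$np, o$np)
    expect_equal(sv$gamma, o$gamma, tolerance = 1e-12)
    expect_equal(sv$avg_dist, o$avg_dist, tolerance = 1e-12)
  }
})

test_that("default binning yields nine 500-m classes on the survey grid", {
  g <- location_grid(5000, 8000, 500)
  s <- data.frame(x = g$nodes$x, y = g$nodes$y,
                  soc = exp(rnorm(187)))
  sv <- empirical_variogram(s, scale = "raw")
  expect_equal(nrow(sv), 9)
  expect_equal(sv$lag, seq(500, 4500, by = 500))
  expect_lte(sum(sv$np), 187 * 186 / 2)
})

test_that("degenerate inputs raise the documented errors", {
  s <- data.frame(x = c(0, 0, 0), y = c(0, 0, 0), soc = c(1, 2, 3))
  expect_error(empirical_variogram(s, scale = "raw"), "coincident")
  expect_error(empirical_variogram(data.frame(x = 1, y = 1, soc = 1)),
               "at least 2")
  s2 <- data.frame(x = c(0, 100), y = c(0, 0), soc = c(1, -3))
  expect_error(empirical_variogram(s2, scale = "ln"), "positive")
})

test_that("a constant field has zero semivariance in every bin", {
  g <- location_grid(2000, 2000, 500)
  s <- data.frame(x = g$nodes$x, y = g$nodes$y, soc = 4)
  sv <- empirical_variogram(s, scale = "raw")
  expect_true(all(sv$gamma == 0))
})

test_that("model semivariances follow their closed forms", {
  m <- variogram_model("exponential", nugget = 0.0019, psill = 0.1029,
                       range = 1347)
  expect_equal(model_gamma(m, 1347), 0.0019 + 0.1029 * (1 - exp(-3)),
               tolerance = 1e-12)
  expect_equal(model_gamma(m, 1347), 0.0997, tolerance = 1e-3)
  expect_equal(model_gamma(m, 1e9), 0.1048, tolerance = 1e-9)
  expect_equal(model_gamma(m, 0), 0) # by convention at exactly zero

  sph <- variogram_model("spherical", nugget = 0.01, psill = 0.09, range = 1200)
  expect_equal(model_gamma(sph, 1200), 0.1)
  expect_equal(model_gamma(sph, 5000), 0.1)
  lin <- variogram_model("linear", nugget = 0.02, slope = 1e-5)
  expect_equal(model_gamma(lin, 1000), 0.03)
  expect_error(model_gamma(m, -5), "lag")
})

test_that("noiseless model curves are recovered exactly for all families", {
  for (fam in c("exponential", "spherical", "gaussian")) {
    truth <- variogram_model(fam, nugget = 0.02, psill = 0.09, range = 1400)
    fit <- fit_variogram(exact_sv(truth), fam)
    expect_equal(fit$nugget, 0.02, tolerance = 1e-3)
    expect_equal(fit$psill, 0.09, tolerance = 1e-3)
    expect_equal(fit$effective_range, 1400, tolerance = 1400 * 1e-3)
    expect_equal(fit$r_squared, 1, tolerance = 1e-6)
  }
  truth <- variogram_model("linear", nugget = 0.01, slope = 2e-5)
  fit <- fit_variogram(exact_sv(truth), "linear")
  expect_equal(fit$nugget, 0.01, tolerance = 1e-10)
  expect_equal(fit$slope, 2e-5, tolerance = 1e-10)
})

test_that("WLS fits beat or match a dense grid-search oracle", {
  set.seed(55)
  g <- location_grid(5000, 8000, 500)
  p <- field_params("0-10", covariates = FALSE)
  for (i in 1:10) {
    sv <- empirical_variogram(simulate_layer(g, p, seed = 600 + i))
    fit <- fit_variogram(sv, "exponential")
    oracle <- brute_variogram_rss(sv, "exponential")
    expect_lte(fit$rss, oracle * 1.01)
  }
})

test_that("model selection picks the generating family on exact data", {
  exp_m <- variogram_model("exponential", nugget = 0.01, psill = 0.1, range = 1300)
  best <- select_variogram(exact_sv(exp_m))
  expect_equal(best$family, "exponential")

  lin_m <- variogram_model("linear", nugget = 0.01, slope = 2e-5)
  best <- select_variogram(exact_sv(lin_m))
  expect_equal(best$family, "linear")

  # selection agrees with exhaustive comparison of the reported RSS values
  fits <- attr(best, "fits")
  rss <- sapply(fits, `[[`, "rss")
  expect_equal(best$rss, min(rss))
})

test_that("nugget-ratio classification follows the 0.25 / 0.75 thresholds", {
  expect_equal(classify_dependence(0.018), "strong")
  expect_equal(classify_dependence(0.25), "moderate")
  expect_equal(classify_dependence(0.75), "moderate")
  expect_equal(classify_dependence(0.9), "weak")
  expect_equal(classify_dependence(c(0.1, 0.5, 0.8)),
               c("strong", "moderate", "weak"))
  expect_error(classify_dependence(1.2), "ratio")
})

test_that("directional semivariograms expose anisotropy and reduce to omnidirectional", {
  g <- location_grid(4000, 4000, 500)
  set.seed(66)
  s <- data.frame(x = g$nodes$x, y = g$nodes$y, soc = rlnorm(81, 0.4, 0.3))
  omni <- empirical_variogram(s, max_dist = 4000)
  wide <- empirical_variogram(s, max_dist = 4000, direction = 45, tol_deg = 90)
  expect_equal(wide$gamma, omni$gamma)
  expect_equal(wide$np, omni$np)

  # strong E-W trend blows up the E-W semivariance but not the N-S one
  s$soc <- s$soc * exp(0.0008 * s$x)
  ew <- empirical_variogram(s, max_dist = 4000, direction = 90, tol_deg = 20)
  ns <- empirical_variogram(s, max_dist = 4000, direction = 0, tol_deg = 20)
  expect_gt(max(ew$gamma), 3 * max(ns$gamma))
  expect_error(empirical_variogram(s, direction = 13.7, tol_deg = 0.001),
               "direction cone")
})
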