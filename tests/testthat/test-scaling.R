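test_that("method enumeration and area grouping match the survey design", {
  m <- enumerate_methods(5, 8)
  expect_equal(nrow(m), 40)
  expect_equal(nrow(enumerate_methods(1, 1)), 1)
  expect_equal(nrow(enumerate_methods(2, 3)), 6)
  expect_error(enumerate_methods(0, 3), "integers")
  expect_error(enumerate_methods(2.5, 3), "integers")

  a <- distinct_areas(m)
  expect_equal(nrow(a), 24)
  expect_equal(sum(a$n_methods), 40)
  a8 <- sort(strsplit(a$methods[a$area == 8], "; ")[[1]])
  expect_equal(a8, sort(c("1x8", "2x4", "4x2")))
  expect_equal(a$methods[a$area == 9], "3x3")
  expect_equal(distinct_areas(enumerate_methods(1, 1))$area, 1)
})

test_that("placement counts match a lattice-enumeration oracle", {
  expect_equal(nrow(placements(5, 8, 5, 8)), 1)
  expect_equal(nrow(placements(1, 1, 5, 8)), 40)
  expect_equal(nrow(placements(4, 3, 5, 8)), 12)
  expect_error(placements(6, 3, 5, 8), "exceeds")
  for (w in 1:5) for (h in 1:8) {
    # oracle: count origins whose closed rectangle fits inside the area
    cnt <- 0
    for (x0 in 0:5) for (y0 in 0:8) if (x0 + w <= 5 && y0 + h <= 8) cnt <- cnt + 1
    expect_equal(nrow(placements(w, h, 5, 8)), cnt)
  }
})

test_that("each 1 km placement holds 9 grid points; the full area all 187", {
  g <- location_grid(5000, 8000, 500)
  s <- data.frame(x = g$nodes$x, y = g$nodes$y, soc = 1,
                  layer = "0-10")
  pl <- placements(1, 1, 5, 8)
  counts <- sapply(seq_len(nrow(pl)), function(i) {
    sum(s$x >= pl$x0[i] * 1000 & s$x <= (pl$x0[i] + 1) * 1000 &
        s$y >= pl$y0[i] * 1000 & s$y <= (pl$y0[i] + 1) * 1000)
  })
  expect_true(all(counts == 9))
  expect_equal(sum(s$x >= 0 & s$x <= 5000 & s$y >= 0 & s$y <= 8000), 187)
})

test_that("the CV-area curve is zero for constant fields and anchored at the full-area CV", {
  g <- location_grid(5000, 8000, 500)
  s <- data.frame(x = g$nodes$x, y = g$nodes$y, soc = 2.5, layer = "0-10")
  curve <- cv_area_curve(s)
  expect_true(all(curve$mean_cv == 0))

  p <- field_params("0-10", covariates = FALSE)
  sim <- simulate_layer(g, p, seed = 17)
  curve <- cv_area_curve(sim)
  expect_equal(curve$mean_cv[curve$area_km2 == 40],
               100 * sd(sim$soc) / mean(sim$soc))
  expect_equal(curve$area_km2, distinct_areas(enumerate_methods(5, 8))$area)
})

test_that("mean CV grows with area for spatially structured fields", {
  g <- location_grid(5000, 8000, 500)
  p <- field_params("0-10", covariates = FALSE)
  rho <- sapply(1:10, function(i) {
    curve <- cv_area_curve(simulate_layer(g, p, seed = 400 + i))
    cor(rank(curve$area_km2), rank(curve$mean_cv))
  })
  expect_true(all(rho > 0.5))
})

test_that("power-law fitting recovers exact curves and flat curves", {
  areas <- distinct_areas(enumerate_methods(5, 8))$area
  exact <- data.frame(area_km2 = areas, mean_cv = 30 * areas^0.05)
  fit <- fit_power_law(exact)
  expect_equal(fit$a, 30, tolerance = 1e-10)
  expect_equal(fit$b, 0.05, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(predict(fit, 100)), 30 * 100^0.05, tolerance = 1e-8)

  flat <- data.frame(area_km2 = areas, mean_cv = 26.7)
  expect_equal(fit_power_law(flat)$b, 0, tolerance = 1e-12)
  expect_error(fit_power_law(exact[1:2, ]), "at least 3")
})

test_that("jittered power-law points recover the exponent within sampling error", {
  areas <- distinct_areas(enumerate_methods(5, 8))$area
  bs <- sapply(1:50, function(i) {
    set.seed(500 + i)
    cv <- 26.7 * areas^0.0789 * exp(rnorm(length(areas), 0, 0.02))
    fit_power_law(data.frame(area_km2 = areas, mean_cv = cv))$b
  })
  expect_lt(abs(mean(bs) - 0.0789), 3 * sd(bs) / sqrt(length(bs)))
})

test_that("the sample-size planner reproduces the worked NRS values", {
  expect_equal(required_samples(26.7, 5, 0.95), 110L)
  expect_equal(required_samples(26.7 * 100^0.0789, 5, 0.95), 227L)
  expect_equal(required_samples(26.7 * 1000^0.0789, 5, 0.95), 326L)
  expect_equal(required_samples(5, 5, 0.95), 4L)
  expect_error(required_samples(26.7, 0), "delta")
})

test_that("required samples is monotone in CV, confidence and accuracy", {
  cvs <- seq(5, 60, by = 5)
  n <- required_samples(cvs, 5, 0.95)
  expect_true(all(diff(n) >= 0))
  expect_true(all(required_samples(30, 5, 0.99) >= required_samples(30, 5, 0.9)))
  expect_true(all(required_samples(30, 2, 0.95) >= required_samples(30, 10, 0.95)))
})
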