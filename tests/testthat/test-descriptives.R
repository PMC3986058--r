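test_that("summary statistics match hand arithmetic and conventions", {
  s <- summarize_layer(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$cv, 50)
  expect_equal(s$median, 2)

  const <- summarize_layer(c(2, 2, 2))
  expect_equal(const$sd, 0)
  expect_equal(const$cv, 0)
  expect_equal(const$skewness, 0)

  expect_error(summarize_layer(5), "at least 2")
  expect_error(summarize_layer(c(-1, 1)), "mean is zero")
})

test_that("skewness/kurtosis use the small-sample-adjusted formulas", {
  set.seed(8)
  x <- rlnorm(60, 0, 0.5)
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  s <- summarize_layer(x)
  expect_equal(s$skewness, G1, tolerance = 1e-10)
  expect_equal(s$kurtosis, G2, tolerance = 1e-10)
  # exactly symmetric sample has zero skewness
  expect_equal(summarize_layer(c(1, 2, 3, 4, 5))$skewness, 0)
})

test_that("CV is scale invariant", {
  set.seed(3)
  for (i in 1:10) {
    v <- rlnorm(30, 1, 0.4)
    k <- runif(1, 0.1, 100)
    expect_equal(summarize_layer(k * v)$cv, summarize_layer(v)$cv)
  }
})

test_that("the K-S test behaves under the null and flags log-normal data", {
  set.seed(14)
  x <- rnorm(500)
  expect_gt(ks_normality(x)$p, 0.05)
  expect_error(ks_normality(c(1, 2, 3)), "at least 5")
  expect_error(ks_normality(rep(1, 10)), "degenerate")
  # raw p below ln-scale p for skewed data in the vast majority of seeds
  wins <- sapply(1:50, function(i) {
    set.seed(200 + i)
    z <- rlnorm(187, 0, sqrt(log(1 + 0.4^2)))
    ks_normality(z)$p < ks_normality(log(z))$p
  })
  expect_gte(mean(wins), 0.9)
  # Lilliefors option returns its corrected p
  expect_lt(ks_normality(x, lilliefors = TRUE)$p, 1)
})

test_that("the log-transform rule fires for skewed positive data only", {
  set.seed(5)
  z <- rlnorm(187, 0.4, 0.5)
  expect_true(summarize_layer(z)$log_transform)
  expect_false(summarize_layer(rnorm(187, 10, 1))$log_transform)
})

test_that("ANOVA + LSD letters separate groups as pairwise t-tests dictate", {
  a <- anova_lsd(list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(10, 11, 12)))
  lets <- setNames(a$means$letters, a$means$group)
  # brute-force pooled-MSE pairwise t oracle
  groups <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(10, 11, 12))
  mse <- mean(sapply(groups, var)) # equal n
  df <- sum(lengths(groups)) - 3
  tstat <- function(a, b) abs(mean(a) - mean(b)) /
    sqrt(mse * (1 / length(a) + 1 / length(b)))
  sig12 <- 2 * pt(-tstat(groups$g1, groups$g2), df) < 0.05
  sig13 <- 2 * pt(-tstat(groups$g1, groups$g3), df) < 0.05
  expect_false(sig12)
  expect_true(sig13)
  expect_true(any(strsplit(lets["g1"], "")[[1]] %in% strsplit(lets["g2"], "")[[1]]))
  expect_false(any(strsplit(lets["g3"], "")[[1]] %in% strsplit(lets["g1"], "")[[1]]))
})

test_that("well-separated groups get distinct letters, null groups share one", {
  set.seed(10)
  a <- anova_lsd(list(lo = rnorm(20, 0, 0.1), hi = rnorm(20, 10, 0.1)))
  expect_false(a$means$letters[1] == a$means$letters[2])

  share <- sapply(1:20, function(i) {
    set.seed(300 + i)
    g <- replicate(4, rnorm(15), simplify = FALSE)
    lets <- anova_lsd(g)$means$letters
    any(sapply(strsplit(lets[1], "")[[1]],
               function(ch) all(grepl(ch, lets, fixed = TRUE))))
  })
  expect_gte(mean(share), 0.6) # LSD's familywise error is liberal, not broken
})

test_that("two-group ANOVA reproduces the pooled t-test (F = t^2)", {
  set.seed(2)
  x <- rnorm(12, 0); y <- rnorm(15, 0.8)
  a <- anova_lsd(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p, tt$p.value, tolerance = 1e-10)
})

test_that("describe_survey returns one row per layer x variable with letters", {
  s <- suppressMessages(simulate_survey(seed = 6))
  d <- describe_survey(s, variables = c("soc", "sand"))
  expect_equal(nrow(d), 8)
  expect_true(all(c("cv", "skewness", "ks_p", "lsd_letters") %in% names(d)))
  expect_true(all(nchar(d$lsd_letters) >= 1))
})
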