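# Weighted Gaussian KDE: fitting, density, sampling, correlations.

toy_points <- function() {
  matrix(c(0.50, 0.20, 0.20,
           0.40, 0.25, 0.25,
           0.60, 0.10, 0.20,
           0.45, 0.30, 0.15,
           0.55, 0.15, 0.25), ncol = 3, byrow = TRUE)
}

test_that("single-kernel model with manual bandwidth is one Gaussian", {
  x0 <- c(0.5, 0.2, 0.2)
  m <- fit_kde(matrix(x0, 1), bandwidth = 0.05)
  probe <- c(0.52, 0.18, 0.22)
  expect_equal(kde_density(m, probe),
               prod(dnorm(probe, x0, 0.05)), tolerance = 1e-12)
})

test_that("weight normalisation invariance and kernel-sum oracle", {
  X <- toy_points()
  m1 <- fit_kde(X, weights = rep(1, 5))
  m2 <- fit_kde(X, weights = rep(2, 5) / 6)
  expect_equal(m1$H, m2$H)
  expect_equal(m1$weights, m2$weights)
  set.seed(3)
  Hinv <- solve(m1$H)
  nc <- (2 * pi)^(-3 / 2) / sqrt(det(m1$H))
  for (i in 1:10) {
    x <- runif(3, 0, 0.8)
    dens <- 0
    for (k in 1:5) {  # explicit kernel-sum oracle
      d <- x - X[k, ]
      dens <- dens + m1$weights[k] * nc * exp(-0.5 * sum(d * (Hinv %*% d)))
    }
    expect_equal(kde_density(m1, x), dens, tolerance = 1e-12)
  }
})

test_that("density integrates to ~1 and errors are informative", {
  X <- toy_points()
  m <- fit_kde(X, bandwidth = 0.04)
  g <- seq(-0.2, 1.0, length.out = 41)
  w <- diff(g[1:2])
  pts <- as.matrix(expand.grid(g, g, g))
  total <- sum(kde_density(m, pts)) * w^3
  expect_equal(total, 1, tolerance = 0.02)
  expect_error(kde_density(m, c(1, 2)), "dimension")
  expect_error(fit_kde(matrix(rep(c(0.3, 0.3, 0.3), 4), 4, byrow = TRUE)),
               "bandwidth")
})

test_that("sampling: determinism, simplex feasibility, kernel frequencies", {
  X <- toy_points()[1:2, ]
  m <- fit_kde(X, weights = c(0.9, 0.1), bandwidth = 0.02)
  s1 <- kde_sample(m, 500, seed = 42)
  s2 <- kde_sample(m, 500, seed = 42)
  expect_identical(s1, s2)
  expect_true(all(s1$x_sugar >= 0 & s1$x_lipids >= 0 & s1$x_proteins >= 0))
  expect_true(all(s1$x_sugar + s1$x_lipids + s1$x_proteins <= 1 + 1e-12))
  expect_equal(s1$x_lignin,
               1 - (s1$x_sugar + s1$x_lipids + s1$x_proteins),
               tolerance = 1e-9)
  # kernel assignment frequencies within binomial 3 sigma of the weights
  f1 <- mean(attr(s1, "kernel_index") == 1)
  expect_lt(abs(f1 - 0.9), 3 * sqrt(0.9 * 0.1 / 500))
})

test_that("single tight kernel concentrates; refit recovers moments", {
  x0 <- c(0.5, 0.2, 0.2)
  m <- fit_kde(matrix(x0, 1), bandwidth = 0.01)
  s <- kde_sample(m, 10000, seed = 1)
  expect_lt(max(abs(colMeans(s[, 1:3]) - x0)), 3 * 0.01 / sqrt(10000) * 3)
  # sample + refit round trip: moments close to source model
  m2 <- fit_kde(toy_points(), bandwidth = 0.03)
  s2 <- kde_sample(m2, 10000, seed = 2)
  mu_model <- colMeans(m2$points)
  expect_lt(max(abs(colMeans(s2[, 1:3]) - mu_model)), 0.01)
})

test_that("pairwise correlations: exact cases and zero-variance flag", {
  x <- c(1, 2, 3, 4, 5)
  cc <- pairwise_correlation(data.frame(a = x, b = -x, c = x * 2))
  expect_equal(unname(cc["a", "b"]), -1)
  expect_equal(unname(cc["a", "c"]), 1)
  set.seed(5)
  ci <- pairwise_correlation(data.frame(u = rnorm(2000), v = rnorm(2000)))
  expect_lt(abs(ci["u", "v"]), 3 / sqrt(2000))
  expect_warning(pairwise_correlation(data.frame(a = x, z = rep(1, 5))),
                 "zero-variance")
})

test_that("fitted feed models show compositional anti-correlations", {
  models <- fixture_feed_models()
  for (ty in c("FW", "AW", "MSW")) {
    s <- kde_sample(models[[ty]], 10000, seed = 17)
    cc <- pairwise_correlation(s[, c("x_sugar", "x_lipids", "x_proteins")])
    expect_lt(cc["x_sugar", "x_proteins"], 0)
    expect_lt(cc["x_sugar", "x_lipids"], 0)
  }
})

test_that("KDE JSON round trip preserves the model", {
  m <- fit_kde(toy_points(), weights = c(2, 1, 1, 3, 1))
  f <- tempfile(fileext = ".json")
  kde_save(m, f)
  m2 <- kde_load(f)
  expect_equal(m2$points, unname(m$points), ignore_attr = TRUE)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$H, unname(m$H), ignore_attr = TRUE)
  x <- c(0.5, 0.2, 0.2)
  expect_equal(kde_density(m2, x), kde_density(m, x), tolerance = 1e-12)
  unlink(f)
})
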