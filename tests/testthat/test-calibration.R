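test_that("bandwidth follows sigma * (4/(3L))^(1/5)", {
  set.seed(1)
  x <- as.numeric(scale(rnorm(100)))  # sd exactly 1, L = 100
  expect_equal(silverman_bandwidth(x), (4 / 300)^0.2)
  expect_equal((4 / 300)^0.2, 0.4217, tolerance = 1e-4)
  expect_equal(silverman_bandwidth(2 * x), 2 * silverman_bandwidth(x))
  expect_identical(silverman_bandwidth(rep(3, 50)), 0)  # degenerate signal
  expect_error(silverman_bandwidth(1), "at least 2")
})

test_that("KDE cumulative evaluator matches numeric integration oracle", {
  set.seed(2)
  x <- rnorm(40, 2, 1.5)
  rho <- silverman_bandwidth(x)
  cdf <- estimate_density_cdf(x, rho)
  # oracle: integrate the mixture density directly
  dens <- function(z) mean(dnorm(z, mean = x, sd = rho))
  for (q in c(-1, 1.5, 3.2)) {
    oracle <- integrate(Vectorize(dens), -Inf, q, rel.tol = 1e-9)$value
    expect_equal(cdf(q), oracle, tolerance = 1e-6)
  }
  # monotone, with proper limits
  grid <- seq(min(x) - 5, max(x) + 5, length.out = 100)
  expect_true(all(diff(cdf(grid)) >= 0))
  expect_lt(cdf(min(x) - 8 * rho), 1e-6)
  expect_gt(cdf(max(x) + 8 * rho), 1 - 1e-6)
  # symmetric sample: median maps to ~0.5
  xs <- c(-3, -1, -0.2, 0.2, 1, 3)
  expect_equal(estimate_density_cdf(xs, 0.5)(0), 0.5)
  # bimodal mass split: Phi(5) ~ fraction of points below 5
  xb <- c(rep(0, 9), 10)
  expect_equal(estimate_density_cdf(xb, 0.1)(5), 0.9, tolerance = 1e-6)
  expect_error(estimate_density_cdf(x, 0), "positive")
})

test_that("tail bounds solve Phi(z) = p_th and match quantile oracle", {
  xs <- c(-4, -2, -0.5, 0.5, 2, 4)
  b <- compute_bounds(xs, p_th = 0.5, rho = 0.7)
  expect_equal(b$z_lb, b$z_ub, tolerance = 1e-6)   # both are the median
  expect_equal(b$z_ub, 0, tolerance = 1e-6)        # symmetric about 0
  b2 <- compute_bounds(xs, p_th = 0.9, rho = 0.7)
  expect_equal(b2$z_lb, -b2$z_ub, tolerance = 1e-6)
  expect_lt(b2$z_lb, b2$z_ub)

  set.seed(33)
  z <- rnorm(10000)
  bb <- compute_bounds(z, p_th = 0.999)
  expect_equal(bb$z_ub, 3.09, tolerance = 0.15)    # vs N(0,1) 99.9% quantile
  expect_equal(bb$z_ub, quantile(z, 0.999)[[1]], tolerance = 0.15)
  expect_error(compute_bounds(z, p_th = 1), "0.5")
  expect_error(compute_bounds(rep(1, 10), p_th = 0.9), "degenerate")
})

test_that("calibration clamps out-of-bound values and nothing else", {
  set.seed(4)
  X <- matrix(rnorm(600), 200, 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  b <- fit_feature_bounds(X, p_th = 0.99)
  Xc <- calibrate_features(X, b)
  expect_identical(dim(Xc), dim(X))             # no rows deleted
  for (j in 1:3) {
    expect_true(all(Xc[, j] >= b$z_lb[j] - 1e-12))
    expect_true(all(Xc[, j] <= b$z_ub[j] + 1e-12))
  }
  inside <- X[, 1] > b$z_lb[1] & X[, 1] < b$z_ub[1]
  expect_identical(Xc[inside, 1], X[inside, 1])
  # a value just above the upper bound is replaced by the bound
  Xhot <- X; Xhot[1, 2] <- b$z_ub[2] + 1
  expect_equal(unname(calibrate_features(Xhot, b)[1, 2]), b$z_ub[2])
  # idempotence
  expect_identical(calibrate_features(Xc, b), Xc)
  # mean strategy replaces by the training mean
  Xm <- calibrate_features(Xhot, b, strategy = "mean")
  expect_equal(unname(Xm[1, 2]), b$center[2])
  expect_identical(calibrate_features(X, b, strategy = "off"), X)
  expect_error(calibrate_features(X[, 1:2], b), "does not match")
})

test_that("flagged fraction approaches 2(1 - p_th) on smooth data", {
  set.seed(5)
  X <- matrix(rnorm(4000), 2000, 2)
  for (p_th in c(0.95, 0.99)) {
    b <- fit_feature_bounds(X, p_th = p_th)
    flagged <- mean(X < rep(b$z_lb, each = nrow(X)) |
                    X > rep(b$z_ub, each = nrow(X)))
    target <- 2 * (1 - p_th)
    expect_lt(abs(flagged - target), 0.5 * target)  # within KDE error
  }
  # p_th -> 1: calibration approaches identity on the training data
  b1 <- fit_feature_bounds(X, p_th = 0.9999)
  expect_equal(calibrate_features(X, b1), X, tolerance = 1e-4)
})

test_that("bounds survive a JSON round trip", {
  set.seed(6)
  X <- cbind(d_01_02 = rnorm(100), v_01 = rnorm(100, 0, 3),
             flat = rep(1, 100))
  expect_warning(b <- fit_feature_bounds(X, p_th = 0.99), "uncalibrated")
  path <- withr::local_tempfile(fileext = ".json")
  write_feature_bounds(b, path)
  b2 <- read_feature_bounds(path)
  expect_equal(as.data.frame(b2), as.data.frame(b))
  expect_equal(attr(b2, "p_th"), 0.99)
  expect_identical(b2$z_ub[3], Inf)  # uncalibrated column restored
})
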