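test_that("membership transformation reproduces the five-class example", {
  o <- c(-0.9, 0.2, -0.4, -0.8, -0.95)
  mu <- fuzzy_membership(o, gamma = 0.5)
  expect_true(max(abs(mu - c(0.0005, 0.6913, 0.2284, 0.0027, 0.0002))) < 1e-4)
  expect_equal(round(mu[2:5], 4), c(0.6913, 0.2284, 0.0027, 0.0002))
  expect_true(all(mu > 0 & mu <= 1))
  # permutation equivariance
  p <- c(3, 1, 5, 2, 4)
  expect_equal(unname(fuzzy_membership(o[p])), unname(mu[p]))
  # constant outputs: sd = 0 forces exp(-1) everywhere
  expect_equal(fuzzy_membership(c(2, 2, 2)), rep(exp(-1), 3))
  # degenerate scale falls back to equal memberships with a warning
  o0 <- c(-1, 1)  # mean 0, gamma 0 -> scale 0
  expect_warning(mu0 <- fuzzy_membership(o0, gamma = 0), "degenerate")
  expect_equal(mu0, rep(exp(-1), 2))
})

test_that("consistency matrix matches the worked example's inner products", {
  mu <- toy_fuzzy_decisions()
  A <- consistency_matrix(mu)
  expect_equal(round(A[1, 2], 2), 0.53)
  expect_equal(round(A[2, 4], 2), 0.72)
  expect_equal(A[2, 2], sum(mu[2, ]^2))          # diagonal = squared norm
  expect_equal(A[1, 2], sum(mu[1, ] * mu[2, ]))
  expect_equal(A, t(A))
  # disjoint support means zero consistency
  expect_equal(consistency_matrix(rbind(c(1, 0), c(0, 1)))[1, 2], 0)
})

test_that("consistency matrices are symmetric, nonnegative, PSD", {
  set.seed(11)
  for (i in 1:20) {
    nr <- sample(3:8, 1); nc <- sample(2:6, 1)
    m <- matrix(runif(nr * nc), nrow = nr)
    A <- consistency_matrix(m)
    expect_equal(A, t(A))
    expect_true(all(A >= 0))
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
})

test_that("elementwise-dominating decisions have larger consistency", {
  set.seed(12)
  for (i in 1:25) {
    mu2 <- runif(5)
    mu1 <- mu2 + runif(5, 0, 0.5)   # mu1 dominates mu2
    mut <- runif(5)
    expect_gte(sum(mu1 * mut), sum(mu2 * mut))
  }
})

test_that("reliabilities rescale the principal eigenvector into [a, a+b]", {
  A <- consistency_matrix(toy_fuzzy_decisions())
  rel <- reliability_weights(A, a = 0.3, b = 0.7)
  expect_equal(round(rel$w[2], 2), 0.44)         # worked example eigenvector
  expect_equal(sum(rel$w^2), 1)                  # unit norm
  expect_true(all(rel$w >= -1e-12))              # Perron-Frobenius orientation
  expect_equal(min(rel$r), 0.3)
  expect_equal(max(rel$r), 1.0)
  expect_equal(round(rel$r, 2)[c(1, 2, 3)], c(0.38, 1.00, 0.30),
               ignore_attr = TRUE)
  # default bounds span [0.6, 1.0]
  r6 <- reliability_weights(A)
  expect_equal(range(r6$r), c(0.6, 1.0))
  # identical frames: degenerate rule assigns a + b everywhere
  same <- matrix(rep(c(0.2, 0.7, 0.1), each = 4), 4)
  rs <- reliability_weights(consistency_matrix(same), a = 0.6, b = 0.4)
  expect_equal(rs$r, rep(1, 4))
  expect_error(reliability_weights(matrix(numeric(0), 0, 0)), "empty")
})

test_that("RWS fusion reproduces the worked global decision", {
  mu <- toy_fuzzy_decisions()
  # weighted average with the tabulated (2 d.p.) reliabilities reproduces
  # the tabulated global decision digit for digit
  r <- toy_reliabilities()$normalized
  expect_equal(round(unname(colSums(r * mu) / 10), 2),
               c(0.11, 0.27, 0.16, 0.14, 0.14))
  # the full-precision pipeline agrees to ~half a printed digit
  g <- rws_fuse(mu, a = 0.3, b = 0.7)
  expect_lt(max(abs(g$membership - colSums(r * mu) / 10)), 0.005)
  expect_identical(g$winner_index, 2L)
  expect_identical(g$winner, "class2")
  # frame order must not matter
  p <- sample(10)
  g2 <- rws_fuse(mu[p, ], a = 0.3, b = 0.7)
  expect_equal(g2$membership, g$membership, tolerance = 1e-12)
  expect_identical(g2$winner_index, g$winner_index)
  # single frame: reliability defaults to a + b, winner is the arg-max
  g1 <- rws_fuse(mu[1, , drop = FALSE])
  expect_identical(g1$winner, "class5")
  expect_equal(unname(g1$membership), unname(mu[1, ]))
})

test_that("RWS with equal reliabilities agrees with the sum rule", {
  same <- matrix(rep(c(0.2, 0.7, 0.4), each = 5), 5)
  expect_identical(rws_fuse(same)$winner_index,
                   baseline_fuse(same, "sum")$winner_index)
  expect_equal(unname(rws_fuse(same)$membership),
               unname(baseline_fuse(same, "sum")$membership))
})

test_that("baseline rules follow their formulas", {
  two <- rbind(c(0.2, 0.7, 0.4), c(0.2, 0.7, 0.4))
  expect_equal(unname(baseline_fuse(two, "sum")$membership), c(0.2, 0.7, 0.4))
  one <- rbind(c(0.5, 0.25))
  gb <- baseline_fuse(one, "belief", delta = 1e-3)
  expect_equal(unname(gb$membership), c(1 / (0.5 + 1e-3), 1 / (0.75 + 1e-3)))
  expect_identical(gb$winner_index, 1L)
  gp <- baseline_fuse(rbind(c(0.5, 0.2), c(0.3, 0.4)), "product",
                      delta = 1e-3)
  expect_equal(unname(gp$membership), c(0.501 * 0.301, 0.201 * 0.401))
  # majority: symmetric votes tie, average memberships tie, index rule
  gm <- baseline_fuse(rbind(c(0.9, 0.1), c(0.1, 0.9)), "majority")
  expect_identical(gm$winner_index, 1L)
  gm2 <- baseline_fuse(rbind(c(0.9, 0.1), c(0.1, 0.95), c(0.2, 0.9)),
                       "majority")
  expect_identical(gm2$winner_index, 2L)
  expect_equal(unname(gm2$membership), c(1 / 3, 2 / 3))
  # weighted belief discounts by the eigenvector reliabilities
  mu <- toy_fuzzy_decisions()
  rel <- reliability_weights(consistency_matrix(mu), a = 0.3, b = 0.7)
  gw <- baseline_fuse(mu, "wbelief", reliabilities = rel)
  byhand <- apply(1 / (1 - rel$r * mu + 1e-3), 2, prod)
  expect_equal(gw$membership, byhand)
  gw2 <- baseline_fuse(mu, "wbelief", a = 0.3, b = 0.7)  # computed inside
  expect_equal(gw2$membership, byhand)
  expect_error(baseline_fuse(mu, "mystery"), "arg")
})

test_that("winners of scale-free rules ignore common positive scaling", {
  set.seed(13)
  for (i in 1:10) {
    m <- matrix(runif(20, 0.05, 0.95), 4, 5)
    s <- runif(1, 0.1, 3)
    for (rule in c("sum", "rws", "majority")) {
      expect_identical(fuse_decisions(m, rule)$winner_index,
                       fuse_decisions(m * s, rule)$winner_index)
    }
  }
})
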