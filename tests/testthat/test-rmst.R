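test_that("density reduces to the nested family members", {
  # standard normal at the mode
  expect_equal(dmst(0, 0, matrix(1), 0, Inf), 1 / sqrt(2 * pi))
  # delta = 0, nu finite: multivariate t (univariate check against dt)
  x <- seq(-4, 4, by = 0.5)
  expect_equal(dmst(matrix(x, ncol = 1), 0, matrix(1), 0, 5),
               stats::dt(x, 5), tolerance = 1e-12)
  # scale family: t with scale s
  s <- 1.7
  expect_equal(dmst(matrix(x, ncol = 1), 0, matrix(s^2), 0, 7),
               stats::dt(x / s, 7) / s, tolerance = 1e-12)
  # nu = Inf, delta = 0, p = 3: multivariate normal
  S <- matrix(c(2, .5, .1, .5, 1, .3, .1, .3, 1.5), 3)
  mu <- c(1, -1, 0)
  y <- rbind(c(0, 0, 0), c(1, 2, -1))
  ld <- -0.5 * (3 * log(2 * pi) + determinant(S)$modulus[1] +
                  stats::mahalanobis(y, mu, S))
  expect_equal(dmst(y, mu, S, rep(0, 3), Inf, log = TRUE), ld,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("density integrates to one (1-D and 2-D quadrature)", {
  f1 <- function(x) dmst(matrix(x, ncol = 1), 0.5, matrix(1.3), 2, 5)
  i1 <- stats::integrate(f1, -40, 80, rel.tol = 1e-9)$value
  expect_lt(abs(i1 - 1), 1e-4)
  # skew-normal member
  f2 <- function(x) dmst(matrix(x, ncol = 1), 0, matrix(1), -1.5, Inf)
  expect_lt(abs(stats::integrate(f2, -30, 30)$value - 1), 1e-6)

  skip_if_not_installed("pracma")
  S <- matrix(c(1, .4, .4, 1), 2)
  f2d <- function(x, y) {
    pts <- cbind(as.numeric(x), as.numeric(y))
    matrix(dmst(pts, c(0, 0), S, c(1.5, 0.5), 6), nrow = nrow(as.matrix(x)))
  }
  i2 <- pracma::integral2(f2d, -12, 25, -12, 25, reltol = 1e-7)$Q
  expect_lt(abs(i2 - 1), 1e-4)
})

test_that("sampler matches the density (Monte Carlo oracle) and is seeded", {
  y1 <- rmst(100, c(0, 0), diag(2), c(1, 0), 8, seed = 3)
  expect_identical(y1, rmst(100, c(0, 0), diag(2), c(1, 0), 8, seed = 3))

  # half-normal mean identity: nu = Inf, E[Y] = mu + delta sqrt(2/pi)
  n <- 4e5
  ys <- rmst(n, c(1, 2), diag(2), c(2, -1), Inf, seed = 17)
  expect_lt(max(abs(colMeans(ys) - (c(1, 2) + c(2, -1) * sqrt(2 / pi)))),
            3 * 2 / sqrt(n) * 3)

  # binned empirical density vs analytic density, p = 1, (0, 1, 2, 5)
  x <- as.numeric(rmst(1e6, 0, matrix(1), 2, 5, seed = 23))
  br <- seq(-1.5, 4, by = 0.25)
  h <- hist(x[x >= -1.5 & x <= 4], breaks = br, plot = FALSE)
  emp <- h$counts / length(x) / diff(br)
  mid <- h$mids
  ana <- dmst(matrix(mid, ncol = 1), 0, matrix(1), 2, 5)
  # cell-wise binomial error plus binning bias
  expect_lt(max(abs(emp - ana) / (ana + 0.01)), 0.05)
})

test_that("mixture sampler respects weights and class parameters", {
  m <- gmm_model("normal", c(0.3, 0.7),
                 list(list(alpha = c(-2, 0), Psi = diag(c(.1, .01)),
                           theta = rep(.2, 3)),
                      list(alpha = c(3, 0), Psi = diag(c(.1, .01)),
                           theta = rep(.2, 3))),
                 time_scores = 0:2)
  y <- rmst_mixture(m, 5000, seed = 9)
  lab <- y[, 1] > 0.5
  expect_lt(abs(mean(lab) - 0.7), 0.03)
  expect_lt(abs(mean(y[lab, 1]) - 3), 0.1)
})
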