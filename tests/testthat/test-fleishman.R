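test_that("Fleishman solver reproduces target moments analytically", {
  # normal target: identity transform
  fc0 <- fleishman_coeffs(0, 0)
  expect_equal(fc0$b, 1, tolerance = 1e-9)
  expect_equal(fc0$c, 0, tolerance = 1e-9)
  expect_equal(fc0$d, 0, tolerance = 1e-9)

  for (tg in list(c(1, 2), c(1.6, 4))) {
    fc <- fleishman_coeffs(tg[1], tg[2])
    m <- fleishman_moments(fc)
    expect_lt(max(abs(m - c(0, 1, tg[1], tg[2]))), 1e-9)
    expect_gt(fc$b, 0)
    expect_equal(fc$a, -fc$c)
  }
})

test_that("Fleishman transform matches targets in large samples", {
  fc <- fleishman_coeffs(1.6, 4)
  z <- stgmm:::with_seed(7, stats::rnorm(2e6))
  x <- fleishman_transform(z, fc)
  # 3 MC standard errors, inflated for the heavy-tailed fourth moment
  expect_lt(abs(mean(x)), 0.005)
  expect_lt(abs(stats::var(x) - 1), 0.02)
  expect_lt(abs(stgmm:::sample_skewness(x) - 1.6), 0.05)
  expect_lt(abs(stgmm:::sample_ex_kurtosis(x) - 4), 0.4)
})

test_that("infeasible moment targets fail loudly", {
  expect_error(fleishman_coeffs(2, 1), "infeasible")
  # feasibility guard of the study conditions
  expect_true(2 >= 1^2 - 2)
  expect_true(4 >= 1.6^2 - 2)
})

test_that("intermediate correlation solves the Vale-Maurelli cubic", {
  fc <- fleishman_coeffs(1.6, 4)
  fcn <- fleishman_coeffs(0, 0)
  expect_equal(intermediate_correlation(0, fc), 0)
  # normal coefficients reduce the relation to the identity
  expect_equal(intermediate_correlation(0.37, fcn), 0.37, tolerance = 1e-9)

  rz <- intermediate_correlation(0.5, fc)
  expect_gt(rz, 0); expect_lt(rz, 1)
  # Monte Carlo cross-check: transformed pairs hit the target correlation
  n <- 1e6
  zs <- stgmm:::with_seed(11, {
    z1 <- stats::rnorm(n)
    z2 <- rz * z1 + sqrt(1 - rz^2) * stats::rnorm(n)
    cbind(z1, z2)
  })
  r_post <- stats::cor(fleishman_transform(zs[, 1], fc),
                       fleishman_transform(zs[, 2], fc))
  expect_lt(abs(r_post - 0.5), 3 * (1 - 0.5^2) / sqrt(n) * 3)
})

test_that("generator is deterministic and hits implied moments and margins", {
  gp <- bauer_curran_params()
  y1 <- generate_growth_data(gp, 1, 2, n = 500, seed = 99)
  y2 <- generate_growth_data(gp, 1, 2, n = 500, seed = 99)
  expect_identical(y1, y2)
  y3 <- generate_growth_data(gp, 1, 2, n = 500, seed = 100)
  expect_false(identical(y1, y3))
  expect_equal(colnames(y1), paste0("t", 1:5))

  mom <- implied_moments(gp)
  n <- 2e5
  y <- generate_growth_data(gp, 1, 2, n = n, seed = 5)
  expect_lt(max(abs(colMeans(y) - mom$mean) / sqrt(diag(mom$cov) / n)), 4)
  expect_lt(max(abs(stats::cov(y) - mom$cov) / mom$cov[1, 1]), 0.06)
  sk <- apply(y, 2, stgmm:::sample_skewness)
  ku <- apply(y, 2, stgmm:::sample_ex_kurtosis)
  expect_lt(max(abs(sk - 1)), 0.08)
  expect_lt(max(abs(ku - 2)), 0.5)
})
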