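test_that("free-parameter counts follow the model structure", {
  expect_identical(n_free_params("normal", 1, 5), 10L)
  expect_identical(n_free_params("normal", 2, 5), 21L)
  expect_identical(n_free_params("skew_t", 1, 5), 16L)
  expect_identical(n_free_params("t", 1, 5), 11L)
  expect_identical(n_free_params("skew_normal", 1, 5), 15L)
  # factor-structured skew: 2 skew parameters instead of p
  expect_identical(n_free_params("skew_t", 1, 5, "factor"), 13L)
  expect_identical(n_free_params("skew_normal", 2, 5, "factor"), 25L)
  # shared covariance parameters: one set of (Psi, theta, delta, nu)
  expect_identical(n_free_params("normal", 2, 5, cov_structure = "shared"), 13L)
  expect_identical(n_free_params("skew_t", 2, 5, "factor", "shared"), 16L)
})

test_that("compiled mixture log-likelihood agrees with the R density", {
  y <- generate_growth_data(study_params, 1, 2, n = 150, seed = 8)
  f <- fit_gmm(y, "skew_t", K = 1, init = start_one_class,
               starts = quick_starts, seed = 1, skew_structure = "factor")
  ll_r <- sum(gmm_obs_loglik(f$model, y))
  expect_equal(f$loglik, ll_r, tolerance = 1e-8)

  f2 <- fit_gmm(y, "normal", K = 2, init = start_two_class,
                starts = quick_starts, seed = 2)
  expect_equal(f2$loglik, sum(gmm_obs_loglik(f2$model, y)), tolerance = 1e-8)
})

test_that("EM log-likelihood trajectory is monotone across random instances", {
  fams <- st_families()
  set.seed(1)
  worst <- 0
  for (i in 1:40) {
    fam <- fams[(i %% 4) + 1]
    K <- 1 + (i %% 2)
    y <- generate_growth_data(study_params, c(0, 1, 1.6)[(i %% 3) + 1],
                              c(0, 2, 4)[(i %% 3) + 1], n = 60,
                              seed = 1000 + i)
    f <- fit_gmm(y, fam, K = K,
                 starts = start_policy(n_random = 2, short_iter = 5, n_final = 1),
                 seed = i, maxit = 30)
    if (length(f$trajectory) > 1) {
      worst <- max(worst, max(-diff(f$trajectory)))
      expect_true(all(diff(f$trajectory) > -1e-8 * (1 + abs(f$loglik))),
                  info = sprintf("instance %d (%s, K=%d)", i, fam, K))
    }
    expect_true(all(abs(rowSums(f$posteriors) - 1) < 1e-8))
  }
  expect_lt(worst, 1e-6)
})

test_that("one-class normal fit recovers the generating parameters", {
  y <- generate_growth_data(study_params, 0, 0, n = 3200, seed = 2024)
  f <- fit_gmm(y, "normal", K = 1, init = start_one_class,
               starts = quick_starts, seed = 1)
  expect_true(f$converged)
  cl <- f$model$classes[[1]]
  # 3 MC standard errors (asymptotic scale ~ sqrt(var/n))
  expect_lt(abs(cl$alpha[1] - 1.00), 3 * sqrt(2 / 3200) * 1.5)
  expect_lt(abs(cl$alpha[2] - 0.80), 3 * sqrt(0.3 / 3200) * 1.5)
  expect_lt(abs(cl$Psi[2, 2] - 0.20), 0.05)
  expect_lt(max(abs(cl$theta - study_params$residual_vars)), 0.4)
})

test_that("nesting ladder holds when larger families start from smaller ones", {
  y <- generate_growth_data(study_params, 1.6, 4, n = 300, seed = 77)
  fits <- list()
  fits$normal <- fit_gmm(y, "normal", K = 1, init = start_one_class,
                         starts = quick_starts, seed = 1)
  chain <- function(fam, from) {
    init <- list(weights = from$model$weights,
                 classes = lapply(from$model$classes, function(cl) {
                   cl$nu <- if (is.finite(cl$nu)) cl$nu else 50
                   cl
                 }))
    fit_gmm(y, fam, K = 1, init = init, starts = quick_starts, seed = 2,
            skew_structure = "observed")
  }
  fits$t <- chain("t", fits$normal)
  fits$skew_normal <- chain("skew_normal", fits$normal)
  fits$skew_t <- chain("skew_t", fits$skew_normal)
  fits$skew_t2 <- chain("skew_t", fits$t)
  tol <- 1e-4
  expect_gte(fits$t$loglik, fits$normal$loglik - tol)
  expect_gte(fits$skew_normal$loglik, fits$normal$loglik - tol)
  expect_gte(fits$skew_t$loglik, fits$skew_normal$loglik - tol)
  expect_gte(max(fits$skew_t$loglik, fits$skew_t2$loglik),
             fits$t$loglik - tol)
})

test_that("skew-t on normal data collapses toward the normal solution", {
  y <- generate_growth_data(study_params, 0, 0, n = 800, seed = 5)
  fn <- fit_gmm(y, "normal", K = 1, init = start_one_class,
                starts = quick_starts, seed = 1)
  fst <- fit_gmm(y, "skew_t", K = 1, init = start_one_class,
                 starts = quick_starts, seed = 1, skew_structure = "factor")
  expect_gte(fst$loglik, fn$loglik - 1e-4)
  # skew should be near zero and df near the normal limit;
  # 2 dLL no larger than boundary noise for 3 extra parameters
  expect_lt(2 * (fst$loglik - fn$loglik), 12)
  expect_lt(max(abs(fst$model$classes[[1]]$delta)), 0.6)
})

test_that("tiny-instance EM optimum matches direct maximization", {
  # p = 2 linear growth, K = 1: the normal model saturates the Gaussian
  # family, so the EM optimum must equal the closed-form saturated loglik
  gp2 <- growth_params(c(1, 0.8), matrix(c(1, .11, .11, .2), 2), c(1, 1.42),
                       time_scores = 0:1)
  y <- generate_growth_data(gp2, 0, 0, n = 40, seed = 31)
  f <- fit_gmm(y, "normal", K = 1, starts = start_policy(10, 10, 3), seed = 1,
               time_scores = 0:1, maxit = 5000, tol = 1e-10)
  S <- stats::cov(y) * (nrow(y) - 1) / nrow(y)
  ll_sat <- sum(-0.5 * (2 * log(2 * pi) + determinant(S)$modulus[1] +
                          stats::mahalanobis(y, colMeans(y), S)))
  expect_equal(f$loglik, ll_sat, tolerance = 1e-5)

  # skew member at p = 2, n = 40: EM vs direct BFGS maximization of the
  # same likelihood, started from the EM solution (stationarity check)
  y2s <- generate_growth_data(gp2, 1, 2, n = 40, seed = 32)
  fem <- fit_gmm(y2s, "skew_normal", K = 1,
                 starts = start_policy(10, 10, 3), seed = 3,
                 time_scores = 0:1, skew_structure = "observed",
                 maxit = 5000, tol = 1e-10)
  ll_opt <- direct_max_loglik(y2s, "skew_normal", 0:1,
                              fem$model$classes[[1]])
  # oracle agreement to 4 significant figures of the log-likelihood
  expect_lt(abs(fem$loglik - ll_opt) / abs(ll_opt), 1e-4)
})

test_that("non-convergence is reported as data, never as an exception", {
  y <- generate_growth_data(study_params, 0, 0, n = 60, seed = 9)
  f <- fit_gmm(y, "normal", K = 2, init = start_two_class,
               starts = start_policy(2, 3, 1), seed = 1, maxit = 3)
  expect_s3_class(f, "gmm_fit")
  expect_false(f$converged)
  expect_true(is.finite(f$loglik))
})

test_that("shared covariance structure constrains the fitted classes", {
  y <- generate_growth_data(study_params, 1, 2, n = 200, seed = 12)
  f <- fit_gmm(y, "skew_t", K = 2, init = start_two_class,
               starts = quick_starts, seed = 4, skew_structure = "factor",
               cov_structure = "shared")
  c1 <- f$model$classes[[1]]; c2 <- f$model$classes[[2]]
  expect_equal(c1$Psi, c2$Psi, tolerance = 1e-10)
  expect_equal(c1$theta, c2$theta, tolerance = 1e-10)
  expect_equal(c1$delta, c2$delta, tolerance = 1e-10)
  expect_equal(c1$nu, c2$nu, tolerance = 1e-10)
  # factor skew: delta in the column space of the loading matrix
  L <- cbind(1, 0:4)
  proj <- L %*% solve(crossprod(L), crossprod(L, c1$delta))
  expect_equal(as.numeric(proj), c1$delta, tolerance = 1e-8)
})
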