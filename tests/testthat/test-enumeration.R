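test_that("information criteria implement the three penalties", {
  fit <- list(loglik = -50, n_params = 3)
  ic <- information_criteria(fit, n = 100)
  expect_equal(ic[["aic"]], 106)
  expect_equal(ic[["bic"]], 100 + 3 * log(100))
  expect_equal(ic[["sbic"]], 100 + 3 * log(102 / 24))
  # monotone penalty ordering: bic >= aic once log(n) >= 2; sbic < bic
  for (n in c(8, 50, 200, 3200)) {
    icn <- information_criteria(fit, n)
    expect_gte(icn[["bic"]], icn[["aic"]])
    expect_lt(icn[["sbic"]], icn[["bic"]])
  }
})

test_that("index selection picks the smallest value, ties to fewer classes", {
  expect_equal(select_by_index(list(c(1, 4106.4), c(2, 4117.2))), 1)
  expect_equal(select_by_index(list(c(1, 5.0), c(2, 5.0))), 1)
  expect_equal(select_by_index(list(c(1, 10.0), c(2, 9.0))), 2)
  expect_equal(select_by_index(data.frame(K = 1:3, v = c(3, 1, 2))), 2)
  expect_error(select_by_index(list()), "no candidates")
})

test_that("weighted chi-square tail matches pchisq in the classical case", {
  wct <- stgmm:::weighted_chisq_tail
  for (x in c(0.5, 2, 5, 11)) {
    expect_equal(wct(x, rep(1, 3)), stats::pchisq(x, 3, lower.tail = FALSE),
                 tolerance = 1e-6)
    expect_equal(wct(x, rep(1, 1)), stats::pchisq(x, 1, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
  # scaled chi-square: sum of two weight-2 components = 2 * chisq_2
  expect_equal(wct(6, c(2, 2)), stats::pchisq(3, 2, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("VLMR/LMR tests behave at the boundaries and enforce preconditions", {
  y <- generate_growth_data(study_params, 0, 0, n = 120, seed = 41)
  f1 <- fit_gmm(y, "normal", K = 1, init = start_one_class,
                starts = quick_starts, seed = 1)
  f2 <- fit_gmm(y, "normal", K = 2, init = start_two_class,
                starts = quick_starts, seed = 2)
  # no improvement => p = 1 (statistic at zero)
  fake2 <- f2
  fake2$loglik <- f1$loglik
  pv <- lmr_tests(fake2, f1, y)
  expect_gte(pv[["vlmr"]], 0.99)
  expect_gte(pv[["lmr"]], 0.99)
  # real comparison: p-values in [0, 1], LMR no smaller than VLMR
  pv2 <- lmr_tests(f2, f1, y)
  expect_true(all(pv2 >= 0 & pv2 <= 1))
  expect_gte(pv2[["lmr"]], pv2[["vlmr"]] - 1e-12)
  # non-converged input is an error
  bad <- f1; bad$converged <- FALSE
  expect_error(lmr_tests(f2, bad, y), "converged")
})

test_that("BLRT p-value is a valid bootstrap proportion and permutation-invariant", {
  y <- generate_growth_data(study_params, 0, 0, n = 50, seed = 55)
  pol <- start_policy(3, 6, 1)
  f1 <- fit_gmm(y, "normal", K = 1, init = start_one_class, starts = pol, seed = 1)
  f2 <- fit_gmm(y, "normal", K = 2, init = start_two_class, starts = pol, seed = 2)
  b <- blrt(y, "normal", k = 2, B = 19, seed = 7, fit_k = f2, fit_km1 = f1,
            starts = pol)
  expect_gte(b$p_value, 1 / 20)
  expect_lte(b$p_value, 1)
  expect_equal(b$p_value,
               (1 + sum(b$lr_boot >= b$lr_obs)) / (b$B_effective + 1))
  # permuting subjects leaves the test unchanged (fits and bootstrap seeded)
  yp <- y[sample(nrow(y)), ]
  f1p <- fit_gmm(yp, "normal", K = 1, init = start_one_class, starts = pol, seed = 1)
  f2p <- fit_gmm(yp, "normal", K = 2, init = start_two_class, starts = pol, seed = 2)
  bp <- blrt(yp, "normal", k = 2, B = 19, seed = 7, fit_k = f2p, fit_km1 = f1p,
             starts = pol)
  expect_equal(bp$p_value, b$p_value)
})

test_that("enumeration assembles criteria and applies the decision rules", {
  y <- generate_growth_data(study_params, 0, 0, n = 100, seed = 66)
  e <- enumerate_classes(y, "normal", K_max = 2,
                         starts = quick_starts, seed = 3)
  expect_s3_class(e, "enumeration_result")
  expect_equal(nrow(e$table), 2)
  expect_true(all(c("aic", "bic", "sbic", "vlmr", "lmr") %in%
                    names(e$selected_by)))
  for (crit in c("aic", "bic", "sbic")) {
    sel <- e$selected_by[[crit]]
    expect_equal(sel, e$table$K[which.min(e$table[[crit]])])
  }
  # LRT rule: 2 classes only when p < alpha
  expect_equal(e$selected_by$vlmr,
               if (is.finite(e$table$vlmr_p[2]) && e$table$vlmr_p[2] < 0.05) 2 else 1)

  js <- enumeration_to_json(e)
  rec <- jsonlite::fromJSON(js)
  expect_equal(rec$family, "normal")
  expect_equal(rec$loglik_K1, e$table$loglik[1])
  expect_equal(rec$selected_bic, e$selected_by$bic)
})
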