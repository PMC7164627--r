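# Class-enumeration criteria: penalized-likelihood indices and likelihood
# ratio tests for k vs k-1 classes.

#' Information criteria of a fitted model
#'
#' `aic = -2LL + 2q`, `bic = -2LL + q log(n)` and the sample-size-adjusted
#' BIC `sbic = -2LL + q log((n + 2) / 24)`, with `q` the number of free
#' parameters.
#'
#' @param fit a `gmm_fit`, or any list with elements `loglik` and
#'   `n_params`.
#' @param n sample size.
#' @return named numeric vector `c(aic, bic, sbic)`.
#' @export
#' @examples
#' information_criteria(list(loglik = -50, n_params = 3), n = 100)
information_criteria <- function(fit, n) {
  stopifnot(is.finite(fit$loglik))
  m2ll <- -2 * fit$loglik
  q <- fit$n_params
  c(aic = m2ll + 2 * q,
    bic = m2ll + q * log(n),
    sbic = m2ll + q * log((n + 2) / 24))
}

#' Select a class count by the smallest index value
#'
#' The preferred model is the one with the smallest index value; ties break
#' toward the smaller class count (parsimony).
#'
#' @param candidates two-column structure of (class count, index value):
#'   a data frame, matrix, or list of length-2 vectors.
#' @return the selected class count.
#' @export
#' @examples
#' select_by_index(list(c(1, 4106.4), c(2, 4117.2)))  # 1
select_by_index <- function(candidates) {
  if (is.data.frame(candidates) || is.matrix(candidates)) {
    k <- candidates[[1]]; v <- candidates[[2]]
    if (is.matrix(candidates)) { k <- candidates[, 1]; v <- candidates[, 2] }
  } else {
    if (!length(candidates)) stop("no candidates supplied")
    k <- vapply(candidates, `[`, 0, 1)
    v <- vapply(candidates, `[`, 0, 2)
  }
  if (!length(k)) stop("no candidates supplied")
  ord <- order(v, k)
  k[ord[1]]
}

# ---- VLMR / LMR likelihood ratio tests --------------------------------

# Pack a gmm_model's free parameters into a flat vector for numerical
# score computation; `map` records slices to rebuild the model.
pack_model <- function(model) {
  flags <- family_flags(model$family)
  factor_skew <- identical(model$skew_structure, "factor")
  shared <- identical(model$cov_structure, "shared")
  L <- cbind(1, model$time_scores)
  x <- numeric(0)
  pack_cov <- function(cl) {
    v <- c(cl$Psi[c(1, 2, 4)], cl$theta)
    if (flags$skew) {
      v <- c(v, if (factor_skew)
        as.numeric(solve(crossprod(L), crossprod(L, cl$delta))) else cl$delta)
    }
    if (flags$tdist) v <- c(v, log(cl$nu))
    v
  }
  for (cl in model$classes) x <- c(x, cl$alpha)
  if (shared) {
    x <- c(x, pack_cov(model$classes[[1]]))
  } else {
    for (cl in model$classes) x <- c(x, pack_cov(cl))
  }
  K <- length(model$classes)
  if (K > 1) x <- c(x, stats::qlogis(model$weights[-K] / sum(model$weights)))
  x
}

unpack_model <- function(x, template) {
  flags <- family_flags(template$family)
  factor_skew <- identical(template$skew_structure, "factor")
  shared <- identical(template$cov_structure, "shared")
  p <- length(template$classes[[1]]$theta)
  L <- cbind(1, template$time_scores)
  K <- length(template$classes)
  i <- 0
  take <- function(m) { v <- x[(i + 1):(i + m)]; i <<- i + m; v }
  alphas <- lapply(seq_len(K), function(k) take(2))
  take_cov <- function() {
    ps <- take(3)
    out <- list(Psi = matrix(c(ps[1], ps[2], ps[2], ps[3]), 2),
                theta = take(p))
    out$delta <- if (!flags$skew) numeric(p)
      else if (factor_skew) as.numeric(L %*% take(2)) else take(p)
    out$nu <- if (flags$tdist) exp(take(1)) else Inf
    out
  }
  covs <- if (shared) rep(list(take_cov()), K)
    else lapply(seq_len(K), function(k) take_cov())
  classes <- lapply(seq_len(K), function(k)
    c(list(alpha = alphas[[k]]), covs[[k]]))
  w <- if (K > 1) {
    e <- stats::plogis(take(K - 1))
    c(e, 1 - sum(e))
  } else 1
  gmm_model(template$family, w / sum(w), classes, template$time_scores,
            template$skew_structure %||% "observed",
            template$cov_structure %||% "class_specific")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# n x q matrix of per-observation scores (central finite differences of
# the per-observation mixture log-density).
score_matrix <- function(model, Y, h = 1e-5) {
  x <- pack_model(model)
  q <- length(x)
  S <- matrix(NA_real_, nrow(Y), q)
  for (j in seq_len(q)) {
    hj <- h * (1 + abs(x[j]))
    xp <- x; xp[j] <- x[j] + hj
    xm <- x; xm[j] <- x[j] - hj
    lp <- suppressWarnings(gmm_obs_loglik(unpack_model(xp, model), Y))
    lm <- suppressWarnings(gmm_obs_loglik(unpack_model(xm, model), Y))
    S[, j] <- (lp - lm) / (2 * hj)
  }
  if (!all(is.finite(S)))
    stop("non-finite scores at the fitted parameters")
  S
}

# P(sum_j lambda_j chi2_1 > x) by Imhof's (1961) inversion formula, with a
# Satterthwaite gamma approximation as fallback.
weighted_chisq_tail <- function(x, lambda) {
  lambda <- lambda[abs(lambda) > 1e-10]
  if (!length(lambda)) return(1)
  imhof <- tryCatch({
    integrand <- function(u) {
      th <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * x * u
      rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
      sin(th) / (u * rho)
    }
    val <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-7,
                            subdivisions = 500L)$value
    0.5 + val / pi
  }, error = function(e) NA_real_)
  if (is.finite(imhof)) return(min(max(imhof, 0), 1))
  m <- sum(lambda)
  v <- 2 * sum(lambda^2)
  if (m <= 0 || v <= 0) return(1)
  stats::pgamma(x, shape = m^2 / v, rate = m / v, lower.tail = FALSE)
}

# Eigenvalue weights of the Vuong-type weighted-chi-square null
# distribution for nested model comparison, from empirical per-observation
# scores of both fitted models.
vuong_weights <- function(fit_k, fit_km1, data) {
  Y <- as.matrix(data)
  S1 <- score_matrix(fit_k$model, Y)
  S0 <- score_matrix(fit_km1$model, Y)
  n <- nrow(Y)
  B1 <- crossprod(S1) / n
  B0 <- crossprod(S0) / n
  C <- crossprod(S1, S0) / n
  r1 <- diag(mean(diag(B1)) * 1e-8, ncol(B1))
  r0 <- diag(mean(diag(B0)) * 1e-8, ncol(B0))
  W <- rbind(cbind(diag(ncol(B1)), solve(B1 + r1, C)),
             cbind(-solve(B0 + r0, t(C)), -diag(ncol(B0))))
  ev <- eigen(W, only.values = TRUE)$values
  Re(ev)
}

#' Vuong-Lo-Mendell-Rubin and adjusted likelihood ratio tests
#'
#' Tests a k-class against a (k-1)-class fit of the same family. The
#' statistic is `2(LL_k - LL_{k-1})`; because the smaller model sits on a
#' non-identified boundary of the larger one, the statistic is referred to
#' a weighted sum of chi-square(1) variables rather than a chi-square. The
#' weights are the eigenvalues of the Vuong-type block matrix built from
#' the empirical per-observation scores of the two fitted models, and the
#' tail probability is computed by Imhof's characteristic-function
#' inversion. `lmr_adjusted_lrt` applies the small-sample correction,
#' dividing the statistic by `c = 1 + [(q_k - q_{k-1}) log n]^{-1}`.
#'
#' @param fit_k,fit_km1 converged `gmm_fit` objects for k and k-1 classes,
#'   same family, fitted to `data`.
#' @param data the n x p data both models were fitted to.
#' @return the p-value.
#' @export
vlmr_lrt <- function(fit_k, fit_km1, data) {
  p <- lmr_tests(fit_k, fit_km1, data)
  p["vlmr"]
}

#' @rdname vlmr_lrt
#' @export
lmr_adjusted_lrt <- function(fit_k, fit_km1, data) {
  p <- lmr_tests(fit_k, fit_km1, data)
  p["lmr"]
}

#' @rdname vlmr_lrt
#' @export
lmr_tests <- function(fit_k, fit_km1, data) {
  if (!isTRUE(fit_k$converged) || !isTRUE(fit_km1$converged))
    stop("both fits must have converged for the VLMR/LMR tests")
  if (fit_k$family != fit_km1$family)
    stop("fits must share the family")
  lr <- 2 * (fit_k$loglik - fit_km1$loglik)
  n <- fit_k$n
  qdiff <- fit_k$n_params - fit_km1$n_params
  if (lr <= 1e-8) return(c(vlmr = 1, lmr = 1))
  lambda <- tryCatch(vuong_weights(fit_k, fit_km1, data),
                     error = function(e) rep(1, qdiff))
  if (sum(lambda) <= 0) lambda <- rep(1, qdiff)
  cfac <- 1 + 1 / (qdiff * log(n))
  c(vlmr = weighted_chisq_tail(lr, lambda),
    lmr = weighted_chisq_tail(lr / cfac, lambda))
}

#' Parametric bootstrap likelihood ratio test (BLRT)
#'
#' Tests k vs k-1 classes by generating `B` datasets from the fitted
#' (k-1)-class model, refitting both class counts on each, and comparing
#' the observed statistic `2(LL_k - LL_{k-1})` with the bootstrap
#' distribution: `p = (1 + #\{LR_b >= LR_obs\}) / (B + 1)`. A bootstrap
#' draw whose refits do not both converge is redrawn once and then dropped
#' with a warning. Available for all four family members.
#'
#' @param data n x p data matrix.
#' @param family family tag.
#' @param k number of classes of the larger model (k >= 2).
#' @param B number of bootstrap draws (>= 19).
#' @param seed integer seed; draws and refits are reproducible.
#' @param fit_k,fit_km1 optional pre-computed fits of the two class counts
#'   (refitted from scratch when omitted).
#' @param starts start policy for the bootstrap refits; a reduced policy
#'   is the default, as is standard for bootstrap LRT inner loops.
#' @param maxit,tol EM control for the refits.
#' @param skew_structure,cov_structure passed to [fit_gmm()] when
#'   refitting.
#' @return list with `p_value`, `lr_obs`, `lr_boot`, `B_effective`.
#' @export
blrt <- function(data, family, k = 2, B = 100, seed = 1,
                 fit_k = NULL, fit_km1 = NULL,
                 starts = start_policy(n_random = 4, short_iter = 6, n_final = 1),
                 maxit = 1000, tol = 1e-6,
                 skew_structure = c("observed", "factor"),
                 cov_structure = c("class_specific", "shared")) {
  stopifnot(B >= 19, k >= 2)
  skew_structure <- match.arg(skew_structure)
  cov_structure <- match.arg(cov_structure)
  Y <- as.matrix(data)
  n <- nrow(Y)
  if (is.null(fit_km1))
    fit_km1 <- fit_gmm(Y, family, K = k - 1, starts = starts, seed = seed,
                       maxit = maxit, tol = tol, skew_structure = skew_structure,
                       cov_structure = cov_structure)
  if (is.null(fit_k))
    fit_k <- fit_gmm(Y, family, K = k, starts = starts, seed = seed + 1,
                     maxit = maxit, tol = tol, skew_structure = skew_structure,
                     cov_structure = cov_structure)
  lr_obs <- max(0, 2 * (fit_k$loglik - fit_km1$loglik))
  null_model <- fit_km1$model
  null_start <- list(weights = null_model$weights, classes = null_model$classes)

  lr_boot <- rep(NA_real_, B)
  dropped <- 0L
  for (b in seq_len(B)) {
    lr_b <- NA_real_
    for (attempt in 1:2) {
      sb <- seed + 1000L * b + attempt
      Yb <- rmst_mixture(null_model, n, seed = sb)
      f0 <- fit_gmm(Yb, family, K = k - 1, init = null_start, starts = starts,
                    seed = sb + 1L, maxit = maxit, tol = tol,
                    skew_structure = fit_km1$model$skew_structure,
                    cov_structure = fit_km1$model$cov_structure)
      f1 <- fit_gmm(Yb, family, K = k, starts = starts,
                    seed = sb + 2L, maxit = maxit, tol = tol,
                    skew_structure = fit_k$model$skew_structure,
                    cov_structure = fit_k$model$cov_structure)
      if (f0$converged && f1$converged) {
        lr_b <- max(0, 2 * (f1$loglik - f0$loglik))
        break
      }
    }
    if (is.na(lr_b)) {
      dropped <- dropped + 1L
      warning(sprintf("bootstrap draw %d dropped after one redraw (non-convergence)", b))
    }
    lr_boot[b] <- lr_b
  }
  ok <- !is.na(lr_boot)
  p <- (1 + sum(lr_boot[ok] >= lr_obs)) / (sum(ok) + 1)
  list(p_value = p, lr_obs = lr_obs, lr_boot = lr_boot[ok],
       B_effective = sum(ok), dropped = dropped)
}

#' Enumerate latent classes with all criteria
#'
#' Fits 1..K_max classes of one family, computes AIC/BIC/SBIC per class
#' count and the VLMR / LMR-adjusted (and optionally bootstrap) LRTs for
#' each k vs k-1 comparison, and applies the decision rules: indices pick
#' the class count with the smallest value; an LRT prefers k classes over
#' k-1 when its p-value is below `alpha`, stepping up from k = 2.
#'
#' @param data n x p data matrix.
#' @param family family tag.
#' @param K_max largest class count considered.
#' @param alpha LRT significance threshold.
#' @param blrt_B bootstrap draws for the BLRT; 0 skips it.
#' @param starts,seed,maxit,tol,skew_structure,cov_structure passed to
#'   [fit_gmm()].
#' @return an `enumeration_result`: list with `fits`, `table` (per class
#'   count: loglik, converged, aic, bic, sbic, vlmr_p, lmr_p, blrt_p) and
#'   `selected_by` (criterion -> class count).
#' @export
enumerate_classes <- function(data, family, K_max = 2, alpha = 0.05,
                              blrt_B = 0, starts = start_policy(), seed = 1,
                              maxit = 1000, tol = 1e-6,
                              skew_structure = c("observed", "factor"),
                              cov_structure = c("class_specific", "shared")) {
  skew_structure <- match.arg(skew_structure)
  cov_structure <- match.arg(cov_structure)
  Y <- as.matrix(data)
  n <- nrow(Y)
  fits <- lapply(seq_len(K_max), function(K)
    fit_gmm(Y, family, K = K, starts = starts, seed = seed + K, maxit = maxit,
            tol = tol, skew_structure = skew_structure,
            cov_structure = cov_structure))
  tab <- data.frame(K = seq_len(K_max),
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    converged = vapply(fits, `[[`, 0 > 1, "converged"),
                    aic = NA_real_, bic = NA_real_, sbic = NA_real_,
                    vlmr_p = NA_real_, lmr_p = NA_real_, blrt_p = NA_real_)
  for (K in seq_len(K_max)) {
    if (is.finite(fits[[K]]$loglik))
      tab[K, c("aic", "bic", "sbic")] <- information_criteria(fits[[K]], n)
    if (K > 1 && fits[[K]]$converged && fits[[K - 1]]$converged) {
      pv <- tryCatch(lmr_tests(fits[[K]], fits[[K - 1]], Y),
                     error = function(e) c(vlmr = NA_real_, lmr = NA_real_))
      tab$vlmr_p[K] <- pv["vlmr"]
      tab$lmr_p[K] <- pv["lmr"]
      if (blrt_B > 0)
        tab$blrt_p[K] <- blrt(Y, family, k = K, B = blrt_B, seed = seed + 77,
                              fit_k = fits[[K]], fit_km1 = fits[[K - 1]],
                              maxit = maxit, tol = tol)$p_value
    }
  }
  conv <- which(tab$converged)
  selected_by <- list()
  for (crit in c("aic", "bic", "sbic")) {
    ok <- conv[is.finite(tab[[crit]][conv])]
    if (length(ok))
      selected_by[[crit]] <- select_by_index(cbind(tab$K[ok], tab[[crit]][ok]))
  }
  for (crit in c("vlmr_p", "lmr_p", "blrt_p")) {
    name <- sub("_p$", "", crit)
    sel <- 1
    for (K in seq_len(K_max)[-1]) {
      pK <- tab[[crit]][K]
      if (is.finite(pK) && pK < alpha && sel == K - 1) sel <- K
    }
    if (any(is.finite(tab[[crit]]))) selected_by[[name]] <- sel
  }
  structure(list(family = family, n = n, fits = fits, table = tab,
                 selected_by = selected_by, alpha = alpha),
            class = "enumeration_result")
}

#' Serialize an enumeration result to a flat JSON record
#'
#' @param x an `enumeration_result`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
enumeration_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "enumeration_result"))
  rec <- list(family = x$family, n = x$n, alpha = x$alpha)
  for (i in seq_len(nrow(x$table))) {
    K <- x$table$K[i]
    for (col in setdiff(names(x$table), "K"))
      rec[[sprintf("%s_K%d", col, K)]] <- unname(x$table[[col]][i])
  }
  for (crit in names(x$selected_by))
    rec[[paste0("selected_", crit)]] <- x$selected_by[[crit]]
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
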