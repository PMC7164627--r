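# Restricted multivariate skew-t (rMST) distribution.
#
# Stochastic representation: Y = mu + delta * |U0| + U1, where U0 (scalar)
# and U1 (p-vector, scale matrix Sigma) are jointly t with a single shared
# Gamma(nu/2, nu/2) scale-mixing variable W:
#   W ~ Gamma(nu/2, nu/2),  U0 | W ~ N(0, 1/W),  U1 | W ~ N_p(0, Sigma/W).
# Marginalising the half-t skewing variable gives the closed-form density
#   f(y) = 2 t_p(y; mu, Omega, nu) T_{nu+p}( q(y) sqrt((nu+p)/(nu+d(y))) ),
# with Omega = Sigma + delta delta', d(y) the Mahalanobis distance under
# Omega, q(y) = delta' Omega^{-1} (y - mu) / sigma and
# sigma^2 = 1 - delta' Omega^{-1} delta.
# Nesting: delta = 0 gives the multivariate t; nu = Inf the skew normal;
# both together the multivariate normal.

#' Family tags of the skew-t family
#'
#' @return character vector of the four family names.
#' @export
st_families <- function() c("normal", "skew_normal", "t", "skew_t")

# (skew free?, df free?) per family
family_flags <- function(family) {
  family <- match.arg(family, st_families())
  list(family = family,
       skew = family %in% c("skew_normal", "skew_t"),
       tdist = family %in% c("t", "skew_t"))
}

#' Restricted multivariate skew-t log-density
#'
#' Evaluates the log-density of the restricted multivariate skew-t
#' distribution at one or more points. `nu = Inf` gives the (skew) normal
#' member; `delta = 0` the symmetric members.
#'
#' @param y numeric vector (one point) or matrix with one point per row.
#' @param mu location vector (length p).
#' @param Sigma p x p positive-definite scale matrix (the covariance of the
#'   symmetric part `U1` up to the t scaling).
#' @param delta length-p skewness vector.
#' @param nu degrees of freedom (> 0, possibly `Inf`).
#' @param log if `TRUE` return log-density.
#' @return numeric vector of (log-)density values, one per row of `y`.
#' @export
#' @examples
#' dmst(0, 0, matrix(1), 2, 5)
dmst <- function(y, mu, Sigma, delta, nu, log = FALSE) {
  if (is.vector(y)) y <- matrix(y, nrow = 1)
  p <- ncol(y)
  mu <- as.numeric(mu); delta <- as.numeric(delta)
  Sigma <- as.matrix(Sigma)
  stopifnot(length(mu) == p, length(delta) == p, all(dim(Sigma) == p))
  Omega <- Sigma + tcrossprod(delta)
  U <- tryCatch(chol(Omega), error = function(e) stop("Omega = Sigma + delta delta' is singular"))
  logdet <- 2 * sum(log(diag(U)))
  yc <- sweep(y, 2, mu)
  z <- yc %*% backsolve(U, diag(p))          # rows: y' U^{-1}
  d <- rowSums(z^2)                           # Mahalanobis under Omega
  oid <- backsolve(U, forwardsolve(t(U), delta))  # Omega^{-1} delta
  sig2 <- 1 - sum(delta * oid)
  q <- as.numeric(yc %*% oid) / sqrt(sig2)
  if (is.finite(nu)) {
    logt <- lgamma((nu + p) / 2) - lgamma(nu / 2) - (p / 2) * log(nu * pi) -
      logdet / 2 - ((nu + p) / 2) * log1p(d / nu)
    out <- log(2) + logt +
      stats::pt(q * sqrt((nu + p) / (nu + d)), df = nu + p, log.p = TRUE)
  } else {
    logn <- -(p / 2) * log(2 * pi) - logdet / 2 - d / 2
    out <- log(2) + logn + stats::pnorm(q, log.p = TRUE)
  }
  if (log) out else exp(out)
}

#' Sample from the restricted multivariate skew-t distribution
#'
#' Draws via the stochastic representation: one shared Gamma(nu/2, nu/2)
#' scale-mixing variable per subject, a half-normal skewing variable and a
#' correlated normal vector, so that `|U0|` is half-t and `U1` the
#' matching multivariate t.
#'
#' @inheritParams dmst
#' @param n number of draws.
#' @param seed integer seed (draws are reproducible given the seed).
#' @return n x p numeric matrix.
#' @export
#' @examples
#' y <- rmst(1000, mu = c(0, 0), Sigma = diag(2), delta = c(2, 0), nu = 8, seed = 1)
rmst <- function(n, mu, Sigma, delta, nu, seed) {
  mu <- as.numeric(mu); delta <- as.numeric(delta)
  Sigma <- as.matrix(Sigma)
  p <- length(mu)
  stopifnot(length(delta) == p, all(dim(Sigma) == p), n >= 1)
  U <- chol(Sigma)
  with_seed(seed, {
    w <- if (is.finite(nu)) stats::rgamma(n, nu / 2, rate = nu / 2) else rep(1, n)
    u0 <- abs(stats::rnorm(n)) / sqrt(w)
    Z <- (matrix(stats::rnorm(n * p), n, p) %*% U) / sqrt(w)
    Y <- sweep(outer(u0, delta) + Z, 2, mu, `+`)
    colnames(Y) <- paste0("t", seq_len(p))
    Y
  })
}

#' Sample from a fitted K-class skew-t family mixture
#'
#' Class labels are drawn from the mixing weights, then observations from
#' each class's restricted skew-t distribution. Used by the parametric
#' bootstrap likelihood ratio test.
#'
#' @param model a `gmm_model` (see [fit_gmm()]'s `$model` element or
#'   [gmm_model()]).
#' @param n number of subjects.
#' @param seed integer seed.
#' @return n x p numeric matrix.
#' @export
rmst_mixture <- function(model, n, seed) {
  stopifnot(inherits(model, "gmm_model"))
  K <- length(model$classes)
  with_seed(seed, {
    g <- sample.int(K, n, replace = TRUE, prob = model$weights)
    seeds <- sample.int(.Machine$integer.max, K)
    p <- length(model$classes[[1]]$mu)
    Y <- matrix(NA_real_, n, p)
    for (k in seq_len(K)) {
      idx <- which(g == k)
      if (!length(idx)) next
      cl <- model$classes[[k]]
      Y[idx, ] <- rmst(length(idx), cl$mu, cl$Sigma, cl$delta, cl$nu,
                       seed = seeds[k])
    }
    colnames(Y) <- paste0("t", seq_len(p))
    Y
  })
}
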