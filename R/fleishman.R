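# Fleishman power-method transform and the Vale-Maurelli multivariate
# extension: X = a + bZ + cZ^2 + dZ^3 with Z standard normal, coefficients
# chosen so X has mean 0, variance 1 and target skewness / excess kurtosis.

#' Solve for Fleishman power-method coefficients
#'
#' Finds coefficients (a, b, c, d) of the cubic transform
#' \eqn{X = a + bZ + cZ^2 + dZ^3} of a standard normal \eqn{Z} such that
#' \eqn{X} has mean 0, variance 1, skewness `skew` and excess kurtosis
#' `ex_kurtosis`. Uses Newton iteration on the three moment equations with
#' analytic Jacobian, started from the identity transform (b, c, d) =
#' (1, 0, 0); the zero-mean constraint fixes a = -c. The root with b > 0 is
#' returned.
#'
#' @param skew target marginal skewness.
#' @param ex_kurtosis target marginal excess kurtosis. Must satisfy the
#'   power-method feasibility condition
#'   `ex_kurtosis >= skew^2 - 2` (necessary; the attainable region is
#'   slightly smaller and infeasible targets make the solver fail loudly).
#' @param tol convergence tolerance on the moment-equation residuals.
#' @return A list of class `fleishman_coeffs` with elements `a`, `b`, `c`,
#'   `d`, `skew`, `ex_kurtosis`.
#' @export
#' @examples
#' fleishman_coeffs(1.6, 4)
fleishman_coeffs <- function(skew, ex_kurtosis, tol = 1e-11) {
  if (ex_kurtosis < skew^2 - 2)
    stop(sprintf(
      "infeasible target (skew = %g, ex_kurtosis = %g): requires ex_kurtosis >= skew^2 - 2",
      skew, ex_kurtosis))
  x <- c(1, 0, 0)  # (b, c, d)
  ok <- FALSE
  for (iter in 1:200) {
    b <- x[1]; cc <- x[2]; d <- x[3]
    f <- c(
      b^2 + 6 * b * d + 2 * cc^2 + 15 * d^2 - 1,
      2 * cc * (b^2 + 24 * b * d + 105 * d^2 + 2) - skew,
      24 * (b * d + cc^2 * (1 + b^2 + 28 * b * d) +
              d^2 * (12 + 48 * b * d + 141 * cc^2 + 225 * d^2)) - ex_kurtosis)
    if (max(abs(f)) < tol && iter > 1) { ok <- TRUE; break }
    J <- matrix(c(
      2 * b + 6 * d, 4 * cc, 6 * b + 30 * d,
      2 * cc * (2 * b + 24 * d),
      2 * (b^2 + 24 * b * d + 105 * d^2 + 2),
      2 * cc * (24 * b + 210 * d),
      24 * (d + cc^2 * (2 * b + 28 * d) + 48 * d^3),
      24 * (2 * cc * (1 + b^2 + 28 * b * d) + 282 * cc * d^2),
      24 * (b + 28 * b * cc^2 + 2 * d * (12 + 48 * b * d + 141 * cc^2 + 225 * d^2) +
              d^2 * (48 * b + 450 * d))
    ), nrow = 3, byrow = TRUE)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step))
      stop(sprintf("Fleishman solver failed (singular Jacobian) for skew = %g, ex_kurtosis = %g",
                   skew, ex_kurtosis))
    # damped Newton keeps iterates in the b > 0 branch
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      if (xn[1] > 0 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    x <- xn
  }
  if (!ok)
    stop(sprintf("Fleishman solver did not converge for skew = %g, ex_kurtosis = %g",
                 skew, ex_kurtosis))
  structure(list(a = -x[2], b = x[1], c = x[2], d = x[3],
                 skew = skew, ex_kurtosis = ex_kurtosis),
            class = "fleishman_coeffs")
}

#' Moments realised by Fleishman coefficients
#'
#' Analytic first four moments (mean, variance, skewness, excess kurtosis)
#' of the cubic transform defined by a set of coefficients. Used as the
#' residual check for the solver.
#'
#' @param coef a [fleishman_coeffs()] object.
#' @return numeric vector `c(mean, var, skew, ex_kurtosis)`.
#' @export
fleishman_moments <- function(coef) {
  b <- coef$b; cc <- coef$c; d <- coef$d
  v <- b^2 + 6 * b * d + 2 * cc^2 + 15 * d^2
  s <- 2 * cc * (b^2 + 24 * b * d + 105 * d^2 + 2)
  k <- 24 * (b * d + cc^2 * (1 + b^2 + 28 * b * d) +
               d^2 * (12 + 48 * b * d + 141 * cc^2 + 225 * d^2))
  c(mean = coef$a + cc, var = v, skew = s, ex_kurtosis = k)
}

#' Apply a Fleishman transform
#'
#' @param z numeric vector/matrix of standard-normal values.
#' @param coef a [fleishman_coeffs()] object.
#' @return transformed values with the same shape as `z`.
#' @export
fleishman_transform <- function(z, coef) {
  coef$a + z * (coef$b + z * (coef$c + z * coef$d))
}

#' Vale-Maurelli intermediate correlation
#'
#' Solves for the correlation \eqn{\rho_z} of the underlying standard
#' normal pair such that, after transforming each margin by its Fleishman
#' cubic, the post-transform correlation equals `target_r`. \eqn{\rho_z}
#' is the root in (-1, 1) of
#' \deqn{\rho_z(b_i b_j + 3 b_i d_j + 3 d_i b_j + 9 d_i d_j) +
#'   2\rho_z^2 c_i c_j + 6 \rho_z^3 d_i d_j = r.}
#'
#' @param target_r target post-transform correlation, |target_r| < 1.
#' @param ci,cj [fleishman_coeffs()] for the two margins (`cj` defaults to
#'   `ci`).
#' @return the intermediate correlation, a number in (-1, 1).
#' @export
#' @examples
#' fc <- fleishman_coeffs(1.6, 4)
#' intermediate_correlation(0.5, fc)
intermediate_correlation <- function(target_r, ci, cj = ci) {
  if (abs(target_r) >= 1) stop("|target_r| must be < 1")
  if (target_r == 0) return(0)
  k1 <- ci$b * cj$b + 3 * ci$b * cj$d + 3 * ci$d * cj$b + 9 * ci$d * cj$d
  k2 <- 2 * ci$c * cj$c
  k3 <- 6 * ci$d * cj$d
  f <- function(r) r * k1 + r^2 * k2 + r^3 * k3 - target_r
  lo <- -1 + 1e-12; hi <- 1 - 1e-12
  if (f(lo) * f(hi) > 0)
    stop(sprintf("no intermediate correlation in (-1, 1) achieves target_r = %g", target_r))
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Generate a single-class nonnormal longitudinal dataset
#'
#' Draws `n` subjects from the growth model's implied moments with the
#' requested marginal skewness and excess kurtosis on every occasion, via
#' the Vale-Maurelli pipeline: standardize the implied covariance to a
#' correlation matrix, solve the intermediate correlations for the
#' Fleishman-transformed margins, draw multivariate normal deviates with
#' that intermediate correlation, apply the cubic transform per column
#' (unit variance preserved), and rescale to the implied means and
#' variances. With `skew = 0, ex_kurtosis = 0` the transform is the
#' identity and the data are exactly multivariate normal.
#'
#' @param params a [growth_params()] object.
#' @param skew,ex_kurtosis target marginal skewness and excess kurtosis
#'   (identical across occasions).
#' @param n number of subjects (>= 2).
#' @param seed integer seed; the dataset is fully reproducible from
#'   (params, skew, ex_kurtosis, n, seed).
#' @return an n x p numeric matrix with columns `t1..tp`.
#' @export
#' @examples
#' y <- generate_growth_data(bauer_curran_params(), 1.6, 4, n = 500, seed = 1)
#' colMeans(y)
generate_growth_data <- function(params, skew, ex_kurtosis, n, seed) {
  stopifnot(inherits(params, "growth_params"), n >= 2)
  mom <- implied_moments(params)
  p <- length(mom$mean)
  sds <- sqrt(diag(mom$cov))
  R <- stats::cov2cor(mom$cov)

  normal_case <- (skew == 0 && ex_kurtosis == 0)
  if (!normal_case) {
    fc <- fleishman_coeffs(skew, ex_kurtosis)
    Rz <- diag(p)
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      Rz[i, j] <- Rz[j, i] <- intermediate_correlation(R[i, j], fc)
    }
  } else {
    Rz <- R
  }
  U <- tryCatch(chol(Rz), error = function(e)
    stop("intermediate correlation matrix is not positive definite; ",
         "the requested skew/kurtosis targets are infeasible for the implied correlations"))
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n * p), n, p) %*% U
    X <- if (normal_case) Z else fleishman_transform(Z, fc)
    Y <- sweep(sweep(X, 2, sds, `*`), 2, mom$mean, `+`)
    colnames(Y) <- paste0("t", seq_len(p))
    Y
  })
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Sample skewness m3 / m2^(3/2) and excess kurtosis m4 / m2^2 - 3
# (moment definitions, no small-sample correction).
sample_skewness <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  mean(x^3) / m2^1.5
}

sample_ex_kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  mean(x^4) / m2^2 - 3
}
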