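#' Linear latent growth model parameters
#'
#' Container for the parameters of an unconditional linear latent growth
#' model: an intercept and a slope factor with means `factor_means`
#' (\eqn{\alpha = [\mu_\alpha, \mu_\beta]}), covariance matrix `factor_cov`
#' (\eqn{\Psi}), occasion-specific residual variances `residual_vars`
#' (the diagonal of \eqn{\Theta}), a loading matrix `loadings`
#' (\eqn{\Lambda}; first column fixed to ones, second column the time
#' scores) and level-1 intercepts (\eqn{\nu}, fixed to zero here: the
#' observed means are carried entirely by the factor means, the standard
#' identification for unconditional growth models).
#'
#' @param factor_means numeric length-2 vector: intercept and slope means.
#' @param factor_cov 2x2 symmetric positive semi-definite matrix.
#' @param residual_vars numeric vector of strictly positive residual
#'   variances, one per measurement occasion.
#' @param time_scores numeric vector of time scores, one per occasion;
#'   defines the second column of the loading matrix.
#' @param level1_intercepts numeric vector of per-occasion intercepts;
#'   defaults to zero.
#'
#' @return An object of class `growth_params`.
#' @export
#' @examples
#' gp <- growth_params(c(1, 0.8), diag(c(1, 0.2)), rep(1, 5))
#' implied_moments(gp)
growth_params <- function(factor_means, factor_cov, residual_vars,
                          time_scores = seq_along(residual_vars) - 1,
                          level1_intercepts = numeric(length(residual_vars))) {
  factor_means <- as.numeric(factor_means)
  factor_cov <- as.matrix(factor_cov)
  residual_vars <- as.numeric(residual_vars)
  time_scores <- as.numeric(time_scores)
  level1_intercepts <- as.numeric(level1_intercepts)
  p <- length(residual_vars)
  if (length(factor_means) != 2L)
    stop("factor_means must have length 2 (intercept and slope)")
  if (!all(dim(factor_cov) == c(2L, 2L)))
    stop("factor_cov must be a 2x2 matrix")
  if (max(abs(factor_cov - t(factor_cov))) > 1e-8)
    stop("factor_cov must be symmetric")
  if (any(eigen(factor_cov, symmetric = TRUE, only.values = TRUE)$values < -1e-8))
    stop("factor_cov must be positive semi-definite")
  if (any(residual_vars <= 0))
    stop("residual_vars must be strictly positive")
  if (length(time_scores) != p || length(level1_intercepts) != p)
    stop("time_scores and level1_intercepts must match length(residual_vars)")
  structure(
    list(factor_means = factor_means,
         factor_cov = (factor_cov + t(factor_cov)) / 2,
         residual_vars = residual_vars,
         time_scores = time_scores,
         level1_intercepts = level1_intercepts),
    class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Linear latent growth model parameters\n")
  cat("  factor means    :", format(x$factor_means), "\n")
  cat("  factor cov (vech):", format(x$factor_cov[c(1, 2, 4)]), "\n")
  cat("  residual vars   :", format(x$residual_vars), "\n")
  cat("  time scores     :", format(x$time_scores), "\n")
  invisible(x)
}

#' Loading matrix of a growth model
#'
#' @param params a [growth_params()] object.
#' @return p x 2 matrix with a unit first column and the time scores in the
#'   second column.
#' @export
loading_matrix <- function(params) {
  cbind(intercept = rep(1, length(params$time_scores)),
        slope = params$time_scores)
}

#' Generating parameters of the Bauer-Curran single-class design
#'
#' The population values of the linear growth model used throughout the
#' simulation study: an increasing mean trajectory
#' (\eqn{\mu_\alpha = 1.00}, \eqn{\mu_\beta = 0.80}), individual variation
#' in both intercepts and slopes (\eqn{\Psi_\alpha = 1.00},
#' \eqn{\Psi_\beta = 0.20}) with a slight positive correlation
#' (\eqn{\Psi_{\alpha\beta} = 0.11}), and residual variances that increase
#' over the five occasions (\eqn{\Theta = diag[1.00, 1.42, 2.25, 3.47,
#' 5.09]}). Time scores default to 0..4 (origin at the first occasion),
#' the usual coding for this design; they can be overridden.
#'
#' @param time_scores time scores for the five occasions.
#' @return A [growth_params()] object.
#' @export
#' @examples
#' bauer_curran_params()
bauer_curran_params <- function(time_scores = 0:4) {
  growth_params(
    factor_means = c(1.00, 0.80),
    factor_cov = matrix(c(1.00, 0.11, 0.11, 0.20), 2, 2),
    residual_vars = c(1.00, 1.42, 2.25, 3.47, 5.09),
    time_scores = time_scores)
}

#' Model-implied observation moments
#'
#' Mean vector and covariance matrix of the repeated measures implied by a
#' linear growth model: \eqn{\mu = \nu + \Lambda\alpha} and
#' \eqn{\Sigma = \Lambda\Psi\Lambda' + \Theta}.
#'
#' @param params a [growth_params()] object.
#' @return A list with components `mean` (length-p vector) and `cov`
#'   (p x p matrix).
#' @export
#' @examples
#' implied_moments(bauer_curran_params())
implied_moments <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  L <- loading_matrix(params)
  list(mean = as.numeric(params$level1_intercepts + L %*% params$factor_means),
       cov = L %*% params$factor_cov %*% t(L) + diag(params$residual_vars))
}

#' Write / read growth parameters as a flat key-value config file
#'
#' Serializes a [growth_params()] object to a flat YAML mapping (matrices
#' row-major) and back.
#'
#' @param params a [growth_params()] object.
#' @param path file path.
#' @return `write_growth_params` returns `path` invisibly;
#'   `read_growth_params` returns a [growth_params()] object.
#' @export
write_growth_params <- function(params, path) {
  stopifnot(inherits(params, "growth_params"))
  x <- list(factor_means = params$factor_means,
            factor_cov = as.numeric(t(params$factor_cov)),
            residual_vars = params$residual_vars,
            time_scores = params$time_scores,
            level1_intercepts = params$level1_intercepts)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_growth_params
#' @export
read_growth_params <- function(path) {
  x <- yaml::read_yaml(path)
  growth_params(factor_means = x$factor_means,
                factor_cov = matrix(x$factor_cov, 2, 2, byrow = TRUE),
                residual_vars = x$residual_vars,
                time_scores = x$time_scores,
                level1_intercepts = x$level1_intercepts)
}
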