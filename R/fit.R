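# Maximum-likelihood fitting of K-class skew-t family growth mixture models.

#' Construct a K-class skew-t family growth mixture model
#'
#' A `gmm_model` holds the family tag, mixing weights and per-class
#' parameters. Each class is a list with growth-structured parameters
#' (`alpha`, `Psi`, `theta` — factor means, factor covariance, residual
#' variances), the skewness vector `delta` (zero for the symmetric
#' families), degrees of freedom `nu` (`Inf` for the normal-limit
#' families), and the implied observation-scale `mu` and `Sigma`.
#'
#' @param family one of `"normal"`, `"skew_normal"`, `"t"`, `"skew_t"`.
#' @param weights mixing proportions, summing to one.
#' @param classes list of per-class parameter lists with elements `alpha`
#'   (length 2), `Psi` (2x2), `theta` (length p), and optionally `delta`
#'   (length p) and `nu`.
#' @param time_scores time scores defining the loading matrix.
#' @param skew_structure how the skewness vector is structured: `"factor"`
#'   constrains `delta` to the column space of the loading matrix (skew on
#'   the growth factors); `"observed"` leaves it free per occasion.
#' @param cov_structure whether `Psi`, `theta`, `delta`, `nu` are
#'   class-specific or shared across classes.
#' @return an object of class `gmm_model`.
#' @export
gmm_model <- function(family, weights, classes, time_scores,
                      skew_structure = c("observed", "factor"),
                      cov_structure = c("class_specific", "shared")) {
  skew_structure <- match.arg(skew_structure)
  cov_structure <- match.arg(cov_structure)
  flags <- family_flags(family)
  weights <- as.numeric(weights)
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  p <- length(classes[[1]]$theta)
  L <- cbind(1, time_scores)
  classes <- lapply(classes, function(cl) {
    cl$alpha <- as.numeric(cl$alpha)
    cl$Psi <- as.matrix(cl$Psi)
    cl$theta <- as.numeric(cl$theta)
    cl$delta <- if (flags$skew && !is.null(cl$delta)) as.numeric(cl$delta) else numeric(p)
    cl$nu <- if (flags$tdist && !is.null(cl$nu)) cl$nu else Inf
    cl$mu <- as.numeric(L %*% cl$alpha)
    cl$Sigma <- L %*% cl$Psi %*% t(L) + diag(cl$theta, p)
    cl
  })
  structure(list(family = flags$family, weights = weights, classes = classes,
                 time_scores = as.numeric(time_scores),
                 skew_structure = skew_structure,
                 cov_structure = cov_structure),
            class = "gmm_model")
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("%d-class %s growth mixture model\n", length(x$classes), x$family))
  for (k in seq_along(x$classes)) {
    cl <- x$classes[[k]]
    cat(sprintf("  class %d (pi = %.3f): alpha = [%s], nu = %s\n", k,
                x$weights[k], paste(sprintf("%.3f", cl$alpha), collapse = ", "),
                if (is.finite(cl$nu)) sprintf("%.1f", cl$nu) else "Inf"))
  }
  invisible(x)
}

#' Number of free parameters of a fitted family/class-count combination
#'
#' Per class: 2 factor means + 3 factor (co)variances + p residual
#' variances, plus the skewness parameters of the skew families (2 when the
#' skew is carried by the growth factors, p when free per occasion) and one
#' degrees-of-freedom parameter for the t families; plus K - 1 mixing
#' weights. Non-mean parameters are counted once per class
#' (`cov_structure = "class_specific"`) or once in total (`"shared"`).
#'
#' @param family family tag.
#' @param K number of classes.
#' @param p number of measurement occasions.
#' @param skew_structure `"factor"` (skew on the intercept/slope factors,
#'   `delta = Lambda delta_eta`, 2 parameters per class) or `"observed"`
#'   (free length-p `delta` per class).
#' @return integer count.
#' @export
#' @examples
#' n_free_params("normal", 1, 5)                        # 10
#' n_free_params("normal", 2, 5)                        # 21
#' n_free_params("skew_t", 1, 5)                        # 16
#' n_free_params("skew_t", 1, 5, "factor")              # 13
#' n_free_params("normal", 2, 5, cov_structure = "shared")  # 13
n_free_params <- function(family, K, p,
                          skew_structure = c("observed", "factor"),
                          cov_structure = c("class_specific", "shared")) {
  skew_structure <- match.arg(skew_structure)
  cov_structure <- match.arg(cov_structure)
  flags <- family_flags(family)
  n_skew <- if (!flags$skew) 0 else if (skew_structure == "factor") 2 else p
  n_cov <- 3 + p + n_skew + (if (flags$tdist) 1 else 0)
  n_cov_sets <- if (cov_structure == "shared") 1 else K
  as.integer(2 * K + n_cov_sets * n_cov + (K - 1))
}

#' Random-start policy for the EM fitter
#'
#' Mirrors the usual mixture-fitting strategy: one deterministic start
#' (supplied initial values, or moment-based values derived from the data)
#' is always run to convergence; `n_random` randomly perturbed starts are
#' each run for `short_iter` EM iterations and the best `n_final` of them
#' are continued to convergence. The study profile used for the simulation
#' replications is `start_policy(100, 10, 20, 1.5)`: one hundred random
#' starts with a ten-iteration initial stage and twenty final-stage runs,
#' the convention of mixture software start searches.
#'
#' @param n_random number of random perturbed starts.
#' @param short_iter EM iterations for the initial short runs.
#' @param n_final number of short-run survivors run to convergence.
#' @param perturb scale multiplier for the random perturbations.
#' @return a list of class `start_policy`.
#' @export
start_policy <- function(n_random = 20, short_iter = 8, n_final = 2,
                         perturb = 1) {
  structure(list(n_random = as.integer(n_random),
                 short_iter = as.integer(short_iter),
                 n_final = as.integer(n_final),
                 perturb = perturb),
            class = "start_policy")
}

# Moment-based deterministic starting values. For K = 2 the intercept and
# slope means follow a low/high pattern around the 1-class values, the
# classic two-group start for growth mixtures.
default_start <- function(Y, time_scores, flags, K) {
  p <- ncol(Y)
  X <- cbind(1, time_scores)
  XtXi <- solve(crossprod(X))
  b <- Y %*% X %*% XtXi            # per-subject OLS intercept/slope
  alpha <- colMeans(b)
  Psi <- stats::cov(b)
  # shrink: per-subject OLS inflates factor variances by residual noise
  Psi <- Psi * 0.7
  Psi[1, 2] <- Psi[2, 1] <- Psi[1, 2] * 0.7
  fitted <- tcrossprod(b, X)
  theta <- pmax(apply(Y - fitted, 2, stats::var), 0.05 * apply(Y, 2, stats::var))
  delta <- if (flags$skew) {
    sk <- apply(Y, 2, sample_skewness)
    0.5 * sign(sk) * sqrt(apply(Y, 2, stats::var))
  } else numeric(p)
  nu <- 20
  base <- list(alpha = alpha, Psi = Psi, theta = theta, delta = delta, nu = nu)
  if (K == 1) return(list(weights = 1, classes = list(base)))
  # split subjects at the median overall level
  lev <- rowMeans(Y)
  grp <- lev > stats::median(lev)
  classes <- lapply(c(FALSE, TRUE), function(g) {
    cl <- base
    sub <- b[grp == g, , drop = FALSE]
    if (nrow(sub) > 2) cl$alpha <- colMeans(sub)
    cl
  })
  list(weights = rep(1 / K, K), classes = classes)
}

# Randomly perturb a start (list(weights, classes)); sizes scale with the
# data's marginal dispersion so perturbations explore genuinely different
# basins, and, for K = 2, class means are sometimes redrawn from the range
# of subject-level trajectories.
perturb_start <- function(start, Y, time_scores, flags, scale) {
  p <- ncol(Y)
  sdy <- stats::sd(Y)
  X <- cbind(1, time_scores)
  b <- Y %*% X %*% solve(crossprod(X))
  K <- length(start$classes)
  classes <- lapply(start$classes, function(cl) {
    cl$alpha <- cl$alpha + stats::rnorm(2, 0, scale * c(stats::sd(b[, 1]), stats::sd(b[, 2])))
    if (stats::runif(1) < 0.3) {
      i <- sample.int(nrow(b), 1)
      cl$alpha <- as.numeric(b[i, ])
    }
    dPsi <- diag(cl$Psi) * exp(stats::rnorm(2, 0, 0.5 * scale))
    rho <- cl$Psi[1, 2] / sqrt(prod(diag(cl$Psi)) + 1e-12) * stats::runif(1)
    cl$Psi <- diag(sqrt(dPsi)) %*% matrix(c(1, rho, rho, 1), 2) %*% diag(sqrt(dPsi))
    cl$theta <- cl$theta * exp(stats::rnorm(p, 0, 0.5 * scale))
    if (flags$skew)
      cl$delta <- cl$delta * exp(stats::rnorm(1, 0, 0.3)) +
        stats::rnorm(p, 0, 0.3 * scale * sdy)
    if (flags$tdist) cl$nu <- exp(stats::runif(1, log(3), log(60)))
    cl
  })
  w <- if (K == 1) 1 else {
    u <- stats::runif(K, 0.25, 1)
    u / sum(u)
  }
  list(weights = w, classes = classes)
}

strip_start <- function(start) {
  lapply(start$classes, function(cl)
    list(alpha = cl$alpha, Psi = cl$Psi, theta = cl$theta,
         delta = if (is.null(cl$delta)) numeric(length(cl$theta)) else cl$delta,
         nu = if (is.null(cl$nu) || !is.finite(cl$nu)) 30 else cl$nu))
}

#' Fit a K-class skew-t family growth mixture model by EM
#'
#' Maximum-likelihood estimation under any of the four nested family
#' members. The mean of each class is growth-structured
#' (\eqn{\mu_g = \Lambda\alpha_g}) and its scale matrix is
#' \eqn{\Sigma_g = \Lambda\Psi_g\Lambda' + \Theta_g} with diagonal
#' \eqn{\Theta_g}; the skewness vector \eqn{\delta_g} is a free
#' per-occasion vector for the skew families and the degrees of freedom
#' \eqn{\nu_g} are estimated (bounded in `nu_bounds`) for the t families.
#' Multiple starts are handled by the [start_policy()]; the best
#' log-likelihood over all completed runs is returned. Runs that collapse
#' (a mixing weight below `1/n`, or a singular scale matrix) are discarded
#' and counted in `n_degenerate`.
#'
#' @param data n x p numeric matrix or data frame, one row per subject.
#' @param family family tag, see [st_families()].
#' @param K number of latent classes.
#' @param time_scores time scores (default 0, 1, ..., p-1).
#' @param init optional deterministic start: a `gmm_model`, or a list with
#'   elements `weights` and `classes` as in [gmm_model()]. Random starts
#'   are perturbations of this start when given.
#' @param starts a [start_policy()].
#' @param seed integer seed controlling the random starts.
#' @param maxit maximum EM iterations per run (the study allowed 1000).
#' @param tol relative log-likelihood change declaring convergence.
#' @param nu_bounds bounds for the degrees of freedom; the upper bound is
#'   treated as the normal limit.
#' @param skew_structure `"observed"` (default: free per-occasion skew
#'   vector) or `"factor"` (skew carried by the intercept and slope
#'   factors, two parameters). See [n_free_params()].
#' @param cov_structure `"class_specific"` (default: every class has its
#'   own Psi, Theta, delta, nu) or `"shared"` (only the factor means and
#'   mixing weights vary by class, the usual mixture-software default and
#'   the convention of the simulation study driver).
#' @return an object of class `gmm_fit`: a list with `model`
#'   ([gmm_model()]), `loglik`, `n_params`, `converged`, `iterations`,
#'   `posteriors` (n x K), `trajectory` (per-iteration log-likelihood of
#'   the best run) and `n_degenerate`.
#' @export
#' @examples
#' y <- generate_growth_data(bauer_curran_params(), 0, 0, n = 200, seed = 1)
#' f <- fit_gmm(y, "normal", K = 1, starts = start_policy(n_random = 4), seed = 1)
#' f$model$classes[[1]]$alpha
fit_gmm <- function(data, family, K = 1, time_scores = NULL, init = NULL,
                    starts = start_policy(), seed = 1, maxit = 1000,
                    tol = 1e-6, nu_bounds = c(2.1, 200),
                    skew_structure = c("observed", "factor"),
                    cov_structure = c("class_specific", "shared")) {
  skew_structure <- match.arg(skew_structure)
  cov_structure <- match.arg(cov_structure)
  Y <- as.matrix(data)
  storage.mode(Y) <- "double"
  n <- nrow(Y); p <- ncol(Y)
  flags <- family_flags(family)
  if (is.null(time_scores)) time_scores <- 0:(p - 1)
  L <- cbind(1, time_scores)
  q <- n_free_params(flags$family, K, p, skew_structure, cov_structure)
  if (n <= q)
    warning("sample size does not exceed the number of free parameters")

  if (inherits(init, "gmm_model")) {
    init <- list(weights = init$weights, classes = init$classes)
  }
  base <- if (is.null(init)) default_start(Y, time_scores, flags, K) else init

  skf <- skew_structure == "factor"
  shc <- cov_structure == "shared"
  run <- function(st, it, tl) {
    .em_fit_cpp(Y, L, strip_start(st), st$weights, flags$skew, flags$tdist,
                skf, shc, it, tl, 1e-8, nu_bounds[1], nu_bounds[2], TRUE)
  }
  resume <- function(res, it, tl) {
    .em_fit_cpp(Y, L, res$classes, res$weights, flags$skew, flags$tdist,
                skf, shc, it, tl, 1e-8, nu_bounds[1], nu_bounds[2], TRUE)
  }

  n_degenerate <- 0L
  finals <- list()
  with_seed(seed, {
    shorts <- list()
    if (starts$n_random > 0) {
      for (s in seq_len(starts$n_random)) {
        st <- perturb_start(base, Y, time_scores, flags, starts$perturb)
        r <- tryCatch(run(st, starts$short_iter, 1e-12), error = function(e) NULL)
        if (is.null(r) || r$degenerate || !is.finite(r$loglik)) {
          n_degenerate <- n_degenerate + 1L
        } else shorts[[length(shorts) + 1L]] <- r
      }
    }
    # deterministic start always goes to convergence
    r0 <- tryCatch(run(base, maxit, tol), error = function(e) NULL)
    if (!is.null(r0) && !r0$degenerate && is.finite(r0$loglik)) {
      finals[[length(finals) + 1L]] <- r0
    } else n_degenerate <- n_degenerate + 1L
    if (length(shorts)) {
      ord <- order(vapply(shorts, function(r) r$loglik, 0), decreasing = TRUE)
      keep <- utils::head(ord, starts$n_final)
      for (i in keep) {
        r <- tryCatch(resume(shorts[[i]], maxit, tol), error = function(e) NULL)
        if (is.null(r) || r$degenerate || !is.finite(r$loglik)) {
          n_degenerate <- n_degenerate + 1L
        } else {
          r$trajectory <- c(shorts[[i]]$trajectory,
                            r$trajectory[-1])
          finals[[length(finals) + 1L]] <- r
        }
      }
    }
  })

  if (!length(finals)) {
    model <- gmm_model(flags$family, base$weights, base$classes, time_scores,
                       skew_structure, cov_structure)
    return(structure(list(model = model, loglik = -Inf, n_params = q,
                          converged = FALSE, iterations = 0L,
                          posteriors = matrix(1 / K, n, K),
                          trajectory = numeric(0), family = flags$family,
                          K = K, n = n, p = p,
                          n_degenerate = n_degenerate),
                     class = "gmm_fit"))
  }
  best <- finals[[which.max(vapply(finals, function(r) r$loglik, 0))]]
  model <- gmm_model(flags$family, as.numeric(best$weights), best$classes,
                     time_scores, skew_structure, cov_structure)
  structure(list(model = model,
                 loglik = best$loglik,
                 n_params = q,
                 converged = isTRUE(best$converged),
                 iterations = best$iterations,
                 posteriors = best$posteriors,
                 trajectory = as.numeric(best$trajectory),
                 family = flags$family, K = K, n = n, p = p,
                 n_degenerate = n_degenerate),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("gmm_fit: %d-class %s family, n = %d\n", x$K, x$family, x$n))
  cat(sprintf("  loglik = %.4f (%d free parameters), converged = %s in %d iterations\n",
              x$loglik, x$n_params, x$converged, x$iterations))
  print(x$model)
  invisible(x)
}

#' Per-observation mixture log-density of a fitted model
#'
#' @param model a `gmm_model`.
#' @param data n x p matrix.
#' @return numeric vector of per-row log-densities.
#' @export
gmm_obs_loglik <- function(model, data) {
  Y <- as.matrix(data)
  comps <- vapply(seq_along(model$classes), function(k) {
    cl <- model$classes[[k]]
    log(model$weights[k]) + dmst(Y, cl$mu, cl$Sigma, cl$delta, cl$nu, log = TRUE)
  }, numeric(nrow(Y)))
  if (is.null(dim(comps))) comps <- matrix(comps, nrow = 1)
  m <- apply(comps, 1, max)
  m + log(rowSums(exp(comps - m)))
}
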