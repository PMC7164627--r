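# Shared fixtures: the study's generating parameters, deterministic starts
# anchored at them, and a lazy cache so expensive fits are computed once
# per test run.

study_params <- bauer_curran_params()

start_one_class <- list(
  weights = 1,
  classes = list(list(alpha = study_params$factor_means,
                      Psi = study_params$factor_cov,
                      theta = study_params$residual_vars,
                      delta = numeric(5), nu = 30)))

start_two_class <- local({
  lo <- start_one_class$classes[[1]]; lo$alpha <- c(0, 0)
  hi <- start_one_class$classes[[1]]; hi$alpha <- c(1.5, 1.6)
  list(weights = c(0.5, 0.5), classes = list(lo, hi))
})

# small policies keep unit tests fast; acceptance tests set their own
quick_starts <- start_policy(n_random = 6, short_iter = 8, n_final = 2)

.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# direct (EM-free) maximization of a 1-class model log-likelihood, used as
# the independent optimization oracle
direct_max_loglik <- function(Y, family, time_scores, init, maxit = 800) {
  flags <- stgmm:::family_flags(family)
  p <- ncol(Y)
  L <- cbind(1, time_scores)
  pack <- function(cl) {
    x <- c(cl$alpha, cl$Psi[c(1, 2, 4)], log(cl$theta))
    if (flags$skew) x <- c(x, cl$delta)
    if (flags$tdist) x <- c(x, log(cl$nu))
    x
  }
  nll <- function(x) {
    alpha <- x[1:2]
    Psi <- matrix(c(x[3], x[4], x[4], x[5]), 2)
    theta <- exp(x[5 + seq_len(p)])
    i <- 5 + p
    delta <- if (flags$skew) { d <- x[i + seq_len(p)]; i <- i + p; d } else numeric(p)
    nu <- if (flags$tdist) exp(x[i + 1]) else Inf
    if (is.finite(nu) && (nu < 2.05 || nu > 300)) return(1e10)
    S <- L %*% Psi %*% t(L) + diag(theta, p)
    val <- suppressWarnings(
      tryCatch(-sum(dmst(Y, L %*% alpha, S, delta, nu, log = TRUE)),
               error = function(e) 1e10))
    if (!is.finite(val)) 1e10 else val
  }
  o <- stats::optim(pack(init), nll, method = "BFGS",
                    control = list(maxit = maxit, reltol = 1e-13))
  -o$value
}
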