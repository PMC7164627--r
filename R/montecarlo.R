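# Monte Carlo driver: factorial design over distribution condition, sample
# size and fitted family; false-positive and convergence rates.

#' One cell of the simulation design
#'
#' @param skew,ex_kurtosis marginal distribution condition of the generated
#'   data.
#' @param n sample size.
#' @param family fitted family tag.
#' @param replications number of Monte Carlo replications (>= 1).
#' @param base_seed integer; replication r uses seed `base_seed + r`.
#' @return a list of class `design_cell`.
#' @export
design_cell <- function(skew, ex_kurtosis, n, family, replications = 100,
                        base_seed = 20200417) {
  stopifnot(replications >= 1, n >= 2)
  family <- match.arg(family, st_families())
  structure(list(skew = skew, ex_kurtosis = ex_kurtosis, n = as.integer(n),
                 family = family, replications = as.integer(replications),
                 base_seed = as.integer(base_seed)),
            class = "design_cell")
}

#' Run one design cell
#'
#' For each replication: generate a single-class dataset with the cell's
#' distribution condition, fit the 1- and 2-class models of the cell's
#' family, compute AIC/BIC/SBIC and the VLMR/LMR (and optionally bootstrap)
#' LRTs, and record which criteria prefer the spurious 2-class solution.
#' Everything is reproducible from the cell definition: replication r uses
#' seed `base_seed + r` for all of its randomness.
#'
#' False-positive denominators are the replications in which BOTH class
#' counts converged (joint convergence).
#'
#' @param cell a [design_cell()].
#' @param params generating growth parameters (defaults to
#'   [bauer_curran_params()]).
#' @param starts start policy for the fits; defaults to the study profile
#'   of 100 random starts. Starts are perturbations of the generating
#'   values, and the 2-class deterministic start uses the low/high pattern
#'   (class 1 alpha = [0, 0], class 2 alpha = [1.5, 1.6]).
#' @param blrt_B bootstrap draws for the BLRT per replication (0 skips the
#'   BLRT, its usual setting since it is by far the most expensive
#'   criterion).
#' @param alpha LRT significance level.
#' @param maxit,tol EM control (the study allowed 1000 iterations).
#' @param skew_structure,cov_structure model structure passed to
#'   [fit_gmm()]; the defaults here are the study conventions (skew on the
#'   growth factors, covariance parameters class-invariant), which differ
#'   from the [fit_gmm()] defaults.
#' @param workers number of parallel workers (forked); results are
#'   independent of `workers` because each replication has its own seed.
#' @param verbose print per-replication progress to stderr.
#' @return a `cell_result`: list with `cell`, `reps` (one row per
#'   replication) and aggregate elements `converged` (per class count),
#'   `fpr` (criterion -> proportion preferring 2 classes among jointly
#'   converged replications), `fpr_denominator`, `mean_bic` (per class
#'   count, over converged fits of that class count).
#' @export
run_cell <- function(cell, params = bauer_curran_params(),
                     starts = start_policy(n_random = 100, short_iter = 10,
                                           n_final = 20, perturb = 1.5),
                     blrt_B = 0, alpha = 0.05, maxit = 1000, tol = 1e-6,
                     skew_structure = c("factor", "observed"),
                     cov_structure = c("class_specific", "shared"),
                     workers = 1L, verbose = FALSE) {
  stopifnot(inherits(cell, "design_cell"))
  skew_structure <- match.arg(skew_structure)
  cov_structure <- match.arg(cov_structure)
  init1 <- list(weights = 1,
                classes = list(list(alpha = params$factor_means,
                                    Psi = params$factor_cov,
                                    theta = params$residual_vars,
                                    delta = numeric(length(params$residual_vars)),
                                    nu = 30)))
  # low/high two-group start pattern used in the study design
  cl2a <- init1$classes[[1]]; cl2a$alpha <- c(0, 0)
  cl2b <- init1$classes[[1]]; cl2b$alpha <- c(1.5, 1.6)
  init2 <- list(weights = c(0.5, 0.5), classes = list(cl2a, cl2b))

  one_rep <- function(r) {
    seed <- cell$base_seed + r
    Y <- generate_growth_data(params, cell$skew, cell$ex_kurtosis, cell$n,
                              seed = seed)
    f1 <- fit_gmm(Y, cell$family, K = 1, time_scores = params$time_scores,
                  init = init1, starts = starts, seed = seed, maxit = maxit,
                  tol = tol, skew_structure = skew_structure,
                  cov_structure = cov_structure)
    f2 <- fit_gmm(Y, cell$family, K = 2, time_scores = params$time_scores,
                  init = init2, starts = starts, seed = seed + 1L,
                  maxit = maxit, tol = tol, skew_structure = skew_structure,
                  cov_structure = cov_structure)
    out <- data.frame(rep = r, seed = seed,
                      converged1 = f1$converged, converged2 = f2$converged,
                      loglik1 = f1$loglik, loglik2 = f2$loglik,
                      aic1 = NA_real_, bic1 = NA_real_, sbic1 = NA_real_,
                      aic2 = NA_real_, bic2 = NA_real_, sbic2 = NA_real_,
                      vlmr_p = NA_real_, lmr_p = NA_real_, blrt_p = NA_real_)
    if (is.finite(f1$loglik))
      out[, c("aic1", "bic1", "sbic1")] <- information_criteria(f1, cell$n)
    if (is.finite(f2$loglik))
      out[, c("aic2", "bic2", "sbic2")] <- information_criteria(f2, cell$n)
    if (f1$converged && f2$converged) {
      pv <- tryCatch(lmr_tests(f2, f1, Y),
                     error = function(e) c(vlmr = NA_real_, lmr = NA_real_))
      out$vlmr_p <- pv[["vlmr"]]
      out$lmr_p <- pv[["lmr"]]
      if (blrt_B > 0)
        out$blrt_p <- blrt(Y, cell$family, k = 2, B = blrt_B, seed = seed,
                           fit_k = f2, fit_km1 = f1, starts = starts,
                           maxit = maxit, tol = tol)$p_value
    }
    if (verbose)
      message(sprintf("[%s skew=%g kurt=%g n=%d] rep %d/%d: conv=(%s,%s)",
                      cell$family, cell$skew, cell$ex_kurtosis, cell$n, r,
                      cell$replications, f1$converged, f2$converged))
    out
  }

  reps <- if (workers > 1L) {
    do.call(rbind, parallel::mclapply(seq_len(cell$replications), one_rep,
                                      mc.cores = workers))
  } else {
    do.call(rbind, lapply(seq_len(cell$replications), one_rep))
  }
  summarize_cell(cell, reps, alpha)
}

summarize_cell <- function(cell, reps, alpha = 0.05) {
  joint <- reps$converged1 & reps$converged2
  denom <- sum(joint)
  fpr <- c(
    aic = if (denom) mean(reps$aic2[joint] < reps$aic1[joint]) else NA_real_,
    bic = if (denom) mean(reps$bic2[joint] < reps$bic1[joint]) else NA_real_,
    sbic = if (denom) mean(reps$sbic2[joint] < reps$sbic1[joint]) else NA_real_,
    vlmr = if (denom) mean(reps$vlmr_p[joint] < alpha, na.rm = TRUE) else NA_real_,
    lmr = if (denom) mean(reps$lmr_p[joint] < alpha, na.rm = TRUE) else NA_real_,
    blrt = if (denom && any(is.finite(reps$blrt_p[joint])))
      mean(reps$blrt_p[joint] < alpha, na.rm = TRUE) else NA_real_)
  structure(list(
    cell = cell, reps = reps, alpha = alpha,
    converged = c(`1` = sum(reps$converged1), `2` = sum(reps$converged2)),
    fpr = fpr,
    fpr_denominator = denom,
    mean_bic = c(`1` = mean(reps$bic1[reps$converged1]),
                 `2` = mean(reps$bic2[reps$converged2]))),
    class = "cell_result")
}

#' @export
print.cell_result <- function(x, ...) {
  cat(sprintf("cell: %s family, skew %g / ex.kurt %g, n = %d, R = %d\n",
              x$cell$family, x$cell$skew, x$cell$ex_kurtosis, x$cell$n,
              x$cell$replications))
  cat(sprintf("  converged: 1-class %d, 2-class %d (joint %d)\n",
              x$converged[1], x$converged[2], x$fpr_denominator))
  cat("  false-positive rates:\n")
  print(round(x$fpr, 3))
  invisible(x)
}

#' False-positive rate of a set of enumeration decisions
#'
#' @param decisions vector of selected class counts.
#' @param truth the generating class count (1 in this study).
#' @return proportion of decisions exceeding `truth`.
#' @export
#' @examples
#' false_positive_rate(c(1, 1, 2, 1))  # 0.25
false_positive_rate <- function(decisions, truth = 1) {
  if (!length(decisions)) stop("no decisions supplied")
  mean(decisions > truth)
}

#' Tabulate cell results into tidy tables
#'
#' @param results list of `cell_result` objects.
#' @return list of two data frames: `fpr` (condition, n, family, criterion,
#'   fpr, denominator, replications) and `convergence` (condition, n,
#'   family, class count, converged count, rate, mean BIC).
#' @export
tabulate_results <- function(results) {
  if (!length(results)) {
    return(list(
      fpr = data.frame(skew = numeric(0), ex_kurtosis = numeric(0),
                       n = integer(0), family = character(0),
                       criterion = character(0), fpr = numeric(0),
                       denominator = integer(0), replications = integer(0)),
      convergence = data.frame(skew = numeric(0), ex_kurtosis = numeric(0),
                               n = integer(0), family = character(0),
                               classes = integer(0), converged = integer(0),
                               rate = numeric(0), mean_bic = numeric(0))))
  }
  fpr <- do.call(rbind, lapply(results, function(x) {
    data.frame(skew = x$cell$skew, ex_kurtosis = x$cell$ex_kurtosis,
               n = x$cell$n, family = x$cell$family,
               criterion = names(x$fpr), fpr = unname(x$fpr),
               denominator = x$fpr_denominator,
               replications = x$cell$replications, row.names = NULL)
  }))
  convergence <- do.call(rbind, lapply(results, function(x) {
    data.frame(skew = x$cell$skew, ex_kurtosis = x$cell$ex_kurtosis,
               n = x$cell$n, family = x$cell$family, classes = 1:2,
               converged = unname(x$converged),
               rate = unname(x$converged) / x$cell$replications,
               mean_bic = unname(x$mean_bic), row.names = NULL)
  }))
  list(fpr = fpr, convergence = convergence)
}

#' Write / read the result tables as CSV (lossless round trip)
#'
#' @param tables output of [tabulate_results()].
#' @param dir directory for `fpr.csv` and `convergence.csv`.
#' @return `write_results_tables` returns `dir` invisibly;
#'   `read_results_tables` the list of tables.
#' @export
write_results_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(tables$fpr, file.path(dir, "fpr.csv"), row.names = FALSE)
  utils::write.csv(tables$convergence, file.path(dir, "convergence.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_results_tables
#' @export
read_results_tables <- function(dir) {
  list(fpr = utils::read.csv(file.path(dir, "fpr.csv")),
       convergence = utils::read.csv(file.path(dir, "convergence.csv")))
}

#' Run a full factorial study from a config
#'
#' The config is a list (or a YAML file holding one) with elements
#' `conditions` (list of `c(skew, ex_kurtosis)` pairs), `ns`, `families`,
#' `replications`, `base_seed`, and optional `blrt_B`, `n_random_starts`,
#' `maxit`, `tol`, `workers`. The default profile is desk-scale
#' (`replications = 100`); the full study profile uses 500 replications.
#'
#' @param config list or path to a YAML file.
#' @param params generating growth parameters.
#' @param verbose print progress.
#' @return list with `results` (cell results) and `tables`
#'   ([tabulate_results()]).
#' @export
run_study <- function(config, params = bauer_curran_params(), verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(conditions = list(c(0, 0), c(1, 2), c(1.6, 4)),
                   ns = c(50, 200, 800, 3200),
                   families = st_families(),
                   replications = 100, base_seed = 20200417, blrt_B = 0,
                   n_random_starts = 100, maxit = 1000, tol = 1e-6,
                   workers = 1)
  # wholesale replacement (modifyList would merge list-valued fields
  # such as `conditions` element-wise)
  for (nm in names(config)) defaults[[nm]] <- config[[nm]]
  config <- defaults
  starts <- start_policy(n_random = config$n_random_starts)
  results <- list()
  for (cond in config$conditions) for (n in config$ns)
    for (family in config$families) {
      cell <- design_cell(cond[1], cond[2], n, family,
                          replications = config$replications,
                          base_seed = config$base_seed)
      if (verbose)
        message(sprintf("running cell: %s, skew %g, n = %d ...", family,
                        cond[1], n))
      results[[length(results) + 1L]] <-
        run_cell(cell, params = params, starts = starts,
                 blrt_B = config$blrt_B, maxit = config$maxit,
                 tol = config$tol, workers = config$workers,
                 verbose = verbose)
    }
  list(results = results, tables = tabulate_results(results))
}
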