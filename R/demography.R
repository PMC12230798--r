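#' Asymptotic population growth rate of a projection matrix
#'
#' Computes the dominant eigenvalue (the asymptotic growth rate `lambda` per
#' projection interval) of a non-negative projection matrix by power
#' iteration, optionally cross-checked against R's full eigendecomposition.
#' For the primitive matrices produced by [build_kernel()] the
#' Perron-Frobenius theorem guarantees a real positive dominant eigenvalue
#' bracketed by the extreme column sums.
#'
#' @param A square non-negative numeric matrix, or an `ipm_matrix`.
#' @param tol relative convergence tolerance of the power iteration
#'   (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @param cross_check compare against `eigen()` and stop if the two routes
#'   disagree beyond `1e-8` relative (default `TRUE`).
#' @return The dominant eigenvalue (a positive scalar).
#' @examples
#' compute_lambda(matrix(c(0.5, 0.25, 1, 0.5), 2))  # 1
#' @export
compute_lambda <- function(A, tol = 1e-10, max_iter = 10000L,
                           cross_check = TRUE) {
  if (inherits(A, "ipm_matrix")) A <- A$A
  if (!is.matrix(A) || nrow(A) != ncol(A)) abort("'A' must be a square matrix")
  if (any(!is.finite(A))) abort("'A' contains non-finite entries")
  if (any(A < 0)) abort("'A' must be non-negative")
  lam <- power_lambda(A, tol, max_iter)
  if (cross_check) {
    lam_eig <- max(Re(eigen(A, only.values = TRUE)$values))
    if (abs(lam - lam_eig) > 1e-8 * max(1, abs(lam_eig))) {
      abort("power iteration (%.12g) and eigendecomposition (%.12g) disagree",
            lam, lam_eig)
    }
  }
  lam
}

power_lambda <- function(A, tol, max_iter) {
  n <- nrow(A)
  v <- rep(1 / n, n)
  lam_old <- 0
  for (it in seq_len(max_iter)) {
    w <- A %*% v
    lam <- sum(abs(w))
    if (lam == 0) abort("projection matrix is nilpotent: lambda = 0")
    v_new <- as.vector(w) / lam
    if (abs(lam - lam_old) <= tol * lam &&
        sum(abs(v_new - v)) <= tol * n) {
      return(lam)
    }
    v <- v_new
    lam_old <- lam
  }
  abort("power iteration did not converge in %d iterations (residual %.3g)",
        max_iter, abs(lam - lam_old) / lam)
}

#' Bootstrap confidence intervals for lambda
#'
#' Resamples individual records with replacement within each
#' origin-by-treatment stratum (and, when field records are supplied, field
#' plants within each population), refits the vital rates, rebuilds each
#' kernel and recomputes lambda, `n_boot` times. The interval is the central
#' 95% percentile interval (2.5th/97.5th empirical percentiles). The
#' demographic constants `e`, `e_sb`, `s_sb` come from external literature
#' and are never resampled. Size limits are resolved once from the full
#' data (both census years pooled) and held fixed across replicates.
#'
#' Replicates whose refit fails (e.g. a resample with no flowering plants in
#' a cell gives perfect separation) are redrawn; more than `20%` redraws is
#' an error.
#'
#' @param records individual records (see [simulate_greenhouse()]).
#' @param field optional field fecundity records; when supplied the regional
#'   seed constant is re-estimated per replicate via
#'   [estimate_seed_constant()] and applied to every origin, so pass
#'   region-specific field data when origins differ.
#' @param config an [ipm_config()].
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param rng_seed integer seed; identical seeds give identical intervals.
#' @param pool_survival_and_shoots passed to [fit_vital_rates()].
#' @param seeds_per_shoot regional seed constants used when `field` is
#'   `NULL` (default the published 79/42).
#' @param resample set `FALSE` to disable resampling (every replicate is the
#'   identity sample; the interval then collapses onto the point estimate).
#' @return A data frame of class `lambda_result`, one row per cell:
#'   `origin`, `treatment`, `lambda`, `ci_low`, `ci_high`; attributes
#'   `n_boot`, `rng_seed`, `n_redraws`, and `replicates` (the lambda draws).
#' @export
bootstrap_lambda <- function(records, field = NULL, config = ipm_config(),
                             n_boot = 1000L, rng_seed,
                             pool_survival_and_shoots = TRUE,
                             seeds_per_shoot = c(invasive_FI = 79, native_US = 42),
                             resample = TRUE) {
  if (missing(rng_seed)) abort("an integer rng_seed is required")
  check_finite_scalar(n_boot, "n_boot")
  if (n_boot < 1) abort("n_boot must be >= 1")
  records <- validate_records(records)
  if (is.null(config$L) || is.null(config$U)) {
    lim <- resolve_size_limits(c(records$size_t, records$size_t1), config)
    config$L <- lim[["L"]]; config$U <- lim[["U"]]
  }

  fit_lambdas <- function(rec, fld) {
    seeds <- seeds_per_shoot
    if (!is.null(fld)) {
      est <- estimate_seed_constant(fld)
      seeds <- stats::setNames(rep(est, length(unique(rec$origin))),
                               unique(rec$origin))
    }
    params <- fit_vital_rates(rec, pool_survival_and_shoots,
                              seeds_per_shoot = seeds)
    vapply(params, function(p) compute_lambda(build_kernel(p, config),
                                              cross_check = FALSE),
           numeric(1))
  }

  point <- fit_lambdas(records, field)
  cells <- strsplit(names(point), ":", fixed = TRUE)

  set.seed(as.integer(rng_seed))
  strata <- split(seq_len(nrow(records)),
                  paste(records$origin, records$treatment))
  fld_strata <- if (!is.null(field)) split(seq_len(nrow(field)),
                                           field$population)
  reps <- matrix(NA_real_, n_boot, length(point),
                 dimnames = list(NULL, names(point)))
  n_redraws <- 0L
  max_redraws <- ceiling(0.2 * n_boot)
  b <- 1L
  while (b <= n_boot) {
    if (resample) {
      idx <- unlist(lapply(strata, function(i) sample(i, length(i),
                                                      replace = TRUE)))
      fld <- if (!is.null(field)) {
        field[unlist(lapply(fld_strata, function(i) sample(i, length(i),
                                                           replace = TRUE))), ]
      }
    } else {
      idx <- seq_len(nrow(records))
      fld <- field
    }
    lam <- tryCatch(fit_lambdas(records[idx, ], fld), error = function(e) NULL)
    if (is.null(lam)) {
      n_redraws <- n_redraws + 1L
      if (n_redraws > max_redraws) {
        abort("more than 20%% of bootstrap replicates failed to refit (%d)",
              n_redraws)
      }
      next
    }
    reps[b, ] <- lam
    b <- b + 1L
  }

  ci <- apply(reps, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(
    origin = vapply(cells, `[`, "", 1L),
    treatment = vapply(cells, `[`, "", 2L),
    lambda = unname(point),
    ci_low = ci[1L, ], ci_high = ci[2L, ],
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "n_boot") <- as.integer(n_boot)
  attr(out, "rng_seed") <- as.integer(rng_seed)
  attr(out, "n_redraws") <- n_redraws
  attr(out, "replicates") <- reps
  class(out) <- c("lambda_result", "data.frame")
  out
}

#' @export
print.lambda_result <- function(x, ...) {
  cat(sprintf("Asymptotic growth rates (bootstrap, %d replicates, seed %d)\n",
              attr(x, "n_boot"), attr(x, "rng_seed")))
  df <- as.data.frame(x)
  df$lambda <- sprintf("%.3f", df$lambda)
  df$`95% CI` <- sprintf("[%.3f, %.3f]", x$ci_low, x$ci_high)
  print.data.frame(df[, c("origin", "treatment", "lambda", "95% CI")],
                   row.names = FALSE)
  if (attr(x, "n_redraws") > 0) {
    cat(sprintf("  (%d failed replicates redrawn)\n", attr(x, "n_redraws")))
  }
  invisible(x)
}

SENS_COMPONENTS <- c("s_intercept", "s_slope", "p_intercept", "p_slope",
                     "g_intercept", "g_slope", "f1_intercept", "f1_slope",
                     "fd_mean", "seed", "e", "s_sb", "e_sb")

perturb_params <- function(params, component, factor = 0.99) {
  p <- params
  switch(component,
    s_intercept  = p$survival[["intercept"]] <- factor * p$survival[["intercept"]],
    s_slope      = p$survival[["slope"]] <- factor * p$survival[["slope"]],
    p_intercept  = p$flowering[["intercept"]] <- factor * p$flowering[["intercept"]],
    p_slope      = p$flowering[["slope"]] <- factor * p$flowering[["slope"]],
    g_intercept  = p$growth[["intercept"]] <- factor * p$growth[["intercept"]],
    g_slope      = p$growth[["slope"]] <- factor * p$growth[["slope"]],
    f1_intercept = p$shoots[["intercept"]] <- factor * p$shoots[["intercept"]],
    f1_slope     = p$shoots[["slope"]] <- factor * p$shoots[["slope"]],
    fd_mean      = p$recruit_size[["mean"]] <- factor * p$recruit_size[["mean"]],
    fd_var       = p$recruit_size[["var"]] <- factor * p$recruit_size[["var"]],
    g_sigma2     = p$growth[["sigma2"]] <- factor * p$growth[["sigma2"]],
    seed         = p$seeds_per_shoot <- factor * p$seeds_per_shoot,
    e            = p$establishment <- factor * p$establishment,
    s_sb         = p$bank_survival <- factor * p$bank_survival,
    e_sb         = p$bank_establishment <- factor * p$bank_establishment,
    abort("unknown parameter component '%s'", component)
  )
  p
}

#' One-at-a-time proportional sensitivity of lambda
#'
#' Reduces each model parameter component in turn by 1% of its value
#' (multiplicatively, `0.99 x`, preserving the sign of negative slopes),
#' rebuilds the kernel, and records the absolute proportional change
#' `|lambda' - lambda| / lambda`. The baseline parameter set is restored
#' between perturbations. Variance parameters (growth residual variance,
#' recruit-size variance) are included only when the config sets
#' `perturb_variances`.
#'
#' @param params a [vital_rate_params].
#' @param config an [ipm_config()]. Size limits are resolved once from the
#'   baseline parameters and held fixed across perturbations, so the
#'   perturbed and baseline eigenvalues are compared on the same mesh.
#' @param factor perturbation multiplier (default 0.99, i.e. a 1%
#'   reduction).
#' @return A data frame of class `sensitivity_table`: `parameter`,
#'   `sensitivity` (= `|lambda' - lambda| / lambda`), with baseline `lambda`
#'   as an attribute.
#' @export
sensitivity_analysis <- function(params, config = ipm_config(), factor = 0.99) {
  config <- kernel_limits(params, config)
  lam0 <- compute_lambda(build_kernel(params, config), cross_check = FALSE)
  comps <- SENS_COMPONENTS
  if (config$perturb_variances) comps <- c(comps, "g_sigma2", "fd_var")
  sens <- vapply(comps, function(cmp) {
    lam1 <- compute_lambda(build_kernel(perturb_params(params, cmp, factor),
                                        config),
                           cross_check = FALSE)
    abs(lam1 - lam0) / lam0
  }, numeric(1))
  out <- data.frame(parameter = comps, sensitivity = unname(sens),
                    stringsAsFactors = FALSE)
  attr(out, "lambda") <- lam0
  attr(out, "factor") <- factor
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat(sprintf(
    "Proportional sensitivities |dlambda|/lambda to a %.0f%% reduction (lambda = %.3f)\n",
    100 * (1 - attr(x, "factor")), attr(x, "lambda")))
  df <- as.data.frame(x)
  df <- df[order(-df$sensitivity), ]
  df$sensitivity <- sprintf("%.5f", df$sensitivity)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
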