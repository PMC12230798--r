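#' @keywords internal
ORIGINS <- c("invasive_FI", "native_US")
#' @keywords internal
TREATMENTS <- c("intact", "autoclaved")

cell_key <- function(origin, treatment) paste(origin, treatment, sep = ":")

#' Vital-rate parameter set for one origin-by-treatment IPM
#'
#' Bundles the size-dependent vital-rate coefficients and the demographic
#' constants that parameterize one seed-bank IPM. Sizes are log-transformed
#' plant heights; survival and flowering are linear on the logit scale,
#' growth and flowering-shoot number are linear on the identity scale, and
#' the recruit-size distribution is Normal.
#'
#' @param survival numeric `c(intercept, slope)` of the survival logistic
#'   `s(x) = inv-logit(a_s + b_s x)`.
#' @param growth numeric `c(intercept, slope, sigma2)`: mean next-year size
#'   `a_g + b_g x` and residual variance of the Gaussian growth kernel.
#' @param flowering numeric `c(intercept, slope)` of the flowering logistic
#'   `p(x)`.
#' @param shoots numeric `c(intercept, slope)` of the flowering-shoot number
#'   `f1(x) = a_f1 + b_f1 x` (clamped at 0 inside the kernel).
#' @param recruit_size numeric `c(mean, var)` of the Normal recruit-size
#'   (size early in life) distribution `f_d`.
#' @param seeds_per_shoot average number of seeds produced per flowering
#'   shoot (a regional constant).
#' @param establishment probability `e` that a fresh seed establishes as a
#'   plant directly, without entering the seed bank.
#' @param bank_establishment probability `e_sb` that a seed-bank seed
#'   establishes in a given year.
#' @param bank_survival annual survival `s_sb` of seeds in the seed bank.
#' @param origin,treatment optional labels attached to the set.
#' @return An object of class `vital_rate_params` (a named list).
#' @examples
#' p <- canonical_params("invasive_FI", "intact")
#' p$growth
#' @export
vital_rate_params <- function(survival, growth, flowering, shoots, recruit_size,
                              seeds_per_shoot,
                              establishment = 0.122,
                              bank_establishment = 0.122,
                              bank_survival = 0.977,
                              origin = NA_character_, treatment = NA_character_) {
  survival <- as_coef(survival, "survival", 2L)
  flowering <- as_coef(flowering, "flowering", 2L)
  shoots <- as_coef(shoots, "shoots", 2L)
  growth <- as_coef(growth, "growth", 3L, c("intercept", "slope", "sigma2"))
  recruit_size <- as_coef(recruit_size, "recruit_size", 2L, c("mean", "var"))
  if (growth[["sigma2"]] <= 0) abort("growth sigma2 must be > 0")
  if (recruit_size[["var"]] <= 0) abort("recruit_size var must be > 0")
  check_finite_scalar(seeds_per_shoot, "seeds_per_shoot")
  if (seeds_per_shoot < 0) abort("seeds_per_shoot must be >= 0")
  check_prob(establishment, "establishment")
  check_prob(bank_establishment, "bank_establishment")
  check_prob(bank_survival, "bank_survival")
  structure(list(
    survival = survival, growth = growth, flowering = flowering,
    shoots = shoots, recruit_size = recruit_size,
    seeds_per_shoot = as.numeric(seeds_per_shoot),
    establishment = as.numeric(establishment),
    bank_establishment = as.numeric(bank_establishment),
    bank_survival = as.numeric(bank_survival),
    origin = origin, treatment = treatment
  ), class = "vital_rate_params")
}

as_coef <- function(x, name, len, nms = c("intercept", "slope")) {
  if (!is.numeric(x) || length(x) != len) {
    abort("'%s' must be a numeric vector of length %d", name, len)
  }
  if (any(!is.finite(x))) {
    bad <- nms[!is.finite(x)][1L]
    abort("non-finite value for %s %s", name, bad)
  }
  stats::setNames(as.numeric(x), nms[seq_len(len)])
}

#' @export
print.vital_rate_params <- function(x, ...) {
  cat(sprintf("Vital rates [%s, %s inoculum]\n",
              ifelse(is.na(x$origin), "?", x$origin),
              ifelse(is.na(x$treatment), "?", x$treatment)))
  cat(sprintf("  survival (logit):  %+.3f %+.3f x\n", x$survival[1], x$survival[2]))
  cat(sprintf("  growth:            %+.3f %+.3f x  (sigma2 = %.3f)\n",
              x$growth[1], x$growth[2], x$growth[3]))
  cat(sprintf("  flowering (logit): %+.3f %+.3f x\n", x$flowering[1], x$flowering[2]))
  cat(sprintf("  shoots:            %+.3f %+.3f x\n", x$shoots[1], x$shoots[2]))
  cat(sprintf("  recruit size:      Normal(%.3f, var %.3f)\n",
              x$recruit_size[1], x$recruit_size[2]))
  cat(sprintf("  seeds/shoot %.1f, e %.3f, e_sb %.3f, s_sb %.3f\n",
              x$seeds_per_shoot, x$establishment, x$bank_establishment,
              x$bank_survival))
  invisible(x)
}

table2_env <- new.env(parent = emptyenv())

load_table2 <- function() {
  if (is.null(table2_env$tab)) {
    path <- system.file("extdata", "table2.yaml", package = "lupineIPM",
                        mustWork = TRUE)
    table2_env$tab <- yaml::read_yaml(path)
  }
  table2_env$tab
}

#' Published vital-rate estimates for one origin-by-treatment cell
#'
#' Returns the vital-rate coefficients and constants of the greenhouse study
#' (shipped in `extdata/table2.yaml`) for one of the four origin-by-treatment
#' cells. Survival and flowering-shoot coefficients were estimated from the
#' pooled data and are therefore identical across cells; growth, flowering
#' and recruit size are cell specific; the seeds-per-shoot constant is
#' regional (79 invasive Finnish, 42 native North American) and the
#' establishment/seed-bank constants (e = e_sb = 0.122, s_sb = 0.977) come
#' from previously published field estimates.
#'
#' @param origin `"invasive_FI"` or `"native_US"`.
#' @param treatment `"intact"` or `"autoclaved"`.
#' @return A [vital_rate_params] object.
#' @examples
#' canonical_params("native_US", "autoclaved")
#' @export
canonical_params <- function(origin, treatment) {
  if (!is.character(origin) || length(origin) != 1L || !origin %in% ORIGINS ||
      !is.character(treatment) || length(treatment) != 1L ||
      !treatment %in% TREATMENTS) {
    abort("unknown cell (%s, %s); valid cells are %s x %s",
          paste(origin, collapse = ","), paste(treatment, collapse = ","),
          paste(ORIGINS, collapse = "/"), paste(TREATMENTS, collapse = "/"))
  }
  tab <- load_table2()
  cell <- tab$cells[[origin]][[treatment]]
  vital_rate_params(
    survival = unlist(tab$pooled$survival),
    growth = unlist(cell$growth),
    flowering = unlist(cell$flowering),
    shoots = unlist(tab$pooled$shoots),
    recruit_size = unlist(cell$recruit_size),
    seeds_per_shoot = tab$constants$seeds_per_shoot[[origin]],
    establishment = tab$constants$establishment,
    bank_establishment = tab$constants$bank_establishment,
    bank_survival = tab$constants$bank_survival,
    origin = origin, treatment = treatment
  )
}

#' All four published parameter sets
#'
#' @return A named list of [vital_rate_params], keyed `"origin:treatment"`.
#' @export
canonical_params_all <- function() {
  out <- list()
  for (o in ORIGINS) for (tr in TREATMENTS) {
    out[[cell_key(o, tr)]] <- canonical_params(o, tr)
  }
  out
}

#' Fit size-dependent vital rates from individual records
#'
#' Fits, for each origin-by-treatment cell: a logistic regression (logit
#' link, maximum likelihood) of survival on size, ordinary least squares of
#' next-year size on size (Gaussian growth; residual variance on the
#' unbiased n - 2 denominator), a logistic regression of flowering on size
#' among survivors, OLS of flowering-shoot number on size among flowering
#' plants, and the sample mean/variance of initial size (the recruit-size
#' distribution). With `pool_survival_and_shoots = TRUE` (the study's
#' convention, motivated by near-uniform survival and few flowering plants)
#' survival and shoot number are fitted once on all records and the common
#' coefficients are copied into every cell's parameter set.
#'
#' Random design effects (population, block) are not modelled: the IPM
#' consumes fixed-effect coefficients only.
#'
#' @param records a data frame of individual records as produced by
#'   [simulate_greenhouse()] (columns `origin`, `treatment`, `size_t`,
#'   `survived`, `size_t1`, `flowered`, `n_shoots`).
#' @param pool_survival_and_shoots fit survival and shoot number on the
#'   pooled data (default `TRUE`).
#' @param seeds_per_shoot named numeric of regional seed constants, e.g.
#'   `c(invasive_FI = 79, native_US = 42)` (the default); typically the
#'   output of [estimate_seed_constant()] per region.
#' @param establishment,bank_establishment,bank_survival demographic
#'   constants; these cannot be estimated from the greenhouse data and
#'   default to the published field values.
#' @return A named list of [vital_rate_params], keyed `"origin:treatment"`.
#' @seealso [canonical_params()] for the published coefficients.
#' @export
fit_vital_rates <- function(records, pool_survival_and_shoots = TRUE,
                            seeds_per_shoot = c(invasive_FI = 79, native_US = 42),
                            establishment = 0.122, bank_establishment = 0.122,
                            bank_survival = 0.977) {
  records <- validate_records(records)
  cells <- unique(records[, c("origin", "treatment")])
  cells <- cells[order(match(cells$origin, ORIGINS),
                       match(cells$treatment, TREATMENTS)), , drop = FALSE]

  if (pool_survival_and_shoots) {
    surv_pool <- fit_logistic(records$size_t, records$survived, "survival",
                              "pooled data")
    fl_pool <- records[records$survived == 1 & records$flowered == 1, ]
    shoots_pool <- fit_ols(fl_pool$size_t, fl_pool$n_shoots, "shoots",
                           "pooled data")
  }

  out <- list()
  for (r in seq_len(nrow(cells))) {
    o <- cells$origin[r]; tr <- cells$treatment[r]
    key <- cell_key(o, tr)
    sub <- records[records$origin == o & records$treatment == tr, ]
    if (nrow(sub) < 2L || length(unique(sub$size_t)) < 2L) {
      abort("insufficient data to fit cell %s", key)
    }
    surv <- if (pool_survival_and_shoots) surv_pool else
      fit_logistic(sub$size_t, sub$survived, "survival", key)
    alive <- sub[sub$survived == 1, ]
    if (nrow(alive) < 3L) abort("insufficient surviving plants in cell %s", key)
    growth <- fit_ols(alive$size_t, alive$size_t1, "growth", key)
    flowering <- fit_logistic(alive$size_t, alive$flowered, "flowering", key)
    shoots <- if (pool_survival_and_shoots) shoots_pool else
      fit_ols(alive$size_t[alive$flowered == 1],
              alive$n_shoots[alive$flowered == 1], "shoots", key)
    seed <- seeds_per_shoot[[o]]
    if (is.null(seed) || is.na(seed)) {
      abort("no seeds_per_shoot constant supplied for origin %s", o)
    }
    out[[key]] <- vital_rate_params(
      survival = surv$coef,
      growth = c(growth$coef, growth$sigma2),
      flowering = flowering$coef,
      shoots = shoots$coef,
      recruit_size = c(mean(sub$size_t), stats::var(sub$size_t)),
      seeds_per_shoot = seed,
      establishment = establishment,
      bank_establishment = bank_establishment,
      bank_survival = bank_survival,
      origin = o, treatment = tr
    )
    attr(out[[key]], "se") <- list(
      survival = surv$se, growth = growth$se, flowering = flowering$se,
      shoots = shoots$se
    )
  }
  out
}

fit_logistic <- function(x, y, rate, where) {
  if (length(y) < 2L) abort("insufficient data for %s fit (%s)", rate, where)
  if (length(unique(y)) < 2L) {
    abort(paste0("perfect separation in the %s fit (%s): only one outcome ",
                 "class present"), rate, where)
  }
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial(link = "logit"),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  mu <- stats::fitted(fit)
  if (!fit$converged || all(mu > 1 - 1e-8 | mu < 1e-8)) {
    abort("perfect separation (or non-convergence) in the %s fit (%s)",
          rate, where)
  }
  list(coef = unname(stats::coef(fit)),
       se = unname(sqrt(diag(stats::vcov(fit)))))
}

fit_ols <- function(x, y, rate, where) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(y) < 3L || length(unique(x)) < 2L) {
    abort("insufficient data for %s fit (%s)", rate, where)
  }
  fit <- stats::lm(y ~ x)
  s2 <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  # suppressed: summary.lm warns on noiseless ("essentially perfect") fits
  se <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))))
  list(coef = unname(stats::coef(fit)), se = se, sigma2 = s2)
}

#' Seeds per flowering shoot from field fecundity records
#'
#' For each plant, the mean number of seeds per pod (over its three sampled
#' pods) is multiplied by its pods-per-inflorescence count; plant values are
#' averaged within population, and population means are averaged to a single
#' regional constant.
#'
#' @param field a data frame as from [simulate_field_fecundity()]: columns
#'   `population`, `plant_id`, `pods_per_inflorescence`, `seeds_per_pod_1`,
#'   `seeds_per_pod_2`, `seeds_per_pod_3`.
#' @return A single number: the regional average seeds per flowering shoot.
#' @export
estimate_seed_constant <- function(field) {
  if (!is.data.frame(field) || nrow(field) == 0L) {
    abort("field fecundity input is empty")
  }
  need <- c("population", "pods_per_inflorescence",
            paste0("seeds_per_pod_", 1:3))
  miss <- setdiff(need, names(field))
  if (length(miss)) abort("field records lack columns: %s",
                          paste(miss, collapse = ", "))
  seeds <- rowMeans(field[, paste0("seeds_per_pod_", 1:3)])
  per_plant <- seeds * field$pods_per_inflorescence
  pop_means <- tapply(per_plant, field$population, mean)
  mean(pop_means)
}

#' Write / read vital-rate parameter sets as YAML
#'
#' @param params a named list of [vital_rate_params] (as from
#'   [fit_vital_rates()] or [canonical_params_all()]).
#' @param path file path.
#' @return `write_params_yaml` returns `path` invisibly; `read_params_yaml`
#'   returns the named list of [vital_rate_params].
#' @export
write_params_yaml <- function(params, path) {
  if (inherits(params, "vital_rate_params")) params <- list(params)
  doc <- lapply(params, function(p) list(
    origin = p$origin, treatment = p$treatment,
    survival = as.list(p$survival), growth = as.list(p$growth),
    flowering = as.list(p$flowering), shoots = as.list(p$shoots),
    recruit_size = as.list(p$recruit_size),
    seeds_per_shoot = p$seeds_per_shoot,
    establishment = p$establishment,
    bank_establishment = p$bank_establishment,
    bank_survival = p$bank_survival
  ))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  out <- lapply(doc, function(d) vital_rate_params(
    survival = unlist(d$survival), growth = unlist(d$growth),
    flowering = unlist(d$flowering), shoots = unlist(d$shoots),
    recruit_size = unlist(d$recruit_size),
    seeds_per_shoot = d$seeds_per_shoot,
    establishment = d$establishment,
    bank_establishment = d$bank_establishment,
    bank_survival = d$bank_survival,
    origin = d$origin, treatment = d$treatment
  ))
  names(out) <- names(doc)
  out
}
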