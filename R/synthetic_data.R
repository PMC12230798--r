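#' Specification for the synthetic greenhouse dataset
#'
#' Describes the generating truth and design of a synthetic greenhouse
#' cohort mirroring the real experiment: 2 origins x 2 soil-inoculum
#' treatments, with 5 source populations per origin, 5 greenhouse blocks and
#' 3 soil-inoculum source sites assigned round-robin. The generating model
#' inverts the fitted-model family: initial size is Normal (the cell's
#' recruit-size moments), survival and flowering are Bernoulli with logistic
#' size dependence, next-year size is Gaussian around the linear growth
#' mean, and shoot counts are Gaussian around the linear shoot mean,
#' truncated at zero.
#'
#' @param params named list of [vital_rate_params], one per cell (default:
#'   all four published sets via [canonical_params_all()]).
#' @param n_per_cell individuals per origin-by-treatment cell (default 55,
#'   the study's cohort size).
#' @param seed integer RNG seed; mandatory so that an identical spec always
#'   yields an identical dataset.
#' @param sigma2_shoots residual variance of the shoot-count model (the
#'   published table prints none; default 1.0).
#' @param population_sd standard deviation of an optional Normal
#'   population-level random intercept added to every linear predictor
#'   (default 0, matching the fixed-effect-only published estimates; used to
#'   stress-test the fitting stage).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(params = canonical_params_all(), n_per_cell = 55L,
                           seed, sigma2_shoots = 1.0, population_sd = 0) {
  if (missing(seed)) abort("an integer RNG seed is required")
  check_finite_scalar(seed, "seed")
  if (!is.list(params) || !length(params) ||
      !all(vapply(params, inherits, TRUE, "vital_rate_params"))) {
    abort("'params' must be a list of vital_rate_params objects")
  }
  check_finite_scalar(n_per_cell, "n_per_cell")
  if (n_per_cell < 1) abort("n_per_cell must be >= 1")
  check_finite_scalar(sigma2_shoots, "sigma2_shoots")
  if (sigma2_shoots <= 0) abort("sigma2_shoots must be > 0")
  check_finite_scalar(population_sd, "population_sd")
  if (population_sd < 0) abort("population_sd must be >= 0")
  structure(list(params = params, n_per_cell = as.integer(n_per_cell),
                 seed = as.integer(seed), sigma2_shoots = sigma2_shoots,
                 population_sd = population_sd),
            class = "generator_spec")
}

#' Simulate a greenhouse demographic cohort
#'
#' Draws one cohort of individual records per parameter set in `spec`.
#' Conditional fields are `NA` where undefined: `size_t1` and `flowered`
#' only exist for survivors, `n_shoots` only for flowering plants.
#'
#' @param spec a [generator_spec()].
#' @return A data frame with columns `origin`, `treatment`,
#'   `inoculum_source`, `population`, `block`, `size_t`, `survived`,
#'   `size_t1`, `flowered`, `n_shoots`.
#' @examples
#' rec <- simulate_greenhouse(generator_spec(seed = 1))
#' table(rec$origin, rec$treatment)
#' @export
simulate_greenhouse <- function(spec) {
  if (!inherits(spec, "generator_spec")) abort("'spec' must be a generator_spec")
  set.seed(spec$seed)
  n <- spec$n_per_cell
  pieces <- lapply(spec$params, function(p) {
    o <- if (is.na(p$origin)) "origin?" else p$origin
    pops <- paste0(o, "_pop", 1:5)
    pop <- rep_len(pops, n)
    pop_eff <- if (spec$population_sd > 0) {
      stats::setNames(stats::rnorm(5, 0, spec$population_sd), pops)[pop]
    } else rep(0, n)

    size_t <- stats::rnorm(n, p$recruit_size[["mean"]],
                           sqrt(p$recruit_size[["var"]])) + pop_eff
    survived <- stats::rbinom(n, 1L,
      inv_logit(p$survival[["intercept"]] + p$survival[["slope"]] * size_t +
                pop_eff))
    size_t1 <- flowered <- n_shoots <- rep(NA_real_, n)
    alive <- survived == 1L
    if (any(alive)) {
      size_t1[alive] <- stats::rnorm(sum(alive),
        p$growth[["intercept"]] + p$growth[["slope"]] * size_t[alive] +
          pop_eff[alive],
        sqrt(p$growth[["sigma2"]]))
      flowered[alive] <- stats::rbinom(sum(alive), 1L,
        inv_logit(p$flowering[["intercept"]] +
                  p$flowering[["slope"]] * size_t[alive] + pop_eff[alive]))
    }
    fl <- !is.na(flowered) & flowered == 1
    if (any(fl)) {
      n_shoots[fl] <- rnorm_trunc_lower(sum(fl),
        p$shoots[["intercept"]] + p$shoots[["slope"]] * size_t[fl] + pop_eff[fl],
        sqrt(spec$sigma2_shoots), lower = 0)
    }
    data.frame(
      origin = o,
      treatment = if (is.na(p$treatment)) "treatment?" else p$treatment,
      inoculum_source = rep_len(paste0("site", 1:3), n),
      population = pop,
      block = rep_len(paste0("block", 1:5), n),
      size_t = size_t, survived = survived, size_t1 = size_t1,
      flowered = as.integer(flowered), n_shoots = n_shoots,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Simulate field fecundity records
#'
#' Emulates the field sampling that closes the life cycle: in each
#' population a fixed number of plants is sampled; for each plant the number
#' of pods on one inflorescence and the seed counts of three pods are
#' recorded. Counts are Poisson (the sampling design prescribes no
#' distribution; Poisson is the standard minimal count model).
#'
#' @param n_populations number of populations.
#' @param n_plants plants sampled per population (default 15, as in the
#'   field survey).
#' @param pod_mean mean pods per inflorescence (> 0).
#' @param seed_mean mean seeds per pod (> 0).
#' @param rng_seed integer RNG seed.
#' @return A data frame with columns `population`, `plant_id`,
#'   `pods_per_inflorescence`, `seeds_per_pod_1..3`.
#' @examples
#' fec <- simulate_field_fecundity(5, pod_mean = 23.2, seed_mean = 3.4,
#'                                 rng_seed = 1)
#' estimate_seed_constant(fec)
#' @export
simulate_field_fecundity <- function(n_populations, n_plants = 15L, pod_mean,
                                     seed_mean, rng_seed) {
  check_finite_scalar(n_populations, "n_populations")
  check_finite_scalar(n_plants, "n_plants")
  check_finite_scalar(pod_mean, "pod_mean")
  check_finite_scalar(seed_mean, "seed_mean")
  check_finite_scalar(rng_seed, "rng_seed")
  if (pod_mean <= 0 || seed_mean <= 0) {
    abort("pod_mean and seed_mean must be > 0")
  }
  set.seed(as.integer(rng_seed))
  n <- as.integer(n_populations) * as.integer(n_plants)
  if (n == 0L) {
    return(data.frame(population = character(), plant_id = character(),
                      pods_per_inflorescence = integer(),
                      seeds_per_pod_1 = integer(), seeds_per_pod_2 = integer(),
                      seeds_per_pod_3 = integer(), stringsAsFactors = FALSE))
  }
  pop <- rep(paste0("pop", seq_len(n_populations)), each = n_plants)
  data.frame(
    population = pop,
    plant_id = paste0(pop, "_plant", rep(seq_len(n_plants), n_populations)),
    pods_per_inflorescence = stats::rpois(n, pod_mean),
    seeds_per_pod_1 = stats::rpois(n, seed_mean),
    seeds_per_pod_2 = stats::rpois(n, seed_mean),
    seeds_per_pod_3 = stats::rpois(n, seed_mean),
    stringsAsFactors = FALSE
  )
}

RECORD_COLS <- c("origin", "treatment", "inoculum_source", "population",
                 "block", "size_t", "survived", "size_t1", "flowered",
                 "n_shoots")

validate_records <- function(records) {
  if (!is.data.frame(records)) abort("records must be a data frame")
  miss <- setdiff(RECORD_COLS[c(1, 2, 6, 7, 8, 9, 10)], names(records))
  if (length(miss)) abort("records lack columns: %s", paste(miss, collapse = ", "))
  if (any(!is.finite(records$size_t))) abort("size_t must be finite")
  dead <- records$survived == 0
  if (any(!is.na(records$size_t1[dead])) || any(!is.na(records$flowered[dead]))) {
    abort("size_t1/flowered must be missing for plants that did not survive")
  }
  nofl <- is.na(records$flowered) | records$flowered == 0
  if (any(!is.na(records$n_shoots[nofl]))) {
    abort("n_shoots must be missing for plants that did not flower")
  }
  if (any(records$n_shoots < 0, na.rm = TRUE)) abort("n_shoots must be >= 0")
  records
}

#' Write / read individual or field records as CSV
#'
#' Plain-CSV serialization with a fixed documented header; conditional
#' fields that are undefined (e.g. next-year size of a dead plant) are
#' written as empty cells and read back as `NA`.
#'
#' @param x data frame of records.
#' @param path file path.
#' @return The writer returns `path` invisibly; readers return the data
#'   frame.
#' @export
write_records_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  if (!file.exists(path)) abort("input file not found: %s", path)
  validate_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname write_records_csv
#' @export
read_field_csv <- function(path) {
  if (!file.exists(path)) abort("input file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a generator spec as YAML
#'
#' @param spec a [generator_spec()].
#' @param path file path.
#' @return `write_generator_spec` returns `path` invisibly;
#'   `read_generator_spec` the reconstructed [generator_spec()].
#' @export
write_generator_spec <- function(spec, path) {
  if (!inherits(spec, "generator_spec")) abort("'spec' must be a generator_spec")
  tmp <- tempfile(fileext = ".yaml")
  write_params_yaml(spec$params, tmp)
  yaml::write_yaml(list(
    seed = spec$seed, n_per_cell = spec$n_per_cell,
    sigma2_shoots = spec$sigma2_shoots, population_sd = spec$population_sd,
    params = yaml::read_yaml(tmp)
  ), path)
  unlink(tmp)
  invisible(path)
}

#' @rdname write_generator_spec
#' @export
read_generator_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$seed)) abort("generator spec file must contain an RNG seed")
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(doc$params, tmp)
  params <- read_params_yaml(tmp)
  unlink(tmp)
  generator_spec(params = params, n_per_cell = doc$n_per_cell,
                 seed = doc$seed, sigma2_shoots = doc$sigma2_shoots,
                 population_sd = doc$population_sd)
}
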