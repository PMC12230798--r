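test_that("canonical parameter sets carry the published estimates", {
  fi_int <- canonical_params("invasive_FI", "intact")
  expect_equal(unname(fi_int$growth), c(4.40, -0.16, 0.22))
  expect_equal(unname(fi_int$flowering), c(7.89, -3.09))
  expect_equal(unname(fi_int$recruit_size), c(2.52, 0.19))
  expect_equal(fi_int$seeds_per_shoot, 79)

  us_auto <- canonical_params("native_US", "autoclaved")
  expect_equal(unname(us_auto$flowering), c(-8.38, 2.45))
  expect_equal(unname(us_auto$recruit_size), c(2.12, 0.26))
  expect_equal(us_auto$seeds_per_shoot, 42)

  for (p in canonical_cells()) {
    expect_equal(unname(p$survival), c(1.13, 1.16))
    expect_equal(unname(p$shoots), c(2.67, -0.49))
    expect_equal(p$establishment, 0.122)
    expect_equal(p$bank_establishment, 0.122)
    expect_equal(p$bank_survival, 0.977)
  }
})

test_that("unknown cells are rejected with the list of valid cells", {
  expect_error(canonical_params("invasive_FI", "mowed"),
               "invasive_FI/native_US.*intact/autoclaved")
  expect_error(canonical_params("france", "intact"), "unknown cell")
})

test_that("parameter validation enforces the domain invariants", {
  expect_error(toy_params(growth = c(2, 0.4, -1)), "sigma2 must be > 0")
  expect_error(toy_params(recruit_size = c(2, 0)), "var must be > 0")
  expect_error(toy_params(seeds_per_shoot = -5), ">= 0")
  expect_error(vital_rate_params(survival = c(1, 1), growth = c(1, 1, 1),
                                 flowering = c(1, 1), shoots = c(1, 1),
                                 recruit_size = c(2, 1), seeds_per_shoot = 10,
                                 establishment = 1.5), "\\[0, 1\\]")
})

test_that("growth OLS equals the closed-form normal-equations solution", {
  x <- c(1.2, 1.9, 2.4, 2.8, 3.3, 3.9, 4.1)
  y <- c(2.1, 2.6, 3.4, 3.2, 4.4, 4.6, 5.2)
  rec <- data.frame(origin = "invasive_FI", treatment = "intact",
                    inoculum_source = "site1", population = "p1", block = "b1",
                    size_t = x, survived = 1L, size_t1 = y,
                    flowered = c(1L, 1L, 0L, 1L, 0L, 1L, 1L),
                    n_shoots = NA_real_)
  rec$n_shoots[rec$flowered == 1] <- 1 + x[rec$flowered == 1]
  # survival is degenerate (all 1) here, so the fit must flag separation
  expect_error(fit_vital_rates(rec, pool_survival_and_shoots = FALSE,
                               seeds_per_shoot = c(invasive_FI = 79)),
               "separation")

  rec$survived <- c(1L, 1L, 1L, 1L, 1L, 0L, 1L)
  rec$size_t1[rec$survived == 0] <- NA
  rec$flowered[rec$survived == 0] <- NA
  rec$n_shoots[rec$survived == 0] <- NA
  fit <- fit_vital_rates(rec, pool_survival_and_shoots = FALSE,
                         seeds_per_shoot = c(invasive_FI = 79))[[1]]
  keep <- rec$survived == 1
  X <- cbind(1, x[keep])
  beta <- solve(t(X) %*% X, t(X) %*% y[keep]) # normal equations by hand
  expect_equal(unname(fit$growth[["intercept"]]), beta[1], tolerance = 1e-10)
  expect_equal(unname(fit$growth[["slope"]]), beta[2], tolerance = 1e-10)
  resid <- y[keep] - X %*% beta
  expect_equal(unname(fit$growth[["sigma2"]]),
               sum(resid^2) / (sum(keep) - 2), tolerance = 1e-10)
})

test_that("a noiseless linear growth relation is recovered exactly", {
  n <- 20
  x <- seq(1, 4, length.out = n)
  rec <- data.frame(origin = "native_US", treatment = "intact",
                    inoculum_source = "site1", population = "p1", block = "b1",
                    size_t = x, survived = rep(c(1L, 0L), 10),
                    size_t1 = NA_real_, flowered = NA_integer_,
                    n_shoots = NA_real_)
  rec$size_t1[rec$survived == 1] <- 2 * x[rec$survived == 1]
  rec$flowered[rec$survived == 1] <- rep(c(0L, 1L), 5)
  rec$n_shoots[rec$flowered == 1 & !is.na(rec$flowered)] <- 2
  fit <- fit_vital_rates(rec, pool_survival_and_shoots = FALSE,
                         seeds_per_shoot = c(native_US = 42))[[1]]
  expect_equal(unname(fit$growth), c(0, 2, 0), tolerance = 1e-12)
})

test_that("degenerate binary outcomes raise the separation error by rate", {
  rec <- simulate_greenhouse(generator_spec(seed = 21L))
  rec$survived <- 1L
  rec$size_t1[is.na(rec$size_t1)] <- mean(rec$size_t1, na.rm = TRUE)
  rec$flowered[is.na(rec$flowered)] <- 0L
  expect_error(fit_vital_rates(rec), "survival")
})

test_that("pooling copies bit-identical survival and shoot coefficients", {
  # a cohort large enough that every cell sees both survival outcomes
  rec <- simulate_greenhouse(generator_spec(seed = 22L, n_per_cell = 300L))
  fits <- fit_vital_rates(rec)
  expect_length(fits, 4)
  s <- lapply(fits, `[[`, "survival")
  f1 <- lapply(fits, `[[`, "shoots")
  for (k in 2:4) {
    expect_identical(s[[k]], s[[1]])
    expect_identical(f1[[k]], f1[[1]])
  }
  # unpooled fits differ across cells
  unpooled <- fit_vital_rates(rec, pool_survival_and_shoots = FALSE)
  expect_false(identical(unpooled[[1]]$shoots, unpooled[[2]]$shoots))
})

test_that("fitting on large simulated cohorts recovers the flowering truth", {
  p <- canonical_params("invasive_FI", "intact")
  rec <- simulate_greenhouse(generator_spec(params = list(p), seed = 23L,
                                            n_per_cell = 10000L))
  fit <- fit_vital_rates(rec, pool_survival_and_shoots = FALSE,
                         seeds_per_shoot = c(invasive_FI = 79))[[1]]
  se <- attr(fit, "se")$flowering
  expect_lt(abs(fit$flowering[["intercept"]] - 7.89), 3 * se[1])
  expect_lt(abs(fit$flowering[["slope"]] - (-3.09)), 3 * se[2])
})

test_that("seed constant aggregates pods and seeds per pod hierarchically", {
  one <- data.frame(population = "p1", plant_id = "a",
                    pods_per_inflorescence = 10, seeds_per_pod_1 = 4,
                    seeds_per_pod_2 = 4, seeds_per_pod_3 = 4)
  expect_equal(estimate_seed_constant(one), 40)

  two <- data.frame(population = c("p1", "p2"), plant_id = c("a", "b"),
                    pods_per_inflorescence = c(10, 10),
                    seeds_per_pod_1 = c(3, 5), seeds_per_pod_2 = c(3, 5),
                    seeds_per_pod_3 = c(3, 5))
  expect_equal(estimate_seed_constant(two), 40) # (30 + 50) / 2

  # population means, then the mean of populations: unbalanced plants count
  # once per population, not once per plant
  three <- data.frame(population = c("p1", "p1", "p2"),
                      plant_id = c("a", "b", "c"),
                      pods_per_inflorescence = c(10, 20, 10),
                      seeds_per_pod_1 = c(2, 2, 6), seeds_per_pod_2 = c(2, 2, 6),
                      seeds_per_pod_3 = c(2, 2, 6))
  expect_equal(estimate_seed_constant(three), (30 + 60) / 2)
  expect_error(estimate_seed_constant(data.frame()), "empty")
})

test_that("simulated field data calibrated to the invasive region lands near 79", {
  fec <- simulate_field_fecundity(5, n_plants = 15, pod_mean = 23.2,
                                  seed_mean = 79 / 23.2, rng_seed = 31L)
  expect_lt(abs(estimate_seed_constant(fec) - 79) / 79, 0.15)
})

test_that("vital-rate parameter YAML round trip is lossless", {
  params <- canonical_cells()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_params_yaml(params, path)
  back <- read_params_yaml(path)
  expect_equal(back, params, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(names(back), names(params))
})
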