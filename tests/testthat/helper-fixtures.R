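# Shared fixtures and independent oracles for the test suite.

# A deliberately plain parameter set for structural tests.
toy_params <- function(...) {
  defaults <- list(
    survival = c(1.13, 1.16),
    growth = c(2.5, 0.4, 0.2),
    flowering = c(0.3, -1.0),
    shoots = c(2.67, -0.49),
    recruit_size = c(2.4, 0.2),
    seeds_per_shoot = 50,
    origin = "invasive_FI", treatment = "intact"
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(vital_rate_params, args)
}

canonical_cells <- function() canonical_params_all()

# Characteristic polynomial by the Faddeev-LeVerrier recursion: an eigenvalue
# oracle independent of both power iteration and LAPACK's eigen().
charpoly_coefs <- function(A) {
  n <- nrow(A)
  coefs <- numeric(n + 1)
  coefs[1] <- 1 # lambda^n
  M <- diag(n)
  for (k in seq_len(n)) {
    M <- A %*% M
    c_k <- -sum(diag(M)) / k
    coefs[k + 1] <- c_k
    M <- M + diag(c_k, n)
  }
  coefs
}

dominant_root <- function(A) {
  roots <- polyroot(rev(charpoly_coefs(A)))
  max(Re(roots[abs(Im(roots)) < 1e-6 * max(1, Mod(roots))]))
}

# Truncated-at-zero draw used to cross-check the generator's shoot counts.
expect_no_na <- function(x) expect_false(anyNA(x))
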