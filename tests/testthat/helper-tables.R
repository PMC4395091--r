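# Build a condition table whose fractions are a model family's exact
# probabilities over all (n_A, n_B) with n_A + n_B in `sums`.
noiseless_table <- function(family, params, sums = 0:9, R = 1L) {
  cond <- expand.grid(n_A = 0:max(sums), n_B = 0:max(sums))
  cond <- cond[(cond$n_A + cond$n_B) %in% sums, , drop = FALSE]
  fraction <- model_probability(family, params, cond$n_A, cond$n_B)
  data.frame(cond, R = R, N_A = NA_integer_, fraction = fraction,
             row.names = NULL)
}

# A stochastic synthetic condition table: binomial counts around a randomly
# parameterised belief model (used for nesting-inequality checks).
random_table <- function(max_sum = 6) {
  cond <- expand.grid(n_A = 0:max_sum, n_B = 0:max_sum)
  cond <- cond[cond$n_A + cond$n_B <= max_sum, , drop = FALSE]
  p <- exp(runif(1, log(0.2), log(5)))
  s <- runif(1, 0.3, 1)
  R <- sample(5:50, nrow(cond), replace = TRUE)
  N_A <- rbinom(nrow(cond), R, belief_from_counts(p, s, cond$n_A, cond$n_B))
  data.frame(cond, R = R, N_A = N_A, fraction = N_A / R, row.names = NULL)
}

# Coarser M6 grid for tests that fit many small tables.
coarse_m6_grid <- function() {
  list(p = grid_spec(0.05, 20, 61, "log"), s = grid_spec(0.02, 1, 50))
}
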