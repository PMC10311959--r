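# shared fixtures: all built in code at test time

# tiny response matrix; 9 denotes MISSING in the human-readable spec rows
rm_from_rows <- function(...) {
  rows <- list(...)
  vals <- do.call(rbind, lapply(rows, function(r) {
    r[r == 9] <- NA_integer_
    as.integer(r)
  }))
  response_matrix(vals)
}

# write a delimited response file and return its path
write_resp_file <- function(text, file = tempfile(fileext = ".csv")) {
  writeLines(text, file)
  file
}

# a small but non-trivial simulated dataset shared by several tests
small_dataset <- function(N = 120, K = 8, seed = 11, ...) {
  generate_dataset(simulation_scenario(N = N, K = K, seed = seed, ...))
}

fast_cfg <- function(seed = 5, n_chains = 2L, n_adapt = 80L, n_burnin = 80L,
                     n_posterior_total = 240L) {
  mcmc_config(n_chains = n_chains, n_adapt = n_adapt, n_burnin = n_burnin,
              n_posterior_total = n_posterior_total, seed = seed,
              escalate = FALSE)
}

# exhaustive distribution of the sequential stopping count for K <= 3
# given per-item continuation probabilities p (independent oracle)
enumerate_stopping <- function(p) {
  K <- length(p)
  mass <- numeric(K + 1L)
  for (a in 0:K) {
    m <- if (a > 0) prod(p[seq_len(a)]) else 1
    if (a < K) m <- m * (1 - p[a + 1L])
    mass[a + 1L] <- m
  }
  mass
}
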