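# Independent oracles: plain term-by-term summation with no log-space
# tricks, no adaptive truncation, and no shared code with the package
# internals.  Valid wherever the terms stay inside double range.

# terms via the exact ratio recursion w_{k+1}/w_k = ((k+1)/k) C_s e^{-k e_r},
# which never forms the overflowing intermediates C_s^k and e^{-k(k-1)e_r/2}
oracle_terms <- function(C_s, e_r, K = 2000L) {
  w <- numeric(K)
  w[1] <- C_s
  for (k in seq_len(K - 1L)) {
    w[k + 1L] <- w[k] * ((k + 1) / k) * C_s * exp(-k * e_r)
  }
  w
}

oracle_adsorption <- function(C_s, e_r, K = 2000L) {
  sum(oracle_terms(C_s, e_r, K))
}

oracle_mean_size <- function(C_s, e_r, K = 2000L) {
  w <- oracle_terms(C_s, e_r, K)
  sum(w) / sum(w / seq_len(K))
}

oracle_step_energy <- function(k, e_r0, k_max) {
  ifelse(k <= k_max,
         k * (k - 1) * e_r0 / 2,
         (k_max * (k_max - 1) + (k - k_max) * (k_max - 1)) * e_r0 / 2)
}

oracle_step_sum <- function(C_s, e_r0, k_max, K_cap) {
  k <- seq_len(K_cap)
  sum(k * exp(-oracle_step_energy(k, e_r0, k_max)) * C_s^k)
}

# deterministic small synthetic radius profile for fitting tests
make_radius_profile <- function(kind = "tension", c1 = 0.7, c2 = 0.61,
                                A = 2, Cs = 1, noise_cv = 0, seed = 1) {
  generate_dataset(generator_spec(
    law = repulsion_law(kind, c1 = c1, c2 = c2),
    A = A, c_0 = 1, concentrations = Cs,
    noise_cv = noise_cv, seed = seed))
}
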