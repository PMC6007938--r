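# Shared helpers and independent oracles for the test suite.

# Analytic pmf of the per-cell burden after n divisions: the number of
# divisions that kept the ancestral strand is k ~ Binomial(n, p); each of the
# other n - k divisions contributed an independent Poisson(muL) increment, so
# burden | k ~ Poisson((n - k) * muL). This closed form is evaluated by direct
# summation over k, independently of the simulator's step kernels.
burden_pmf_oracle <- function(x, n, p, muL) {
  vapply(x, function(xi) {
    sum(vapply(0:n, function(k) {
      stats::dbinom(k, n, p) * stats::dpois(xi, (n - k) * muL)
    }, numeric(1)))
  }, numeric(1))
}

# Standard error of a sample variance without a normality assumption
# (delta-method on the fourth central moment).
se_of_sample_var <- function(x) {
  n <- length(x)
  m <- mean(x)
  m4 <- mean((x - m)^4)
  s2 <- stats::var(x)
  sqrt((m4 - s2^2 * (n - 3) / (n - 1)) / n)
}

quick_params <- function(p_seg = 0.7, mu_L = 6, n_cells = 1000, ...) {
  model_params(n_cells = n_cells, p_seg = p_seg, mu_L = mu_L, ...)
}

# Repeatedly run the asymmetric kernel on a single-cell population for
# n_divisions rounds and return the replicate burdens.
replicate_single_cell <- function(n_reps, n_divisions, params, seed) {
  set.seed(seed)
  out <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    st <- new_population(1L)
    for (d in seq_len(n_divisions)) st <- step_asymmetric(st, params)
    out[r] <- st$burdens
  }
  out
}
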