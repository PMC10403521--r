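# Shared fixtures. Everything is generated in code at a fixed seed; the
# moderate-size null cohort is cached per session because several files use
# it.

small_sim <- function(seed = 11, ...) {
  simulate_cohort(sim_config(n_studies = 2, n_cases = 120, n_controls = 120,
                             n_variants = 5, seed = seed, ...))
}

null_sim_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(sim_config(
        n_studies = 2, n_cases = 400, n_controls = 400, n_variants = 40,
        beta_g = 0, beta_gxe = 0, gamma_ge = 0, seed = 2024))
    }
    cache
  }
})

# 12-subject worked dataset used against brute-force likelihood oracles
toy12 <- function() {
  data.frame(
    y = c(0, 0, 1, 0, 1, 1, 0, 1, 0, 1, 1, 0),
    g = c(0, 1, 2, 0, 1, 2, 1, 0, 2, 1, 0, 1),
    e = c(0, 0, 0, 1, 1, 1, 0, 1, 0, 1, 0, 1))
}

# Dense grid maximization of the Bernoulli-logit likelihood, the
# independent oracle for the IRLS fitter (intercept + one slope).
grid_logit_2par <- function(x, y, lim = 4, step = 0.001) {
  b0 <- seq(-lim, lim, by = step)
  b1 <- seq(-lim, lim, by = step)
  best <- c(NA, NA); best_ll <- -Inf
  for (b in b1) {
    eta <- outer(b0, b * x, "+")       # grid of intercepts x subjects
    ll <- drop(eta %*% y) - rowSums(log1p(exp(eta)))
    i <- which.max(ll)
    if (ll[i] > best_ll) { best_ll <- ll[i]; best <- c(b0[i], b) }
  }
  list(coef = best, ll = best_ll)
}
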