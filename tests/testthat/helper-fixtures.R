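# Shared fixtures, built in code. Simulations are memoized so different
# test files can reuse the same table without re-generating it.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# Mid-size model-conforming experiment at the default true parameters
# (s_fac = 1.2, s_add = 0.01 + 0.15 exp(-2 cc)), normal noise.
sim_default <- function() cached("default", {
  simulate_experiment(sim_config(n_miller = 4000, multiplicity_mean = 6,
                                 n_lattices = 300, seed = 7001))
})

# Constant additional error (Ev11 generative model: s_add_1 = 0).
sim_constant_sadd <- function() cached("constant_sadd", {
  simulate_experiment(sim_config(n_miller = 9000, multiplicity_mean = 6,
                                 n_lattices = 300, s_fac = 1.3,
                                 s_add_0 = 0.08, s_add_1 = 0, s_add_2 = 0,
                                 seed = 7002))
})

# A tiny deterministic table written by hand: 3 Miller groups, 2 lattices.
toy_table <- function() {
  obs <- data.frame(
    h = c(1, 1, 1, 2, 2, 3),
    k = c(2, 2, 2, 0, 0, 1),
    l = c(3, 3, 3, 0, 0, 1),
    lattice_id = c("a", "b", "a", "a", "b", "b"),
    intensity = c(10, 12, 11, 5, 6, 2.5),
    sigma = c(1, 1.2, 0.9, 0.7, 0.8, 0.5)
  )
  lat <- data.frame(lattice_id = c("a", "b"), cc = c(0.9, 0.6))
  refl_table(obs, lat)
}

# One Miller group with n observations; sigma chosen so that the
# identity-parameter sigma' equals `sigma_prime`.
one_group_table <- function(intensities, sigma_prime = 1, cc = 0.8,
                            hkl = c(1, 2, 3)) {
  n <- length(intensities)
  obs <- data.frame(h = hkl[1], k = hkl[2], l = hkl[3],
                    lattice_id = sprintf("L%02d", seq_len(n)),
                    intensity = intensities,
                    sigma = rep(sigma_prime, n))
  lat <- data.frame(lattice_id = sprintf("L%02d", seq_len(n)), cc = cc)
  refl_table(obs, lat)
}

# Central finite differences for gradient checks.
numeric_gradient <- function(f, x, h_rel = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- h_rel * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}
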