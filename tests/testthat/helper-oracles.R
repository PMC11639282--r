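# Shared fixtures and independent oracles for the test suite.

# random positive rate sets, log-uniform over four decades
random_rates <- function(n, seed = 1, lo = 0.01, hi = 100) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i)
      as_rate_constants(10^stats::runif(6, log10(lo), log10(hi))))
  })
}

# independent oracle: adaptive stiff ODE integration of dp/dt = G p
ode_propagate <- function(p0, G, times) {
  f <- function(t, y, parms) list(as.vector(G %*% y))
  out <- deSolve::lsoda(y = p0, times = c(0, times), func = f,
                        rtol = 1e-11, atol = 1e-13)
  t(out[-1, -1, drop = FALSE])  # 8 x length(times)
}

# independent oracle: single-conformation yields by enumerating the two
# independent sites, each relaxing as p18(t) = a_in + (a_f - a_in)(1 - e^-kt)
two_site_enumeration <- function(times, k_f, k_s, alpha_in, alpha_f) {
  pf <- alpha_in + (alpha_f - alpha_in) * (1 - exp(-k_f * times))
  ps <- alpha_in + (alpha_f - alpha_in) * (1 - exp(-k_s * times))
  one <- pf * (1 - ps) + ps * (1 - pf)
  both <- pf * ps
  data.frame(time_s = times,
             y34 = one / (2 * alpha_f * (1 - alpha_f)),
             y36 = both / alpha_f^2)
}

# a single-conformation rate set: all mass stays in LS
single_conf_rates <- function(k_f, k_s) {
  rate_constants(k_f1 = k_f, k_f2 = 0, k_s1 = k_s, k_s2 = 0,
                 k_c1 = 0, k_c2 = 0)
}

no_corrections <- function() {
  list(mixing = mixing_spec(mode = "instant"), s3 = s3_spec(enabled = FALSE))
}
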