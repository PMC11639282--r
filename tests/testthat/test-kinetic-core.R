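test_that("rate and enrichment constructors validate their inputs", {
  expect_error(rate_constants(-1, 1, 1, 1, 1, 1), "non-negative")
  expect_error(rate_constants(Inf, 1, 1, 1, 1, 1), "finite")
  expect_error(enrichment_spec(alpha_in = 0.5, alpha_f = 0.25), "exceed")
  expect_error(enrichment_spec(alpha_f = 1), "\\(0, 1\\)")
  r <- as_rate_constants(c(k_c2 = 6, k_c1 = 5, k_s2 = 4, k_s1 = 3,
                           k_f2 = 2, k_f1 = 1))
  expect_equal(unname(r[["k_f1"]]), 1)  # named coercion reorders
  expect_equal(unname(r[["k_c2"]]), 6)
})

test_that("generator has conservation structure and no double transitions", {
  expect_true(all(exchange_generator(rate_constants(0, 0, 0, 0, 0, 0), 0.3) == 0))
  for (r in random_rates(5, seed = 11)) {
    G <- exchange_generator(r, 0.25)
    expect_lt(max(abs(colSums(G))), 1e-12)
    offdiag <- G - diag(diag(G))
    expect_true(all(offdiag >= 0))
    # transitions change exactly one coordinate of (conf, slow, fast)
    coords <- expand.grid(f = 0:1, s = 0:1, conf = 0:1)
    for (i in 1:8) for (j in 1:8) {
      nd <- sum(coords[i, ] != coords[j, ])
      if (nd > 1L) expect_identical(G[j, i], 0)
    }
  }
})

test_that("generator spectrum contains the closed-form slow pair", {
  r <- rate_constants(k_f1 = 120, k_f2 = 65, k_s1 = 1.0, k_s2 = 50,
                      k_c1 = 3.6, k_c2 = 12)
  lam <- Re(eigen(exchange_generator(r, 0.25), only.values = TRUE)$values)
  expect_true(any(abs(lam - (-11.96)) < 0.005))
  expect_true(any(abs(lam - (-54.64)) < 0.005))
})

test_that("equilibrium initial state follows the conformational balance", {
  r <- rate_constants(1, 1, 1, 1, k_c1 = 2, k_c2 = 2)
  s <- equilibrium_state(r, alpha_in = 0)
  expect_equal(unname(s[1]), 0.5)            # LS(16,16)
  expect_equal(unname(s[5]), 0.5)            # HS(16,16)
  expect_equal(sum(s[c(2:4, 6:8)]), 0)

  r2 <- rate_constants(120, 65, 1, 50, k_c1 = 3.6, k_c2 = 12)
  s2 <- equilibrium_state(r2, alpha_in = 0)
  expect_equal(sum(s2[5:8]), 12 / 15.6, tolerance = 1e-12)

  s3 <- equilibrium_state(r2, alpha_in = 0.007)
  # each site labelled independently
  expect_equal(sum(s3[c(4, 8)]), 0.007^2, tolerance = 1e-15)
  expect_equal(sum(s3[c(2, 3, 6, 7)]), 2 * 0.007 * 0.993, tolerance = 1e-15)

  r0 <- rate_constants(1, 1, 1, 1, 0, 0)
  expect_error(equilibrium_state(r0, 0), "hs_fraction")
  s4 <- equilibrium_state(r0, 0, hs_fraction = 0.25)
  expect_equal(sum(s4[5:8]), 0.25)
})

test_that("propagation conserves probability and reaches the stationary law", {
  r <- random_rates(1, seed = 5)[[1]]
  G <- exchange_generator(r, 0.3)
  s0 <- equilibrium_state(r, 0)

  expect_identical(propagate(s0, G, 0), s0)

  for (dt in c(1e-3, 0.1, 2)) {
    s <- propagate(s0, G, dt)
    expect_lt(abs(sum(s) - 1), 1e-12)
    expect_true(all(s >= -1e-14))
  }

  # ergodic limit: conformations at k_c2/(k_c1+k_c2), sites labelled at alpha
  s_inf <- propagate(s0, G, 50 / min(r[r > 0]))
  hs <- r[["k_c2"]] / (r[["k_c1"]] + r[["k_c2"]])
  expect_equal(sum(s_inf[5:8]), hs, tolerance = 1e-9)
  p18_slow <- sum(s_inf[c(3, 4, 7, 8)])
  expect_equal(p18_slow, 0.3, tolerance = 1e-9)

  # propagating the stationary distribution changes nothing
  s_again <- propagate(s_inf, G, 1)
  expect_lt(max(abs(as.vector(s_again) - as.vector(s_inf))), 1e-10)
})

test_that("single-site marginal matches the scalar relaxation law", {
  # one conformation, slow site exchanging at k_s1: P(slow = 18O at t)
  # must follow alpha (1 - exp(-k t)), the per-site relaxation solution
  k <- 0.7
  r <- single_conf_rates(k_f = 3, k_s = k)
  G <- exchange_generator(r, 0.25)
  s0 <- equilibrium_state(r, 0, hs_fraction = 0)
  for (t in c(0.1, 1, 5)) {
    s <- propagate(s0, G, t)
    expect_equal(sum(s[c(3, 4)]), 0.25 * (1 - exp(-k * t)), tolerance = 1e-10)
  }
})

test_that("matrix-exponential propagation agrees with the ODE oracle", {
  skip_if_not_installed("deSolve")
  times <- 10^seq(-2, 1.5, length.out = 10)
  for (r in random_rates(20, seed = 42)) {
    G <- exchange_generator(r, 0.25)
    p0 <- as.vector(equilibrium_state(r, 0.007))
    P_exp <- wexchange:::propagate_times(p0, G, times)
    P_ode <- ode_propagate(p0, G, times)
    expect_lt(max(abs(P_exp - P_ode)), 1e-8)
  }
})

test_that("yields normalise to the plateau and reduce to the product form", {
  enr <- enrichment_spec(0, 0.25)
  r <- random_rates(1, seed = 9)[[1]]
  # fully equilibrated state at alpha_f
  G <- exchange_generator(r, 0.25)
  s_inf <- propagate(equilibrium_state(r, 0), G, 200 / min(r[r > 0]))
  y <- state_yields(s_inf, enr)
  expect_equal(unname(y), c(1, 1), tolerance = 1e-8)

  s16 <- equilibrium_state(r, 0)
  expect_equal(unname(state_yields(s16, enr)), c(0, 0))
  expect_error(state_yields(s16, structure(list(alpha_f = 0),
                                           class = "enrichment_spec")))

  # single conformation, alpha_in = 0: the closed-form product/cross formulas,
  # cross-checked against independent two-site enumeration
  kf <- 40; ks <- 0.9
  rc <- single_conf_rates(kf, ks)
  Gc <- exchange_generator(rc, 0.25)
  s0 <- equilibrium_state(rc, 0, hs_fraction = 0)
  tt <- c(0.01, 0.05, 0.3, 1, 4)
  oracle <- two_site_enumeration(tt, kf, ks, 0, 0.25)
  for (i in seq_along(tt)) {
    y <- state_yields(propagate(s0, Gc, tt[i]), enr)
    expect_equal(unname(y[["y36"]]),
                 (1 - exp(-kf * tt[i])) * (1 - exp(-ks * tt[i])),
                 tolerance = 1e-10)
    expect_equal(unname(y[["y34"]]), oracle$y34[i], tolerance = 1e-10)
    expect_equal(unname(y[["y36"]]), oracle$y36[i], tolerance = 1e-10)
  }
})
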