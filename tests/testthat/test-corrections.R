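test_that("single-site solutions obey limits, continuity and the shift identity", {
  enr <- enrichment_spec(0.007, 0.25)
  expect_equal(single_site_instant(0, 3, enr), 0.007)
  expect_equal(single_site_instant(1e6, 3, enr), 0.25)
  t0 <- 0.4; k <- log(2) / t0
  expect_equal(single_site_instant(t0, k, enr), 0.007 + (0.25 - 0.007) / 2)

  t_m <- 0.006
  expect_equal(single_site_linear(0, 5, enr, t_m), 0.007)
  # the two branch formulas agree exactly at t = t_m
  k <- 50
  ramp_at_tm <- 0.007 + (0.25 - 0.007) * (exp(-k * t_m) - 1 + k * t_m) / (k * t_m)
  expect_lt(abs(ramp_at_tm -
                single_site_instant(t_m - t_shift(k, t_m), k, enr)), 1e-12)

  # linear-mixing solution is the time-shifted instant solution for t >= t_m
  withr::with_seed(8, {
    for (i in 1:20) {
      k <- 10^stats::runif(1, -2, 3)
      e <- enrichment_spec(stats::runif(1, 0, 0.02), stats::runif(1, 0.1, 0.9))
      tt <- t_m + 10^stats::runif(5, -3, 1)
      tk <- t_shift(k, t_m)
      expect_lt(max(abs(single_site_linear(tt, k, e, t_m) -
                        single_site_instant(tt - tk, k, e))), 1e-12)
    }
  })
})

test_that("mixing time shift has the right limits, bounds and monotonicity", {
  t_m <- 0.006
  expect_equal(t_shift(0, t_m), 0.003)
  expect_equal(t_shift(1e-9, t_m), 0.003, tolerance = 1e-9)
  expect_equal(t_shift(250, t_m), 0.0033682, tolerance = 1e-4)
  expect_equal(t_shift(200, t_m), 0.0032965, tolerance = 1e-4)
  # the shift stays at ~3 ms through the resolvable range and only passes
  # 3.3 ms for rates beyond ~200/s
  expect_lt(t_shift(200, t_m), 0.0033)
  expect_gt(t_shift(250, t_m), 0.0033)

  kk <- 10^seq(-3, 4, length.out = 200)
  tk <- t_shift(kk, t_m)
  expect_true(all(diff(tk) > 0))
  expect_true(all(tk > t_m / 2 & tk < t_m))
})

test_that("S3 carryover propagates under the S3 rates and acts as identity when off", {
  r <- wex_preset("sr_pH8.3_hb")
  enr <- enrichment_spec(0.007, 0.25)
  G <- exchange_generator(r, enr$alpha_f)
  mid <- propagate(equilibrium_state(r, enr$alpha_in), G, 0.05)

  expect_identical(apply_s3_carryover(mid, s3_spec(enabled = FALSE), r, enr), mid)
  expect_identical(apply_s3_carryover(mid, s3_spec(duration = 0), r, enr), mid)
  expect_identical(apply_s3_carryover(mid, s3_spec(k_f = 0, k_s = 0), r, enr),
                   mid)

  out <- apply_s3_carryover(mid, s3_spec(), r, enr)
  y_mid <- state_yields(mid, enr)
  y_out <- state_yields(out, enr)
  expect_gt(y_out[["y34"]], y_mid[["y34"]])
  expect_gt(y_out[["y36"]], y_mid[["y36"]])
})

test_that("S3 carryover is equivalent to a small shift to earlier times", {
  r <- wex_preset("sr_pH8.3_hb")
  tt <- 10^seq(log10(0.01), 1, length.out = 40)
  off <- simulate_exchange(r, tt, enrichment_spec(0.007, 0.25),
                           mixing_spec(mode = "instant"),
                           s3_spec(enabled = FALSE))
  on <- simulate_exchange(r, tt, enrichment_spec(0.007, 0.25),
                          mixing_spec(mode = "instant"), s3_spec())
  # curves move up (earlier apparent times) ...
  expect_true(all(on$y34 >= off$y34 - 1e-12))
  expect_true(all(on$y36 >= off$y36 - 1e-12))
  # ... and a single time advance reproduces the corrected curve within 5%
  shifted_diff <- function(d) {
    s <- simulate_exchange(r, tt + d, enrichment_spec(0.007, 0.25),
                           mixing_spec(mode = "instant"),
                           s3_spec(enabled = FALSE))
    max(abs(s$y34 - on$y34), abs(s$y36 - on$y36))
  }
  best <- stats::optimize(shifted_diff, c(0, 0.05))
  expect_lt(best$objective, 0.05)
})

test_that("corrected simulation reduces to the closed form and shifts as expected", {
  # all corrections off, single conformation, alpha_in = 0
  kf <- 30; ks <- 0.8
  rc <- single_conf_rates(kf, ks)
  tt <- 10^seq(-2, 1.5, length.out = 20)
  yc <- simulate_exchange(rc, tt, enrichment_spec(0, 0.25),
                          mixing_spec(mode = "instant"),
                          s3_spec(enabled = FALSE), hs_fraction = 0)
  oracle <- two_site_enumeration(tt, kf, ks, 0, 0.25)
  expect_equal(yc$y34, oracle$y34, tolerance = 1e-10)
  expect_equal(yc$y36, oracle$y36, tolerance = 1e-10)

  r <- wex_preset("sr_pH8.3_hb")
  base <- simulate_exchange(r, tt, enrichment_spec(0, 0.25),
                            mixing_spec(mode = "instant"),
                            s3_spec(enabled = FALSE))
  enr_only <- simulate_exchange(r, tt, enrichment_spec(0.007, 0.25),
                                mixing_spec(mode = "instant"),
                                s3_spec(enabled = FALSE))
  mix_only <- simulate_exchange(r, tt, enrichment_spec(0, 0.25),
                                mixing_spec(), s3_spec(enabled = FALSE))
  # enrichment correction raises yields (earlier apparent exchange), the
  # injection shift lowers them (later apparent exchange)
  expect_true(all(enr_only$y34 >= base$y34 - 1e-12))
  expect_true(all(enr_only$y36 >= base$y36 - 1e-12))
  expect_true(all(mix_only$y34 <= base$y34 + 1e-12))
  expect_true(all(mix_only$y36 <= base$y36 + 1e-12))
})

test_that("the three corrections mostly cancel in combination", {
  tt <- 10^seq(-2, 2, length.out = 50)
  for (name in c("ca_pH8.6_hb", "sr_pH6.0_tw", "sr_pH8.3_hb")) {
    r <- wex_preset(name)
    base <- simulate_exchange(r, tt, enrichment_spec(0, 0.25),
                              mixing_spec(mode = "instant"),
                              s3_spec(enabled = FALSE))
    single_effects <- vapply(list(
      simulate_exchange(r, tt, enrichment_spec(0.007, 0.25),
                        mixing_spec(mode = "instant"), s3_spec(enabled = FALSE)),
      simulate_exchange(r, tt, enrichment_spec(0, 0.25),
                        mixing_spec(), s3_spec(enabled = FALSE)),
      simulate_exchange(r, tt, enrichment_spec(0, 0.25),
                        mixing_spec(mode = "instant"), s3_spec())),
      function(s) max(abs(s$y34 - base$y34), abs(s$y36 - base$y36)),
      numeric(1))
    all3 <- simulate_exchange(r, tt, enrichment_spec(0.007, 0.25),
                              mixing_spec(), s3_spec())
    combined <- max(abs(all3$y34 - base$y34), abs(all3$y36 - base$y36))
    expect_lt(combined, max(single_effects))
  }
})
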