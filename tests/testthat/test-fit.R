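sr60 <- function() wex_preset("sr_pH6.0_tw")
sr60_fixed <- c(k_f1 = 120, k_f2 = 75, k_s1 = 0.01)

test_that("noiseless data are refit exactly", {
  d <- wex_synth(sr60(), n_points = 24, noise_sd = 0, seed = 1)
  fit <- wex_fit(d, "full", fixed = sr60_fixed, n_starts = 4, seed = 1)
  expect_lt(fit$chi2, 1e-12)
  truth <- sr60()[fit$free]
  expect_equal(unname(coef(fit)[fit$free]), unname(truth), tolerance = 1e-6)
})

test_that("the chi2 objective is invariant under data reordering", {
  d <- wex_synth(sr60(), n_points = 16, noise_sd = 0.02, seed = 5)
  fit <- wex_fit(d, "full", fixed = sr60_fixed, n_starts = 2, seed = 1)
  # reversing then re-sorting the rows must change nothing
  d2 <- d[rev(seq_len(nrow(d))), ]
  d2 <- d2[order(d2$time_s), ]
  rownames(d2) <- NULL
  fit2 <- wex_fit(d2, "full", fixed = sr60_fixed, n_starts = 2, seed = 1)
  expect_equal(fit$chi2, fit2$chi2, tolerance = 1e-10)
  expect_equal(coef(fit), coef(fit2), tolerance = 1e-8)
})

test_that("fitting validates dataset shape and degrees of freedom", {
  d <- wex_synth(sr60(), n_points = 10, seed = 1)
  expect_error(wex_fit(d[, c("time_s", "y34")], "full"), "y36")
  d_bad <- d; d_bad$time_s <- rev(d_bad$time_s)
  expect_error(wex_fit(d_bad, "full"), "increasing")
  tiny <- d[1:2, ]
  expect_error(wex_fit(tiny, "full", fixed = c(k_f1 = 120)),
               "observations")
  expect_error(wex_fit(d, "full", fixed = c(bogus = 1)), "unknown fixed")
})

test_that("per-point sigmas weight the objective", {
  d <- wex_synth(sr60(), n_points = 16, noise_sd = 0.02, seed = 9)
  d$sigma34 <- rep(0.02, nrow(d))
  d$sigma36 <- rep(0.02, nrow(d))
  fit_w <- wex_fit(d, "full", fixed = sr60_fixed, n_starts = 2, seed = 1)
  fit_u <- wex_fit(d[, 1:3], "full", fixed = sr60_fixed, n_starts = 2, seed = 1)
  # constant weights rescale chi2 by 1/sigma^2 but leave the optimum alone
  # (up to optimizer stopping differences)
  expect_equal(coef(fit_w), coef(fit_u), tolerance = 0.01)
  expect_equal(fit_w$chi2, fit_u$chi2 / 0.02^2, tolerance = 1e-3)
})

test_that("synthetic generator is seeded, calibrated and truth-anchored", {
  r <- sr60()
  d1 <- wex_synth(r, n_points = 12, seed = 7)
  d2 <- wex_synth(r, n_points = 12, seed = 7)
  expect_identical(d1$y34, d2$y34)
  expect_identical(d1$y36, d2$y36)
  d3 <- wex_synth(r, n_points = 12, seed = 8)
  expect_false(identical(d1$y34, d3$y34))

  d0 <- wex_synth(r, n_points = 12, noise_sd = 0, seed = 7)
  truth <- attr(d0, "truth")
  expect_equal(d0$y34, truth$y34)
  expect_equal(d0$y36, truth$y36)
  tt <- simulate_exchange(r, d0$time_s)
  expect_equal(truth$y34, tt$y34)

  # realised noise sd matches the requested level (law of large numbers)
  big <- wex_synth(r, n_points = 1000, noise_sd = 0.02, seed = 3)
  resid <- c(big$y34 - attr(big, "truth")$y34,
             big$y36 - attr(big, "truth")$y36)
  expect_equal(stats::sd(resid), 0.02, tolerance = 0.1)
})

test_that("fit methods expose coefficients, predictions and residuals coherently", {
  d <- wex_synth(sr60(), n_points = 16, noise_sd = 0.02, seed = 2)
  fit <- wex_fit(d, "full", fixed = sr60_fixed, n_starts = 2, seed = 1)

  expect_named(coef(fit), names(sr60()))
  expect_equal(predict(fit)$y34, fitted(fit)$y34)
  pr <- predict(fit, c(0.5, 5))
  expect_equal(nrow(pr), 2L)
  r <- residuals(fit)
  expect_equal(r$y34 + fitted(fit)$y34, d$y34)
  expect_equal(sum(residuals(fit, weighted = TRUE)$y34^2) +
               sum(residuals(fit, weighted = TRUE)$y36^2),
               fit$chi2, tolerance = 1e-10)

  s <- summary(fit)
  expect_s3_class(s, "summary.wex_fit")
  expect_true(all(rownames(s$table)[s$table$fixed] %in% names(sr60_fixed)))
  expect_equal(unname(s$lambda3),
               unname(lambda3_exact(as_rate_constants(coef(fit)))))
  expect_output(print(fit), "chi2")

  sims <- simulate(fit, nsim = 3, seed = 11, noise_sd = 0.02)
  expect_length(sims, 3L)
  expect_identical(simulate(fit, 2, seed = 4), simulate(fit, 2, seed = 4))

  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off(), add = TRUE)
  expect_silent(plot(fit))
})

test_that("degenerate interpretations fit the same data near-equally", {
  # the package's central scientific point: on one dataset, both published
  # parameterisations (slowest phase = E_LS exchange vs = LS->HS conversion)
  # reach chi2 within 5% of each other
  d <- wex_synth(wex_preset("sr_pH6.0_hb"), n_points = 30,
                 noise_sd = 0.02, seed = 31)
  fit_hb <- wex_fit(d, "full", fixed = c(k_f1 = 120, k_f2 = 75, k_s1 = 1.0),
                    start = wex_preset("sr_pH6.0_hb")[c("k_s2", "k_c1", "k_c2")],
                    n_starts = 4, seed = 1)
  fit_tw <- wex_fit(d, "full", fixed = c(k_f1 = 120, k_f2 = 75, k_s1 = 0.01),
                    start = wex_preset("sr_pH6.0_tw")[c("k_s2", "k_c1", "k_c2")],
                    n_starts = 4, seed = 1)
  expect_lt(abs(fit_hb$chi2 - fit_tw$chi2) / fit_hb$chi2, 0.05)
})
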