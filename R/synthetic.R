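#' Generate a synthetic TR-MIMS exchange dataset
#'
#' Emulates a substrate-water exchange measurement: log-spaced incubation
#' times (the instrument samples decades from ~10 ms to ~100 s), noiseless
#' yields from the fully corrected forward model
#' (\code{\link{simulate_exchange}}), plus i.i.d. additive Gaussian noise
#' on both channels. Noise is not clipped: measured normalised yields can
#' fall slightly outside \code{[0, 1]}, as real ion-current ratios do.
#'
#' The defaults are the study conditions used throughout the package's
#' parameter-recovery tests: 30 points from 0.01 s to 100 s, noise sd
#' 0.02, initial enrichment 0.7\%, final enrichment 25\%, all three
#' measurement corrections applied.
#'
#' @param rates A \code{\link{rate_constants}} object (or coercible).
#' @param enrichment,mixing,s3 Correction settings; see
#'   \code{\link{simulate_exchange}}.
#' @param n_points Number of incubation times (at least 4; default 30).
#' @param t_min,t_max Time range in seconds (defaults 0.01 and 100).
#' @param noise_sd Gaussian noise standard deviation per channel
#'   (default 0.02).
#' @param seed Integer seed; the dataset is reproducible given the seed.
#' @param hs_fraction Optional explicit initial high-spin fraction.
#' @return A data frame of class \code{"exchange_data"} with columns
#'   \code{time_s}, \code{y34}, \code{y36}, and attributes \code{"truth"}
#'   (the noiseless curve), \code{"rates"}, \code{"noise_sd"},
#'   \code{"seed"}.
#' @examples
#' d <- wex_synth(wex_preset("sr_pH6.0_tw"), n_points = 12, seed = 3)
#' head(d)
#' @export
wex_synth <- function(rates,
                      enrichment = enrichment_spec(),
                      mixing = mixing_spec(),
                      s3 = s3_spec(),
                      n_points = 30, t_min = 0.01, t_max = 100,
                      noise_sd = 0.02, seed = 1, hs_fraction = NULL) {
  stopifnot(n_points >= 4, t_min > 0, t_max > t_min, noise_sd >= 0)
  rates <- as_rate_constants(rates)
  times <- log_times(n_points, t_min, t_max)
  truth <- simulate_exchange(rates, times, enrichment = enrichment,
                             mixing = mixing, s3 = s3,
                             hs_fraction = hs_fraction)
  noisy <- with_seed(seed, {
    data.frame(time_s = times,
               y34 = truth$y34 + stats::rnorm(n_points, 0, noise_sd),
               y36 = truth$y36 + stats::rnorm(n_points, 0, noise_sd))
  })
  structure(noisy, class = c("exchange_data", "data.frame"),
            truth = truth, rates = rates, noise_sd = noise_sd, seed = seed)
}
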