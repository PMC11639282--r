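#' Classical bi-exponential yield model
#'
#' The traditional description of TR-MIMS exchange data for a
#' single-conformation system with two independent sites exchanging at
#' well-separated rates (\code{k_f >> k_s}):
#' \deqn{^{34}Y = a (1 - e^{-k_f t}) + (1 - a)(1 - e^{-k_s t}), \quad
#'       ^{36}Y = 1 - e^{-k_s t}.}
#' The fast-phase amplitude \code{a} is fixed by the bulk enrichments
#' (\code{\link{a_from_enrichment}}).
#'
#' @param t Incubation time(s) in seconds, non-negative (vectorised).
#' @param a Fast-phase amplitude of 34Y, in \code{[0, 1]}.
#' @param k_f Fast exchange rate, 1/s.
#' @param k_s Slow exchange rate, 1/s.
#' @return A data frame with columns \code{time_s}, \code{y34}, \code{y36}.
#' @examples
#' biexp_yields(c(0.01, 0.1, 1, 10), a = 2/3, k_f = 40, k_s = 1.5)
#' @export
biexp_yields <- function(t, a, k_f, k_s) {
  stopifnot(all(t >= 0), a >= 0, a <= 1, k_f >= 0, k_s >= 0)
  data.frame(
    time_s = t,
    y34 = a * (1 - exp(-k_f * t)) + (1 - a) * (1 - exp(-k_s * t)),
    y36 = 1 - exp(-k_s * t))
}

#' Tri-exponential two-conformation yield model
#'
#' Extension of the bi-exponential model for samples containing
#' significant fractions of both S2 conformations, where the slow-site
#' exchange resolves into an intermediate phase (rate \code{k_i}, assigned
#' to Ws exchange in the high-spin conformation) and a slow phase (rate
#' \code{k_s}, attributable either to Ws exchange in the low-spin
#' conformation or to the conformational conversion itself):
#' \deqn{^{36}Y = b (1 - e^{-k_i t}) + (1 - b)(1 - e^{-k_s t}),}
#' with 34Y adding the fast phase of amplitude \code{a} on top. The
#' amplitude \code{b} reflects the conformational equilibrium.
#'
#' @inheritParams biexp_yields
#' @param b Intermediate-phase amplitude, in \code{[0, 1]}.
#' @param k_i Intermediate exchange rate, 1/s.
#' @return A data frame with columns \code{time_s}, \code{y34}, \code{y36}.
#' @examples
#' triexp_yields(c(0.01, 0.1, 1, 10), a = 2/3, b = 0.7,
#'               k_f = 40, k_i = 10, k_s = 0.5)
#' @export
triexp_yields <- function(t, a, b, k_f, k_i, k_s) {
  stopifnot(all(t >= 0), a >= 0, a <= 1, b >= 0, b <= 1,
            k_f >= 0, k_i >= 0, k_s >= 0)
  slow <- b * (1 - exp(-k_i * t)) + (1 - b) * (1 - exp(-k_s * t))
  data.frame(
    time_s = t,
    y34 = a * (1 - exp(-k_f * t)) + (1 - a) * slow,
    y36 = slow)
}
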