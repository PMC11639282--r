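#' Injection/mixing specification
#'
#' Describes how the labelled-water injection is treated. The injection
#' and mixing are approximately linear over about 6 ms (observed with a
#' fluorescent dye); for data taken after mixing is complete this is
#' exactly equivalent to an instantaneous injection shifted later by a
#' rate-dependent time \code{t_k} (see \code{\link{t_shift}}). The full
#' model uses a fixed representative shift of 3 ms by default, since
#' \code{t_k} stays near \code{t_m/2} for all exchange rates the method
#' can resolve.
#'
#' @param t_m Linear mixing duration in seconds (default 0.006).
#' @param mode \code{"shift"} (default; fixed time shift \code{t_k}),
#'   \code{"instant"} (no correction), or \code{"per-rate"} (recompute
#'   \code{t_k} from a supplied rate via \code{\link{t_shift}}).
#' @param t_k Time shift in seconds used in \code{"shift"} mode
#'   (default 0.003); must lie in \code{(0, t_m)}.
#' @return An object of class \code{"mixing_spec"}.
#' @examples
#' mixing_spec()                      # the default 3 ms shift
#' mixing_spec(mode = "instant")      # correction off
#' @export
mixing_spec <- function(t_m = 0.006, mode = c("shift", "instant", "per-rate"),
                        t_k = 0.003) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(t_m), length(t_m) == 1L, t_m > 0)
  if (mode == "shift") {
    stopifnot(is.numeric(t_k), length(t_k) == 1L)
    if (t_k <= 0 || t_k >= t_m)
      stop("t_k must lie strictly between 0 and t_m", call. = FALSE)
  }
  structure(list(t_m = t_m, mode = mode, t_k = t_k), class = "mixing_spec")
}

#' S3-state carryover-exchange specification
#'
#' In an S2-state measurement the sample spends a short time (usually
#' 10 ms) in the S3 state between the final two flashes, during which
#' substrate-water exchange continues at the S3-state rates. This spec
#' holds the S3 fast- and slow-site exchange rates and the duration; the
#' correction propagates the end-of-incubation state for \code{duration}
#' seconds under a generator using these site rates in both conformations.
#'
#' @param enabled Apply the correction (default TRUE).
#' @param duration Time spent in S3 in seconds (default 0.010).
#' @param k_f Fast-site exchange rate in S3, 1/s (default 19.5).
#' @param k_s Slow-site exchange rate in S3, 1/s (default 0.25).
#' @return An object of class \code{"s3_spec"}.
#' @examples
#' s3_spec()
#' @export
s3_spec <- function(enabled = TRUE, duration = 0.010, k_f = 19.5, k_s = 0.25) {
  stopifnot(is.logical(enabled), length(enabled) == 1L,
            is.numeric(duration), duration >= 0,
            is.numeric(k_f), k_f >= 0, is.numeric(k_s), k_s >= 0)
  structure(list(enabled = enabled, duration = duration,
                 k_f = k_f, k_s = k_s), class = "s3_spec")
}

#' Single-site labelled fraction under instantaneous mixing
#'
#' Solution of \code{dE/dt = k (alpha - E)} with constant bulk enrichment
#' \code{alpha_f} and initial value \code{alpha_in}:
#' \code{E(t) = alpha_in + (alpha_f - alpha_in)(1 - exp(-k t))}.
#'
#' @param t Time(s) in seconds, non-negative (vectorised).
#' @param k Apparent exchange rate, 1/s.
#' @param enrichment An \code{\link{enrichment_spec}}.
#' @return Labelled fraction(s) in \code{[alpha_in, alpha_f]}.
#' @export
single_site_instant <- function(t, k, enrichment) {
  stopifnot(all(t >= 0), k >= 0, inherits(enrichment, "enrichment_spec"))
  enrichment$alpha_in +
    (enrichment$alpha_f - enrichment$alpha_in) * (1 - exp(-k * t))
}

#' Single-site labelled fraction under linear mixing
#'
#' Solution of the same relaxation equation when the bulk enrichment ramps
#' linearly from \code{alpha_in} to \code{alpha_f} over \code{[0, t_m]}:
#' piecewise, with
#' \code{E(t) = alpha_in + (alpha_f - alpha_in)(exp(-k t) - 1 + k t)/(k t_m)}
#' during the ramp, and for \code{t >= t_m} exactly the instantaneous
#' solution delayed by \code{\link{t_shift}(k, t_m)}.
#'
#' @inheritParams single_site_instant
#' @param t_m Linear mixing duration in seconds.
#' @return Labelled fraction(s); continuous at \code{t = t_m}.
#' @export
single_site_linear <- function(t, k, enrichment, t_m = 0.006) {
  stopifnot(all(t >= 0), k >= 0, t_m > 0,
            inherits(enrichment, "enrichment_spec"))
  ai <- enrichment$alpha_in
  af <- enrichment$alpha_f
  ramp <- function(tt) {
    if (k == 0) return(rep(ai, length(tt)))  # no exchange at all
    ai + (af - ai) * (exp(-k * tt) - 1 + k * tt) / (k * t_m)
  }
  out <- numeric(length(t))
  early <- t <= t_m
  out[early] <- ramp(t[early])
  if (any(!early)) {
    tk <- t_shift(k, t_m)
    out[!early] <- ai + (af - ai) * (1 - exp(-k * (t[!early] - tk)))
  }
  out
}

#' Equivalent time shift of a linear mixing ramp
#'
#' For observation times after the ramp, linear mixing over \code{t_m}
#' is exactly an instantaneous injection delayed by
#' \deqn{t_k = \ln\bigl[(e^{k t_m} - 1)/(k t_m)\bigr] / k.}
#' \code{t_k} grows from \code{t_m/2} at small \code{k} (evaluated by
#' series for \code{k t_m < 1e-4} to avoid cancellation) towards
#' \code{t_m} as \code{k} grows, exceeding \code{0.55 t_m} only for rates
#' beyond the method's time resolution.
#'
#' @param k Apparent exchange rate(s), 1/s, non-negative (vectorised).
#' @param t_m Linear mixing duration in seconds.
#' @return Time shift(s) in seconds, in \code{[t_m/2, t_m)}.
#' @examples
#' t_shift(0, 0.006)    # 0.003
#' t_shift(250, 0.006)  # ~0.00337
#' @export
t_shift <- function(k, t_m = 0.006) {
  stopifnot(all(k >= 0), t_m > 0)
  x <- k * t_m
  out <- numeric(length(k))
  small <- x < 1e-4
  # ln((e^x - 1)/x) = x/2 + x^2/24 - x^4/2880 + ...  =>  t_k = t_m/2 + k t_m^2/24 - ...
  out[small] <- t_m / 2 + k[small] * t_m^2 / 24
  if (any(!small))
    out[!small] <- log((exp(x[!small]) - 1) / x[!small]) / k[!small]
  out
}

# generator used for the S3 carryover: same conformational rates, S3 site
# rates in both conformations
s3_generator <- function(rates, s3, alpha) {
  rates <- as_rate_constants(rates)
  r3 <- rate_constants(k_f1 = s3$k_f, k_f2 = s3$k_f,
                       k_s1 = s3$k_s, k_s2 = s3$k_s,
                       k_c1 = rates[["k_c1"]], k_c2 = rates[["k_c2"]])
  exchange_generator(r3, alpha)
}

#' Apply the S3-state carryover exchange to a state
#'
#' Takes the isotopologue populations at the end of the S2 incubation and
#' propagates them for \code{spec$duration} seconds under the S3-state
#' exchange rates (one fast and one slow site rate, used in both
#' conformations; the conformational interconversion rates are retained).
#' This emulates the extra exchange during the ~10 ms spent in S3 before
#' the O2-evolving flash, which shifts apparent exchange curves to
#' earlier times.
#'
#' @param state An \code{isotopologue_state}.
#' @param spec An \code{\link{s3_spec}}.
#' @param rates The S2-state \code{\link{rate_constants}} (conformational
#'   rates are reused).
#' @param enrichment An \code{\link{enrichment_spec}}; exchange during the
#'   carryover happens at \code{alpha_f}.
#' @return The propagated \code{isotopologue_state}.
#' @export
apply_s3_carryover <- function(state, spec, rates, enrichment) {
  validate_state(state)
  stopifnot(inherits(spec, "s3_spec"), inherits(enrichment, "enrichment_spec"))
  if (!spec$enabled || spec$duration == 0) return(state)
  if (spec$k_f == 0 && spec$k_s == 0) return(state)  # nothing exchanges
  G3 <- s3_generator(rates, spec, enrichment$alpha_f)
  propagate(state, G3, spec$duration)
}

#' Simulate corrected TR-MIMS exchange curves
#'
#' The full forward model: for each incubation time \code{t} the effective
#' exchange time is \code{t' = max(t - t_k, 0)} (non-instant injection as
#' a time shift; \code{t_k = 0} in \code{"instant"} mode); the
#' pre-injection equilibrium state at \code{alpha_in} is propagated for
#' \code{t'} under the S2 generator at \code{alpha_f}; the S3 carryover is
#' applied if enabled; and the populations are converted to normalised
#' 34Y/36Y yields.
#'
#' @param rates A \code{\link{rate_constants}} object (or coercible).
#' @param times Incubation times in seconds, non-negative.
#' @param enrichment An \code{\link{enrichment_spec}}.
#' @param mixing A \code{\link{mixing_spec}}; default the 3 ms shift.
#' @param s3 An \code{\link{s3_spec}}; default the 10 ms S3 carryover at
#'   the published S3 rates.
#' @param hs_fraction Optional explicit initial high-spin fraction.
#' @param normalized Plateau-1 normalisation (default TRUE).
#' @return An object of classes \code{"yield_curve"} and
#'   \code{"data.frame"}: columns \code{time_s}, \code{y34}, \code{y36}.
#' @examples
#' simulate_exchange(wex_preset("sr_pH8.3_hb"),
#'                   times = 10^seq(-2, 2, length.out = 5))
#' @export
simulate_exchange <- function(rates, times,
                              enrichment = enrichment_spec(),
                              mixing = mixing_spec(),
                              s3 = s3_spec(),
                              hs_fraction = NULL,
                              normalized = TRUE) {
  rates <- as_rate_constants(rates)
  stopifnot(is.numeric(times), all(is.finite(times)), all(times >= 0),
            inherits(enrichment, "enrichment_spec"),
            inherits(mixing, "mixing_spec"), inherits(s3, "s3_spec"))

  tk <- switch(mixing$mode,
               instant = 0,
               shift = mixing$t_k,
               # rate-dependent refinement: the shift matters only while the
               # fast site still exchanges, so its rate sets t_k
               `per-rate` = t_shift(max(rates[["k_f1"]], rates[["k_f2"]]),
                                    mixing$t_m))
  teff <- pmax(times - tk, 0)

  G <- exchange_generator(rates, enrichment$alpha_f)
  p0 <- as.vector(equilibrium_state(rates, enrichment$alpha_in, hs_fraction))
  P <- propagate_times(p0, G, teff)                     # 8 x n

  if (s3$enabled && s3$duration > 0 && (s3$k_f > 0 || s3$k_s > 0)) {
    G3 <- s3_generator(rates, s3, enrichment$alpha_f)
    M3 <- as.matrix(Matrix::expm(Matrix::Matrix(G3 * s3$duration)))
    P <- M3 %*% P
  }

  y <- yields_from_matrix(P, enrichment$alpha_f, normalized)
  structure(data.frame(time_s = times, y34 = y$y34, y36 = y$y36),
            class = c("yield_curve", "data.frame"),
            normalized = normalized)
}
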