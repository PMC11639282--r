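#' Bootstrap parameter uncertainties for an exchange-curve fit
#'
#' Case-resampling bootstrap: data triplets \code{(time, y34, y36)} are
#' resampled with replacement, each replicate is refitted (starting from
#' the original optimum plus a small number of scattered restarts), and
#' per-parameter percentile intervals are reported. The published fits
#' quote their parameter errors the same way; here the \code{+/-} error is
#' the half-width of the central 68\% percentile interval. Residual
#' resampling (refitting fitted + resampled residuals at the original
#' times) is available as an alternative flavour.
#'
#' Replicates whose refit fails to converge are dropped; more than 20\%
#' failures aborts with an error, since the distribution would no longer
#' be trustworthy. Results are deterministic for a given seed.
#'
#' @param fit A \code{\link{wex_fit}} object.
#' @param n_boot Number of bootstrap replicates (at least 100).
#' @param seed Integer seed.
#' @param type \code{"case"} (default) or \code{"residual"}.
#' @param level Confidence level for the percentile intervals (default
#'   0.68, mirroring the +/- convention of the published tables).
#' @param n_starts Starts per replicate refit (default 2: the original
#'   optimum plus one scattered start).
#' @return The input \code{wex_fit} with a \code{bootstrap} element added:
#'   list with \code{samples} (replicate x free-parameter matrix),
#'   \code{ci} (percentile interval matrix), \code{errors} (half-widths),
#'   \code{type}, \code{level}, \code{seed}, \code{n_failed}.
#' @examples
#' \donttest{
#' d <- wex_synth(wex_preset("sr_pH6.0_tw"), n_points = 20, seed = 7)
#' f <- wex_fit(d, "full", fixed = c(k_f1 = 120, k_f2 = 75, k_s1 = 0.01),
#'              n_starts = 4)
#' f <- wex_bootstrap(f, n_boot = 100, seed = 1)
#' confint(f)
#' }
#' @export
wex_bootstrap <- function(fit, n_boot = 500, seed = 1,
                          type = c("case", "residual"),
                          level = 0.68, n_starts = 2) {
  stopifnot(inherits(fit, "wex_fit"))
  type <- match.arg(type)
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)

  data <- fit$data
  n <- nrow(data)
  res <- residuals(fit)

  fit_one <- function(d) {
    tryCatch({
      f <- wex_fit(d, model = fit$model, fixed = fit$fixed,
                   start = fit$coefficients[fit$free],
                   lower = fit$bounds$lower, upper = fit$bounds$upper,
                   enrichment = fit$enrichment, mixing = fit$mixing,
                   s3 = fit$s3, hs_fraction = fit$hs_fraction,
                   a_free = TRUE,  # fixing decisions already encoded in `fixed`
                   n_starts = n_starts,
                   seed = sample.int(.Machine$integer.max, 1L))
      f$coefficients[fit$free]
    }, error = function(e) NULL)
  }

  samples <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, length(fit$free),
                  dimnames = list(NULL, fit$free))
    for (b in seq_len(n_boot)) {
      if (type == "case") {
        idx <- sort(sample.int(n, n, replace = TRUE))
        d <- data[idx, , drop = FALSE]
        # refitting needs strictly increasing times; duplicated resampled
        # times are collapsed by tiny jitter-free de-duplication: keep
        # duplicates by offsetting each repeat by a negligible epsilon
        dup <- duplicated(d$time_s)
        while (any(dup)) {
          d$time_s[dup] <- d$time_s[dup] * (1 + 1e-9)
          dup <- duplicated(d$time_s)
        }
        d <- d[order(d$time_s), , drop = FALSE]
      } else {
        idx <- sample.int(n, n, replace = TRUE)
        d <- data
        d$y34 <- fit$fitted$y34 + res$y34[idx]
        idx2 <- sample.int(n, n, replace = TRUE)
        d$y36 <- fit$fitted$y36 + res$y36[idx2]
      }
      est <- fit_one(d)
      if (!is.null(est)) out[b, ] <- est
    }
    out
  })

  failed <- apply(samples, 1L, function(r) any(!is.finite(r)))
  if (mean(failed) > 0.20)
    stop(sprintf("%.0f%% of bootstrap replicates failed to converge",
                 100 * mean(failed)), call. = FALSE)
  ok <- samples[!failed, , drop = FALSE]
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- t(apply(ok, 2L, stats::quantile, probs = pr, names = FALSE))
  colnames(ci) <- paste0(format(100 * pr, trim = TRUE), "%")
  fit$bootstrap <- list(samples = samples, ci = ci,
                        errors = (ci[, 2] - ci[, 1]) / 2,
                        type = type, level = level, seed = seed,
                        n_failed = sum(failed))
  fit
}

#' Bootstrap percentile confidence intervals
#'
#' @param object A \code{\link{wex_fit}} that has been through
#'   \code{\link{wex_bootstrap}}.
#' @param parm Parameters to report (default: all free).
#' @param level Ignored; the level chosen at bootstrap time is reported.
#' @param ... Unused.
#' @return Matrix of percentile intervals for the free parameters.
#' @export
confint.wex_fit <- function(object, parm = NULL, level = NULL, ...) {
  if (is.null(object$bootstrap))
    stop("no bootstrap distributions present; run wex_bootstrap() first",
         call. = FALSE)
  ci <- object$bootstrap$ci
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}
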