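# ---- parameter templates ---------------------------------------------------
# Each model exposes a named parameter set. Rates are optimised on a log10
# scale (they span orders of magnitude and must stay positive); amplitudes on
# the natural scale in [0, 1].

param_template <- function(model, enrichment) {
  switch(model,
    full = list(
      names = c("k_f1", "k_f2", "k_s1", "k_s2", "k_c1", "k_c2"),
      default = c(k_f1 = 100, k_f2 = 70, k_s1 = 1, k_s2 = 30,
                  k_c1 = 1, k_c2 = 1),
      lower = c(k_f1 = 1e-4, k_f2 = 1e-4, k_s1 = 1e-4, k_s2 = 1e-4,
                k_c1 = 1e-4, k_c2 = 1e-4),
      upper = c(k_f1 = 1e4, k_f2 = 1e4, k_s1 = 1e4, k_s2 = 1e4,
                k_c1 = 1e4, k_c2 = 1e4),
      log = c(k_f1 = TRUE, k_f2 = TRUE, k_s1 = TRUE, k_s2 = TRUE,
              k_c1 = TRUE, k_c2 = TRUE)),
    biexp = list(
      names = c("a", "k_f", "k_s"),
      default = c(a = a_from_enrichment(enrichment), k_f = 40, k_s = 1),
      lower = c(a = 0, k_f = 1e-4, k_s = 1e-4),
      upper = c(a = 1, k_f = 1e4, k_s = 1e4),
      log = c(a = FALSE, k_f = TRUE, k_s = TRUE)),
    triexp = list(
      names = c("a", "b", "k_f", "k_i", "k_s"),
      default = c(a = a_from_enrichment(enrichment), b = 0.5,
                  k_f = 40, k_i = 10, k_s = 0.5),
      lower = c(a = 0, b = 0, k_f = 1e-4, k_i = 1e-4, k_s = 1e-4),
      upper = c(a = 1, b = 1, k_f = 1e4, k_i = 1e4, k_s = 1e4),
      log = c(a = FALSE, b = FALSE, k_f = TRUE, k_i = TRUE, k_s = TRUE)),
    stop("unknown model '", model, "'", call. = FALSE))
}

model_curve <- function(model, pars, times, enrichment, mixing, s3,
                        hs_fraction) {
  switch(model,
    full = simulate_exchange(as_rate_constants(pars), times,
                             enrichment = enrichment, mixing = mixing,
                             s3 = s3, hs_fraction = hs_fraction),
    biexp = biexp_yields(times, pars[["a"]], pars[["k_f"]], pars[["k_s"]]),
    triexp = triexp_yields(times, pars[["a"]], pars[["b"]], pars[["k_f"]],
                           pars[["k_i"]], pars[["k_s"]]))
}

to_internal <- function(x, log) ifelse(log, log10(x), x)
from_internal <- function(x, log) ifelse(log, 10^x, x)

# ---- dataset validation ----------------------------------------------------

check_dataset <- function(data) {
  need <- c("time_s", "y34", "y36")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("dataset lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(data$time_s)) || any(!is.finite(data$y34)) ||
      any(!is.finite(data$y36)))
    stop("dataset contains non-finite values", call. = FALSE)
  if (is.unsorted(data$time_s, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  data
}

dataset_sigma <- function(data) {
  s34 <- if ("sigma34" %in% names(data)) data$sigma34 else rep(1, nrow(data))
  s36 <- if ("sigma36" %in% names(data)) data$sigma36 else rep(1, nrow(data))
  if (any(c(s34, s36) <= 0))
    stop("sigma columns must be positive", call. = FALSE)
  list(s34 = s34, s36 = s36)
}

# ---- the fitting function --------------------------------------------------

#' Fit an exchange model to TR-MIMS yield curves
#'
#' Chi-square-minimising fit of either the full corrected two-site,
#' two-conformation kinetic model or one of the empirical multi-exponential
#' models to measured (or synthetic) normalised 34Y/36Y exchange curves.
#' The objective \eqn{\chi^2 = \sum (obs - model)^2 / \sigma^2} runs over
#' both yield channels (unit weights when no sigma columns are present).
#' Minimisation uses bounded Levenberg-Marquardt least squares restarted
#' from \code{n_starts} scattered initial guesses (the model is multimodal
#' by construction — distinct rate assignments can describe the same
#' curves), keeping the best optimum; every start's outcome is retained in
#' the result for inspection.
#'
#' Rates are optimised on a log10 scale; amplitudes on the natural scale.
#' Any parameter can be held fixed through \code{fixed}. For the empirical
#' models the fast-phase amplitude \code{a} is fixed to its
#' enrichment-implied value (\code{\link{a_from_enrichment}}) by default;
#' pass \code{a_free = TRUE} to release it.
#'
#' @param data A data frame with columns \code{time_s} (strictly
#'   increasing), \code{y34}, \code{y36}, optionally \code{sigma34},
#'   \code{sigma36}.
#' @param model \code{"full"} (corrected kinetic model), \code{"biexp"}, or
#'   \code{"triexp"}.
#' @param fixed Named numeric vector/list of parameters to hold fixed.
#' @param start Optional named numeric vector of initial guesses for free
#'   parameters (first start; remaining starts are scattered).
#' @param lower,upper Optional named bounds for free parameters.
#' @param enrichment,mixing,s3 Correction settings for the full model (and
#'   the enrichment-implied \code{a} of the empirical models); see
#'   \code{\link{enrichment_spec}}, \code{\link{mixing_spec}},
#'   \code{\link{s3_spec}}.
#' @param hs_fraction Optional explicit initial high-spin fraction.
#' @param a_free Release the empirical amplitude \code{a} (default FALSE:
#'   fixed to the enrichment-implied value unless supplied in
#'   \code{fixed}).
#' @param n_starts Number of multi-start initial guesses (default 8).
#' @param seed Integer seed for the start scatter (default 1).
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @return An object of class \code{"wex_fit"}; see
#'   \code{\link{summary.wex_fit}}, \code{\link{coef.wex_fit}},
#'   \code{\link{predict.wex_fit}}, \code{\link{plot.wex_fit}},
#'   \code{\link{simulate.wex_fit}}, \code{\link{wex_bootstrap}}.
#' @examples
#' truth <- wex_preset("sr_pH6.0_tw")
#' d <- wex_synth(truth, n_points = 20, noise_sd = 0.02, seed = 42)
#' fit <- wex_fit(d, model = "full",
#'                fixed = c(k_f1 = 120, k_f2 = 75, k_s1 = 0.01),
#'                n_starts = 4, seed = 1)
#' coef(fit)
#' @export
wex_fit <- function(data, model = c("full", "biexp", "triexp"),
                    fixed = NULL, start = NULL, lower = NULL, upper = NULL,
                    enrichment = enrichment_spec(), mixing = mixing_spec(),
                    s3 = s3_spec(), hs_fraction = NULL, a_free = FALSE,
                    n_starts = 8, seed = 1, maxiter = 200) {
  model <- match.arg(model)
  data <- check_dataset(as.data.frame(data))
  stopifnot(inherits(enrichment, "enrichment_spec"),
            inherits(mixing, "mixing_spec"), inherits(s3, "s3_spec"))
  tmpl <- param_template(model, enrichment)

  fixed <- unlist(fixed)
  if (model %in% c("biexp", "triexp") && !a_free && !("a" %in% names(fixed)))
    fixed <- c(fixed, a = unname(tmpl$default["a"]))
  if (length(fixed)) {
    bad <- setdiff(names(fixed), tmpl$names)
    if (length(bad))
      stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  free <- setdiff(tmpl$names, names(fixed))
  if (!length(free)) stop("no free parameters to fit", call. = FALSE)

  n_obs <- 2L * nrow(data)
  if (n_obs < length(free) + 2L)
    stop("need at least ", length(free) + 2L,
         " observations (both channels) for ", length(free),
         " free parameters", call. = FALSE)

  lo <- tmpl$lower[free]; hi <- tmpl$upper[free]
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)
  if (any(lo >= hi)) stop("lower bounds must be below upper bounds",
                          call. = FALSE)
  st0 <- tmpl$default[free]
  if (!is.null(start)) {
    start <- unlist(start)
    st0[intersect(names(start), free)] <- start[intersect(names(start), free)]
  }
  st0 <- pmin(pmax(st0, lo), hi)
  logmask <- tmpl$log[free]

  sg <- dataset_sigma(data)
  assemble <- function(theta_free) {
    pars <- c(theta_free, fixed)[tmpl$names]
    names(pars) <- tmpl$names
    pars
  }
  resid_fn <- function(theta_int) {
    theta <- from_internal(theta_int, logmask)
    names(theta) <- free
    m <- model_curve(model, assemble(theta), data$time_s,
                     enrichment, mixing, s3, hs_fraction)
    c((data$y34 - m$y34) / sg$s34, (data$y36 - m$y36) / sg$s36)
  }

  # multi-start scatter: start 1 is the supplied/default guess, the rest are
  # uniform draws in the (internal-scale) box
  starts <- with_seed(seed, {
    S <- matrix(NA_real_, n_starts, length(free),
                dimnames = list(NULL, free))
    S[1L, ] <- to_internal(st0, logmask)
    if (n_starts > 1L) {
      lo_i <- to_internal(lo, logmask); hi_i <- to_internal(hi, logmask)
      for (j in seq_along(free))
        S[-1L, j] <- stats::runif(n_starts - 1L, lo_i[j], hi_i[j])
    }
    S
  })

  runs <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    runs[[i]] <- tryCatch({
      res <- minpack.lm::nls.lm(
        par = starts[i, ], fn = resid_fn,
        lower = to_internal(lo, logmask), upper = to_internal(hi, logmask),
        control = minpack.lm::nls.lm.control(maxiter = maxiter))
      theta <- from_internal(res$par, logmask)
      names(theta) <- free
      list(ok = res$info %in% 1:4, info = res$info,
           message = res$message, chi2 = res$deviance, par = theta)
    }, error = function(e) list(ok = FALSE, info = NA_integer_,
                                message = conditionMessage(e),
                                chi2 = Inf, par = NULL))
  }
  ok <- vapply(runs, function(r) isTRUE(r$ok) && is.finite(r$chi2), logical(1))
  if (!any(ok)) {
    msgs <- vapply(runs, function(r) paste0("[info=", r$info, "] ", r$message),
                   character(1))
    stop("no start converged:\n", paste(" -", msgs, collapse = "\n"),
         call. = FALSE)
  }
  best <- which.min(vapply(runs, function(r)
    if (isTRUE(r$ok)) r$chi2 else Inf, numeric(1)))
  est <- runs[[best]]$par
  pars <- assemble(est)

  fitted_curve <- model_curve(model, pars, data$time_s,
                              enrichment, mixing, s3, hs_fraction)
  chi2 <- runs[[best]]$chi2

  if (model %in% c("biexp", "triexp") && "k_s" %in% names(pars) &&
      pars[["k_f"]] < 10 * pars[["k_s"]])
    warning("fitted k_f/k_s < 10: the multi-exponential decomposition ",
            "presumes k_f >> k_s and is ill-conditioned here", call. = FALSE)

  structure(list(
    coefficients = pars, free = free, fixed = fixed,
    chi2 = chi2, convergence = runs[[best]]$info,
    model = model, data = data,
    fitted = data.frame(time_s = data$time_s,
                        y34 = fitted_curve$y34, y36 = fitted_curve$y36),
    enrichment = enrichment, mixing = mixing, s3 = s3,
    hs_fraction = hs_fraction,
    bounds = list(lower = lo, upper = hi),
    starts = list(values = starts, runs = runs, best = best,
                  n_converged = sum(ok)),
    seed = seed, n_starts = n_starts,
    bootstrap = NULL), class = "wex_fit")
}

# ---- methods ---------------------------------------------------------------

#' @export
print.wex_fit <- function(x, ...) {
  cat(sprintf("Exchange-curve fit (model: %s)\n", x$model))
  est <- x$coefficients
  tag <- ifelse(names(est) %in% names(x$fixed), " (fixed)", "")
  for (i in seq_along(est))
    cat(sprintf("  %-5s = %-10.4g%s\n", names(est)[i], est[i], tag[i]))
  cat(sprintf("chi2 = %.6g over %d points x 2 channels (%d/%d starts converged)\n",
              x$chi2, nrow(x$data), x$starts$n_converged, x$n_starts))
  invisible(x)
}

#' Summarise an exchange-curve fit
#'
#' @param object A \code{\link{wex_fit}} object.
#' @param ... Unused.
#' @return An object of class \code{"summary.wex_fit"}: the parameter table
#'   (estimate, fixed flag, bootstrap 68\% interval when available), chi2,
#'   convergence diagnostics, and the slow eigenvalue pair implied by the
#'   fitted rates (full model only).
#' @export
summary.wex_fit <- function(object, ...) {
  est <- object$coefficients
  tab <- data.frame(estimate = unname(est),
                    fixed = names(est) %in% names(object$fixed),
                    row.names = names(est))
  if (!is.null(object$bootstrap)) {
    ci <- object$bootstrap$ci
    tab$boot_lo <- NA_real_; tab$boot_hi <- NA_real_; tab$boot_err <- NA_real_
    tab[rownames(ci), "boot_lo"] <- ci[, 1]
    tab[rownames(ci), "boot_hi"] <- ci[, 2]
    tab[rownames(ci), "boot_err"] <- (ci[, 2] - ci[, 1]) / 2
  }
  lam3 <- if (object$model == "full")
    lambda3_exact(as_rate_constants(est)) else NULL
  structure(list(table = tab, chi2 = object$chi2, model = object$model,
                 n = nrow(object$data), lambda3 = lam3,
                 n_converged = object$starts$n_converged,
                 n_starts = object$n_starts,
                 n_boot = if (!is.null(object$bootstrap))
                   nrow(object$bootstrap$samples) else 0L),
            class = "summary.wex_fit")
}

#' @export
print.summary.wex_fit <- function(x, ...) {
  cat(sprintf("Exchange-curve fit summary (model: %s, n = %d time points)\n",
              x$model, x$n))
  print(signif(as.matrix(x$table[, !vapply(x$table, is.logical, logical(1)),
                                 drop = FALSE]), 4))
  fixed <- rownames(x$table)[x$table$fixed]
  if (length(fixed)) cat("fixed:", paste(fixed, collapse = ", "), "\n")
  cat(sprintf("chi2 = %.6g; %d/%d starts converged\n",
              x$chi2, x$n_converged, x$n_starts))
  if (!is.null(x$lambda3))
    cat(sprintf("implied slow eigenvalue pair: %.4g / %.4g 1/s\n",
                x$lambda3[1], x$lambda3[2]))
  if (x$n_boot > 0)
    cat(sprintf("bootstrap: %d replicates; errors are 68%% percentile half-widths\n",
                x$n_boot))
  invisible(x)
}

#' @export
coef.wex_fit <- function(object, ...) object$coefficients

#' Predicted yield curves from a fit
#'
#' @param object A \code{\link{wex_fit}} object.
#' @param times Incubation times (s) at which to evaluate; defaults to the
#'   fitted data's times.
#' @param ... Unused.
#' @return Data frame with \code{time_s}, \code{y34}, \code{y36}.
#' @export
predict.wex_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$fitted)
  stopifnot(all(times >= 0))
  model_curve(object$model, object$coefficients, times,
              object$enrichment, object$mixing, object$s3,
              object$hs_fraction)[, c("time_s", "y34", "y36")]
}

#' @export
fitted.wex_fit <- function(object, ...) object$fitted

#' Residuals of an exchange-curve fit
#'
#' @param object A \code{\link{wex_fit}} object.
#' @param weighted Divide by the per-point sigmas when present.
#' @param ... Unused.
#' @return Data frame with \code{time_s}, \code{y34}, \code{y36} residual
#'   columns (observed minus fitted).
#' @export
residuals.wex_fit <- function(object, weighted = FALSE, ...) {
  r34 <- object$data$y34 - object$fitted$y34
  r36 <- object$data$y36 - object$fitted$y36
  if (weighted) {
    sg <- dataset_sigma(object$data)
    r34 <- r34 / sg$s34; r36 <- r36 / sg$s36
  }
  data.frame(time_s = object$data$time_s, y34 = r34, y36 = r36)
}

#' Plot an exchange-curve fit
#'
#' Two panels (34Y left, 36Y right) on a logarithmic time axis: observed
#' points and the fitted curve evaluated on a fine log-spaced grid.
#'
#' @param x A \code{\link{wex_fit}} object.
#' @param n_grid Number of grid points for the fitted curve.
#' @param ... Passed to \code{plot.default} for the data points.
#' @return Invisibly, \code{x}.
#' @export
plot.wex_fit <- function(x, n_grid = 200, ...) {
  tmin <- max(min(x$data$time_s), 1e-4)
  grid <- log_times(n_grid, tmin, max(x$data$time_s))
  pr <- predict(x, grid)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (ch in c("y34", "y36")) {
    graphics::plot(x$data$time_s, x$data[[ch]], log = "x",
                   xlab = "incubation time (s)",
                   ylab = if (ch == "y34") expression({}^34 * Y)
                          else expression({}^36 * Y),
                   ylim = range(0, 1.05, x$data[[ch]]), ...)
    graphics::lines(grid, pr[[ch]], col = "steelblue", lwd = 2)
  }
  invisible(x)
}

#' Simulate datasets from a fitted model
#'
#' Parametric simulation: evaluates the fitted curve at the original times
#' and adds i.i.d. Gaussian noise. The noise standard deviation defaults to
#' the root-mean-square residual of the fit.
#'
#' @param object A \code{\link{wex_fit}} object.
#' @param nsim Number of datasets.
#' @param seed Integer seed (optional).
#' @param noise_sd Noise standard deviation; default the fit's RMS residual.
#' @param ... Unused.
#' @return A list of \code{nsim} data frames shaped like the fitted data.
#' @export
simulate.wex_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = NULL, ...) {
  if (is.null(noise_sd)) {
    r <- residuals(object)
    noise_sd <- sqrt(mean(c(r$y34, r$y36)^2))
  }
  gen <- function() {
    out <- object$fitted
    out$y34 <- out$y34 + stats::rnorm(nrow(out), 0, noise_sd)
    out$y36 <- out$y36 + stats::rnorm(nrow(out), 0, noise_sd)
    out
  }
  if (!is.null(seed)) with_seed(seed, replicate(nsim, gen(), simplify = FALSE))
  else replicate(nsim, gen(), simplify = FALSE)
}
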