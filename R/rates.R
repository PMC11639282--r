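#' Rate constants of the two-site, two-conformation exchange scheme
#'
#' Bundles the six first-order rate constants that define one S2-state
#' water-exchange model: exchange of the fast substrate water (Wf) and the
#' slowly exchanging substrate water (Ws) in each of the two cluster
#' conformations (low-spin E_LS and high-spin E_HS), plus the two
#' conformational interconversion rates.
#'
#' All rates are apparent pseudo-first-order rate constants in 1/s. The
#' conformation change \code{k_c2} takes E_LS to E_HS and \code{k_c1} takes
#' E_HS back to E_LS, so the equilibrium high-spin fraction is
#' \code{k_c2 / (k_c1 + k_c2)}.
#'
#' @param k_f1 Fast-site (Wf) exchange rate in E_LS (1/s).
#' @param k_f2 Fast-site (Wf) exchange rate in E_HS (1/s).
#' @param k_s1 Slow-site (Ws) exchange rate in E_LS (1/s).
#' @param k_s2 Slow-site (Ws) exchange rate in E_HS (1/s).
#' @param k_c1 Conformational conversion rate E_HS -> E_LS (1/s).
#' @param k_c2 Conformational conversion rate E_LS -> E_HS (1/s).
#'
#' @return An object of class \code{"rate_constants"}: a named numeric vector
#'   of length six.
#'
#' @examples
#' rate_constants(k_f1 = 120, k_f2 = 65, k_s1 = 1.0, k_s2 = 50,
#'                k_c1 = 3.6, k_c2 = 12)
#' @export
rate_constants <- function(k_f1, k_f2, k_s1, k_s2, k_c1, k_c2) {
  k <- c(k_f1 = k_f1, k_f2 = k_f2, k_s1 = k_s1, k_s2 = k_s2,
         k_c1 = k_c1, k_c2 = k_c2)
  if (!is.numeric(k) || length(k) != 6L)
    stop("all six rate constants must be single numeric values", call. = FALSE)
  if (any(!is.finite(k)))
    stop("rate constants must be finite", call. = FALSE)
  if (any(k < 0))
    stop("rate constants must be non-negative; got ",
         paste(names(k)[k < 0], collapse = ", "), call. = FALSE)
  structure(k, class = "rate_constants")
}

#' Coerce to rate constants
#'
#' @param x A \code{rate_constants} object, or a numeric vector of length six
#'   (named with the six rate names in any order, or unnamed in the order
#'   \code{k_f1, k_f2, k_s1, k_s2, k_c1, k_c2}).
#' @return A \code{rate_constants} object.
#' @export
as_rate_constants <- function(x) {
  if (inherits(x, "rate_constants")) return(x)
  nm <- c("k_f1", "k_f2", "k_s1", "k_s2", "k_c1", "k_c2")
  x <- unlist(x)
  if (length(x) != 6L)
    stop("need six rate constants", call. = FALSE)
  if (!is.null(names(x)) && all(nzchar(names(x)))) {
    if (!setequal(names(x), nm))
      stop("rate names must be ", paste(nm, collapse = ", "), call. = FALSE)
    x <- x[nm]
  } else {
    names(x) <- nm
  }
  do.call(rate_constants, as.list(x))
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Two-site / two-conformation exchange rates (1/s):\n")
  print(unclass(x), ...)
  kc <- x[["k_c1"]] + x[["k_c2"]]
  if (kc > 0)
    cat(sprintf("Equilibrium high-spin fraction: %.4f\n", x[["k_c2"]] / kc))
  invisible(x)
}

#' Published rate-constant presets
#'
#' Named parameter sets for the Ca2+- and Sr2+-substituted photosystem II
#' samples at the pH values for which S2-state substrate-water exchange has
#' been characterised, each in the two degenerate interpretations: the
#' "hb" variants fix the slow low-spin exchange near the slowest observed
#' phase (slowest component = Ws exchange in E_LS), while the "tw" variants
#' make E_LS exchange-inert so the slowest phase reflects the E_LS -> E_HS
#' conversion. \code{"s3_rates"} returns the S3-state carryover-exchange
#' settings instead (see \code{\link{s3_spec}}).
#'
#' Point estimates only; the published bootstrap uncertainties are attached
#' as an \code{"errors"} attribute and are never used as priors.
#'
#' @param name One of \code{"ca_pH8.6_hb"}, \code{"ca_pH8.6_tw"},
#'   \code{"sr_pH6.0_hb"}, \code{"sr_pH6.0_tw"}, \code{"sr_pH8.3_hb"},
#'   \code{"sr_pH8.3_tw"}, \code{"s3_rates"}.
#' @return A \code{\link{rate_constants}} object with attributes
#'   \code{"errors"} (named numeric, \code{NA} where fixed) and
#'   \code{"fixed"} (character vector of parameters that were held fixed in
#'   the published fit), or an \code{\link{s3_spec}} for \code{"s3_rates"}.
#' @examples
#' wex_preset("sr_pH8.3_hb")
#' @export
wex_preset <- function(name) {
  tab <- list(
    # k_f1, k_f2, k_s1, k_s2, k_c1, k_c2 ; err NA = fixed in the source fit
    "ca_pH8.6_hb" = list(k = c(94, 73, 1.1, 11.7, 0.084, 0.62),
                         err = c(NA, 14, NA, 1.3, 0.13, 0.63)),
    "ca_pH8.6_tw" = list(k = c(94, 73, 0.01, 11, 0.13, 1.5),
                         err = c(NA, 20, NA, 1, 0.1, 0.7)),
    "sr_pH6.0_hb" = list(k = c(120, 75, 1.0, 28.6, 0.30, 0.32),
                         err = c(NA, 21, NA, 13.5, 0.30, 0.23)),
    "sr_pH6.0_tw" = list(k = c(120, 75, 0.01, 26, 1.1, 1.3),
                         err = c(NA, NA, NA, 7, 0.4, 0.2)),
    "sr_pH8.3_hb" = list(k = c(120, 65, 1.0, 50, 3.6, 12),
                         err = c(NA, 9, NA, 10, 2.9, 6)),
    "sr_pH8.3_tw" = list(k = c(120, 65, 11, 57, 0.6, 1.0),
                         err = c(NA, NA, 3, 14, 0.3, NA))
  )
  if (identical(name, "s3_rates"))
    return(s3_spec(enabled = TRUE, duration = 0.010, k_f = 19.5, k_s = 0.25))
  if (!name %in% names(tab))
    stop("unknown preset '", name, "'; valid names: ",
         paste(c(names(tab), "s3_rates"), collapse = ", "), call. = FALSE)
  entry <- tab[[name]]
  k <- as_rate_constants(entry$k)
  err <- entry$err
  names(err) <- names(k)
  attr(k, "errors") <- err
  attr(k, "fixed") <- names(err)[is.na(err)]
  attr(k, "preset") <- name
  k
}

#' Names of available presets
#' @return Character vector of valid \code{\link{wex_preset}} names.
#' @export
wex_preset_names <- function() {
  c("ca_pH8.6_hb", "ca_pH8.6_tw", "sr_pH6.0_hb", "sr_pH6.0_tw",
    "sr_pH8.3_hb", "sr_pH8.3_tw", "s3_rates")
}
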