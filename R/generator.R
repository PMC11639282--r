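# State indexing for the 8-state isotopologue space, fixed so that
# serialised states are portable:
#   index = 4*(conformation: LS=0, HS=1) + 2*(slow site: 16O=0, 18O=1)
#         + (fast site: 16O=0, 18O=1) + 1      (R is 1-based)
# i.e. 1 = LS(16,16), 2 = LS(16,18), 3 = LS(18,16), 4 = LS(18,18),
#      5 = HS(16,16), ..., 8 = HS(18,18).
wex_state_names <- function() {
  c("LS.s16.f16", "LS.s16.f18", "LS.s18.f16", "LS.s18.f18",
    "HS.s16.f16", "HS.s16.f18", "HS.s18.f16", "HS.s18.f18")
}

state_index <- function(conf, slow18, fast18) {
  4L * conf + 2L * slow18 + fast18 + 1L
}

#' Generator matrix of the isotopologue master equation
#'
#' Builds the 8x8 continuous-time generator of the two-site,
#' two-conformation exchange scheme at a fixed bulk enrichment
#' \code{alpha}. Each substrate site independently swaps its bound oxygen
#' with the bulk at the conformation's site rate, landing on 18O with
#' probability \code{alpha} and on 16O with probability \code{1 - alpha};
#' the conformational interconversion preserves the bound labels. Only
#' single-coordinate transitions have non-zero rates.
#'
#' The matrix uses the column convention: \code{dp/dt = G p} with
#' \code{G[j, i]} the rate from state \code{i} to state \code{j}, so every
#' column sums to zero and off-diagonal entries are non-negative.
#'
#' @param rates A \code{\link{rate_constants}} object (or coercible).
#' @param alpha Bulk H2(18)O enrichment in \code{[0, 1)} governing the
#'   label landing probabilities.
#' @return An 8x8 numeric matrix with dimnames the state labels
#'   (conformation LS/HS, slow-site label, fast-site label).
#' @examples
#' G <- exchange_generator(wex_preset("sr_pH8.3_hb"), alpha = 0.25)
#' colSums(G)  # all zero
#' @export
exchange_generator <- function(rates, alpha) {
  rates <- as_rate_constants(rates)
  stopifnot(is.numeric(alpha), length(alpha) == 1L)
  if (!is.finite(alpha) || alpha < 0 || alpha >= 1)
    stop("alpha must lie in [0, 1)", call. = FALSE)

  G <- matrix(0, 8L, 8L, dimnames = list(wex_state_names(), wex_state_names()))
  k_f <- c(rates[["k_f1"]], rates[["k_f2"]])  # site rates per conformation
  k_s <- c(rates[["k_s1"]], rates[["k_s2"]])

  for (conf in 0:1) {
    for (s in 0:1) {
      for (f in 0:1) {
        i <- state_index(conf, s, f)
        # fast-site label swap
        kf <- k_f[conf + 1L]
        G[state_index(conf, s, 1L - f), i] <- G[state_index(conf, s, 1L - f), i] +
          kf * (if (f == 0L) alpha else 1 - alpha)
        # slow-site label swap
        ks <- k_s[conf + 1L]
        G[state_index(conf, 1L - s, f), i] <- G[state_index(conf, 1L - s, f), i] +
          ks * (if (s == 0L) alpha else 1 - alpha)
        # conformational change, labels preserved
        kc <- if (conf == 0L) rates[["k_c2"]] else rates[["k_c1"]]
        G[state_index(1L - conf, s, f), i] <- G[state_index(1L - conf, s, f), i] + kc
      }
    }
  }
  diag(G) <- diag(G) - colSums(G)
  G
}

#' Pre-injection equilibrium isotopologue state
#'
#' The initial condition of the exchange measurement: the conformational
#' equilibrium between E_LS and E_HS (set by the interconversion rates) is
#' assumed established before the labelled-water injection, and each
#' substrate site independently carries 18O with probability
#' \code{alpha_in}.
#'
#' @param rates A \code{\link{rate_constants}} object; only the
#'   conformational rates are used.
#' @param alpha_in Pre-injection enrichment in \code{[0, 1)}.
#' @param hs_fraction Optional explicit high-spin fraction in \code{[0, 1]}.
#'   Required when \code{k_c1 = k_c2 = 0}, where no equilibrium exists and
#'   assuming one silently would fabricate physics.
#' @return An object of class \code{"isotopologue_state"}: a numeric vector
#'   of 8 populations summing to one, with a \code{"time"} attribute (0).
#' @examples
#' equilibrium_state(wex_preset("sr_pH8.3_hb"), alpha_in = 0.007)
#' @export
equilibrium_state <- function(rates, alpha_in = 0.007, hs_fraction = NULL) {
  rates <- as_rate_constants(rates)
  if (!is.finite(alpha_in) || alpha_in < 0 || alpha_in >= 1)
    stop("alpha_in must lie in [0, 1)", call. = FALSE)
  kc <- rates[["k_c1"]] + rates[["k_c2"]]
  if (is.null(hs_fraction)) {
    if (kc <= 0)
      stop("k_c1 = k_c2 = 0: no conformational equilibrium exists; ",
           "supply hs_fraction explicitly", call. = FALSE)
    hs_fraction <- rates[["k_c2"]] / kc
  } else {
    stopifnot(is.numeric(hs_fraction), length(hs_fraction) == 1L,
              hs_fraction >= 0, hs_fraction <= 1)
  }
  p_conf <- c(1 - hs_fraction, hs_fraction)
  p_lab <- c(1 - alpha_in, alpha_in)
  p <- numeric(8L)
  for (conf in 0:1)
    for (s in 0:1)
      for (f in 0:1)
        p[state_index(conf, s, f)] <- p_conf[conf + 1L] * p_lab[s + 1L] * p_lab[f + 1L]
  new_state(p, time = 0)
}

new_state <- function(p, time = 0) {
  names(p) <- wex_state_names()
  structure(p, time = time, class = "isotopologue_state")
}

validate_state <- function(state) {
  if (!inherits(state, "isotopologue_state") || length(state) != 8L)
    stop("expected an isotopologue_state of length 8", call. = FALSE)
  if (any(!is.finite(state)))
    stop("state populations must be finite", call. = FALSE)
  if (abs(sum(state) - 1) > 1e-9)
    stop("state populations must sum to 1", call. = FALSE)
  invisible(state)
}

#' @export
print.isotopologue_state <- function(x, ...) {
  cat(sprintf("Isotopologue state at t = %g s:\n", attr(x, "time")))
  print(round(unclass(x), 6), ...)
  invisible(x)
}

# Eigendecomposition of the generator with a guard against near-defective
# matrices. The scheme is reversible (Kolmogorov's cycle condition holds for
# every elementary cycle), so eigenvalues are real; complex round-off is
# stripped after checking it is negligible.
generator_eigen <- function(G) {
  e <- eigen(G)
  V <- e$vectors
  lam <- e$values
  if (max(abs(Im(lam))) > 1e-8 * max(1, max(abs(Re(lam)))))
    return(NULL)
  lam <- Re(lam)
  V <- Re(V)
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi)) return(NULL)
  # reject badly conditioned eigenbases (near-defective generator)
  if (max(abs(V %*% Vi - diag(nrow(G)))) > 1e-8) return(NULL)
  list(values = lam, vectors = V, inverse = Vi)
}

# Populations at several times from one initial vector.
# Returns an 8 x length(times) matrix. Uses the eigenbasis when it is
# well-conditioned, otherwise falls back to a scaling-and-squaring matrix
# exponential per time point.
propagate_times <- function(p0, G, times) {
  stopifnot(all(is.finite(G)))
  eg <- generator_eigen(G)
  if (!is.null(eg)) {
    a <- eg$inverse %*% p0
    E <- exp(outer(eg$values, times))       # 8 x n
    P <- eg$vectors %*% (E * as.vector(a))
  } else {
    P <- vapply(times, function(dt) {
      as.vector(as.matrix(Matrix::expm(Matrix::Matrix(G * dt))) %*% p0)
    }, numeric(8L))
    P <- matrix(P, nrow = 8L)
  }
  # clip tiny negative round-off, renormalise within tolerance
  P[P < 0 & P > -1e-12] <- 0
  P
}

#' Propagate an isotopologue state
#'
#' Advances the populations by \code{dt} seconds under a fixed generator,
#' i.e. applies the matrix exponential \code{expm(G dt)} to the population
#' vector. The generator is time-independent after the mixing
#' approximation, so this is the exact solution of the master equation.
#'
#' @param state An \code{isotopologue_state}.
#' @param generator An 8x8 generator matrix from
#'   \code{\link{exchange_generator}}.
#' @param dt Time step in seconds, non-negative.
#' @return The propagated \code{isotopologue_state}, time advanced by
#'   \code{dt}.
#' @examples
#' r <- wex_preset("sr_pH8.3_hb")
#' s0 <- equilibrium_state(r, 0)
#' propagate(s0, exchange_generator(r, 0.25), dt = 0.1)
#' @export
propagate <- function(state, generator, dt) {
  validate_state(state)
  stopifnot(is.numeric(dt), length(dt) == 1L, dt >= 0)
  if (!all(is.finite(generator)))
    stop("generator entries must be finite", call. = FALSE)
  if (dt == 0) return(state)
  p <- propagate_times(as.vector(state), generator, dt)[, 1L]
  new_state(p, time = attr(state, "time") + dt)
}

#' Oxygen-isotopologue yields from an isotopologue state
#'
#' Converts site-label populations into the observable O2 isotopologue
#' yields. The double-labelled yield 36Y is the probability that both
#' substrate sites carry 18O; the single-labelled yield 34Y is the
#' probability of exactly one 18O. Under the plateau-1 convention
#' (\code{normalized = TRUE}, the default, matching how TR-MIMS data are
#' reported) these are divided by their isotopic-equilibrium values
#' \code{alpha_f^2} and \code{2 alpha_f (1 - alpha_f)}, so both approach 1
#' as exchange completes.
#'
#' @param state An \code{isotopologue_state}.
#' @param enrichment An \code{\link{enrichment_spec}}; its \code{alpha_f}
#'   sets the normalisation.
#' @param normalized Report plateau-normalised yields (default) or raw
#'   isotopologue probabilities.
#' @return Named numeric vector \code{c(y34 = , y36 = )}.
#' @examples
#' r <- wex_preset("sr_pH8.3_hb")
#' s <- propagate(equilibrium_state(r, 0), exchange_generator(r, 0.25), 1)
#' state_yields(s, enrichment_spec(0, 0.25))
#' @export
state_yields <- function(state, enrichment, normalized = TRUE) {
  validate_state(state)
  stopifnot(inherits(enrichment, "enrichment_spec"))
  af <- enrichment$alpha_f
  if (af <= 0) stop("alpha_f must be positive", call. = FALSE)
  p <- as.vector(state)
  y <- yields_from_matrix(matrix(p, ncol = 1L), af, normalized)
  c(y34 = y$y34[1L], y36 = y$y36[1L])
}

# vectorised yield extraction from an 8 x n population matrix
yields_from_matrix <- function(P, alpha_f, normalized = TRUE) {
  idx <- expand.grid(f = 0:1, s = 0:1, conf = 0:1)  # fastest-varying first
  n18 <- idx$s + idx$f   # number of labelled sites per state, in index order
  one <- colSums(P[n18 == 1L, , drop = FALSE])
  both <- colSums(P[n18 == 2L, , drop = FALSE])
  if (normalized) {
    list(y34 = one / (2 * alpha_f * (1 - alpha_f)), y36 = both / alpha_f^2)
  } else {
    list(y34 = one, y36 = both)
  }
}
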