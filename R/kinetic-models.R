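#' Effective proliferation rates lambda and kappa
#'
#' The two combined rate parameters that govern unseeded aggregation curves:
#' \deqn{\lambda = \sqrt{2 k_+ k_n m_0^{n_c}}}
#' \deqn{\kappa = \sqrt{\frac{2 k_+ k_2 m_0^{n_2+1}}{1 + m_0^{n_2}/K_M}}}
#' \eqn{\lambda} measures proliferation through primary nucleation,
#' \eqn{\kappa} through fibril-catalyzed secondary nucleation; the saturation
#' factor in \eqn{\kappa} is absent (unity) for the single-step model.
#'
#' @param params a [kinetic_params] object.
#' @param m0 initial monomer concentration (uM), > 0.
#' @return A list with components `lambda` and `kappa` (time^-1).
#' @export
effective_rates <- function(params, m0) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.numeric(m0) || length(m0) != 1L || !is.finite(m0) || m0 <= 0)
    stop("m0 must be a single finite positive concentration")
  lambda <- sqrt(2 * params$kp_kn * m0^params$n_c)
  sat <- 1 + m0^params$n_2 / params$K_M  # = 1 when K_M = Inf (single-step)
  kappa <- sqrt(2 * params$kp_k2 * m0^(params$n_2 + 1) / sat)
  list(lambda = lambda, kappa = kappa)
}

# Derived coefficients of the integrated rate law. With C+- = +-lambda^2 /
# (2 kappa^2) and k_inf_tilde = sqrt(k_inf^2 - 4 C+ C- kappa^2), the fibril
# mass fraction is
#   M(t)/m0 = 1 - (R(t))^(k_inf^2/(kappa k_inf_tilde)) * exp(-k_inf t),
#   R(t) = (B+ + C+)(B- + C+ e^{kappa t}) / ((B- + C+)(B+ + C+ e^{kappa t})),
# with B+- = (k_inf +- k_inf_tilde)/(2 kappa). The late-time relaxation rate
# k_inf equals 2 k+ P(infinity); its self-consistent estimate is
#   k_inf^2 = 4 k+ k2 int_0^m0 m^(n2-1) (m0-m) / (1 + m^n2/K_M) dm
#           + 2 lambda^2 / n_c,
# which reduces to the familiar 2 kappa^2/(n2(n2+1)) + 2 lambda^2/nc when
# K_M = Inf and tracks the true (ODE) late-time rate to ~0.1% under
# saturation. The integral is done by adaptive quadrature (deterministic).
closed_form_coefs <- function(params, m0) {
  er <- effective_rates(params, m0)
  lambda <- er$lambda; kappa <- er$kappa
  n2 <- params$n_2; nc <- params$n_c
  Cp <- lambda^2 / (2 * kappa^2)         # C+ ( = -C- )
  if (is.infinite(params$K_M)) {
    I2 <- m0^(n2 + 1) / (n2 * (n2 + 1))
  } else {
    I2 <- stats::integrate(function(m) m^(n2 - 1) * (m0 - m) /
                             (1 + m^n2 / params$K_M),
                           0, m0, rel.tol = 1e-10)$value
  }
  kinf <- sqrt(4 * params$kp_k2 * I2 + 2 * lambda^2 / nc)
  ktil <- sqrt(kinf^2 + lambda^4 / kappa^2)  # k_inf^2 - 4 C+ C- kappa^2
  Bp <- (kinf + ktil) / (2 * kappa)
  Bm <- (kinf - ktil) / (2 * kappa)
  list(lambda = lambda, kappa = kappa, Cp = Cp, kinf = kinf, ktil = ktil,
       Bp = Bp, Bm = Bm, expo = kinf^2 / (kappa * ktil))
}

#' Closed-form fibril mass fraction M(t)/m0
#'
#' Evaluates the integrated rate law for unseeded aggregation with primary
#' nucleation, elongation, and single-step or saturating secondary
#' nucleation (see [closed_form_coefs] internals and the package vignette
#' for the formula). The multi-step model differs from single-step only
#' through the saturation factor inside \eqn{\kappa}.
#'
#' The power term is evaluated in log space; for large \eqn{\kappa t} the
#' exponential branch has converged and the asymptote 1 is returned, so no
#' overflow can occur.
#'
#' Accuracy note: the rate law is derived under secondary-nucleation
#' dominance and is accurate to better than 1e-2 (absolute, on the
#' normalized curve) for \eqn{\kappa \ge \lambda}; [mass_fraction_ode] is
#' the numerical reference outside that regime.
#'
#' @inheritParams effective_rates
#' @param t numeric vector of time points, non-negative and increasing.
#' @return Numeric vector of the same length as `t` with values in [0, 1].
#' @examples
#' p <- kinetic_params(kp_kn = 1e-4, kp_k2 = 10)
#' mass_fraction_closed(p, t = seq(0, 2, 0.1), m0 = 3)
#' @export
mass_fraction_closed <- function(params, t, m0) {
  check_time_grid(t)
  cf <- closed_form_coefs(params, m0)
  kt <- cf$kappa * t
  out <- numeric(length(t))

  safe <- kt < 500  # e^{kt} representable and ratio not yet fully converged
  if (any(safe)) {
    E <- exp(kt[safe])
    ratio <- ((cf$Bp + cf$Cp) * (cf$Bm + cf$Cp * E)) /
             ((cf$Bm + cf$Cp) * (cf$Bp + cf$Cp * E))
    # ratio > 0 throughout the validity domain; evaluate power in log space
    logterm <- cf$expo * log(ratio) - cf$kinf * t[safe]
    out[safe] <- 1 - exp(logterm)
  }
  if (any(!safe)) {
    # e^{kappa t} dominates both parenthesized factors: R -> (B+ + C+)/(B- + C+)
    logRinf <- log((cf$Bp + cf$Cp) / (cf$Bm + cf$Cp))
    logterm <- cf$expo * logRinf - cf$kinf * t[!safe]
    out[!safe] <- 1 - exp(pmin(logterm, 0))
  }
  pmin(pmax(out, 0), 1)
}

#' Numerical (ODE) fibril mass fraction M(t)/m0
#'
#' Integrates the moment equations for unseeded aggregation
#' \deqn{dP/dt = k_n m^{n_c} + k_2 m^{n_2} M / (1 + m^{n_2}/K_M)}
#' \deqn{dM/dt = 2 k_+ m P, \quad m = m_0 - M, \quad P(0) = M(0) = 0}
#' with a stiff-safe adaptive integrator (`deSolve::ode`, lsoda). Because
#' only the products \eqn{k_+ k_n} and \eqn{k_+ k_2} enter the normalized
#' solution, the system is integrated in the rescaled number concentration
#' \eqn{P' = 2 k_+ P}. This routine is the numerical reference ("oracle")
#' for [mass_fraction_closed].
#'
#' @inheritParams mass_fraction_closed
#' @param rtol,atol relative and absolute integration tolerances.
#' @return Numeric vector of M(t)/m0 at `t`, values in [0, 1].
#' @export
mass_fraction_ode <- function(params, t, m0, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "kinetic_params"))
  check_time_grid(t)
  if (!is.numeric(m0) || length(m0) != 1L || !is.finite(m0) || m0 <= 0)
    stop("m0 must be a single finite positive concentration")

  times <- t
  prepend0 <- times[1] > 0
  if (prepend0) times <- c(0, times)

  deriv <- function(tt, y, parms) {
    M <- min(max(y[2], 0), m0)
    m <- m0 - M
    sat <- 1 + m^params$n_2 / params$K_M
    dP2 <- 2 * (params$kp_kn * m^params$n_c +
                params$kp_k2 * m^params$n_2 * M / sat)
    dM <- m * y[1]
    list(c(dP2, dM))
  }

  sol <- deSolve::ode(y = c(P2 = 0, M = 0), times = times, func = deriv,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  Mt <- sol[, "M"]
  if (nrow(sol) != length(times) || anyNA(Mt))
    stop("ODE integration failed (returned ", nrow(sol), "/", length(times),
         " steps); istate = ", attr(sol, "istate")[1],
         "; try looser tolerances or check the parameters")
  if (prepend0) Mt <- Mt[-1]
  pmin(pmax(Mt / m0, 0), 1)
}

#' Model-predicted aggregation half time
#'
#' Solves \eqn{M(\tau_{1/2})/m_0 = 1/2} on the closed-form curve with a
#' bracketing root finder (relative tolerance 1e-6). The normalized curve is
#' monotone for unseeded kinetics, so the root is unique.
#'
#' @inheritParams effective_rates
#' @param horizon optional maximum time to search; by default the bracket is
#'   expanded geometrically from \eqn{1/\kappa} up to \eqn{10^6/\kappa}.
#' @return The half time (same time units as the rate constants).
#' @export
model_halftime <- function(params, m0, horizon = NULL) {
  cf <- closed_form_coefs(params, m0)
  f <- function(t) mass_fraction_closed(params, t, m0) - 0.5
  upper <- 1 / cf$kappa
  cap <- if (is.null(horizon)) 1e6 / cf$kappa else horizon
  while (f(upper) < 0) {
    if (upper >= cap)
      stop("curve does not reach M/m0 = 0.5 within the search horizon (",
           signif(cap, 4), " time units)")
    upper <- min(upper * 2, cap)
  }
  root <- stats::uniroot(f, lower = 0, upper = upper,
                         tol = 1e-6 * upper)
  root$root
}

check_time_grid <- function(t) {
  if (!is.numeric(t) || length(t) < 1L || anyNA(t))
    stop("t must be a numeric vector without NA")
  if (t[1] < 0) stop("time points must be >= 0")
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("time points must be strictly increasing")
  invisible(t)
}
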