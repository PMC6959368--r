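#' Fit a sigmoid and extract the aggregation half time
#'
#' Fits the four-parameter logistic
#' \deqn{F(t) = base + \frac{plateau - base}{1 + e^{-(t - t_{mid})/w}}}
#' to a trace by Levenberg-Marquardt least squares and reports the
#' aggregation half time \eqn{\tau_{1/2}}, defined as the time where the
#' fitted curve crosses \eqn{(base + plateau)/2} (which equals \eqn{t_{mid}}
#' for this form). Declining traces are handled by the sign of
#' \eqn{plateau - base}; no flipping is needed.
#'
#' Initialization is multi-start: \eqn{t_{mid}} is seeded at the raw
#' half-crossing of the data, \eqn{w} at 5% of the observed time span, with
#' alternative widths (2%, 10%, 20% of span) tried until convergence.
#'
#' @param trace an [aggregation_trace], spanning its transition (the raw
#'   signal must cross its own midpoint).
#' @return An object of class `half_time_estimate`: a list with `tau_half`,
#'   `tau_half_se` (from the fit covariance), `width` (w, > 0), `base`,
#'   `plateau`, `rss`, `n`, and `m0` carried over from the trace.
#' @examples
#' t <- seq(0, 200, 2)
#' tr <- aggregation_trace(t, 1 / (1 + exp(-(t - 100) / 10)))
#' fit_sigmoid(tr)$tau_half
#' @export
fit_sigmoid <- function(trace) {
  stopifnot(inherits(trace, "aggregation_trace"))
  t <- trace$time; y <- trace$signal
  n <- length(t)

  head_m <- mean(y[seq_len(max(3L, floor(n * 0.1)))])
  tail_m <- mean(y[seq.int(n - max(3L, floor(n * 0.1)) + 1L, n)])
  mid <- (head_m + tail_m) / 2
  cross <- which(diff(sign(y - mid)) != 0)
  if (abs(tail_m - head_m) < 1e-12 * max(abs(y), 1) || length(cross) == 0L)
    stop("trace ", trace_label(trace),
         " does not cross its own midpoint; no transition to fit")
  i <- cross[1]
  t_mid0 <- t[i] + (t[i + 1] - t[i]) *
    (mid - y[i]) / (y[i + 1] - y[i])

  span <- diff(range(t))
  resid_fn <- function(p) y - (p[1] + (p[2] - p[1]) /
                                 (1 + exp(-(t - p[3]) / p[4])))
  fits <- list()
  for (wfrac in c(0.05, 0.02, 0.1, 0.2)) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = c(base = head_m, plateau = tail_m,
                                 t_mid = t_mid0, w = wfrac * span),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(out) && out$info %in% 1:4) fits[[length(fits) + 1L]] <- out
  }
  # discard converged-but-absurd local optima (midpoint outside the data)
  fits <- Filter(function(f) f$par[["t_mid"]] >= min(t) &&
                   f$par[["t_mid"]] <= max(t), fits)
  if (length(fits) == 0L)
    stop("sigmoid fit did not converge for trace ", trace_label(trace),
         " from any start (or only to a midpoint outside the data)")
  rss <- vapply(fits, function(f) f$deviance, numeric(1))
  fit <- fits[[which.min(rss)]]

  co <- fit$par
  # w < 0 is the same curve with base/plateau swapped; canonicalize to w > 0
  if (co[["w"]] < 0) {
    co[c("base", "plateau")] <- co[c("plateau", "base")]
    co[["w"]] <- -co[["w"]]
  }
  # standard errors from the Gauss-Newton covariance sigma^2 (J'J)^-1
  se <- tryCatch({
    sigma2 <- fit$deviance / max(n - 4L, 1L)
    sqrt(diag(sigma2 * solve(fit$hessian)))[["t_mid"]]
  }, error = function(e) NA_real_)

  structure(
    list(tau_half = co[["t_mid"]], tau_half_se = se, width = co[["w"]],
         base = co[["base"]], plateau = co[["plateau"]],
         rss = fit$deviance, n = n, m0 = trace$m0,
         direction = if (co[["plateau"]] >= co[["base"]]) "rising"
                     else "declining"),
    class = "half_time_estimate"
  )
}

#' @export
print.half_time_estimate <- function(x, ...) {
  cat(sprintf("tau_1/2 = %.4g +/- %.2g (width %.3g, base %.4g, plateau %.4g, rss %.3g)\n",
              x$tau_half, x$tau_half_se, x$width, x$base, x$plateau, x$rss))
  invisible(x)
}

#' Half-time concentration scaling (the exponent gamma)
#'
#' Ordinary least squares of \eqn{\log \tau_{1/2}} on \eqn{\log m_0}: the
#' slope is the scaling exponent \eqn{\gamma} in
#' \eqn{\tau_{1/2} \propto m_0^{\gamma}}, the standard mechanistic
#' diagnostic read off a double-logarithmic plot. For unsaturated
#' secondary-nucleation-dominated kinetics with \eqn{n_2 = 2} the limit is
#' \eqn{\gamma = -3/2}; full saturation gives \eqn{-1/2}; intermediate
#' saturation interpolates.
#'
#' @param m0 concentrations (uM), or a data.frame/list with columns/fields
#'   `m0` and `tau_half`.
#' @param tau_half half times (same length as `m0`), or missing when `m0`
#'   is a data.frame. [half_time_estimate] objects are also accepted in a
#'   list via `tau_half`.
#' @return An object of class `scaling_fit`: list with `gamma`, `gamma_se`,
#'   `log_intercept` (natural-log scale), `r_squared`, `n`.
#' @export
scaling_exponent <- function(m0, tau_half = NULL) {
  if (is.data.frame(m0)) {
    tau_half <- m0$tau_half; m0 <- m0$m0
  }
  if (is.list(tau_half))
    tau_half <- vapply(tau_half, function(x)
      if (inherits(x, "half_time_estimate")) x$tau_half else as.numeric(x),
      numeric(1))
  if (length(m0) != length(tau_half)) stop("m0 and tau_half lengths differ")
  keep <- is.finite(m0) & is.finite(tau_half)
  m0 <- m0[keep]; tau_half <- tau_half[keep]
  if (length(unique(m0)) < 3L)
    stop("scaling_exponent needs at least 3 distinct concentrations")
  if (any(m0 <= 0) || any(tau_half <= 0))
    stop("concentrations and half times must be positive")

  fit <- stats::lm(log(tau_half) ~ log(m0))
  sm <- suppressWarnings(summary(fit))  # perfect fits are legitimate here
  structure(
    list(gamma = unname(stats::coef(fit)[2]),
         gamma_se = unname(sm$coefficients[2, 2]),
         log_intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared,
         n = length(m0)),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("gamma = %.3f +/- %.3f (R^2 = %.4f, n = %d)\n",
              x$gamma, x$gamma_se, x$r_squared, x$n))
  invisible(x)
}

#' Linearity of the final signal in the initial monomer concentration
#'
#' OLS of the final (plateau) intensity on m0. A linear relation with
#' near-zero intercept indicates that essentially all initially monomeric
#' peptide is converted into signal-active fibril mass.
#'
#' @param m0 concentrations (uM), or a data.frame with columns `m0`,
#'   `final`.
#' @param final final intensities (a.u.).
#' @return List with `slope` (a.u./uM), `intercept` (a.u.), `r_squared`,
#'   `n`.
#' @export
plateau_linearity <- function(m0, final = NULL) {
  if (is.data.frame(m0)) {
    final <- m0$final; m0 <- m0$m0
  }
  if (length(m0) != length(final)) stop("m0 and final lengths differ")
  if (length(m0) < 3L) stop("plateau_linearity needs at least 3 points")
  if (length(unique(m0)) < 2L)
    stop("degenerate input: all concentrations identical")
  fit <- stats::lm(final ~ m0)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit))$r.squared,
       n = length(m0))
}

#' Per-concentration half times from a set of traces
#'
#' Convenience pipeline step mirroring the standard plate-reader analysis:
#' per-trace normalization, replicate averaging per concentration, then a
#' sigmoid fit of each averaged trace.
#'
#' @param traces list of [aggregation_trace] objects (e.g. from
#'   [read_traces]).
#' @return A data.frame with one row per concentration: `m0`, `tau_half`,
#'   `tau_half_se`, `width`, `rss`, `n_replicates`.
#' @export
halftimes_by_concentration <- function(traces) {
  m0s <- vapply(traces, function(x) x$m0, numeric(1))
  if (anyNA(m0s)) stop("all traces need a known m0")
  out <- lapply(sort(unique(m0s)), function(conc) {
    grp <- traces[m0s == conc]
    avg <- average_replicates(lapply(grp, normalize_trace))
    est <- fit_sigmoid(avg)
    data.frame(m0 = conc, tau_half = est$tau_half,
               tau_half_se = est$tau_half_se, width = est$width,
               rss = est$rss, n_replicates = length(grp))
  })
  do.call(rbind, out)
}
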