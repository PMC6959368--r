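#' Kinetic parameters of the nucleation-elongation aggregation model
#'
#' Container for the rate constants and reaction orders of unseeded amyloid
#' aggregation with primary nucleation, fibril-end elongation and secondary
#' nucleation. Secondary nucleation is either single-step (rate
#' \eqn{k_2 m^{n_2} M}) or multi-step, i.e. saturating through a
#' Michaelis-type factor \eqn{1/(1 + m^{n_2}/K_M)}.
#'
#' Normalized, unseeded mass-fraction curves depend on the rate constants only
#' through the products \eqn{k_+ k_n} and \eqn{k_+ k_2}: those products are
#' the canonical parameterization stored here. You may alternatively supply
#' the raw constants `k_n`, `k_plus`, `k_2`; they are folded into the
#' products immediately (the individual constants are not identifiable from
#' normalized traces and are not retained).
#'
#' Concentrations are in micromolar throughout; `K_M` is therefore in
#' \eqn{\mu M^{n_2}}. Time units are whatever the data use (minutes in all
#' shipped defaults); the rate-constant units follow.
#'
#' @param kp_kn product \eqn{k_+ k_n} (\eqn{\mu M^{-n_c} \cdot} conc
#'   \eqn{\cdot} time\eqn{^{-2}}, i.e. \eqn{\mu M^{1-n_c}} time\eqn{^{-2}}).
#' @param kp_k2 product \eqn{k_+ k_2} (\eqn{\mu M^{-1-n_2}} time\eqn{^{-2}}).
#' @param n_c primary nucleation reaction order (default 2, the standard
#'   value for amyloid-beta in this framework).
#' @param n_2 secondary nucleation reaction order (default 2).
#' @param K_M saturation (Michaelis) constant of secondary nucleation in
#'   \eqn{\mu M^{n_2}}; `Inf` selects the single-step model.
#' @param model `"single_step"`, `"multi_step"`, or `NULL` to infer from
#'   `K_M` (`Inf` implies single-step). A supplied value must be consistent
#'   with `K_M`.
#' @param k_n,k_plus,k_2 optional raw rate constants; if given (all three of
#'   `k_plus` and at least one of `k_n`, `k_2`), they override the
#'   corresponding products via `kp_kn = k_plus * k_n`, `kp_k2 = k_plus * k_2`.
#'
#' @return An object of class `kinetic_params`.
#' @examples
#' p <- kinetic_params(kp_kn = 3.5e-7, kp_k2 = 7e-5, K_M = 18)
#' effective_rates(p, m0 = 3)
#' @export
kinetic_params <- function(kp_kn = NULL, kp_k2 = NULL, n_c = 2, n_2 = 2,
                           K_M = Inf, model = NULL,
                           k_n = NULL, k_plus = NULL, k_2 = NULL) {
  if (!is.null(k_plus)) {
    if (!is.null(k_n)) kp_kn <- k_plus * k_n
    if (!is.null(k_2)) kp_k2 <- k_plus * k_2
  }
  if (is.null(kp_kn) || is.null(kp_k2))
    stop("supply either the products kp_kn and kp_k2, or k_plus with k_n and k_2")
  stopifnot(is.numeric(kp_kn), length(kp_kn) == 1L,
            is.numeric(kp_k2), length(kp_k2) == 1L,
            is.numeric(n_c), length(n_c) == 1L,
            is.numeric(n_2), length(n_2) == 1L,
            is.numeric(K_M), length(K_M) == 1L)
  if (!is.finite(kp_kn) || kp_kn <= 0) stop("kp_kn must be finite and > 0")
  if (!is.finite(kp_k2) || kp_k2 <= 0) stop("kp_k2 must be finite and > 0")
  if (n_c < 1) stop("n_c must be >= 1")
  if (n_2 < 1) stop("n_2 must be >= 1")
  if (is.na(K_M) || K_M <= 0) stop("K_M must be > 0 (Inf for single-step)")

  inferred <- if (is.infinite(K_M)) "single_step" else "multi_step"
  if (is.null(model)) {
    model <- inferred
  } else {
    model <- match.arg(model, c("single_step", "multi_step"))
    if (model != inferred)
      stop("model = ", model, " is inconsistent with K_M = ", K_M,
           " (single_step requires K_M = Inf)")
  }

  structure(
    list(kp_kn = kp_kn, kp_k2 = kp_k2, n_c = n_c, n_2 = n_2,
         K_M = K_M, model = model),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Aggregation kinetic parameters (", x$model, ")\n", sep = "")
  cat(sprintf("  k+*kn = %.4g, k+*k2 = %.4g (uM, per-time^2 units)\n",
              x$kp_kn, x$kp_k2))
  cat(sprintf("  n_c = %g, n_2 = %g, K_M = %g uM^n_2\n", x$n_c, x$n_2, x$K_M))
  invisible(x)
}

#' Serialize kinetic parameters to/from JSON
#'
#' The JSON schema is `{"kp_kn", "kp_k2", "nc", "n2", "KM", "model"}` with
#' `KM` either a number or the string `"inf"`.
#'
#' @param params a [kinetic_params] object.
#' @param path optional file path; if `NULL`, the JSON string is returned.
#' @return `params_to_json`: a JSON string (or `path`, invisibly, when
#'   writing); `params_from_json`: a [kinetic_params] object.
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  obj <- list(kp_kn = params$kp_kn, kp_k2 = params$kp_k2,
              nc = params$n_c, n2 = params$n_2,
              KM = if (is.infinite(params$K_M)) "inf" else params$K_M,
              model = params$model)
  if (is.null(path))
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param json a JSON string or a path to a JSON file.
#' @rdname params_to_json
#' @export
params_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  km <- obj$KM
  if (is.character(km)) {
    if (!identical(tolower(km), "inf")) stop("unrecognized KM value: ", km)
    km <- Inf
  }
  kinetic_params(kp_kn = obj$kp_kn, kp_k2 = obj$kp_k2,
                 n_c = obj$nc, n_2 = obj$n2, K_M = km, model = obj$model)
}
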