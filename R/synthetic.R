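#' Specification of a synthetic aggregation experiment
#'
#' Bundles everything the generators need: the kinetic ground truth, the
#' concentration series, replication, time grid, noise and signal
#' calibration. All randomness flows from the single mandatory `seed`.
#'
#' @param params a [kinetic_params] object (the ground truth).
#' @param concentrations monomer concentrations in uM (default 1..9 uM, the
#'   span of a typical ThT concentration series).
#' @param n_replicates wells per concentration (default 6).
#' @param t_grid shared time grid, in the time unit of `params` (hours for
#'   [default_tht_params]: 0-25 h every 5 min).
#' @param noise_sd i.i.d. Gaussian noise, as a fraction of each trace's
#'   amplitude (default 0.02).
#' @param gain fluorescence gain in a.u. per uM of fibril mass (default 500).
#' @param baseline instrument baseline in a.u. (default 100).
#' @param seed integer seed (mandatory: no implicit entropy).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(params = default_tht_params(),
                           concentrations = 1:9, n_replicates = 6,
                           t_grid = seq(0, 25, length.out = 301),
                           noise_sd = 0.02, gain = 500, baseline = 100,
                           seed) {
  stopifnot(inherits(params, "kinetic_params"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer seed is mandatory")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  check_time_grid(t_grid)
  structure(
    list(params = params, concentrations = sort(concentrations),
         n_replicates = as.integer(n_replicates), t_grid = t_grid,
         noise_sd = noise_sd, gain = gain, baseline = baseline,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Default ground-truth parameters for the ThT concentration series
#'
#' Multi-step (saturating) secondary nucleation with n_c = n_2 = 2 and
#' K_M = 8.24 uM^2, which places the 1-9 uM series in the partially
#' saturated regime: the local scaling exponent runs from near -3/2 at 1 uM
#' toward -1/2 at 9 uM, and K_M is anchored (by root-finding at design
#' time) so that the series-average designed exponent is gamma = -1.0, the
#' standard value for amyloid-beta 42 under quiescent plate-reader
#' conditions. Time is in hours for this fixture; the rate products set the
#' 3 uM half time to ~2.5 h with kappa/lambda ~ 17 (strongly
#' secondary-dominated), typical of this peptide.
#'
#' @return A [kinetic_params] object.
#' @export
default_tht_params <- function() {
  kinetic_params(kp_kn = 1.26e-3, kp_k2 = 0.252, n_c = 2, n_2 = 2, K_M = 8.24)
}

#' Default ground-truth parameters for the 19F-NMR decay fixture
#'
#' Saturating-model parameters anchored so that the model half time at
#' 50 uM is exactly 258 min: starting from the ThT shape parameters with
#' K_M = 300 uM^2, both rate products are rescaled by the square of the
#' required time factor (the time-rescaling symmetry of the rate law), which
#' moves the half time onto the anchor without changing the curve shape.
#'
#' @param tau_target target half time in minutes at `m0`.
#' @param m0 monomer concentration of the experiment (uM).
#' @return A [kinetic_params] object.
#' @export
default_f19_params <- function(tau_target = 258, m0 = 50) {
  p0 <- kinetic_params(kp_kn = 3.5e-7, kp_k2 = 7e-5, n_c = 2, n_2 = 2,
                       K_M = 300)
  tau0 <- model_halftime(p0, m0)
  a <- tau0 / tau_target   # t -> t/a under k -> a k, i.e. products -> a^2
  kinetic_params(kp_kn = p0$kp_kn * a^2, kp_k2 = p0$kp_k2 * a^2,
                 n_c = p0$n_c, n_2 = p0$n_2, K_M = p0$K_M)
}

#' Generate a synthetic ThT plate-reader dataset
#'
#' One well per (concentration, replicate). Each well's signal is
#' `baseline + gain * m0 * M(t)/m0` plus i.i.d. Gaussian noise with standard
#' deviation `noise_sd * gain * m0` (amplitude-proportional). The returned
#' ground truth records the generating parameters, the per-concentration
#' model half times, the designed scaling exponent (from those noiseless
#' half times) and the designed plateau slope (= `gain`).
#'
#' @param spec a [synthetic_spec].
#' @param dir optional output directory; when given, writes `traces.csv`,
#'   `meta.json` and `truth.json` there.
#' @return List with `traces` (named list of [aggregation_trace]), `meta`
#'   (well metadata list), `truth` (ground-truth list), and `files` (paths,
#'   when `dir` was given).
#' @export
generate_tht_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  traces <- list()
  meta <- list()
  for (ci in seq_along(spec$concentrations)) {
    m0 <- spec$concentrations[ci]
    curve <- mass_fraction_closed(spec$params, spec$t_grid, m0)
    amp <- spec$gain * m0
    for (r in seq_len(spec$n_replicates)) {
      well <- sprintf("c%02d_r%d", ci, r)
      noise <- if (spec$noise_sd > 0)
        stats::rnorm(length(curve), 0, spec$noise_sd * amp) else 0
      traces[[well]] <- aggregation_trace(
        spec$t_grid, spec$baseline + amp * curve + noise,
        m0 = m0, replicate_id = well, modality = "tht",
        direction = "rising")
      meta[[well]] <- list(m0_uM = m0, replicate = well,
                           modality = "tht", direction = "rising")
    }
  }
  tau <- vapply(spec$concentrations, function(m)
    model_halftime(spec$params, m), numeric(1))
  designed_gamma <- if (length(unique(spec$concentrations)) >= 3L)
    scaling_exponent(spec$concentrations, tau)$gamma else NA_real_
  truth <- list(
    params = jsonlite::fromJSON(params_to_json(spec$params)),
    concentrations_uM = spec$concentrations,
    model_halftimes = tau,  # in the time unit of the spec's t_grid/params
    designed_gamma = designed_gamma,
    designed_plateau_slope_au_per_uM = spec$gain,
    baseline_au = spec$baseline,
    noise_sd_fraction = spec$noise_sd,
    n_replicates = spec$n_replicates,
    seed = spec$seed)
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- file.path(dir, c("traces.csv", "meta.json", "truth.json"))
    write_traces(traces, files[1], files[2])
    jsonlite::write_json(truth, files[3], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  list(traces = traces, meta = meta, truth = truth, files = files)
}

#' Generate a synthetic 19F-NMR signal-decay trace
#'
#' A declining trace at a single concentration:
#' `baseline + amplitude * (1 - M(t)/m0)` plus noise. The default parameters
#' ([default_f19_params]) anchor the model half time at 50 uM to 258 min.
#'
#' @param m0 monomer concentration (uM), default 50.
#' @param params ground-truth [kinetic_params].
#' @param t_grid time grid (min).
#' @param noise_sd noise as a fraction of `amplitude` (default 0.03).
#' @param baseline residual signal level at completion (a.u.).
#' @param amplitude signal amplitude (a.u.).
#' @param seed mandatory integer seed.
#' @param dir optional output directory (`f19_trace.csv`, `f19_meta.json`,
#'   `f19_truth.json`).
#' @return List with `trace` (an [aggregation_trace], direction
#'   `"declining"`), `truth` (including the model half time) and `files`.
#' @export
generate_f19_trace <- function(m0 = 50, params = default_f19_params(),
                               t_grid = seq(0, 600, by = 2),
                               noise_sd = 0.03, baseline = 50,
                               amplitude = 1000, seed, dir = NULL) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer seed is mandatory")
  set.seed(as.integer(seed))
  curve <- mass_fraction_closed(params, t_grid, m0)
  noise <- if (noise_sd > 0)
    stats::rnorm(length(curve), 0, noise_sd * amplitude) else 0
  tr <- aggregation_trace(t_grid, baseline + amplitude * (1 - curve) + noise,
                          m0 = m0, replicate_id = "f19_r1", modality = "f19",
                          direction = "declining")
  truth <- list(params = jsonlite::fromJSON(params_to_json(params)),
                m0_uM = m0, model_halftime_min = model_halftime(params, m0),
                amplitude_au = amplitude, baseline_au = baseline,
                noise_sd_fraction = noise_sd, seed = as.integer(seed))
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- file.path(dir, c("f19_trace.csv", "f19_meta.json",
                              "f19_truth.json"))
    write_traces(list(f19 = tr), files[1], files[2])
    jsonlite::write_json(truth, files[3], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  list(trace = tr, truth = truth, files = files)
}

#' Two-state CD basis spectra with a designed isodichroic point
#'
#' Smooth synthetic coil and beta-sheet basis spectra (Gaussian-band
#' parameterizations of the canonical shapes: coil minimum near 198 nm;
#' beta positive band near 196 nm and minimum near 218 nm). The beta
#' spectrum is offset so the two bases cross exactly once in [200, 215] nm,
#' at `iso_nm`: every two-state mixture of the bases then passes through
#' that isodichroic point. Units are mean residue ellipticity (10^3 deg
#' cm^2/dmol).
#'
#' @param wavelengths wavelength grid in nm.
#' @param iso_nm designed isodichroic wavelength (default 208 nm).
#' @return Object of class `cd_basis`: list with `wavelength`, `coil`,
#'   `beta`, `iso_nm`.
#' @export
cd_basis <- function(wavelengths = seq(190, 260, by = 1), iso_nm = 208) {
  if (iso_nm < 200 || iso_nm > 215)
    stop("the designed isodichroic point must lie in [200, 215] nm")
  coil_f <- function(l) -22 * exp(-(l - 198)^2 / (2 * 8^2)) +
    1.5 * exp(-(l - 220)^2 / (2 * 12^2))
  beta0_f <- function(l) 14 * exp(-(l - 196)^2 / (2 * 6^2)) -
    13 * exp(-(l - 218)^2 / (2 * 9^2))
  offset <- coil_f(iso_nm) - beta0_f(iso_nm)
  beta_f <- function(l) beta0_f(l) + offset

  # two-state mixtures cross where coil == beta; require a unique crossing
  # (checked on a half-nm offset grid to avoid the designed exact zero)
  grid <- seq(200.25, 214.75, by = 0.5)  # offset to skip the designed zero
  dd <- coil_f(grid) - beta_f(grid)
  if (sum(diff(sign(dd)) != 0) != 1L || any(dd == 0))
    stop("basis spectra do not cross exactly once in [200, 215] nm")
  structure(list(wavelength = wavelengths, coil = coil_f(wavelengths),
                 beta = beta_f(wavelengths), iso_nm = iso_nm),
            class = "cd_basis")
}

#' Generate a synthetic CD spectral series for an aggregating sample
#'
#' A two-state mixture following the kinetic curve:
#' `s(lambda, t) = alpha(t) * coil(lambda) + (1 - alpha(t)) * beta(lambda)`
#' with `alpha(t) = 1 - M(t)/m0` the monomeric (coil) fraction, plus
#' optional Gaussian noise. All noiseless spectra intersect at the basis
#' crossing (the isodichroic point), the signature of a two-state
#' transition.
#'
#' @param params ground-truth [kinetic_params].
#' @param m0 monomer concentration (uM), default 10.
#' @param times spectrum acquisition times (min).
#' @param basis a [cd_basis].
#' @param noise_sd absolute noise per (wavelength, time) point in mean
#'   residue ellipticity units (default 0).
#' @param seed integer seed (required when `noise_sd > 0`).
#' @param csv optional path: writes wavelength rows x time columns.
#' @return List with `wavelength`, `times`, `spectra` (matrix wavelength x
#'   time), `alpha` (coil fraction), `basis`, `truth` (incl. the alpha half
#'   time).
#' @export
generate_cd_series <- function(params = default_tht_params(), m0 = 10,
                               times = seq(0, 300, by = 15),
                               basis = cd_basis(), noise_sd = 0, seed = NULL,
                               csv = NULL) {
  stopifnot(inherits(basis, "cd_basis"))
  curve <- mass_fraction_closed(params, times, m0)
  alpha <- 1 - curve
  spectra <- outer(basis$coil, alpha) + outer(basis$beta, 1 - alpha)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed is required when noise_sd > 0")
    set.seed(as.integer(seed))
    spectra <- spectra + stats::rnorm(length(spectra), 0, noise_sd)
  }
  dimnames(spectra) <- list(NULL, sprintf("t_%g", times))
  truth <- list(m0_uM = m0, alpha = alpha,
                alpha_halftime_min = model_halftime(params, m0),
                iso_nm = basis$iso_nm)
  if (!is.null(csv)) {
    df <- data.frame(wavelength = basis$wavelength, spectra,
                     check.names = FALSE)
    utils::write.csv(df, csv, row.names = FALSE)
  }
  list(wavelength = basis$wavelength, times = times, spectra = spectra,
       alpha = alpha, basis = basis, truth = truth)
}

#' Extract CD-extreme time courses from a spectral series
#'
#' Returns the time courses at the wavelengths nearest the coil minimum
#' (198 nm, rising toward beta) and the beta minimum (218 nm, declining) as
#' [aggregation_trace] objects, the standard way a two-state CD kinetic
#' series is reduced to aggregation traces.
#'
#' @param series output of [generate_cd_series] (or a compatible list).
#' @param extremes the two wavelengths to track (nm).
#' @return Named list of two [aggregation_trace] objects (`"198"`, `"218"`
#'   by default).
#' @export
cd_extreme_traces <- function(series, extremes = c(198, 218)) {
  out <- lapply(extremes, function(wl) {
    i <- which.min(abs(series$wavelength - wl))
    y <- series$spectra[i, ]
    aggregation_trace(series$times, as.numeric(y),
                      m0 = series$truth$m0_uM %||% NA_real_,
                      replicate_id = paste0("cd", wl),
                      modality = "cd_extreme",
                      direction = if (y[length(y)] >= y[1]) "rising"
                                  else "declining")
  })
  names(out) <- as.character(extremes)
  out
}
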