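#' Construct an aggregation trace
#'
#' One experimental (or synthetic) time series: a ThT fluorescence curve, a
#' 19F-NMR signal-decay curve, or the time course of a CD extreme, with its
#' initial monomer concentration and replicate label.
#'
#' @param time numeric vector, strictly increasing (minutes in all shipped
#'   defaults).
#' @param signal numeric vector, same length as `time` (arbitrary units).
#' @param m0 initial monomer concentration in uM (may be `NA` for traces
#'   whose concentration is irrelevant, e.g. a bare CD extreme).
#' @param replicate_id replicate label.
#' @param modality one of `"tht"`, `"f19"`, `"cd_extreme"`.
#' @param direction `"rising"` (signal grows with aggregation, e.g. ThT) or
#'   `"declining"` (signal decays, e.g. 19F monomer signal).
#' @return An object of class `aggregation_trace`.
#' @export
aggregation_trace <- function(time, signal, m0 = NA_real_,
                              replicate_id = "r1",
                              modality = c("tht", "f19", "cd_extreme"),
                              direction = c("rising", "declining")) {
  modality <- match.arg(modality)
  direction <- match.arg(direction)
  if (!is.numeric(time) || !is.numeric(signal))
    stop("time and signal must be numeric")
  if (length(time) != length(signal))
    stop("time and signal must have equal length")
  if (length(time) < 10L)
    stop("a trace needs at least 10 points (got ", length(time), ")")
  if (anyNA(time) || any(diff(time) <= 0))
    stop("time must be strictly increasing without NA")
  if (!is.na(m0) && m0 <= 0) stop("m0 must be > 0 (or NA)")
  structure(
    list(time = unname(as.numeric(time)), signal = unname(as.numeric(signal)),
         m0 = unname(as.numeric(m0)),
         replicate_id = unname(as.character(replicate_id)),
         modality = modality, direction = direction),
    class = "aggregation_trace"
  )
}

#' @export
print.aggregation_trace <- function(x, ...) {
  cat(sprintf("<aggregation_trace %s/%s> %d points, t in [%g, %g], m0 = %s uM\n",
              x$modality, x$replicate_id, length(x$time),
              min(x$time), max(x$time),
              if (is.na(x$m0)) "?" else format(x$m0)))
  invisible(x)
}

trace_label <- function(trace) {
  paste0(trace$modality, ":", trace$replicate_id,
         if (!is.na(trace$m0)) paste0("@", trace$m0, "uM") else "")
}

#' Normalize a trace to the unit aggregation extent
#'
#' Maps the fitted sigmoid baseline to 0 and the fitted plateau to 1, so the
#' signal becomes the aggregation extent. Declining traces (e.g. 19F monomer
#' decay) are thereby flipped to rising; the original orientation is kept in
#' the `orig_direction` attribute. Baseline and plateau come from the
#' four-parameter logistic fit of [fit_sigmoid], not from raw extrema, for
#' noise robustness.
#'
#' @param trace an [aggregation_trace].
#' @return The normalized [aggregation_trace] (direction `"rising"`), with
#'   attributes `orig_direction`, `norm_base`, `norm_plateau` and
#'   `normalized = TRUE`.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "aggregation_trace"))
  est <- tryCatch(fit_sigmoid(trace),
                  error = function(e)
                    stop("cannot normalize trace ", trace_label(trace), ": ",
                         conditionMessage(e), call. = FALSE))
  span <- est$plateau - est$base
  if (abs(span) < .Machine$double.eps^0.5 * max(abs(c(est$base, est$plateau)), 1))
    stop("cannot normalize trace ", trace_label(trace),
         ": no resolvable transition (plateau equals baseline)")
  out <- trace
  out$signal <- (trace$signal - est$base) / span  # span < 0 flips declining
  out$direction <- "rising"
  attr(out, "orig_direction") <- trace$direction
  attr(out, "norm_base") <- est$base
  attr(out, "norm_plateau") <- est$plateau
  attr(out, "normalized") <- TRUE
  out
}

#' Average replicate traces
#'
#' Pointwise mean of replicate traces sharing the same monomer concentration
#' and modality. Traces are linearly interpolated onto the time points of the
#' first trace restricted to the intersection of all time ranges (no
#' extrapolation).
#'
#' @param traces a list of [aggregation_trace] objects.
#' @return An [aggregation_trace] with `replicate_id = "mean"` and an
#'   `n_replicates` attribute.
#' @export
average_replicates <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  lapply(traces, function(x) stopifnot(inherits(x, "aggregation_trace")))
  m0s <- vapply(traces, function(x) x$m0, numeric(1))
  if (length(unique(stats::na.omit(m0s))) > 1L)
    stop("replicates have mixed monomer concentrations: ",
         paste(unique(m0s), collapse = ", "))
  mods <- unique(vapply(traces, function(x) x$modality, character(1)))
  if (length(mods) > 1L)
    stop("replicates have mixed modalities: ", paste(mods, collapse = ", "))

  lo <- max(vapply(traces, function(x) min(x$time), numeric(1)))
  hi <- min(vapply(traces, function(x) max(x$time), numeric(1)))
  if (lo >= hi) stop("trace time ranges do not overlap")
  grid <- traces[[1]]$time[traces[[1]]$time >= lo & traces[[1]]$time <= hi]
  if (length(grid) < 10L) stop("fewer than 10 common time points")

  mat <- vapply(traces,
                function(x) stats::approx(x$time, x$signal, xout = grid)$y,
                numeric(length(grid)))
  avg <- aggregation_trace(grid, rowMeans(mat), m0 = m0s[1],
                           replicate_id = "mean", modality = mods,
                           direction = traces[[1]]$direction)
  attr(avg, "n_replicates") <- length(traces)
  if (isTRUE(attr(traces[[1]], "normalized"))) attr(avg, "normalized") <- TRUE
  avg
}

#' Read a wide trace CSV with its JSON metadata
#'
#' The CSV has a `time` column plus one signal column per well; the JSON
#' metadata maps each well id to
#' `{"m0_uM": <num>, "replicate": <str>, "modality": "tht"|"f19"|"cd_extreme",
#' "direction": "rising"|"declining"}`.
#'
#' @param csv path to the trace CSV.
#' @param meta path to the metadata JSON (or an already-parsed list).
#' @return A named list of [aggregation_trace] objects (one per well).
#' @export
read_traces <- function(csv, meta) {
  df <- utils::read.csv(csv, check.names = FALSE)
  if (!"time" %in% names(df)) stop("trace CSV must contain a 'time' column")
  if (is.character(meta)) meta <- jsonlite::fromJSON(meta, simplifyVector = FALSE)
  wells <- setdiff(names(df), "time")
  missing <- setdiff(wells, names(meta))
  if (length(missing))
    stop("wells missing from metadata: ", paste(missing, collapse = ", "))
  out <- lapply(wells, function(w) {
    m <- meta[[w]]
    aggregation_trace(df$time, df[[w]],
                      m0 = if (is.null(m$m0_uM)) NA_real_ else m$m0_uM,
                      replicate_id = if (is.null(m$replicate)) w else m$replicate,
                      modality = if (is.null(m$modality)) "tht" else m$modality,
                      direction = if (is.null(m$direction)) "rising" else m$direction)
  })
  names(out) <- wells
  out
}

#' Write traces to the wide CSV + JSON metadata dialect
#'
#' Inverse of [read_traces]; all traces must share one time grid.
#'
#' @param traces named list of [aggregation_trace] objects.
#' @param csv,meta output paths.
#' @return Invisibly, the CSV path.
#' @export
write_traces <- function(traces, csv, meta) {
  stopifnot(length(traces) >= 1L)
  if (is.null(names(traces)) || anyNA(names(traces)) || any(names(traces) == ""))
    names(traces) <- vapply(traces, function(x) x$replicate_id, character(1))
  t0 <- traces[[1]]$time
  for (tr in traces)
    if (!isTRUE(all.equal(tr$time, t0)))
      stop("write_traces requires a shared time grid")
  df <- data.frame(time = t0, check.names = FALSE)
  for (w in names(traces)) df[[w]] <- traces[[w]]$signal
  utils::write.csv(df, csv, row.names = FALSE)
  md <- lapply(traces, function(x)
    list(m0_uM = x$m0, replicate = x$replicate_id,
         modality = x$modality, direction = x$direction))
  jsonlite::write_json(md, meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv)
}
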