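#' Pacing protocol
#'
#' Standard pacing: 1-ms current stimuli of 60 pA/pF at a fixed cycle
#' length.
#'
#' @param CL cycle length (ms), at least 100.
#' @param amplitude stimulus amplitude (pA/pF).
#' @param width stimulus width (ms).
#' @return object of class \code{tp06_protocol}.
#' @export
make_pacing <- function(CL, amplitude = 60, width = 1) {
  if (CL < 100) stop("CL must be >= 100 ms")
  if (CL <= width) stop("CL must exceed the stimulus width")
  if (width <= 0) stop("stimulus width must be positive")
  if (amplitude < 0) stop("stimulus amplitude must be >= 0")
  structure(list(CL = CL, amplitude = amplitude, width = width),
            class = "tp06_protocol")
}

#' Voltage-clamp pulse-train protocol
#'
#' Repeated step depolarisations from a holding potential, the default
#' being 1-s steps from -85 mV to -10 mV at 0.5 Hz.
#'
#' @param V_hold holding potential (mV).
#' @param V_test test potential (mV).
#' @param pulse_ms pulse duration (ms).
#' @param period_ms pulse-train period (ms).
#' @param duration_min train duration (simulated minutes).
#' @return object of class \code{tp06_clamp_protocol}.
#' @export
make_clamp_protocol <- function(V_hold = -85, V_test = -10,
                                pulse_ms = 1000, period_ms = 2000,
                                duration_min = 10) {
  if (pulse_ms <= 0 || period_ms <= pulse_ms || duration_min <= 0)
    stop("invalid clamp protocol: need 0 < pulse < period and duration > 0")
  structure(list(V_hold = V_hold, V_test = V_test, pulse_ms = pulse_ms,
                 period_ms = period_ms, duration_min = duration_min),
            class = "tp06_clamp_protocol")
}

#' Regular parameter grid
#'
#' @param axis axis name: a scaling knob or \code{"CL"}.
#' @param from,to,by range and step.
#' @param descending traverse from \code{to} down to \code{from} (the
#'   warm-start chaining order is part of the grid definition because
#'   hysteresis can make sweep results order-dependent).
#' @return object of class \code{tp06_grid} with a \code{values} vector in
#'   traversal order.
#' @export
make_grid <- function(axis, from, to, by, descending = FALSE) {
  if (!(axis %in% c(.tp06_scale_names, "CL")))
    stop("unknown axis: ", axis)
  if (by <= 0) stop("grid step must be positive")
  if (!is.finite(from) || !is.finite(to)) stop("grid range must be finite")
  v <- seq(from, to, by = by)
  if (descending) v <- rev(v)
  structure(list(axis = axis, from = from, to = to, by = by,
                 descending = descending, values = v),
            class = "tp06_grid")
}

#' Beta-adrenergic stimulation scaling set
#'
#' Multiplicative scalings mimicking beta-adrenergic stimulation; the
#' principal effects are the increases of the L-type Ca2+ conductance (up
#' to 250\%), the slow delayed-rectifier conductance (up to 200\%) and the
#' SR Ca2+ uptake rate.  Additional scalings may be supplied via
#' \code{extra} (e.g. from a transcription of a published full table).
#'
#' @param gCaL_fold,gKs_fold,Pup_fold fold changes (> 0).
#' @param extra named list of further scaling folds.
#' @return named numeric vector usable as \code{overrides} in
#'   \code{\link{build_parameters}}.
#' @export
beta_as_scalings <- function(gCaL_fold = 2.5, gKs_fold = 2.0,
                             Pup_fold = 2.0, extra = list()) {
  folds <- c(gCaL = gCaL_fold, gKs = gKs_fold, Pup = Pup_fold,
             unlist(extra))
  if (any(folds <= 0)) stop("fold changes must be > 0")
  bad <- setdiff(names(folds), .tp06_scale_names)
  if (length(bad)) stop("unknown scaling(s): ", paste(bad, collapse = ", "))
  folds
}

#' Short regression fixture trace
#'
#' Simulates a short paced trace under a variant and protocol and returns
#' it together with full provenance, for bit-level regression testing of
#' the integrator stack.
#'
#' @param variant model variant.
#' @param protocol pacing protocol.
#' @param n_beats number of beats.
#' @param overrides normalized scaling overrides.
#' @return a \code{tp06_paced} object whose \code{provenance} field records
#'   variant, scalings, protocol and solver tolerances.
#' @export
regression_fixture <- function(variant = "mTP06b", protocol = make_pacing(2000),
                               n_beats = 5, overrides = list()) {
  params <- build_parameters(variant, overrides = overrides)
  tr <- simulate_paced(params, protocol, n_beats = n_beats, stop = "beats")
  tr$provenance <- list(variant = variant, overrides = overrides,
                        protocol = unclass(protocol),
                        rtol = .default_rtol, atol = .default_atol())
  tr
}
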