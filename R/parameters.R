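#' @useDynLib mtp06, .registration = TRUE
#' @importFrom stats approx optimize setNames
#' @importFrom utils modifyList write.csv
NULL

## state variable names, in the order used by the compiled model
.tp06_state_names <- c("V", "m", "h", "j", "d", "f", "f2", "fCass",
                       "xr1", "xr2", "xs", "r", "s", "Rbar",
                       "Nai", "Ki", "Cai", "Cass", "CaSR")

## baseline M-cell constants (ms, mV, mM, pA/pF convention)
.tp06_base <- c(
  gNa = 14.838, gK1 = 5.405, gto = 0.294, gKr = 0.153, gKs = 0.098,
  gCaL = 3.98e-5, gbNa = 0.00029, gbCa = 0.000592, gpK = 0.0146,
  gpCa = 0.1238, PNaK = 2.724, kNaCa = 1000, Pup = 0.006375,
  Vrel = 0.102, Vleak = 0.00036, Vxfer = 0.0038,
  Ko = 5.4, Nao = 140, Cao = 2.0
)

## scaling knobs recognised in presets, overrides and beta-AS sets
.tp06_scale_names <- c("gNa", "gK1", "gto", "gKr", "gKs", "gCaL", "gbNa",
                       "gbCa", "gpK", "gpCa", "PNaK", "NCX", "Pup",
                       "Vrel", "Vleak", "Vxfer", "tau_fL", "tau_f", "tau_f2")

.tp06_presets <- list(
  original = c(),
  mTP06a = c(gKs = 0.4, gKr = 1.5, Pup = 0.6),
  mTP06b = c(gKs = 0.4, gKr = 1.5, Pup = 0.6, tau_fL = 0.5, gCaL = 2.0)
)

#' Build a model parameter set
#'
#' Constructs a full parameter set for the TP06 M-cell model or one of its
#' modified variants.  The \code{mTP06a} variant reduces the maximum I_Ks
#' conductance to 40\% of control, raises the maximum I_Kr conductance by
#' 50\% and reduces the SR Ca2+ uptake rate to 60\% of control; the
#' \code{mTP06b} variant additionally halves the voltage-dependent I_CaL
#' inactivation time constants and doubles the maximum I_CaL conductance.
#'
#' Scaling overrides are interpreted as \emph{normalized} values, i.e.
#' ratios to the control value of the active variant, and are applied
#' multiplicatively on top of the variant preset.  For example
#' \code{build_parameters("mTP06b", list(gKr = 0.4))} yields an effective
#' I_Kr conductance of \code{1.5 * 0.4} times the original TP06 value.
#'
#' @param variant one of \code{"original"}, \code{"mTP06a"}, \code{"mTP06b"}.
#' @param overrides named list/vector of normalized scale factors; names
#'   must be scaling knobs (\code{gKs}, \code{gKr}, \code{gCaL}, \code{Pup},
#'   \code{NCX}, \code{tau_fL}, \code{tau_f}, \code{tau_f2}, ...).
#' @param fix_Ki fix myoplasmic K+ (used for bifurcation analyses).
#' @param Ki_value fixed K+ concentration (mM).
#' @param fix_Nai fix myoplasmic Na+ (slow-fast and voltage-clamp analyses).
#' @param Nai_value fixed Na+ concentration (mM).
#' @param clamp_Vm clamp the membrane potential.
#' @param Vm_value clamped potential (mV).
#' @param stim_in_Ki logical; carry the stimulus charge in the K+ balance
#'   (charge-conservative convention).
#' @return an object of class \code{tp06_params}.
#' @export
build_parameters <- function(variant = c("original", "mTP06a", "mTP06b"),
                             overrides = list(),
                             fix_Ki = FALSE, Ki_value = 140,
                             fix_Nai = FALSE, Nai_value = 6,
                             clamp_Vm = FALSE, Vm_value = -85,
                             stim_in_Ki = TRUE) {
  variant <- match.arg(variant)
  overrides <- unlist(overrides)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), .tp06_scale_names)
    if (length(bad))
      stop("unknown scaling override(s): ", paste(bad, collapse = ", "))
    if (any(overrides < 0)) stop("scale factors must be >= 0")
  }
  scale <- setNames(rep(1, length(.tp06_scale_names)), .tp06_scale_names)
  preset <- .tp06_presets[[variant]]
  scale[names(preset)] <- preset
  norm <- setNames(rep(1, length(.tp06_scale_names)), .tp06_scale_names)
  if (length(overrides)) norm[names(overrides)] <- overrides
  structure(list(
    variant = variant,
    base = .tp06_base,
    preset = scale,       # multipliers defining the variant control
    normalized = norm,    # user scalings relative to the variant control
    fix_Ki = fix_Ki, Ki_value = Ki_value,
    fix_Nai = fix_Nai, Nai_value = Nai_value,
    clamp_Vm = clamp_Vm, Vm_value = Vm_value,
    freeze = setNames(rep(FALSE, 19), .tp06_state_names),
    freeze_values = setNames(rep(NA_real_, 19), .tp06_state_names),
    stim_in_Ki = stim_in_Ki
  ), class = "tp06_params")
}

#' Effective multipliers relative to the original TP06 constants
#' @param params a \code{tp06_params} object.
#' @return named numeric vector of effective scale factors.
#' @export
effective_scales <- function(params) {
  stopifnot(inherits(params, "tp06_params"))
  params$preset * params$normalized
}

#' @export
print.tp06_params <- function(x, ...) {
  eff <- effective_scales(x)
  cat("TP06 M-cell parameter set, variant:", x$variant, "\n")
  ns <- eff[eff != 1]
  if (length(ns)) {
    cat("  effective scalings (vs original TP06):\n")
    for (n in names(ns)) cat(sprintf("    %-8s %.4g\n", n, ns[[n]]))
  } else cat("  all scalings at 1 (original constants)\n")
  if (x$fix_Ki) cat("  K_i fixed at", x$Ki_value, "mM\n")
  if (x$fix_Nai) cat("  Na_i fixed at", x$Nai_value, "mM\n")
  if (x$clamp_Vm) cat("  V_m clamped at", x$Vm_value, "mV\n")
  fr <- names(x$freeze)[x$freeze]
  if (length(fr)) cat("  frozen state variables:", paste(fr, collapse = ", "), "\n")
  invisible(x)
}

#' Freeze additional state variables (slow-fast decomposition)
#'
#' Returns a copy of \code{params} in which the named state variables are
#' held constant at the given values; their derivatives are forced to zero
#' and initial states are overwritten accordingly.
#'
#' @param params a \code{tp06_params} object.
#' @param ... named fixed values, e.g. \code{xs = 0.2, CaSR = 1.5}.
#' @return modified \code{tp06_params}.
#' @export
freeze_states <- function(params, ...) {
  vals <- unlist(list(...))
  bad <- setdiff(names(vals), .tp06_state_names)
  if (length(bad)) stop("unknown state variable(s): ", paste(bad, collapse = ", "))
  for (n in names(vals)) {
    if ((n == "V" && params$clamp_Vm && vals[[n]] != params$Vm_value))
      stop("V is already clamped at a different value")
    params$freeze[n] <- TRUE
    params$freeze_values[n] <- vals[[n]]
  }
  params
}

## translate a parameter set into the compiled model's parameter vector
param_cvec <- function(params, stim = 0) {
  stopifnot(inherits(params, "tp06_params"))
  eff <- effective_scales(params)
  b <- params$base
  p <- c(b[["gNa"]] * eff[["gNa"]], b[["gK1"]] * eff[["gK1"]],
         b[["gto"]] * eff[["gto"]], b[["gKr"]] * eff[["gKr"]],
         b[["gKs"]] * eff[["gKs"]], b[["gCaL"]] * eff[["gCaL"]],
         b[["gbNa"]] * eff[["gbNa"]], b[["gbCa"]] * eff[["gbCa"]],
         b[["gpK"]] * eff[["gpK"]], b[["gpCa"]] * eff[["gpCa"]],
         b[["PNaK"]] * eff[["PNaK"]], b[["kNaCa"]] * eff[["NCX"]],
         b[["Pup"]] * eff[["Pup"]], b[["Vrel"]] * eff[["Vrel"]],
         b[["Vleak"]] * eff[["Vleak"]], b[["Vxfer"]] * eff[["Vxfer"]],
         b[["Ko"]], b[["Nao"]], b[["Cao"]],
         eff[["tau_fL"]] * eff[["tau_f"]],
         eff[["tau_fL"]] * eff[["tau_f2"]],
         stim, as.numeric(params$stim_in_Ki))
  freeze <- params$freeze
  if (params$fix_Ki) freeze["Ki"] <- TRUE
  if (params$fix_Nai) freeze["Nai"] <- TRUE
  if (params$clamp_Vm) freeze["V"] <- TRUE
  c(p, as.numeric(freeze))
}

## impose fixed/clamped values on a state vector
apply_clamps <- function(state, params) {
  state <- as_state(state)
  if (params$fix_Ki) state["Ki"] <- params$Ki_value
  if (params$fix_Nai) state["Nai"] <- params$Nai_value
  if (params$clamp_Vm) state["V"] <- params$Vm_value
  frozen <- names(params$freeze)[params$freeze]
  for (n in frozen) {
    if (!is.na(params$freeze_values[n])) state[n] <- params$freeze_values[n]
  }
  state
}

as_state <- function(state) {
  state <- unlist(state)
  if (length(state) != 19)
    stop("state vector must have length 19, got ", length(state))
  if (is.null(names(state))) names(state) <- .tp06_state_names
  if (!all(.tp06_state_names %in% names(state)))
    stop("state vector is missing required variables")
  state[.tp06_state_names]   # NaN/Inf pass through to the finiteness checks
}

#' State variable names of the model
#' @return character vector of length 19.
#' @export
state_names <- function() .tp06_state_names
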