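.current_names <- c("I_Na", "I_CaL", "I_Kr", "I_Ks", "I_to", "I_K1",
                    "I_pK", "I_bNa", "I_bCa", "I_NaK", "I_NCX", "I_pCa",
                    "J_up", "J_rel", "J_leak", "J_xfer")

#' Right-hand side of the model
#'
#' Evaluates the time derivative of the 19-variable state.  Derivative
#' entries for variables that are fixed (K_i, Na_i), clamped (V_m) or frozen
#' (slow-fast decomposition) are exactly zero.
#'
#' @param t time (ms); the autonomous model ignores it.
#' @param state named numeric state vector (see \code{\link{state_names}}).
#' @param params a \code{tp06_params} object.
#' @param stim applied stimulus current (pA/pF), depolarising positive.
#' @return named numeric vector of derivatives (per ms).
#' @export
rhs <- function(t, state, params, stim = 0) {
  state <- as_state(state)
  if (!all(is.finite(state))) {
    bad <- names(state)[!is.finite(state)]
    stop("non-finite state variable(s): ", paste(bad, collapse = ", "))
  }
  out <- .Call(C_tp06_rhs, as.numeric(state), param_cvec(params, stim))
  setNames(out$deriv, .tp06_state_names)
}

#' Membrane currents and SR fluxes at a state
#'
#' @inheritParams rhs
#' @return named numeric vector: the 12 sarcolemmal currents (pA/pF) and the
#'   SR uptake, release, leak and subspace-transfer fluxes (mM/ms).
#' @export
compute_currents <- function(state, params) {
  state <- as_state(state)
  if (!all(is.finite(state))) {
    bad <- names(state)[!is.finite(state)]
    stop("non-finite state variable(s): ", paste(bad, collapse = ", "))
  }
  out <- .Call(C_tp06_rhs, as.numeric(state), param_cvec(params, 0))
  setNames(out$aux, .current_names)
}

#' Voltage-dependent steady-state gate values
#'
#' Steady-state (infinity) curves of the voltage-gated channels, used to
#' build resting initial conditions and the steady-state xs^2 curve of the
#' slow-fast decomposition.
#'
#' @param V membrane potential (mV), vectorised.
#' @return a data.frame with one row per voltage and one column per gate.
#' @export
gate_steady_state <- function(V) {
  data.frame(
    V = V,
    m = 1 / (1 + exp((-56.86 - V) / 9.03))^2,
    h = 1 / (1 + exp((V + 71.55) / 7.43))^2,
    j = 1 / (1 + exp((V + 71.55) / 7.43))^2,
    d = 1 / (1 + exp((-8 - V) / 7.5)),
    f = 1 / (1 + exp((V + 20) / 7)),
    f2 = 0.67 / (1 + exp((V + 35) / 7)) + 0.33,
    xr1 = 1 / (1 + exp((-26 - V) / 7)),
    xr2 = 1 / (1 + exp((V + 88) / 24)),
    xs = 1 / (1 + exp((-5 - V) / 14)),
    r = 1 / (1 + exp((20 - V) / 6)),
    s = 1 / (1 + exp((V + 20) / 5))
  )
}

#' Resting-state initial conditions
#'
#' Gates are set to their voltage-dependent steady-state values at
#' \code{V_rest}; the Ca2+-dependent gates (fCass, Rbar) are equilibrated
#' against the supplied subspace/SR Ca2+; concentrations default to the
#' published resting values of the original M-cell model.
#'
#' For the P_up-reduced variants (mTP06a/b) the default concentrations are
#' lower-Ca_SR resting values consistent with their smaller SR load; the
#' g_Kr-reduced mTP06b cell is bistable, and pacing it from the original
#' model's high Ca_SR (4.272 mM) lands in a spurious EAD attractor.
#'
#' @param V_rest resting potential (mV), between -100 and -60.
#' @param params a \code{tp06_params} object.
#' @param Nai,Ki,Cai,Cass,CaSR initial concentrations (mM); defaults depend
#'   on the variant (see Details).
#' @return named state vector satisfying the model invariants.
#' @export
steady_state_initials <- function(V_rest = -85.423, params = build_parameters(),
                                  Nai = NULL, Ki = NULL, Cai = NULL,
                                  Cass = NULL, CaSR = NULL) {
  reduced_Pup <- effective_scales(params)[["Pup"]] < 1
  if (is.null(Nai)) Nai <- if (reduced_Pup) 10 else 10.132
  if (is.null(Ki)) Ki <- if (reduced_Pup) 140 else 138.52
  if (is.null(Cai)) Cai <- if (reduced_Pup) 1e-4 else 0.000153
  if (is.null(Cass)) Cass <- if (reduced_Pup) 2e-4 else 0.00042
  if (is.null(CaSR)) CaSR <- if (reduced_Pup) 1.5 else 4.272
  if (V_rest < -100 || V_rest > -60)
    stop("V_rest outside the physiological resting range (-100, -60) mV")
  g <- gate_steady_state(V_rest)
  fCass <- 0.6 / (1 + (Cass / 0.05)^2) + 0.4
  kcasr <- 2.5 - 1.5 / (1 + (1.5 / CaSR)^2)
  k2 <- 0.045 * kcasr
  Rbar <- 0.005 / (0.005 + k2 * Cass)  # dRbar/dt = 0 at this Cass, CaSR
  st <- c(V = V_rest, m = g$m, h = g$h, j = g$j, d = g$d, f = g$f,
          f2 = g$f2, fCass = fCass, xr1 = g$xr1, xr2 = g$xr2, xs = g$xs,
          r = g$r, s = g$s, Rbar = Rbar, Nai = Nai, Ki = Ki,
          Cai = Cai, Cass = Cass, CaSR = CaSR)
  apply_clamps(st, params)
}
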