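#' Simulate the voltage-clamped cell under a pulse train
#'
#' Clamps V_m to the protocol schedule (holding potential with periodic
#' step depolarisations) with Na_i and K_i fixed, and records the
#' intracellular Ca2+ concentrations (plus currents on request).
#'
#' @param params a \code{tp06_params} object; Na_i is fixed (default 6 mM)
#'   and K_i fixed at 140 mM.
#' @param protocol a \code{\link{make_clamp_protocol}} object.
#' @param init initial state; defaults to steady state at the holding
#'   potential (gates and Ca2+ subsystem relaxed under the clamp).
#' @param record state variables to record.
#' @param step output step (ms).
#' @param rtol,atol solver tolerances.
#' @return object of class \code{tp06_clamped}: \code{time},
#'   \code{states}, \code{V} (the clamp schedule), \code{pulse_onsets},
#'   \code{final_state}.
#' @export
simulate_clamped <- function(params, protocol, init = NULL,
                             record = c("Cai", "Cass", "CaSR"),
                             step = 2, rtol = .default_rtol,
                             atol = .default_atol()) {
  stopifnot(inherits(protocol, "tp06_clamp_protocol"))
  params$fix_Nai <- TRUE
  params$fix_Ki <- TRUE
  params$clamp_Vm <- TRUE
  n_pulses <- floor(protocol$duration_min * 60000 / protocol$period_ms)
  if (is.null(init)) {
    params$Vm_value <- protocol$V_hold
    st <- steady_state_initials(V_rest = protocol$V_hold, params = params)
    hold <- integrate_span(st, params, c(0, 60000), stim = 0,
                           rtol = rtol, atol = atol)
    init <- setNames(hold[nrow(hold), 2:20], .tp06_state_names)
  }
  rec_idx <- match(record, .tp06_state_names)
  state <- as_state(init)
  time_l <- list(); v_l <- list(); vm_l <- list()
  t0 <- 0
  for (p in seq_len(n_pulses)) {
    for (phase in 1:2) {
      params$Vm_value <- if (phase == 1) protocol$V_test else protocol$V_hold
      state["V"] <- params$Vm_value
      dur <- if (phase == 1) protocol$pulse_ms else
        protocol$period_ms - protocol$pulse_ms
      tt <- seq(0, dur, by = step)
      out <- integrate_span(state, params, tt, stim = 0,
                            rtol = rtol, atol = atol)
      state <- setNames(out[nrow(out), 2:20], .tp06_state_names)
      keep <- seq_len(nrow(out) - 1)
      time_l[[length(time_l) + 1]] <- t0 + out[keep, 1]
      v_l[[length(v_l) + 1]] <- out[keep, 1 + rec_idx, drop = FALSE]
      vm_l[[length(vm_l) + 1]] <- rep(params$Vm_value, length(keep))
      t0 <- t0 + dur
    }
  }
  states <- do.call(rbind, v_l)
  colnames(states) <- record
  structure(list(time = unlist(time_l), states = states,
                 V = unlist(vm_l),
                 pulse_onsets = (seq_len(n_pulses) - 1) * protocol$period_ms,
                 final_state = state, params = params, protocol = protocol),
            class = "tp06_clamped")
}

#' Detect spontaneous SR Ca2+ release events
#'
#' An event is an abrupt fall of Ca_SR — at least \code{drop_frac} of its
#' local value within \code{window} ms — accompanied by a rise in Ca_i.
#' Events whose onset lies within \code{pulse_grace} ms after a pulse onset
#' are flagged pulse-triggered and excluded from the spontaneous count.
#'
#' @param trace a \code{tp06_clamped} object (or data.frame with time,
#'   CaSR, Cai columns).
#' @param drop_frac fractional Ca_SR drop defining a release.
#' @param window detection window (ms).
#' @param pulse_grace exclusion window after pulse onsets (ms).
#' @param pulse_onsets pulse onset times when \code{trace} is a plain
#'   data.frame.
#' @return data.frame of events: onset, drop_mM, drop_frac, peak_Cai,
#'   pulse_triggered.
#' @export
detect_release_events <- function(trace, drop_frac = 0.05, window = 100,
                                  pulse_grace = 50, pulse_onsets = NULL) {
  if (inherits(trace, "tp06_clamped")) {
    time <- trace$time; casr <- trace$states[, "CaSR"]
    cai <- trace$states[, "Cai"]
    pulse_onsets <- trace$pulse_onsets
  } else {
    tr <- as.data.frame(trace)
    time <- tr$time; casr <- tr$CaSR; cai <- tr$Cai
  }
  n <- length(time)
  if (n < 3) return(.empty_events())
  dt <- stats::median(diff(time))
  k <- max(1L, round(window / dt))
  idx <- seq_len(n - k)
  drop <- (casr[idx] - casr[idx + k]) / casr[idx]
  hit <- drop >= drop_frac
  events <- list()
  i <- 1L
  while (i <= length(hit)) {
    if (!hit[i]) { i <- i + 1L; next }
    j <- i
    while (j < length(hit) && casr[j + 1] <= casr[j]) j <- j + 1L
    onset <- time[i]
    seg <- idx >= i & idx <= j + k
    dmax <- max((casr[i] - casr[i:min(j + k, n)]))
    peak_cai <- max(cai[i:min(j + k, n)])
    rise <- peak_cai > cai[i]
    ## the forward-looking drop criterion can fire up to one window before
    ## the drop itself, so the exclusion interval extends that far back
    ptrig <- !is.null(pulse_onsets) &&
      any(onset - pulse_onsets >= -window &
          onset - pulse_onsets <= pulse_grace)
    if (rise)
      events[[length(events) + 1]] <- data.frame(
        onset = onset, drop_mM = dmax, drop_frac = dmax / casr[i],
        peak_Cai = peak_cai, pulse_triggered = ptrig)
    ## skip past this event: wait until CaSR rises again for > window
    i <- j + k
    while (i <= length(hit) && hit[i]) i <- i + 1L
  }
  if (!length(events)) return(.empty_events())
  do.call(rbind, events)
}

.empty_events <- function() {
  data.frame(onset = numeric(0), drop_mM = numeric(0),
             drop_frac = numeric(0), peak_Cai = numeric(0),
             pulse_triggered = logical(0))
}

## equilibrium of the voltage-clamped Ca subsystem at a fixed potential
.clamped_ep <- function(params, Vm, init = NULL, relax_ms = 0) {
  params$clamp_Vm <- TRUE; params$Vm_value <- Vm
  params$fix_Nai <- TRUE; params$fix_Ki <- TRUE
  if (is.null(init)) init <- steady_state_initials(V_rest = -85, params = params)
  sol <- .ca_ep(params, Vm, params$Nai_value, init)
  if (is.null(sol)) return(NULL)
  list(state = sol, params = params, stability = ep_stability(sol, params))
}

#' Bifurcation diagram of the clamped Ca2+ subsystem versus V_m
#'
#' Scans the clamped membrane potential, locating the intracellular
#' steady state and its stability at each value, bisecting the two Hopf
#' points (H_1, H_2) bounding the unstable range, and optionally measuring
#' the spontaneous Ca2+ oscillation (CaO) extrema and period by direct
#' simulation inside the unstable range.
#'
#' @param params a \code{tp06_params} (Na_i fixed at 6 mM by convention).
#' @param V_values clamped-V_m grid (mV).
#' @param hb_tol V_m resolution of the Hopf bisection (mV).
#' @param oscillations if TRUE, simulate at each unstable grid point for
#'   CaO extrema/periods.
#' @param osc_ms simulation length for oscillation measurement.
#' @return object of class \code{tp06_ca_diagram}: \code{points} (V, Cai,
#'   Cass, stable, leading eigenvalue), \code{hopf} (bisected H values),
#'   optional \code{oscillations}.
#' @export
ca_bifurcation_vs_vm <- function(params, V_values = seq(-80, 20, by = 2),
                                 hb_tol = 0.05, oscillations = FALSE,
                                 osc_ms = 120000) {
  rows <- list(); prev <- NULL
  states <- list()
  add_row <- function(V, ep) {
    rows[[length(rows) + 1]] <<- data.frame(
      V = V, Cai = ep$state[["Cai"]], Cass = ep$state[["Cass"]],
      CaSR = ep$state[["CaSR"]], stable = ep$stability$stable,
      re_lead = Re(ep$stability$eigenvalues[1]),
      im_lead = Im(ep$stability$eigenvalues[1]))
    states[[as.character(V)]] <<- ep$state
  }
  for (V in V_values) {
    ep <- .clamped_ep(params, V, init = if (!is.null(prev)) prev$state)
    if (is.null(ep)) next
    add_row(V, ep)
    prev <- ep
  }
  ## backward retry for grid points the forward pass could not solve,
  ## warm-starting from the nearest solved neighbour
  missing <- setdiff(V_values, vapply(rows, function(r) r$V, 0))
  for (V in rev(missing)) {
    solved <- as.numeric(names(states))
    if (!length(solved)) break
    warm <- states[[as.character(solved[which.min(abs(solved - V))])]]
    ep <- .clamped_ep(params, V, init = warm)
    if (!is.null(ep)) add_row(V, ep)
  }
  pts <- do.call(rbind, rows)
  if (!is.null(pts)) pts <- pts[order(pts$V), ]
  hopf <- numeric(0)
  if (!is.null(pts) && nrow(pts) > 1) {
    flips <- which(diff(pts$stable) != 0)
    for (fl in flips) {
      lo <- pts$V[fl]; hi <- pts$V[fl + 1]
      st <- states[[as.character(lo)]]
      while (hi - lo > hb_tol) {
        mid <- (lo + hi) / 2
        ep <- .clamped_ep(params, mid, init = st, relax_ms = 5000)
        if (is.null(ep)) break
        st <- ep$state
        if (identical(ep$stability$stable, pts$stable[fl])) lo <- mid
        else hi <- mid
      }
      hopf <- c(hopf, (lo + hi) / 2)
    }
  }
  out <- list(points = pts, hopf = hopf, params = params)
  if (oscillations && length(hopf) == 2) {
    un <- pts$V[!pts$stable]
    osc <- lapply(un, function(V) {
      p <- params; p$clamp_Vm <- TRUE; p$Vm_value <- V
      p$fix_Nai <- TRUE; p$fix_Ki <- TRUE
      st <- states[[as.character(V)]]
      st["Cai"] <- st[["Cai"]] * 1.2 + 1e-5   # kick off the oscillation
      tr <- integrate_span(st, p, seq(0, osc_ms, by = 5), stim = 0)
      sel <- tr[, "time"] >= osc_ms / 2
      ca <- tr[sel, "Cai"]
      ex <- .find_extrema(tr[sel, "time"], ca, diff(range(ca)) / 20)
      pk <- tr[sel, "time"][ex$idx][ex$kind == 1L]
      data.frame(V = V, CaO_min = min(ca), CaO_max = max(ca),
                 period = if (length(pk) > 2) mean(diff(pk)) else NA_real_,
                 oscillating = diff(range(ca)) > 1e-5)
    })
    out$oscillations <- do.call(rbind, osc)
  }
  class(out) <- "tp06_ca_diagram"
  out
}

#' Hopf locus of the clamped Ca2+ subsystem in a (parameter, V_m) plane
#'
#' For each value of a scaling parameter, locates the pair of Hopf V_m
#' values bounding the unstable range of the intracellular steady state
#' (empty when the steady state is stable at all potentials).
#'
#' @param params base \code{tp06_params}.
#' @param axis scaling name: \code{"Pup"}, \code{"NCX"} or \code{"gCaL"}.
#' @param values normalized axis values.
#' @param V_values V_m scan grid (mV).
#' @param hb_tol Hopf bisection tolerance (mV).
#' @return data.frame: value, V_low, V_high (NA when no instability).
#' @export
hb_locus <- function(params, axis = c("Pup", "NCX", "gCaL"), values,
                     V_values = seq(-65, 15, by = 2), hb_tol = 0.1) {
  axis <- match.arg(axis)
  rows <- lapply(values, function(v) {
    pv <- .with_axis(params, axis, v)
    d <- ca_bifurcation_vs_vm(pv, V_values, hb_tol = hb_tol)
    if (length(d$hopf) >= 2)
      data.frame(value = v, V_low = min(d$hopf), V_high = max(d$hopf))
    else data.frame(value = v, V_low = NA_real_, V_high = NA_real_)
  })
  do.call(rbind, rows)
}
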