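## default solver tolerances: relative tolerance per the study protocol,
## absolute tolerances scaled to each variable's magnitude
.default_rtol <- 1e-8

.default_atol <- function() {
  a <- setNames(rep(1e-8, 19), .tp06_state_names)
  a[c("V", "Nai", "Ki")] <- 1e-6
  a[c("Cai", "Cass")] <- 1e-11
  a["CaSR"] <- 1e-8
  a
}

#' Integrate the model over a time span
#'
#' Low-level wrapper around the stiff solver working on the compiled model.
#' The stimulus current is held constant over the span; pacing protocols are
#' built by chaining spans (see \code{\link{simulate_paced}}).
#'
#' @param state named initial state vector.
#' @param params a \code{tp06_params} object.
#' @param times output time grid (ms); integration runs over its range.
#' @param stim constant applied current (pA/pF) over the span.
#' @param rtol,atol solver tolerances; \code{atol} may be per-variable.
#' @param with_currents if TRUE, auxiliary current/flux columns are returned.
#' @return deSolve matrix with one row per output time.
#' @export
integrate_span <- function(state, params, times, stim = 0,
                           rtol = .default_rtol, atol = .default_atol(),
                           with_currents = FALSE) {
  state <- apply_clamps(state, params)
  out <- deSolve::ode(
    y = as.numeric(state), times = times, func = "tp06_derivs",
    parms = param_cvec(params, stim), dllname = "mtp06",
    initfunc = "tp06_initmod",
    nout = if (with_currents) 16L else 0L,
    outnames = if (with_currents) .current_names else NULL,
    method = "lsoda", rtol = rtol, atol = unname(atol), maxsteps = 50000
  )
  if (attr(out, "istate")[1] < 0)
    stop("integration failed at t = ", utils::tail(out[, 1], 1), " ms")
  colnames(out)[2:20] <- .tp06_state_names
  out
}

## output grid for one inter-stimulus interval: fine sampling through the
## stimulus and upstroke, coarser sampling elsewhere
.beat_times <- function(CL, width, fine_step = 0.25, step = 1) {
  c(seq(0, width + 4, by = fine_step),
    seq(ceiling(width + 4 + step), CL, by = step))
}

#' Simulate the paced model cell
#'
#' Applies 1-ms current stimuli at the protocol's cycle length and records
#' the membrane potential (plus any requested state variables).  Per-beat
#' action-potential features are extracted on the fly; the run stops after a
#' fixed number of beats, at the beat-to-beat convergence criterion
#' (relative change of V_min, V_max and APD_90 each below \code{conv_tol}),
#' or at the first beat carrying an EAD, depending on \code{stop}.
#'
#' @param params a \code{tp06_params} object.
#' @param protocol pacing protocol from \code{\link{make_pacing}}.
#' @param init initial state; defaults to resting steady-state initials.
#' @param n_beats maximum number of stimuli.
#' @param stop stopping rule: \code{"beats"} (run all \code{n_beats}),
#'   \code{"converge"} (stop at the convergence criterion) or
#'   \code{"first_ead"} (stop at the first EAD-bearing beat).
#' @param conv_tol beat-to-beat relative convergence tolerance.
#' @param record state variables to keep in the returned trace.
#' @param rtol,atol solver tolerances.
#' @param feature_opts EAD/feature options, see \code{\link{feature_options}}.
#' @return object of class \code{tp06_paced}: recorded trace, stimulus
#'   times, per-beat feature table, final state, convergence flag.
#' @export
simulate_paced <- function(params, protocol, init = NULL,
                           n_beats = 30, stop = c("beats", "converge", "first_ead"),
                           conv_tol = 1e-3, record = "V",
                           rtol = .default_rtol, atol = .default_atol(),
                           feature_opts = feature_options()) {
  stop <- match.arg(stop)
  stopifnot(inherits(protocol, "tp06_protocol"))
  if (is.null(init)) init <- steady_state_initials(params = params)
  state <- apply_clamps(as_state(init), params)
  CL <- protocol$CL; width <- protocol$width; amp <- protocol$amplitude
  rec_idx <- match(record, .tp06_state_names)
  if (anyNA(rec_idx)) stop("unknown state variable in 'record'")
  tgrid <- .beat_times(CL, width)
  n_keep <- length(tgrid)

  time_l <- vector("list", n_beats); v_l <- vector("list", n_beats)
  beats <- vector("list", n_beats)
  converged <- FALSE; n_done <- 0L
  prev_feat <- NULL
  pend <- NULL   # beats whose APD90 awaits a later repolarisation

  for (b in seq_len(n_beats)) {
    t0 <- (b - 1) * CL
    if (amp != 0) {
      seg1 <- integrate_span(state, params, c(0, width), stim = amp,
                             rtol = rtol, atol = atol)
      state <- setNames(seg1[nrow(seg1), 2:20], .tp06_state_names)
      seg2 <- integrate_span(state, params, tgrid[tgrid >= width] - width,
                             stim = 0, rtol = rtol, atol = atol)
      tt <- c(0, tgrid[tgrid >= width][-1])
      vv <- rbind(seg1[1, 2:20, drop = FALSE], seg2[-1, 2:20, drop = FALSE])
    } else {
      seg2 <- integrate_span(state, params, tgrid, stim = 0,
                             rtol = rtol, atol = atol)
      tt <- tgrid
      vv <- seg2[, 2:20, drop = FALSE]
    }
    state <- setNames(vv[nrow(vv), ], .tp06_state_names)
    ## half-open beat windows: the final sample (t = CL) belongs to the
    ## next beat, so drop it from storage and per-beat features except on
    ## the last beat
    keep <- if (b == n_beats) seq_len(nrow(vv)) else seq_len(nrow(vv) - 1L)
    tt <- tt[keep]; vv <- vv[keep, , drop = FALSE]
    time_l[[b]] <- t0 + tt
    v_l[[b]] <- vv[, rec_idx, drop = FALSE]
    n_done <- b

    feat <- .beat_features(t0 + tt, vv[, 1], t_stim = t0,
                           prev_vmin = if (b > 1) beats[[b - 1]]$V_min else vv[1, 1],
                           opts = feature_opts)
    feat$beat <- b
    beats[[b]] <- feat
    ## resolve APD90 of earlier unrepolarised beats using this beat's trace
    if (length(pend)) {
      for (pb in pend) {
        upd <- .resolve_apd(beats[[pb]], t0 + tt, vv[, 1])
        beats[[pb]] <- upd
      }
      pend <- pend[vapply(pend, function(pb) is.na(beats[[pb]]$APD90), TRUE)]
    }
    if (is.na(feat$APD90)) pend <- c(pend, b)

    if (stop == "first_ead" && feat$n_ead > 0) break
    if (stop == "converge" && !is.null(prev_feat) &&
        !is.na(feat$APD90) && !is.na(prev_feat$APD90)) {
      dv <- abs(c(feat$V_min - prev_feat$V_min,
                  feat$V_max - prev_feat$V_max,
                  feat$APD90 - prev_feat$APD90) /
                c(prev_feat$V_min, prev_feat$V_max, prev_feat$APD90))
      if (all(dv < conv_tol)) { converged <- TRUE; break }
    }
    prev_feat <- feat
  }

  time <- unlist(time_l[seq_len(n_done)])
  mat <- do.call(rbind, v_l[seq_len(n_done)])
  colnames(mat) <- record
  beats <- do.call(rbind, lapply(beats[seq_len(n_done)], as.data.frame))
  structure(list(
    time = time, states = mat, stim_times = (seq_len(n_done) - 1) * CL,
    beats = beats, final_state = state, converged = converged,
    params = params, protocol = protocol, n_beats = n_done
  ), class = "tp06_paced")
}

#' @export
print.tp06_paced <- function(x, ...) {
  cat("Paced simulation:", x$n_beats, "beats at CL", x$protocol$CL, "ms",
      if (x$converged) "(converged)" else "", "\n")
  lb <- utils::tail(x$beats, 1)
  cat(sprintf("  last beat: V_min %.1f mV, V_max %.1f mV, APD90 %s ms, EAD extrema %d\n",
              lb$V_min, lb$V_max,
              ifelse(is.na(lb$APD90), "unresolved", sprintf("%.1f", lb$APD90)),
              lb$n_ead))
  invisible(x)
}

#' Simulate the unstimulated (non-paced) cell
#'
#' @param params a \code{tp06_params} object.
#' @param init initial state.
#' @param duration run length (ms).
#' @param step output step (ms).
#' @param record state variables to record.
#' @param rtol,atol solver tolerances.
#' @return matrix with time and recorded columns.
#' @export
simulate_free <- function(params, init, duration, step = 1, record = "V",
                          rtol = .default_rtol, atol = .default_atol()) {
  out <- integrate_span(as_state(init), params, seq(0, duration, by = step),
                        stim = 0, rtol = rtol, atol = atol)
  out[, c("time", record), drop = FALSE]
}
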