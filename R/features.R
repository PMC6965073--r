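#' Options controlling AP feature extraction and EAD detection
#'
#' @param peak_window ms after stimulus onset within which the AP peak is
#'   sought.
#' @param ead_delay ms after the AP peak before which plateau oscillations
#'   are not counted as EADs (late phase 2 criterion).
#' @param prominence minimum extremum prominence (mV) for an oscillation to
#'   count as an EAD; suppresses integrator ripple.
#' @param rest_V membrane potential (mV) below which the cell is considered
#'   repolarised to rest.
#' @param vmax_window ms window after the AP peak over which the early
#'   phase-2 maximum (V_max) is measured.
#' @param local_V floor (mV): if the inter-stimulus potential never falls
#'   below it the cell is trapped near the depolarised equilibrium (local
#'   response when quiescent there, repolarisation failure when plateau
#'   oscillations persist).
#' @return list of options.
#' @export
feature_options <- function(peak_window = 50, ead_delay = 200,
                            prominence = 1, rest_V = -75,
                            vmax_window = c(25, 200),
                            local_V = -40) {
  list(peak_window = peak_window, ead_delay = ead_delay,
       prominence = prominence, rest_V = rest_V,
       vmax_window = vmax_window, local_V = local_V)
}

## alternating local extrema of a sampled signal, pruned to a minimum
## prominence by removing the smallest adjacent min/max excursions
.find_extrema <- function(t, v, min_prom) {
  n <- length(v)
  if (n < 3) return(list(idx = integer(0), kind = integer(0)))
  dv <- diff(v)
  sg <- sign(dv)
  sg[sg == 0] <- 1
  turns <- which(diff(sg) != 0) + 1L   # interior extremum indices
  if (!length(turns)) return(list(idx = integer(0), kind = integer(0)))
  kind <- ifelse(v[turns + 1L] < v[turns], 1L, -1L)  # 1 max, -1 min
  keep <- rep(TRUE, length(turns))
  repeat {
    idx <- turns[keep]
    if (length(idx) < 2) break
    amp <- abs(diff(v[idx]))
    k <- which.min(amp)
    if (amp[k] >= min_prom) break
    w <- which(keep)
    keep[w[c(k, k + 1L)]] <- FALSE   # drop the small excursion pair
  }
  list(idx = turns[keep], kind = kind[keep])
}

## first downward crossing of v below thr after index i0 (linear interp)
.cross_down <- function(t, v, thr, i0 = 1L) {
  n <- length(v)
  if (i0 >= n) return(NA_real_)
  seg <- i0:(n - 1L)
  hit <- seg[v[seg] >= thr & v[seg + 1L] < thr]
  if (!length(hit)) return(NA_real_)
  i <- hit[1L]
  t[i] + (t[i + 1L] - t[i]) * (thr - v[i]) / (v[i + 1L] - v[i])
}

## features of one inter-stimulus window
.beat_features <- function(time, V, t_stim, prev_vmin, opts) {
  ipk <- which(time <= t_stim + opts$peak_window)
  ipk <- ipk[which.max(V[ipk])]
  V_peak <- V[ipk]; t_peak <- time[ipk]
  win <- time >= t_peak + opts$vmax_window[1] &
         time <= t_peak + opts$vmax_window[2]
  V_max <- if (any(win)) max(V[win]) else V_peak
  V_min <- min(V)
  inter_min <- min(V[time > t_peak])   # inter-stimulus floor after peak

  thr <- V_peak - 0.9 * (V_peak - prev_vmin)
  tc <- .cross_down(time, V, thr, ipk)
  APD90 <- if (is.na(tc)) NA_real_ else tc - t_stim

  ## EAD extrema: late phase 2 (>= ead_delay after the peak), before
  ## repolarisation to rest
  t_end <- .cross_down(time, V, opts$rest_V, ipk)
  sel <- time >= t_peak + opts$ead_delay &
         (is.na(t_end) | time <= t_end)
  n_ead <- 0L; ead_vmax <- NA_real_; ead_vmin <- NA_real_
  if (sum(sel) > 2) {
    ex <- .find_extrema(time[sel], V[sel], opts$prominence)
    vsel <- V[sel]
    if (length(ex$idx)) {
      vmax <- vsel[ex$idx][ex$kind == 1L]
      vmin <- vsel[ex$idx][ex$kind == -1L]
      vmax <- vmax[vmax > opts$rest_V]
      n_ead <- length(vmax)
      if (n_ead) ead_vmax <- max(vmax)
      if (length(vmin)) ead_vmin <- min(vmin)
    }
  }
  ## quiescence measure: V_m excursion over the final fifth of the window
  t_end_w <- time[length(time)]
  lsel <- time >= t_end_w - 0.2 * (t_end_w - t_stim)
  late_range <- if (sum(lsel) > 1) diff(range(V[lsel])) else 0
  list(V_min = V_min, V_max = V_max, V_peak = V_peak, t_peak = t_peak,
       t_stim = t_stim, apd_thr = thr, APD90 = APD90,
       n_ead = n_ead, ead_vmax = ead_vmax, ead_vmin = ead_vmin,
       inter_min = inter_min, late_range = late_range)
}

## complete APD90 of an unrepolarised beat using a later trace chunk
.resolve_apd <- function(feat, time, V) {
  tc <- .cross_down(time, V, feat$apd_thr)
  if (!is.na(tc)) feat$APD90 <- tc - feat$t_stim
  feat
}

#' Extract per-beat action-potential features from a trace
#'
#' Recomputes, for every stimulus in a paced trace (or for explicit
#' time/voltage/stimulus-time vectors), the phase-4 minimum, early phase-2
#' maximum, APD at 90\% repolarisation, and local extrema of late-plateau
#' V_m oscillations (EADs).  APD_90 of a beat that repolarises only after
#' later stimuli is measured across them.
#'
#' @param trace a \code{tp06_paced} object with \code{"V"} recorded, or a
#'   numeric time vector.
#' @param V,stim_times voltage samples and stimulus onset times, when
#'   \code{trace} is a plain time vector.
#' @param opts options from \code{\link{feature_options}}.
#' @return data.frame with one row per stimulus.
#' @export
extract_ap_features <- function(trace, V = NULL, stim_times = NULL,
                                opts = feature_options()) {
  if (inherits(trace, "tp06_paced")) {
    if (!("V" %in% colnames(trace$states)))
      stop("trace does not record V")
    time <- trace$time; V <- trace$states[, "V"]
    stim_times <- trace$stim_times
  } else time <- trace
  if (length(stim_times) < 1) stop("trace contains no stimulus")
  feats <- vector("list", length(stim_times))
  bnd <- c(stim_times, max(time) + 1)
  prev_vmin <- V[1]
  for (b in seq_along(stim_times)) {
    sel <- time >= bnd[b] & time < bnd[b + 1]
    if (sum(sel) < 3) stop("trace too short for stimulus ", b)
    f <- .beat_features(time[sel], V[sel], t_stim = stim_times[b],
                        prev_vmin = prev_vmin, opts = opts)
    if (is.na(f$APD90)) {
      later <- time >= bnd[b + 1]
      if (any(later)) f <- .resolve_apd(f, time[later], V[later])
    }
    f$beat <- b
    prev_vmin <- f$V_min
    feats[[b]] <- as.data.frame(f)
  }
  do.call(rbind, feats)
}

#' Classify paced-cell behavior
#'
#' Labels a converged (or capped) paced run as \code{no_EAD}, \code{fR}
#' (EADs with fast repolarisation, APD_90 <= 5 s), \code{RF} (repolarisation
#' failure) or \code{local_response} (stimulus-evoked deflections around the
#' depolarised equilibrium that never constitute full APs).  Assessment
#' pools the last \code{n_last} stimuli.
#'
#' @param trace a \code{tp06_paced} object.
#' @param n_last number of final stimuli pooled for the assessment.
#' @param fr_limit APD_90 limit (ms) separating fR from RF.
#' @param opts feature options (thresholds for the local-response rule).
#' @param extra_stimulus if TRUE, the fR/RF call is confirmed by applying
#'   one extra stimulus after the final beat and checking repolarisation to
#'   rest within \code{fr_limit}.
#' @return character label.
#' @export
classify_behavior <- function(trace, n_last = 10, fr_limit = 5000,
                              opts = feature_options(),
                              extra_stimulus = FALSE) {
  stopifnot(inherits(trace, "tp06_paced"))
  fb <- utils::tail(trace$beats, n_last)
  ## cell trapped at depolarised potentials between stimuli: a local
  ## response if it settles there quiescently (stable depolarised
  ## equilibrium), repolarisation failure if plateau oscillations persist
  if (all(fb$inter_min > opts$local_V)) {
    quiescent <- all(fb$n_ead == 0) || all(fb$late_range < 1)
    return(if (quiescent) "local_response" else "RF")
  }
  if (all(fb$n_ead == 0) && !anyNA(fb$APD90)) return("no_EAD")
  if (all(fb$n_ead == 0)) {
    ## no plateau oscillation but unresolved repolarisation: treat as RF
    return("RF")
  }
  apd <- fb$APD90[fb$n_ead > 0]
  lab <- if (all(!is.na(apd)) && max(apd) <= fr_limit) "fR" else "RF"
  if (extra_stimulus) {
    pr <- trace$protocol
    seg <- integrate_span(trace$final_state, trace$params,
                          c(0, pr$width), stim = pr$amplitude)
    st <- setNames(seg[nrow(seg), 2:20], .tp06_state_names)
    free <- simulate_free(trace$params, st, duration = fr_limit, step = 2)
    repol <- any(free[, "V"] < opts$rest_V)
    lab <- if (repol) "fR" else "RF"
  }
  lab
}

#' Locate a critical parameter value by warm-started bisection
#'
#' Finds the normalized parameter value at which the paced-cell behavior
#' label switches between the two bracket endpoints, mirroring the sweep
#' protocol in which each run inherits its initial state from the nearest
#' previously computed parameter value.
#'
#' @param params base \code{tp06_params}; the axis scaling is applied as a
#'   normalized override on top of it.
#' @param protocol pacing protocol.
#' @param axis scaling name (\code{"gKr"}, \code{"gCaL"}, ...).
#' @param bracket numeric length-2: normalized values with differing labels.
#' @param resolution bisection stops when the bracket is narrower than this.
#' @param n_beats per-point stimulus budget (convergence-stopped).
#' @param classify_opts passed to \code{\link{classify_behavior}}.
#' @param label_fn optional function(trace) -> label, replacing the default
#'   coarse grouping \{no_EAD, EAD, local_response\}.
#' @param init initial state for the first endpoint; defaults to the
#'   resting steady state.
#' @param rtol,atol solver tolerances.
#' @return list: \code{value} (critical normalized value, midpoint of the
#'   final bracket), \code{bracket}, \code{labels} at the endpoints,
#'   \code{evaluations} (value/label table).
#' @export
find_critical_parameter <- function(params, protocol, axis, bracket,
                                    resolution = 0.001, n_beats = 40,
                                    classify_opts = list(),
                                    label_fn = NULL, init = NULL,
                                    rtol = .default_rtol,
                                    atol = .default_atol()) {
  if (!(axis %in% .tp06_scale_names)) stop("unknown axis: ", axis)
  if (is.null(label_fn))
    label_fn <- function(trace) {
      lb <- do.call(classify_behavior, c(list(trace), classify_opts))
      if (lb %in% c("fR", "RF")) "EAD" else lb
    }
  if (is.null(init)) init <- steady_state_initials(params = params)
  evals <- list()   # value -> list(label, state)
  run_at <- function(value, start) {
    ov <- params$normalized
    ov[axis] <- ov[axis] * value
    p <- params; p$normalized <- ov
    tr <- simulate_paced(p, protocol, init = start, n_beats = n_beats,
                         stop = "converge", rtol = rtol, atol = atol)
    list(label = label_fn(tr), state = tr$final_state)
  }
  nearest_state <- function(value) {
    vals <- as.numeric(names(evals))
    evals[[which.min(abs(vals - value))]]$state
  }
  lo <- min(bracket); hi <- max(bracket)
  e_hi <- run_at(hi, init)
  evals[[sprintf("%.17g", hi)]] <- e_hi
  e_lo <- run_at(lo, nearest_state(lo))
  evals[[sprintf("%.17g", lo)]] <- e_lo
  if (e_lo$label == e_hi$label)
    stop("bracket endpoints classify identically ('", e_lo$label, "')")
  lab_lo <- e_lo$label; lab_hi <- e_hi$label
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    e <- run_at(mid, nearest_state(mid))
    evals[[sprintf("%.17g", mid)]] <- e
    if (e$label == lab_lo) lo <- mid else hi <- mid
  }
  ev <- data.frame(value = as.numeric(names(evals)),
                   label = vapply(evals, `[[`, "", "label"))
  ev <- ev[order(ev$value), ]; rownames(ev) <- NULL
  list(value = (lo + hi) / 2, bracket = c(lo, hi),
       labels = c(lower = lab_lo, upper = lab_hi), evaluations = ev)
}

#' First EAD-bearing stimulus after a pacing-rate switch
#'
#' Paces the model at \code{CL_pre} to its steady state (30 simulated
#' minutes, the protocol used for a first parameter set), switches the
#' cycle length to \code{CL_post}, and returns the 1-based index of the
#' first post-switch stimulus whose AP contains a detected EAD.
#'
#' @param params a \code{tp06_params} object.
#' @param CL_pre,CL_post pre- and post-switch cycle lengths (ms).
#' @param max_post cap on post-switch stimuli.
#' @param prepace_min duration of the pre-switch pacing (simulated minutes).
#' @param init optional pre-paced state; when supplied the pre-pacing phase
#'   is skipped (used to share one pre-pace across several switches).
#' @param rtol,atol solver tolerances.
#' @param opts feature options.
#' @return list: \code{index} (integer or NA if no EAD within the cap) and
#'   \code{prepaced_state}.
#' @export
first_ead_stimulus_index <- function(params, CL_pre, CL_post,
                                     max_post = 250, prepace_min = 30,
                                     init = NULL,
                                     rtol = .default_rtol,
                                     atol = .default_atol(),
                                     opts = feature_options()) {
  if (is.null(init)) {
    pre <- simulate_paced(params, make_pacing(CL_pre),
                          n_beats = ceiling(prepace_min * 60000 / CL_pre),
                          stop = "beats", rtol = rtol, atol = atol,
                          feature_opts = opts)
    init <- pre$final_state
  }
  if (CL_post == CL_pre) return(list(index = NA_integer_, prepaced_state = init))
  post <- simulate_paced(params, make_pacing(CL_post), init = init,
                         n_beats = max_post, stop = "first_ead",
                         rtol = rtol, atol = atol, feature_opts = opts)
  idx <- which(post$beats$n_ead > 0)
  list(index = if (length(idx)) idx[1] else NA_integer_,
       prepaced_state = init)
}
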