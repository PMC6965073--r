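#' Fast-subsystem specification for slow-fast decomposition
#'
#' Two decompositions are supported.  \code{type = "xs"}: the slow
#' variables are the I_Ks activation gate xs (entering as the parameter
#' xs^2, the channel open probability), Na_i and Ca_SR; the fast subsystem
#' is the remaining 15 free variables (K_i fixed).  \code{type = "CaSR"}:
#' the voltage-clamped fast subsystem in which Ca_SR is the parameter and
#' V_m is clamped with Na_i and K_i fixed; its essential dynamics are the
#' Ca2+-dependent variables (fCass, Rbar, Ca_ss, Ca_i) while the voltage
#' gates equilibrate at the clamped potential.
#'
#' @param type \code{"xs"} or \code{"CaSR"}.
#' @param params base \code{tp06_params}.
#' @param Nai fixed Na_i (mM).
#' @param CaSR fixed Ca_SR for the xs decomposition (mM).
#' @param Vm clamped potential for the CaSR decomposition (mV).
#' @param Ki fixed K_i (mM).
#' @return function(axis_value) -> frozen \code{tp06_params} for the fast
#'   subsystem at that slow-variable value, with attributes \code{type} and
#'   \code{axis}.
#' @export
fast_subsystem <- function(type = c("xs", "CaSR"), params,
                           Nai = 6, CaSR = NULL, Vm = NULL, Ki = 140) {
  type <- match.arg(type)
  params$fix_Ki <- TRUE; params$Ki_value <- Ki
  params$fix_Nai <- TRUE; params$Nai_value <- Nai
  if (type == "xs") {
    if (is.null(CaSR)) stop("the xs decomposition requires a fixed Ca_SR")
    if (!is.null(params$freeze) && params$clamp_Vm)
      stop("V_m cannot be clamped in the xs decomposition")
    fb <- function(xs2) {
      if (xs2 < 0 || xs2 > 1) stop("xs^2 must lie in [0, 1]")
      freeze_states(params, xs = sqrt(xs2), CaSR = CaSR)
    }
  } else {
    if (is.null(Vm)) stop("the CaSR decomposition requires a clamped V_m")
    params$clamp_Vm <- TRUE; params$Vm_value <- Vm
    fb <- function(casr) {
      if (casr <= 0) stop("Ca_SR must be positive")
      freeze_states(params, CaSR = casr)
    }
  }
  attr(fb, "type") <- type
  attr(fb, "axis") <- if (type == "xs") "xs2" else "CaSR"
  fb
}

#' Quasi-equilibrium / quasi-limit-cycle branch of a fast subsystem
#'
#' Continues the fast subsystem's equilibria over the slow-variable axis
#' with warm-started Newton corrections, classifies stability (with spiral
#' sink/source annotation from the leading complex pair), bisects Hopf
#' points, and optionally follows a quasi-limit-cycle branch by shooting.
#'
#' @param subsystem a builder from \code{\link{fast_subsystem}}.
#' @param axis_values slow-variable grid in traversal order.
#' @param init template state for concentration initialisation.
#' @param hb_tol axis resolution of Hopf bisection.
#' @param track_lc if TRUE, seed a quasi-LC from simulation at unstable
#'   axis points and follow it across the grid.
#' @return object of class \code{tp06_quasi_branch}: data.frame
#'   \code{points} (axis, branch, V, Cass, stability, annotation),
#'   \code{bifurcations}, and for the xs decomposition the steady-state
#'   xs^2 curve data.
#' @export
quasi_branch <- function(subsystem, axis_values, init = NULL,
                         hb_tol = NULL, track_lc = FALSE) {
  type <- attr(subsystem, "type")
  if (is.null(hb_tol))
    hb_tol <- diff(range(axis_values)) / (length(axis_values) - 1) / 50
  p1 <- subsystem(axis_values[1])
  eps0 <- find_equilibria(p1, init = init)
  branches <- lapply(eps0, function(e) e$state)
  rows <- list(); bifs <- list()
  prev_stab <- rep(NA, length(branches)); prev_v <- axis_values[1]
  for (v in axis_values) {
    pv <- subsystem(v)
    for (bi in seq_along(branches)) {
      if (is.null(branches[[bi]])) next
      st0 <- branches[[bi]]
      st0 <- apply_clamps(st0, pv)   # impose the new slow value
      sol <- .newton_ep(st0, pv)
      if (is.null(sol)) {
        ## try to re-seed once (fold regions)
        re <- find_equilibria(pv, init = st0,
                              V_seeds = st0[["V"]] + seq(-12, 12, by = 3))
        if (length(re)) {
          dd <- vapply(re, function(e)
            max(abs(e$state - st0) / .state_typical), 0)
          sol <- re[[which.min(dd)]]$state
        }
      }
      if (is.null(sol)) {
        bifs[[length(bifs) + 1]] <- list(type = "SNB_EP", value = v,
                                         branch = bi)
        branches[bi] <- list(NULL)
        next
      }
      st <- ep_stability(sol, pv)
      rows[[length(rows) + 1]] <- data.frame(
        value = v, branch = bi, V = sol[["V"]], Cass = sol[["Cass"]],
        Cai = sol[["Cai"]], stable = st$stable, spiral = st$spiral,
        annotation = st$annotation)
      if (!is.na(prev_stab[bi]) && xor(prev_stab[bi], st$stable)) {
        hb <- .refine_qhb(subsystem, prev_v, v, branches[[bi]], hb_tol)
        if (!is.null(hb)) { hb$branch <- bi; bifs[[length(bifs) + 1]] <- hb }
      }
      prev_stab[bi] <- st$stable
      branches[[bi]] <- sol
    }
    prev_v <- v
  }
  pts <- do.call(rbind, rows)
  out <- list(points = pts, bifurcations = bifs, type = type,
              axis = attr(subsystem, "axis"))
  if (type == "xs") {
    Vg <- seq(-90, 40, by = 1)
    out$xs_inf_curve <- data.frame(V = Vg,
                                   xs2 = gate_steady_state(Vg)$xs^2)
  }
  if (track_lc && !is.null(pts)) {
    out$lc <- .track_quasi_lc(subsystem, axis_values, pts)
  }
  class(out) <- "tp06_quasi_branch"
  out
}

## Hopf bisection for a frozen-value axis
.refine_qhb <- function(subsystem, v_lo, v_hi, state, tol) {
  stab_at <- function(v, st) {
    pv <- subsystem(v)
    sol <- .newton_ep(apply_clamps(st, pv), pv)
    if (is.null(sol)) return(NULL)
    s <- ep_stability(sol, pv)
    list(sol = sol, stable = s$stable, ev = s$eigenvalues[1])
  }
  a <- stab_at(v_lo, state); b <- stab_at(v_hi, state)
  if (is.null(a) || is.null(b) || identical(a$stable, b$stable)) return(NULL)
  st <- state
  while (abs(v_hi - v_lo) > tol) {
    mid <- (v_lo + v_hi) / 2
    m <- stab_at(mid, st)
    if (is.null(m)) break
    st <- m$sol
    if (identical(m$stable, a$stable)) { v_lo <- mid; a <- m }
    else { v_hi <- mid; b <- m }
  }
  list(type = "HB", value = (v_lo + v_hi) / 2, state = st,
       omega = abs(Im(a$ev)))
}

## follow a quasi-limit-cycle branch seeded from simulation at the first
## unstable axis point
.track_quasi_lc <- function(subsystem, axis_values, pts) {
  un <- pts[!pts$stable, ]
  if (!nrow(un)) return(NULL)
  v0 <- un$value[which.max(table(un$value))[1]]
  v0 <- un$value[ceiling(nrow(un) / 2)]
  pv <- subsystem(v0)
  ep <- un[un$value == v0, ][1, ]
  st <- steady_state_initials(params = pv)
  st["V"] <- ep$V + 5
  st <- apply_clamps(st, pv)
  anchor <- if (attr(subsystem, "type") == "xs") "V" else "Cass"
  sd <- seed_orbit_from_simulation(pv, st, duration = 30000, anchor = anchor)
  if (is.null(sd)) return(NULL)
  rows <- list(); y <- sd$seed; T <- sd$period
  for (v in axis_values[axis_values >= v0]) {
    pvv <- subsystem(v)
    orb <- tryCatch(suppressWarnings(
      find_limit_cycle(pvv, apply_clamps(y, pvv), T, anchor = anchor)),
      error = function(e) NULL)
    if (is.null(orb)) break
    rows[[length(rows) + 1]] <- data.frame(
      value = v, period = orb$period, stable = orb$stable,
      amin = orb$extrema[1, anchor], amax = orb$extrema[2, anchor])
    y <- orb$state; T <- orb$period
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Overlay a full-system trajectory on a fast-subsystem diagram
#'
#' Projects a trajectory computed with the decomposition's slow variables
#' fixed onto the (slow variable, fast variable) plane and reports the
#' trapping diagnostics: for the xs decomposition, the dwell time within a
#' neighborhood of the stable quasi-equilibrium segment before the
#' trajectory crosses the steady-state xs^2 curve; for the CaSR
#' decomposition, whether and when Ca_SR exceeds the Hopf value (the
#' spontaneous-release criterion).
#'
#' @param trace matrix/data.frame with columns \code{time} plus \code{V},
#'   \code{xs} (xs decomposition) or \code{CaSR}, \code{Cass} (CaSR
#'   decomposition).
#' @param branch a \code{tp06_quasi_branch}.
#' @param neighborhood half-width (mV) of the trapping neighborhood around
#'   the stable quasi-EP.
#' @param dwell_threshold dwell time (ms) above which trapping is reported.
#' @return list with the projected trajectory and the trapping report.
#' @export
overlay_trajectory <- function(trace, branch, neighborhood = 2,
                               dwell_threshold = 100) {
  stopifnot(inherits(branch, "tp06_quasi_branch"))
  tr <- as.data.frame(trace)
  pts <- branch$points
  if (branch$type == "xs") {
    if (!all(c("time", "V", "xs") %in% names(tr)))
      stop("trace must provide time, V and xs")
    proj <- data.frame(time = tr$time, xs2 = tr$xs^2, V = tr$V)
    ## stable depolarised quasi-EP segment (upper branch)
    sb <- pts[pts$stable & pts$V > -40, ]
    inside <- rep(FALSE, nrow(proj))
    if (nrow(sb) > 1) {
      vq <- approx(sb$value, sb$V, xout = proj$xs2, rule = 1)$y
      inside <- !is.na(vq) & abs(proj$V - vq) <= neighborhood
    } else if (nrow(sb) == 1) {
      inside <- abs(proj$xs2 - sb$value) <=
        (max(pts$value) - min(pts$value)) / 50 &
        abs(proj$V - sb$V) <= neighborhood
    }
    xsc <- branch$xs_inf_curve
    gap <- proj$xs2 - approx(xsc$V, xsc$xs2, xout = proj$V, rule = 2)$y
    crossed <- which(diff(sign(gap)) != 0)
    t_cross <- if (length(crossed)) proj$time[crossed[1] + 1] else NA_real_
    upto <- if (is.na(t_cross)) rep(TRUE, nrow(proj)) else proj$time <= t_cross
    dt <- c(diff(proj$time), 0)
    dwell <- sum(dt[inside & upto])
    list(projection = proj,
         trapping = list(dwell_ms = dwell,
                         trapped = dwell >= dwell_threshold,
                         crossed_xs_curve_at = t_cross))
  } else {
    if (!all(c("time", "CaSR", "Cass") %in% names(tr)))
      stop("trace must provide time, CaSR and Cass")
    proj <- data.frame(time = tr$time, CaSR = tr$CaSR, Cass = tr$Cass)
    hbv <- vapply(Filter(function(b) b$type == "HB", branch$bifurcations),
                  `[[`, 0, "value")
    hb <- if (length(hbv)) min(hbv) else NA_real_
    crossed <- !is.na(hb) && any(proj$CaSR > hb)
    t_cross <- if (crossed) proj$time[which(proj$CaSR > hb)[1]] else NA_real_
    list(projection = proj,
         trapping = list(hb_CaSR = hb, crossed_hb = isTRUE(crossed),
                         crossed_at = t_cross))
  }
}
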