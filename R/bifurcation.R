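## typical magnitudes used to scale Newton residuals, finite-difference
## steps and duplicate-merging distances
.state_typical <- c(V = 100, m = 1, h = 1, j = 1, d = 1, f = 1, f2 = 1,
                    fCass = 1, xr1 = 1, xr2 = 1, xs = 1, r = 1, s = 1,
                    Rbar = 1, Nai = 10, Ki = 140, Cai = 1e-3, Cass = 1e-3,
                    CaSR = 3)

## indices of the free (non-frozen) state variables under a parameter set
.free_indices <- function(params) {
  freeze <- params$freeze
  if (params$fix_Ki) freeze["Ki"] <- TRUE
  if (params$fix_Nai) freeze["Nai"] <- TRUE
  if (params$clamp_Vm) freeze["V"] <- TRUE
  which(!freeze)
}

## fast RHS on the C core, avoiding repeated parameter translation
.rhs_fun <- function(params, stim = 0) {
  pv <- param_cvec(params, stim)
  function(y) .Call(C_tp06_rhs, y, pv)$deriv
}

#' Jacobian of the model right-hand side
#'
#' Central finite differences with per-variable relative steps on the free
#' (non-frozen) state variables.
#'
#' @param state named state vector.
#' @param params a \code{tp06_params} object.
#' @param free integer indices of free variables; defaults to all variables
#'   not fixed/clamped/frozen by \code{params}.
#' @param rel_step relative finite-difference step.
#' @return square matrix over the free variables (dimnames = state names).
#' @export
jacobian <- function(state, params, free = .free_indices(params),
                     rel_step = 1e-6) {
  y <- as.numeric(apply_clamps(state, params))
  f <- .rhs_fun(params)
  n <- length(free)
  J <- matrix(0, n, n, dimnames = list(.tp06_state_names[free],
                                       .tp06_state_names[free]))
  for (k in seq_len(n)) {
    i <- free[k]
    h <- rel_step * max(abs(y[i]), .state_typical[i] * 1e-3)
    yp <- y; yp[i] <- y[i] + h
    ym <- y; ym[i] <- y[i] - h
    J[, k] <- (f(yp)[free] - f(ym)[free]) / (2 * h)
  }
  J
}

#' Stability classification of an equilibrium point
#'
#' @param state equilibrium state vector.
#' @param params a \code{tp06_params} object.
#' @return list: \code{eigenvalues} (sorted by decreasing real part),
#'   \code{stable}, \code{spiral} (leading pair complex), \code{class} one
#'   of \code{"stable"}, \code{"unstable"}, \code{"saddle"}, with spiral
#'   sink/source annotation in \code{annotation}.
#' @export
ep_stability <- function(state, params) {
  J <- jacobian(state, params)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  if (any(!is.finite(ev)))
    return(list(eigenvalues = ev, stable = NA, spiral = NA,
                class = "indeterminate", annotation = "indeterminate"))
  stable <- max(Re(ev)) < 0
  ## spiral annotation: a complex pair among the dominant modes — the pair
  ## must either lead the spectrum (unstable case) or decay no more than
  ## 4x faster than the slowest mode (stable case)
  cplx <- ev[Im(ev) != 0]
  maxre <- max(Re(ev))
  spiral <- length(cplx) > 0 &&
    max(Re(cplx)) >= min(maxre, 4 * maxre) - 1e-12
  n_pos <- sum(Re(ev) > 0)
  cls <- if (stable) "stable"
         else if (n_pos < length(ev) && all(Im(ev[Re(ev) > 0]) == 0) &&
                  n_pos <= 2) "saddle" else "unstable"
  ann <- if (spiral && stable) "spiral sink"
         else if (spiral && !stable) "spiral source"
         else if (stable) "node" else "saddle/node"
  list(eigenvalues = ev, stable = stable, spiral = spiral,
       class = cls, annotation = ann)
}

## At any equilibrium the gating variables sit exactly on their
## steady-state curves (dg/dt = 0 implies g = g_inf), so the equilibrium
## problem reduces to the slow unknowns: V, Na_i, K_i, Ca_i, Ca_ss, Ca_SR,
## minus whatever the parameter set clamps, fixes or freezes.

.slow_names <- c("V", "Nai", "Ki", "Cai", "Cass", "CaSR")

## assemble a full state from slow-variable values, with gates at their
## steady states (frozen gates keep their frozen values); hot path — plain
## arithmetic, no data.frame construction
.assemble_state <- function(params, slow) {
  V <- slow[["V"]]
  Cass <- slow[["Cass"]]; CaSR <- slow[["CaSR"]]
  hj <- 1 / (1 + exp((V + 71.55) / 7.43))^2
  fCass <- 0.6 / (1 + (Cass / 0.05)^2) + 0.4
  kcasr <- 2.5 - 1.5 / (1 + (1.5 / CaSR)^2)
  Rbar <- 0.005 / (0.005 + 0.045 * kcasr * Cass)
  st <- c(V = V,
          m = 1 / (1 + exp((-56.86 - V) / 9.03))^2,
          h = hj, j = hj,
          d = 1 / (1 + exp((-8 - V) / 7.5)),
          f = 1 / (1 + exp((V + 20) / 7)),
          f2 = 0.67 / (1 + exp((V + 35) / 7)) + 0.33,
          fCass = fCass,
          xr1 = 1 / (1 + exp((-26 - V) / 7)),
          xr2 = 1 / (1 + exp((V + 88) / 24)),
          xs = 1 / (1 + exp((-5 - V) / 14)),
          r = 1 / (1 + exp((20 - V) / 6)),
          s = 1 / (1 + exp((V + 20) / 5)),
          Rbar = Rbar,
          Nai = slow[["Nai"]], Ki = slow[["Ki"]],
          Cai = slow[["Cai"]], Cass = Cass, CaSR = CaSR)
  names(st) <- .tp06_state_names   # guard against name propagation
  if (params$fix_Ki) st["Ki"] <- params$Ki_value
  if (params$fix_Nai) st["Nai"] <- params$Nai_value
  if (params$clamp_Vm) st["V"] <- params$Vm_value
  if (any(params$freeze)) {
    frozen <- which(params$freeze & !is.na(params$freeze_values))
    st[frozen] <- params$freeze_values[frozen]
  }
  st
}

## slow unknowns that remain free under a parameter set
.free_slow <- function(params) {
  freeze <- params$freeze
  if (params$fix_Ki) freeze["Ki"] <- TRUE
  if (params$fix_Nai) freeze["Nai"] <- TRUE
  if (params$clamp_Vm) freeze["V"] <- TRUE
  .slow_names[!freeze[.slow_names]]
}

## damped Newton on the reduced slow system; concentrations are solved in
## log space (positivity built in, scale-free steps)
.reduced_newton <- function(params, slow, tol = 1e-12, max_iter = 80) {
  un <- .free_slow(params)
  if (!length(un)) return(.assemble_state(params, slow))
  f <- .rhs_fun(params)
  typ <- .state_typical[.slow_names]
  ui <- match(un, .tp06_state_names)
  tun <- typ[un]
  is_conc <- un %in% c("Nai", "Ki", "Cai", "Cass", "CaSR")
  to_u <- function(sl) {
    v <- unlist(sl[un])
    v[is_conc] <- log(v[is_conc])
    v
  }
  from_u <- function(u, sl) {
    for (k in seq_along(un))
      sl[[un[k]]] <- if (is_conc[k]) exp(u[k]) else u[k]
    sl
  }
  resid_u <- function(u, sl) {
    if (any(!is.finite(u)) || any(u[is_conc] > log(50)) ||
        (!all(is_conc) && any(abs(u[!is_conc]) > 150)))
      return(rep(Inf, length(un)))
    st <- .assemble_state(params, from_u(u, sl))
    f(as.numeric(st))[ui] / tun
  }
  sl <- slow
  u <- to_u(sl)
  r <- tryCatch(resid_u(u, sl), error = function(e) rep(Inf, length(un)))
  r0 <- max(abs(r))
  for (it in seq_len(max_iter)) {
    if (!is.finite(r0)) return(NULL)
    if (r0 < tol) break
    n <- length(un)
    J <- matrix(0, n, n)
    for (k in seq_len(n)) {
      h <- if (is_conc[k]) 1e-7 else 1e-7 * max(abs(u[k]), 0.1)
      up <- u; up[k] <- u[k] + h
      um <- u; um[k] <- u[k] - h
      J[, k] <- (resid_u(up, sl) - resid_u(um, sl)) / (2 * h)
    }
    if (any(!is.finite(J))) return(NULL)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    ## cap log-space steps to stay on the basin
    cap <- pmin(1, 3 / max(abs(step)))
    step <- step * cap
    lambda <- 1
    repeat {
      u2 <- u + lambda * step
      r2 <- tryCatch(max(abs(resid_u(u2, sl))), error = function(e) Inf)
      if (is.finite(r2) && r2 < r0) break
      lambda <- lambda / 2
      if (lambda < 1e-8) return(NULL)
    }
    u <- u2
    r <- resid_u(u, sl); r0 <- max(abs(r))
  }
  if (r0 >= tol * 100) return(NULL)
  .assemble_state(params, from_u(u, sl))
}

## equilibrium refinement from a full-state guess (keeps the historical
## interface: extracts the slow variables and runs the reduced Newton)
.newton_ep <- function(state, params, tol = 1e-12, max_iter = 80) {
  st <- apply_clamps(as_state(state), params)
  slow <- as.list(st[.slow_names])
  .reduced_newton(params, slow, tol = tol, max_iter = max_iter)
}

## Ca-subsystem equilibrium at fixed V and Na_i (3-4 unknowns), retried
## from a seed ladder on failure
.ca_ep <- function(params, V, Nai, warm) {
  pc <- params
  pc$clamp_Vm <- TRUE; pc$Vm_value <- V
  if (!pc$fix_Nai && !pc$freeze["Nai"]) {
    pc$fix_Nai <- TRUE; pc$Nai_value <- Nai
  }
  st <- as_state(warm); st["V"] <- V; st["Nai"] <- Nai
  sol <- .newton_ep(st, pc)
  if (!is.null(sol)) return(sol)
  for (seed in list(c(Cai = 1e-4, Cass = 2e-4, CaSR = 1.5),
                    c(Cai = 1e-3, Cass = 2e-3, CaSR = 4),
                    c(Cai = 3e-5, Cass = 6e-5, CaSR = 0.3),
                    c(Cai = 5e-3, Cass = 1e-2, CaSR = 8))) {
    st2 <- st; st2[names(seed)] <- seed
    sol <- .newton_ep(st2, pc)
    if (!is.null(sol)) return(sol)
  }
  ## last resort: relax the clamped subsystem; when it oscillates
  ## (unstable spiral EP, spontaneous Ca2+ cycling) seed from the cycle
  ## average
  rel <- tryCatch(
    integrate_span(apply_clamps(st, pc), pc, seq(0, 30000, by = 20),
                   stim = 0),
    error = function(e) NULL)
  if (!is.null(rel)) {
    tailw <- rel[rel[, "time"] > 20000, 2:20, drop = FALSE]
    for (cand in list(rel[nrow(rel), 2:20], colMeans(tailw))) {
      st2 <- setNames(as.numeric(cand), .tp06_state_names)
      sol <- .newton_ep(st2, pc)
      if (!is.null(sol)) return(sol)
    }
  }
  NULL
}

## clamped-subsystem equilibrium at a given V.  When Na_i is free its
## balance is solved by a deterministic grid scan plus bisection over the
## Ca-subsystem equilibria (the balance is near-monotone in Na_i but the
## Ca subsystem is strongly nonlinear, so a scan is used rather than a
## secant).  Returns the root nearest the warm-start Na_i.
.xstar_at_V <- function(params, V, warm, relax_ms = 0,
                        Nai_grid = c(0.5, 1, 2, 3, 4.5, 6, 8, 10, 13, 16,
                                     20, 25, 30, 36, 42)) {
  warm <- as_state(warm)
  if (params$fix_Nai || params$freeze["Nai"])
    return(.ca_ep(params, V, warm[["Nai"]], warm))
  nai_balance <- function(sol) rhs(0, sol, params)[["Nai"]]
  bisect <- function(lo, hi, glo, w) {
    while (hi - lo > 1e-9) {
      mid <- (lo + hi) / 2
      sm <- .ca_ep(params, V, mid, w)
      if (is.null(sm)) return(NULL)
      w <- sm
      gm <- nai_balance(sm)
      if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else hi <- mid
    }
    .ca_ep(params, V, (lo + hi) / 2, w)
  }
  ## fast path: walk outward from the warm-start Na_i until the balance
  ## changes sign, then bisect (warm-started continuation along a scan)
  s0 <- warm[["Nai"]]
  sol0 <- .ca_ep(params, V, s0, warm)
  if (!is.null(sol0)) {
    g0 <- nai_balance(sol0)
    dir <- if (g0 > 0) 1 else -1
    s1 <- s0; g1 <- g0; w <- sol0; step <- 0.25
    repeat {
      s2 <- s1 + dir * step
      if (s2 < 0.2 || s2 > 45) break
      sol2 <- .ca_ep(params, V, s2, w)
      if (is.null(sol2)) break
      g2 <- nai_balance(sol2)
      if (sign(g2) != sign(g1)) {
        fin <- bisect(min(s1, s2), max(s1, s2),
                      if (s1 < s2) g1 else g2, w)
        if (!is.null(fin)) return(fin)
        break
      }
      s1 <- s2; g1 <- g2; w <- sol2; step <- step * 1.8
    }
  }
  ## fallback: full grid scan for sign changes
  g <- rep(NA_real_, length(Nai_grid))
  sols <- vector("list", length(Nai_grid))
  w <- warm
  for (i in seq_along(Nai_grid)) {
    s <- .ca_ep(params, V, Nai_grid[i], w)
    if (is.null(s)) next
    w <- s
    sols[[i]] <- s
    g[i] <- nai_balance(s)
  }
  ok <- which(!is.na(g))
  roots <- list()
  for (k in seq_len(max(length(ok) - 1, 0))) {
    i <- ok[k]; j <- ok[k + 1]
    if (sign(g[i]) == sign(g[j])) next
    fin <- bisect(Nai_grid[i], Nai_grid[j], g[i], sols[[i]])
    if (!is.null(fin)) roots[[length(roots) + 1]] <- fin
  }
  if (!length(roots)) return(NULL)
  d <- vapply(roots, function(r) abs(r[["Nai"]] - warm[["Nai"]]), 0)
  roots[[which.min(d)]]
}

#' Locate equilibrium points of the non-paced cell
#'
#' Reduces the equilibrium problem to one dimension: for each membrane
#' potential on a scan grid the clamped subsystem (gates, Ca2+ and ion
#' balances) is equilibrated by a nested Newton solve, and the total
#' membrane current at that quasi-static state is evaluated; sign changes
#' over the grid are bisected and polished into full equilibria.  Returns
#' up to three equilibria sorted by membrane potential (branch ids
#' V_E1 < V_E2 < V_E3 for the low/middle/high branches).
#'
#' @param params a \code{tp06_params} object (fix K_i for the standard
#'   non-degenerate analysis).
#' @param V_seeds membrane-potential scan grid (mV); sign changes of the
#'   quasi-static total current between neighbours are refined.
#' @param init optional template state supplying initial concentrations.
#' @param V_tol bisection tolerance on V (mV).
#' @return list of equilibria; each has \code{state}, \code{residual}
#'   (scaled max RHS), \code{stability} (from \code{\link{ep_stability}}),
#'   \code{branch}.
#' @export
find_equilibria <- function(params, V_seeds = seq(-95, 25, by = 2.5),
                            init = NULL, V_tol = 1e-7) {
  if (is.null(init)) init <- steady_state_initials(params = params)
  ## V_m clamped/frozen: the equilibrium problem is the clamped subsystem
  if (params$clamp_Vm || params$freeze["V"]) {
    sol <- .newton_ep(apply_clamps(init, params), params)
    if (is.null(sol)) {
      x0 <- .xstar_at_V(params,
                        if (params$clamp_Vm) params$Vm_value
                        else params$freeze_values[["V"]],
                        init, relax_ms = 20000)
      sol <- x0
    }
    if (is.null(sol)) return(list())
    free <- .free_indices(params)
    res <- max(abs(rhs(0, sol, params)[free]) / .state_typical[free])
    return(list(list(state = sol, residual = res,
                     stability = ep_stability(sol, params),
                     branch = "V_E1")))
  }
  warm <- as_state(init)
  Fv <- rep(NA_real_, length(V_seeds))
  xs <- vector("list", length(V_seeds))
  first <- TRUE
  for (i in seq_along(V_seeds)) {
    x <- .xstar_at_V(params, V_seeds[i], warm,
                     relax_ms = if (first) 20000 else 2000)
    if (is.null(x)) next
    first <- FALSE
    warm <- x
    xs[[i]] <- x
    Fv[i] <- rhs(0, x, params)[["V"]]
  }
  sols <- list()
  ok <- which(!is.na(Fv))
  for (k in seq_len(length(ok) - 1)) {
    i <- ok[k]; j <- ok[k + 1]
    if (j != i + 1 || sign(Fv[i]) == sign(Fv[j])) next
    lo <- V_seeds[i]; hi <- V_seeds[j]
    flo <- Fv[i]
    wm <- xs[[i]]
    while (hi - lo > V_tol) {
      mid <- (lo + hi) / 2
      xm <- .xstar_at_V(params, mid, wm, relax_ms = 0)
      if (is.null(xm)) break
      wm <- xm
      fm <- rhs(0, xm, params)[["V"]]
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    sol <- .xstar_at_V(params, (lo + hi) / 2, wm, relax_ms = 0)
    if (is.null(sol)) next
    free <- .free_indices(params)
    res <- max(abs(rhs(0, sol, params)[free]) / .state_typical[free])
    dup <- any(vapply(sols, function(s2)
      max(abs(sol - s2$state) / .state_typical) < 1e-5, TRUE))
    if (!dup && res < 1e-8)
      sols[[length(sols) + 1]] <- list(state = sol, residual = res)
  }
  if (!length(sols)) return(list())
  ord <- order(vapply(sols, function(s) s$state[["V"]], 0))
  sols <- sols[ord]
  for (i in seq_along(sols)) {
    sols[[i]]$stability <- ep_stability(sols[[i]]$state, params)
    sols[[i]]$branch <- paste0("V_E", i)
  }
  sols
}

## apply a normalized axis value onto a parameter set (internal: permits
## non-physical negative values used by extended branch diagrams)
.with_axis <- function(params, axis, value) {
  params$normalized[axis] <- value
  params
}

#' One-parameter equilibrium branch continuation
#'
#' Natural-parameter continuation of all equilibrium branches over a grid
#' of normalized axis values, with warm-started Newton corrections, Hopf
#' bifurcations refined by bisection on the leading complex pair's real
#' part, and saddle-node points flagged where a branch is lost or a real
#' eigenvalue crosses zero.  Negative axis values are permitted (the
#' extended, non-physical branch segments) and marked.
#'
#' @param params base \code{tp06_params} (axis override is applied on top).
#' @param axis scaling knob name.
#' @param values normalized axis values in traversal order.
#' @param hb_tol axis resolution for Hopf-point bisection.
#' @return object of class \code{tp06_branch}: data.frame \code{points}
#'   (value, branch, V, leading eigenvalue, stability, physical flag) and
#'   list \code{bifurcations} (type, value, branch, state).
#' @export
continue_ep_branch <- function(params, axis, values, hb_tol = 1e-4) {
  if (!(axis %in% .tp06_scale_names)) stop("unknown axis: ", axis)
  eps0 <- find_equilibria(.with_axis(params, axis, values[1]))
  if (!length(eps0)) stop("no equilibria at the start of the range")
  branches <- lapply(eps0, function(e) e$state)
  rows <- list(); bifs <- list()
  prev_stab <- rep(NA, length(branches))
  prev_val <- values[1]
  for (v in values) {
    pv <- .with_axis(params, axis, v)
    for (bi in seq_along(branches)) {
      if (is.null(branches[[bi]])) next
      sol <- .newton_ep(branches[[bi]], pv)
      if (is.null(sol)) {   # fold / branch lost
        bifs[[length(bifs) + 1]] <- list(type = "SNB_EP", value = v,
                                         branch = bi,
                                         state = branches[[bi]])
        branches[bi] <- list(NULL)   # keep slot, mark branch as lost
        next
      }
      st <- ep_stability(sol, pv)
      lead <- st$eigenvalues[1]
      rows[[length(rows) + 1]] <- data.frame(
        value = v, branch = bi, V = sol[["V"]],
        re_lead = Re(lead), im_lead = Im(lead),
        stable = st$stable, spiral = st$spiral,
        physical = v >= 0)
      ## Hopf: leading COMPLEX pair real part changes sign
      if (!is.na(prev_stab[bi]) && xor(prev_stab[bi], st$stable)) {
        hb <- .refine_hb(params, axis, prev_val, v, branches[[bi]], hb_tol)
        if (!is.null(hb)) {
          hb$branch <- bi
          bifs[[length(bifs) + 1]] <- hb
        }
      }
      prev_stab[bi] <- st$stable
      branches[[bi]] <- sol
    }
    prev_val <- v
  }
  structure(list(points = do.call(rbind, rows), bifurcations = bifs,
                 axis = axis, params = params),
            class = "tp06_branch")
}

## bisect a stability change between two axis values; classifies HB
## (complex pair crossing) vs eigenvalue-zero crossing (fold-type)
.refine_hb <- function(params, axis, v_lo, v_hi, state, tol) {
  stab_at <- function(v, st) {
    sol <- .newton_ep(st, .with_axis(params, axis, v))
    if (is.null(sol)) return(NULL)
    s <- ep_stability(sol, .with_axis(params, axis, v))
    list(sol = sol, stable = s$stable, spiral = s$spiral,
         ev = s$eigenvalues[1])
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
  crossing <- if (Im(a$ev) != 0 || Im(b$ev) != 0) "HB" else "ZE"
  list(type = crossing, value = (v_lo + v_hi) / 2, state = st,
       omega = abs(Im(a$ev)))
}

#' @export
print.tp06_branch <- function(x, ...) {
  cat("Equilibrium branch along", x$axis, "(",
      nrow(x$points), "points )\n")
  for (b in x$bifurcations)
    cat(sprintf("  %s at %s = %.5g (branch %s)\n", b$type, x$axis,
                b$value, b$branch))
  invisible(x)
}

#' Classify post-pacing behavior of the non-paced cell
#'
#' Runs the unstimulated model from a supplied state and classifies the
#' outcome over the final window: sustained spontaneous V_m oscillation
#' (SO), decay to a depolarised equilibrium (arrest), or repolarisation to
#' the resting state.
#'
#' @param params a \code{tp06_params} object.
#' @param init initial state (typically a post-pacing state).
#' @param duration total run (ms).
#' @param window final analysis window (ms).
#' @param min_amp minimum sustained V_m oscillation amplitude (mV).
#' @param rest_V resting-potential threshold (mV).
#' @return list: \code{outcome} in \{"SO", "EP_depolarized", "rest"\}; for
#'   SOs the mean period and the V_m extrema (\code{SO_min}, \code{SO_max}).
#' @export
detect_spontaneous_oscillation <- function(params, init, duration = 300000,
                                           window = 60000, min_amp = 1,
                                           rest_V = -75) {
  tr <- simulate_free(params, init, duration, step = 2)
  sel <- tr[, "time"] >= duration - window
  V <- tr[sel, "V"]; tt <- tr[sel, "time"]
  if (utils::tail(V, 1) < rest_V && max(V) < rest_V)
    return(list(outcome = "rest"))
  ex <- .find_extrema(tt, V, min_amp)
  if (length(ex$idx) >= 4) {
    pk <- tt[ex$idx][ex$kind == 1L]
    return(list(outcome = "SO", period = mean(diff(pk)),
                SO_min = min(V[ex$idx]), SO_max = max(V[ex$idx])))
  }
  if (utils::tail(V, 1) >= rest_V) return(list(outcome = "EP_depolarized"))
  list(outcome = "rest")
}

#' Two-parameter bifurcation curves of the non-paced cell
#'
#' For each value of the second axis, locates along the first axis the
#' Hopf point of the depolarised equilibrium branch (stability-change
#' bisection) and the onset/offset of spontaneous oscillations (bisection
#' on \code{\link{detect_spontaneous_oscillation}} outcomes from a
#' post-pacing state), assembling the HB, SO_1 and SO_2 loci that separate
#' the quiescent, oscillating and arrested areas of the plane.
#'
#' @param params base \code{tp06_params} (K_i fixed by convention).
#' @param axis1,range1 scanned axis: name and c(lo, hi) normalized range.
#' @param axis2,values2 second axis name and its grid.
#' @param tol1 bisection tolerance on axis1.
#' @param so if TRUE, also locate the spontaneous-oscillation boundaries
#'   (costly: each probe is a long unstimulated run).
#' @param so_duration,so_window run length and analysis window (ms) per
#'   SO probe.
#' @param pace_protocol pacing used to reach the post-pacing state for SO
#'   probes.
#' @param pace_beats stimulus budget per SO probe.
#' @return data.frame with one row per axis2 value: \code{HB} (axis1 value
#'   of the stability change of the depolarised equilibrium, NA when its
#'   stability does not change over the range), \code{SO1}, \code{SO2}
#'   (oscillation onset/offset, NA when absent).
#' @export
two_parameter_curves <- function(params, axis1, range1, axis2, values2,
                                 tol1 = 0.01, so = TRUE,
                                 so_duration = 120000, so_window = 40000,
                                 pace_protocol = make_pacing(5000),
                                 pace_beats = 20) {
  if (!(axis1 %in% .tp06_scale_names)) stop("unknown axis1: ", axis1)
  if (!(axis2 %in% .tp06_scale_names)) stop("unknown axis2: ", axis2)
  top_ep <- function(p) {
    eps <- find_equilibria(p)
    if (!length(eps)) return(NULL)
    eps[[length(eps)]]
  }
  so_state <- function(p) {
    tr <- simulate_paced(p, pace_protocol, n_beats = pace_beats,
                         stop = "converge")
    out <- detect_spontaneous_oscillation(p, tr$final_state,
                                          duration = so_duration,
                                          window = so_window)
    out$outcome == "SO"
  }
  rows <- lapply(values2, function(v2) {
    base <- .with_axis(params, axis2, v2)
    ## HB: bisect the stability change of the depolarised equilibrium
    p_lo <- .with_axis(base, axis1, range1[1])
    p_hi <- .with_axis(base, axis1, range1[2])
    e_lo <- top_ep(p_lo); e_hi <- top_ep(p_hi)
    hb <- NA_real_
    if (!is.null(e_lo) && !is.null(e_hi) &&
        xor(e_lo$stability$stable, e_hi$stability$stable)) {
      lo <- range1[1]; hi <- range1[2]
      s_lo <- e_lo$stability$stable
      while (hi - lo > tol1) {
        mid <- (lo + hi) / 2
        em <- top_ep(.with_axis(base, axis1, mid))
        if (is.null(em)) break
        if (identical(em$stability$stable, s_lo)) lo <- mid else hi <- mid
      }
      hb <- (lo + hi) / 2
    }
    so1 <- so2 <- NA_real_
    if (so) {
      grid <- seq(range1[1], range1[2], length.out = 5)
      has <- vapply(grid, function(g)
        so_state(.with_axis(base, axis1, g)), TRUE)
      flips <- which(diff(has) != 0)
      bisect_so <- function(lo, hi, lo_has) {
        while (hi - lo > max(tol1, 0.02)) {
          mid <- (lo + hi) / 2
          if (identical(so_state(.with_axis(base, axis1, mid)), lo_has))
            lo <- mid else hi <- mid
        }
        (lo + hi) / 2
      }
      if (length(flips) >= 1)
        so1 <- bisect_so(grid[flips[1]], grid[flips[1] + 1], has[flips[1]])
      if (length(flips) >= 2)
        so2 <- bisect_so(grid[flips[2]], grid[flips[2] + 1], has[flips[2]])
    }
    data.frame(axis2 = v2, HB = hb, SO1 = so1, SO2 = so2)
  })
  out <- do.call(rbind, rows)
  attr(out, "axes") <- c(axis1, axis2)
  out
}
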