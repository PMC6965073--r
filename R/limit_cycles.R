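## flow map over the free variables: integrate the full model for T ms.
## lsoda can return early ("excessive precision") on strongly perturbed
## initial conditions; detect truncated output and retry with relaxed
## tolerances rather than silently using the wrong time point.
.flow <- function(y_full, params, T, rtol = .default_rtol,
                  atol = .default_atol()) {
  for (relax in c(1, 100, 1e4)) {
    out <- tryCatch(
      suppressWarnings(
        integrate_span(setNames(y_full, .tp06_state_names), params,
                       c(0, T / 2, T), stim = 0,
                       rtol = rtol * relax, atol = atol * relax)),
      error = function(e) NULL)
    if (!is.null(out) && nrow(out) == 3 &&
        abs(out[3, 1] - T) < 1e-9 * max(T, 1) &&
        all(is.finite(out[3, 2:20])))
      return(as.numeric(out[3, 2:20]))
  }
  stop("flow map integration failed for T = ", T)
}

#' Locate a limit cycle by single shooting
#'
#' Solves for a periodic orbit of the autonomous model (period as unknown)
#' with a Poincare phase anchor (time derivative of the anchor variable
#' zero at the section).  The monodromy matrix is built by forward
#' finite-difference integration of perturbed initial conditions; Floquet
#' multipliers are its eigenvalues, and convergence requires the trivial
#' multiplier to lie within \code{triv_tol} of 1.
#'
#' @param params a \code{tp06_params} object.
#' @param seed named state near the orbit (ideally at an extremum of the
#'   anchor variable).
#' @param period_guess initial period (ms).
#' @param anchor anchor variable; defaults to \code{"V"} when free, else
#'   the first free variable.
#' @param tol shooting residual tolerance (scaled).
#' @param triv_tol tolerance on the trivial Floquet multiplier.
#' @param max_iter Newton iteration cap.
#' @return object of class \code{tp06_orbit}: \code{state} (initial point),
#'   \code{period}, \code{multipliers}, \code{stable} (non-trivial
#'   multipliers inside the unit circle), \code{extrema} (per-variable
#'   min/max over one period), \code{residual}; or NULL with a warning on
#'   non-convergence.
#' @export
find_limit_cycle <- function(params, seed, period_guess, anchor = NULL,
                             tol = 1e-7, triv_tol = 1e-3, max_iter = 25) {
  free <- .free_indices(params)
  if (is.null(anchor))
    anchor <- if (1 %in% free) "V" else .tp06_state_names[free[1]]
  ia <- match(anchor, .tp06_state_names)
  if (!(ia %in% free)) stop("anchor variable is frozen")
  y <- as.numeric(apply_clamps(as_state(seed), params))
  T <- period_guess
  f <- .rhs_fun(params)
  typ <- .state_typical
  n <- length(free)
  ## phase anchor: the anchor coordinate of the initial point is pinned to
  ## its seed value, so the unknowns are the remaining free coordinates
  ## plus the period (pinning works at any phase of the orbit, unlike a
  ## derivative-zero section, and the seed is taken in the orbit's quiet
  ## phase where the closure error is least sensitive to the period)
  vfree <- setdiff(free, ia)
  res_fun <- function(y, T) {
    ph <- .flow(y, params, T)
    (ph[free] - y[free]) / typ[free]
  }
  ## pre-refine the period: spiky (relaxation-type) orbits make the
  ## closure residual exquisitely sensitive to sub-ms period errors, far
  ## outside Newton's basin when the seed period comes from sampled peaks
  if (T > 50) {
    gT <- function(Tc) {
      ph <- .flow(y, params, Tc)
      sqrt(sum(((ph[free] - y[free]) / typ[free])^2))
    }
    ## the closure error of spiky orbits has a deep, narrow minimum in T:
    ## locate it by grid search, then polish by local optimisation
    Ts <- seq(T * 0.99 - 2, T * 1.01 + 2, length.out = 41)
    gs <- vapply(Ts, function(Tc) tryCatch(gT(Tc), error = function(e) Inf), 0)
    k <- which.min(gs)
    lo <- Ts[max(1, k - 1)]; hi <- Ts[min(length(Ts), k + 1)]
    opt <- stats::optimize(gT, c(lo, hi), tol = 1e-8)
    T <- opt$minimum
  }
  best <- NULL
  for (it in seq_len(max_iter)) {
    ph <- .flow(y, params, T)
    Fv <- (ph[free] - y[free]) / typ[free]
    rn <- max(abs(Fv))
    if (is.null(best) || rn < best$rn)
      best <- list(y = y, T = T, rn = rn, ph = ph)
    if (rn < tol) break
    ## Jacobian columns: perturbed-flow differences for the unpinned
    ## coordinates, plus the period derivative
    J <- matrix(0, n, n)
    for (k in seq_along(vfree)) {
      j <- vfree[k]
      h <- 1e-6 * max(abs(y[j]), 1e-3 * typ[j])
      yp <- y; yp[j] <- y[j] + h
      dcol <- (.flow(yp, params, T)[free] - ph[free]) / h
      dcol[match(j, free)] <- dcol[match(j, free)] - 1
      J[, k] <- dcol / typ[free]
    }
    J[, n] <- f(ph)[free] / typ[free]
    step <- tryCatch(solve(J, -Fv), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      y2 <- y; y2[vfree] <- y[vfree] + lam * step[seq_along(vfree)]
      T2 <- T + lam * step[n]
      if (T2 > max(1, 0.3 * period_guess) && T2 < 3 * period_guess) {
        r2 <- tryCatch(max(abs(res_fun(y2, T2))), error = function(e) Inf)
        if (is.finite(r2) && r2 < rn) break
      }
      lam <- lam / 2
      if (lam < 1e-4) break
    }
    if (lam < 1e-4) break
    y <- y2; T <- T2
  }
  if (best$rn > tol * 100) {
    warning("shooting did not converge; best residual ", signif(best$rn, 3))
    return(NULL)
  }
  y <- best$y; T <- best$T
  ## monodromy by central differences at tightened solver tolerance — the
  ## trivial-multiplier accuracy is the convergence gate
  atol_m <- .default_atol() / 100
  M <- matrix(0, n, n)
  for (k in seq_len(n)) {
    j <- free[k]
    h <- 3e-5 * max(abs(y[j]), 1e-2 * typ[j])
    yp <- y; yp[j] <- y[j] + h
    ym <- y; ym[j] <- y[j] - h
    M[, k] <- (.flow(yp, params, T, rtol = 1e-10, atol = atol_m)[free] -
               .flow(ym, params, T, rtol = 1e-10, atol = atol_m)[free]) /
      (2 * h)
  }
  mu <- eigen(M, only.values = TRUE)$values
  mu <- mu[order(-Mod(mu))]
  i_triv <- which.min(Mod(mu - 1))
  if (Mod(mu[i_triv] - 1) > triv_tol)
    warning("trivial Floquet multiplier off by ",
            signif(Mod(mu[i_triv] - 1), 3))
  nontriv <- mu[-i_triv]
  orb <- integrate_span(setNames(y, .tp06_state_names), params,
                        seq(0, T, length.out = 201), stim = 0)
  extrema <- apply(orb[, 2:20, drop = FALSE], 2, range)
  structure(list(state = setNames(y, .tp06_state_names), period = T,
                 multipliers = mu, trivial_error = Mod(mu[i_triv] - 1),
                 stable = all(Mod(nontriv) < 1),
                 extrema = extrema, residual = best$rn, anchor = anchor),
            class = "tp06_orbit")
}

#' @export
print.tp06_orbit <- function(x, ...) {
  cat(sprintf("Limit cycle: period %.2f ms, %s, |mu|max(nontrivial) %.4f\n",
              x$period, if (x$stable) "stable" else "unstable",
              max(Mod(x$multipliers[-which.min(Mod(x$multipliers - 1))]))))
  invisible(x)
}

#' Seed a shooting run from a simulated oscillation
#'
#' Measures the oscillation period from peaks of the anchor variable in a
#' free-run trace and returns, as the seed, the state in the final cycle
#' at which the scaled right-hand side is smallest — the orbit's quiet
#' phase, where the shooting closure error is least sensitive to period
#' and phase errors.
#'
#' @param params parameter set used for the trace.
#' @param init state to start the free run from.
#' @param duration run length (ms).
#' @param anchor variable whose peaks define the period.
#' @param min_amp minimal oscillation amplitude for peak detection.
#' @return list(seed, period) or NULL when no oscillation is found.
#' @export
seed_orbit_from_simulation <- function(params, init, duration = 60000,
                                       anchor = "V", min_amp = 0.5) {
  tr <- integrate_span(as_state(init), params, seq(0, duration, by = 1),
                       stim = 0)
  a <- tr[, anchor]
  tt <- tr[, "time"]
  half <- tt > duration / 2
  ex <- .find_extrema(tt[half], a[half], min_amp)
  pk <- which(ex$kind == 1L)
  if (length(pk) < 3) return(NULL)
  i2 <- ex$idx[pk[length(pk) - 1]]
  i1 <- ex$idx[pk[length(pk) - 2]]
  period <- tt[half][i2] - tt[half][i1]
  ## quiet-phase selection over the final cycle: the state whose velocity,
  ## normalised by each variable's own oscillation amplitude, is smallest
  ## (this lands in the slow refill phase, away from the release spike)
  cyc <- which(half)[i1:i2]
  f <- .rhs_fun(params)
  free <- .free_indices(params)
  amp <- apply(tr[cyc, 1 + free, drop = FALSE], 2, function(v)
    max(diff(range(v)), 1e-12))
  speeds <- vapply(cyc, function(i)
    max(abs(f(as.numeric(tr[i, 2:20]))[free]) / amp), 0)
  idx <- cyc[which.min(speeds)]
  list(seed = setNames(tr[idx, 2:20], .tp06_state_names),
       period = period)
}

#' One-parameter limit-cycle branch continuation
#'
#' Warm-started shooting along an axis grid; flags Floquet-multiplier
#' crossings of the unit circle between consecutive points (saddle-node of
#' limit cycles at +1, period doubling at -1, Neimark-Sacker for a complex
#' pair) and a homoclinic-like termination when the period exceeds
#' \code{hom_period} or grows rapidly as the branch is lost.
#'
#' @param params base parameter set.
#' @param axis scaling knob name.
#' @param values normalized axis values in traversal order.
#' @param seed,period_guess starting orbit (at \code{values[1]}).
#' @param hom_period period cap (ms) interpreted as homoclinic approach.
#' @param anchor anchor variable for the phase condition.
#' @return object of class \code{tp06_lc_branch}: data.frame \code{points}
#'   (value, period, stable, leading nontrivial multiplier modulus,
#'   per-anchor extrema) and list \code{events}.
#' @export
continue_lc_branch <- function(params, axis, values, seed, period_guess,
                               hom_period = 20000, anchor = NULL) {
  rows <- list(); events <- list()
  prev <- NULL
  y <- seed; T <- period_guess
  for (v in values) {
    pv <- .with_axis(params, axis, v)
    orb <- tryCatch(
      suppressWarnings(find_limit_cycle(pv, y, T, anchor = anchor)),
      error = function(e) NULL)
    if (is.null(orb)) {
      events[[length(events) + 1]] <-
        list(type = if (!is.null(prev) && prev$period > 0.5 * hom_period)
                      "hom" else "branch_lost",
             value = v)
      break
    }
    if (orb$period > hom_period) {
      events[[length(events) + 1]] <- list(type = "hom", value = v,
                                           period = orb$period)
      break
    }
    mu_nt <- orb$multipliers[-which.min(Mod(orb$multipliers - 1))]
    lead <- mu_nt[which.max(Mod(mu_nt))]
    av <- if (is.null(anchor)) "V" else anchor
    rows[[length(rows) + 1]] <- data.frame(
      value = v, period = orb$period, stable = orb$stable,
      mod_lead = Mod(lead), re_lead = Re(lead), im_lead = Im(lead),
      amin = orb$extrema[1, av], amax = orb$extrema[2, av])
    if (!is.null(prev) && xor(prev$stable, orb$stable)) {
      type <- if (abs(Im(lead)) > 1e-8) "NSB"
              else if (Re(lead) < 0) "PDB" else "SNB_LC"
      events[[length(events) + 1]] <-
        list(type = type, value = v, multiplier = lead)
    }
    prev <- orb
    y <- orb$state; T <- orb$period
  }
  structure(list(points = do.call(rbind, rows), events = events,
                 axis = axis), class = "tp06_lc_branch")
}
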