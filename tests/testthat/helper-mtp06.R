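# shared fixtures, built in code

# resting-range initial state for the modified variants
low_ca_init <- function(params) steady_state_initials(params = params)

# a synthetic AP-like voltage trace on a 1-ms grid: linear upstroke,
# exponential repolarisation with analytically known 90% crossing time,
# optional damped plateau oscillations
synth_ap <- function(CL = 4000, V_rest = -85, V_peak = 40, tau = 120,
                     t_up = 2, osc = NULL) {
  tt <- seq(0, CL - 1)
  V <- ifelse(tt <= t_up, V_rest + (V_peak - V_rest) * tt / t_up,
              V_rest + (V_peak - V_rest) * exp(-(tt - t_up) / tau))
  if (!is.null(osc)) {
    w <- tt >= osc$t0 & tt <= osc$t1
    V[w] <- V[w] + osc$amp * exp(-(tt[w] - osc$t0) / osc$tau) *
      sin(2 * pi * (tt[w] - osc$t0) / osc$period)
  }
  list(time = tt, V = V)
}

# analytic APD90 of synth_ap without oscillations: V crosses
# V_peak - 0.9 (V_peak - V_rest) when exp(-(t - t_up)/tau) = 0.1
synth_apd90 <- function(tau = 120, t_up = 2) t_up + tau * log(10)

# shared fixture: the unstable EAD-type quasi-limit cycle of the
# xs^2-frozen fast subsystem of the g_Kr-reduced mTP06b cell, located by
# shooting seeded from the Hopf normal form
qlc_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    p <- build_parameters("mTP06b", list(gKr = 0.6))
    fs <- fast_subsystem("xs", p, Nai = 6, CaSR = 1.5)
    pv <- fs(0.18)
    eps <- find_equilibria(pv)
    e3 <- eps[[length(eps)]]
    eg <- eigen(jacobian(e3$state, pv))
    cc <- which(Im(eg$values) != 0)
    k <- cc[which.max(Re(eg$values[cc]))]
    omega <- abs(Im(eg$values[k]))
    vec <- Re(eg$vectors[, k])
    free <- mtp06:::.free_indices(pv)
    seed <- e3$state
    seed[free] <- seed[free] + (4 / abs(vec[1])) * vec
    orb <- suppressWarnings(
      find_limit_cycle(pv, seed, 2 * pi / omega, anchor = "V"))
    cache <<- list(params = pv, ep = e3, omega = omega, orbit = orb)
    cache
  }
})
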