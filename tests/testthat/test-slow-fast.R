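test_that("the reduced RHS equals the full RHS on the free variables", {
  p <- build_parameters("mTP06b", list(gKr = 0.6))
  fs <- fast_subsystem("xs", p, Nai = 6, CaSR = 1.5)
  pv <- fs(0.09)
  free <- mtp06:::.free_indices(pv)
  set.seed(11)
  base <- steady_state_initials(params = pv)
  for (i in 1:25) {
    st <- base
    st["V"] <- runif(1, -90, 30)
    st["Cai"] <- base[["Cai"]] * exp(runif(1, -1, 1))
    st["Cass"] <- base[["Cass"]] * exp(runif(1, -1, 1))
    g <- runif(11, 0, 1)
    st[c("m", "h", "j", "d", "f", "f2", "xr1", "xr2", "r", "s", "fCass")] <- g
    st <- mtp06:::apply_clamps(st, pv)
    d_red <- rhs(0, st, pv)
    d_full <- rhs(0, st, p)   # unfrozen model at the same state
    expect_equal(d_red[free], d_full[free], tolerance = 1e-12)
    expect_true(all(d_red[c("xs", "Nai", "Ki", "CaSR")] == 0))
  }
})

test_that("xs^2 = 0 silences I_Ks in the reduced system", {
  p <- build_parameters("mTP06b")
  fs <- fast_subsystem("xs", p, Nai = 6, CaSR = 0.5)
  pv <- fs(0)
  st <- steady_state_initials(params = pv)
  st["V"] <- -10
  st <- mtp06:::apply_clamps(st, pv)
  expect_identical(compute_currents(st, pv)[["I_Ks"]], 0)
})

test_that("freezing at a full equilibrium leaves the reduced equilibrium fixed", {
  p <- build_parameters("mTP06b", list(gKr = 0.7), fix_Ki = TRUE,
                        fix_Nai = TRUE, Nai_value = 6)
  eps <- find_equilibria(p)
  e3 <- eps[[length(eps)]]
  fs <- fast_subsystem("xs", p, Nai = 6, CaSR = e3$state[["CaSR"]])
  pv <- fs(e3$state[["xs"]]^2)
  sol <- mtp06:::.newton_ep(e3$state, pv)
  expect_false(is.null(sol))
  free <- mtp06:::.free_indices(pv)
  ## agreement is conditioning-limited: residuals converge to ~1e-12 but
  ## near-neutral slow modes amplify them into state differences of up to
  ## ~1e-6 (scaled)
  expect_lt(max(abs(sol[free] - e3$state[free]) /
                mtp06:::.state_typical[free]), 1e-6)
})

test_that("spiral type of the depolarised quasi-equilibrium separates the variants", {
  ## g_Kr-reduced mTP06b: spiral sink; g_Kr-reduced mTP06a: spiral source
  pb <- build_parameters("mTP06b", list(gKr = 0.6))
  eb <- find_equilibria(fast_subsystem("xs", pb, Nai = 6, CaSR = 1.5)(0))
  e3b <- eb[[length(eb)]]
  expect_true(e3b$stability$stable)
  expect_identical(e3b$stability$annotation, "spiral sink")

  pa <- build_parameters("mTP06a", list(gKr = 0.6))
  ea <- find_equilibria(fast_subsystem("xs", pa, Nai = 6, CaSR = 0.5)(0))
  e3a <- ea[[length(ea)]]
  expect_false(e3a$stability$stable)
  expect_identical(e3a$stability$annotation, "spiral source")
})

test_that("trajectory overlays report trapping only for the g_Kr-reduced mTP06b", {
  run_case <- function(variant, gKr, casr) {
    ov <- if (gKr != 1) list(gKr = gKr) else list()
    p <- build_parameters(variant, overrides = ov)
    fs <- fast_subsystem("xs", p, Nai = 6, CaSR = casr)
    qb <- quasi_branch(fs, seq(0, 0.3, by = 0.02))
    pf <- p; pf$fix_Ki <- TRUE; pf$fix_Nai <- TRUE; pf$Nai_value <- 6
    pf <- freeze_states(pf, CaSR = casr)
    tr <- simulate_paced(pf, make_pacing(10000), n_beats = 1,
                         stop = "beats", record = c("V", "xs"))
    overlay_trajectory(data.frame(time = tr$time, V = tr$states[, "V"],
                                  xs = tr$states[, "xs"]), qb)
  }
  ov_b <- run_case("mTP06b", 0.6, 1.5)
  expect_true(ov_b$trapping$trapped)
  expect_gte(ov_b$trapping$dwell_ms, 100)
  ov_n <- run_case("mTP06b", 1.0, 0.5)
  expect_false(ov_n$trapping$trapped)
  ov_a <- run_case("mTP06a", 0.6, 0.5)
  expect_false(ov_a$trapping$trapped)
})

test_that("degenerate overlays behave: constant trajectory projects to a point", {
  p <- build_parameters("mTP06b", list(gKr = 0.6))
  fs <- fast_subsystem("xs", p, Nai = 6, CaSR = 1.5)
  qb <- quasi_branch(fs, seq(0, 0.1, by = 0.05))
  tr <- data.frame(time = 0:10, V = rep(-85, 11), xs = rep(0.1, 11))
  ov <- overlay_trajectory(tr, qb)
  expect_identical(nrow(unique(ov$projection[, c("xs2", "V")])), 1L)
  expect_error(overlay_trajectory(data.frame(time = 1, foo = 2), qb),
               "must provide")
})
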