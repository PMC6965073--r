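# the non-paced analyses fix K_i at 140 mM (removal of the conservation
# degeneracy); Na_i stays free unless a protocol fixes it

test_that("the resting equilibrium matches the relaxation limit", {
  p <- build_parameters("mTP06b", fix_Ki = TRUE)
  eps <- find_equilibria(p, V_seeds = seq(-95, -75, by = 2.5))
  expect_gte(length(eps), 1)
  e1 <- eps[[1]]
  expect_lt(e1$residual, 1e-10)
  expect_true(e1$stability$stable)
  ## a 1-mV perturbation decays back in direct simulation
  st <- e1$state; st["V"] <- st[["V"]] + 1
  fr <- simulate_free(p, st, 2000, step = 5)
  expect_lt(abs(fr[nrow(fr), "V"] - e1$state[["V"]]), 0.05)
})

test_that("three equilibria exist with V_E3 unstable at positive g_Kr", {
  p <- build_parameters("mTP06b", list(gKr = 0.7), fix_Ki = TRUE)
  eps <- find_equilibria(p)
  expect_identical(length(eps), 3L)
  expect_true(all(vapply(eps, function(e) e$residual, 0) < 1e-10))
  V <- vapply(eps, function(e) e$state[["V"]], 0)
  expect_true(all(diff(V) > 0))
  expect_false(eps[[3]]$stability$stable)
  expect_true(eps[[1]]$stability$stable)
})

test_that("Jacobian eigenvalues are finite-difference converged", {
  p <- build_parameters("mTP06b", fix_Ki = TRUE)
  eps <- find_equilibria(p, V_seeds = seq(-95, -75, by = 2.5))
  st <- eps[[1]]$state
  e1 <- eigen(jacobian(st, p, rel_step = 1e-6), only.values = TRUE)$values
  e2 <- eigen(jacobian(st, p, rel_step = 5e-7), only.values = TRUE)$values
  l1 <- e1[which.max(Re(e1))]; l2 <- e2[which.max(Re(e2))]
  expect_lt(Mod(l1 - l2) / Mod(l2), 1e-4)
})

test_that("branch continuation records stability without spurious bifurcations", {
  p <- build_parameters("mTP06b", fix_Ki = TRUE)
  br <- continue_ep_branch(p, "gKr", seq(1.0, 0.4, by = -0.1))
  pts <- br$points
  expect_identical(length(unique(pts$branch)), 3L)
  b1 <- pts[pts$branch == 1, ]
  expect_true(all(b1$stable))            # resting branch uniformly stable
  b3 <- pts[pts$branch == 3, ]
  expect_true(all(!b3$stable))           # depolarised branch unstable
  expect_identical(length(br$bifurcations), 0L)
})

test_that("I_Ks-eliminated cell has a stabilized depolarised equilibrium", {
  ## with g_Ks = 0 the Hopf point moves above the control g_Kr, so V_E3 is
  ## already stable at g_Kr = 1
  p <- build_parameters("mTP06b", list(gKs = 0), fix_Ki = TRUE)
  eps <- find_equilibria(p, V_seeds = seq(-20, 20, by = 2.5))
  e3 <- eps[[length(eps)]]
  expect_gt(e3$state[["V"]], -20)
  expect_true(e3$stability$stable)
})

test_that("spontaneous-oscillation detection separates SO from quiescence", {
  p <- build_parameters("mTP06b", list(gKr = 0.15), fix_Ki = TRUE)
  pre <- simulate_paced(p, make_pacing(5000), n_beats = 60, stop = "converge")
  so <- detect_spontaneous_oscillation(p, pre$final_state,
                                       duration = 120000, window = 40000)
  expect_identical(so$outcome, "SO")
  expect_gt(so$SO_max - so$SO_min, 1)
  expect_gt(so$period, 100)

  p2 <- build_parameters("mTP06b", fix_Ki = TRUE)
  st <- steady_state_initials(params = p2)
  so2 <- detect_spontaneous_oscillation(p2, st, duration = 30000,
                                        window = 10000)
  expect_identical(so2$outcome, "rest")
})

test_that("two-parameter curves handle a line without bifurcations", {
  ## the I_Ks-free cell keeps a stable depolarised equilibrium across the
  ## whole g_Kr range: no Hopf crossing, no spontaneous oscillations
  p <- build_parameters("mTP06b", fix_Ki = TRUE)
  cv <- two_parameter_curves(p, "gKr", c(0.3, 1.0), "gKs", 0,
                             tol1 = 0.05, so = FALSE)
  expect_identical(nrow(cv), 1L)
  expect_true(is.na(cv$HB))
  expect_identical(attr(cv, "axes"), c("gKr", "gKs"))
  expect_error(two_parameter_curves(p, "bogus", c(0, 1), "gKs", 0),
               "unknown axis1")
})
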