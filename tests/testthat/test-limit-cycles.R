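test_that("shooting converges on the quasi-limit cycle with a clean trivial multiplier", {
  fx <- qlc_fixture()
  expect_false(is.null(fx$orbit))
  expect_lt(fx$orbit$residual, 1e-5)
  expect_lt(fx$orbit$trivial_error, 1e-3)
  expect_false(fx$orbit$stable)   # the periodic branches here are unstable
})

test_that("the Hopf frequency predicts the nascent orbit period within 20%", {
  fx <- qlc_fixture()
  T_hopf <- 2 * pi / fx$omega
  expect_lt(abs(fx$orbit$period - T_hopf) / fx$orbit$period, 0.2)
})

test_that("limit-cycle period matches long-simulation oscillation period", {
  ## stable/weakly modulated Ca oscillation of the voltage-clamped cell
  p <- build_parameters("mTP06b")
  p$clamp_Vm <- TRUE; p$Vm_value <- -1.5
  p$fix_Nai <- TRUE; p$fix_Ki <- TRUE
  st <- steady_state_initials(V_rest = -85, params = p)
  st["V"] <- -1.5
  sd <- seed_orbit_from_simulation(p, st, duration = 120000,
                                   anchor = "Cass", min_amp = 0.001)
  expect_false(is.null(sd))
  orb <- suppressWarnings(
    find_limit_cycle(p, sd$seed, sd$period, anchor = "CaSR"))
  expect_false(is.null(orb))
  expect_lt(abs(orb$period - sd$period) / sd$period, 0.01)
})
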