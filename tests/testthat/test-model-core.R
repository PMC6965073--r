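test_that("variant presets carry the published scalings", {
  a <- effective_scales(build_parameters("mTP06a"))
  expect_equal(a[["gKs"]], 0.4)
  expect_equal(a[["gKr"]], 1.5)
  expect_equal(a[["Pup"]], 0.6)
  expect_equal(a[["gCaL"]], 1)
  expect_equal(a[["tau_fL"]], 1)

  b <- effective_scales(build_parameters("mTP06b"))
  expect_equal(b[["tau_fL"]], 0.5)
  expect_equal(b[["gCaL"]], 2.0)
  expect_equal(b[["gKs"]], 0.4)

  o <- effective_scales(build_parameters("original"))
  expect_true(all(o == 1))

  ## overrides are normalized to the variant control and multiply the preset
  m <- effective_scales(build_parameters("mTP06b", list(gKr = 0.4)))
  expect_equal(m[["gKr"]], 1.5 * 0.4)

  expect_error(build_parameters("mTP06b", list(gXX = 1)), "unknown scaling")
  expect_error(build_parameters("mTP06b", list(gKr = -1)), ">= 0")
  expect_error(build_parameters("tp08"))
})

test_that("rhs and compute_currents are mutually consistent", {
  p <- build_parameters("mTP06b")
  st <- steady_state_initials(params = p)
  d <- rhs(0, st, p)
  cur <- compute_currents(st, p)
  ## dV/dt = stim - sum of the 12 sarcolemmal currents, exactly
  expect_equal(d[["V"]], -sum(cur[1:12]), tolerance = 1e-12)
  d60 <- rhs(0, st, p, stim = 60)
  expect_equal(d60[["V"]] - d[["V"]], 60, tolerance = 1e-12)

  ## zeroed conductance kills its current at any state
  p0 <- build_parameters("mTP06b", list(gKs = 0))
  st2 <- st; st2["V"] <- -20; st2["xs"] <- 0.5
  expect_identical(compute_currents(st2, p0)[["I_Ks"]], 0)

  expect_error(rhs(0, replace(st, "V", NaN), p), "non-finite")
})

test_that("NCX current reverses sign exactly once along a V sweep", {
  p <- build_parameters("original")
  st <- steady_state_initials(params = p)
  Vs <- seq(-90, 60, by = 0.5)
  incx <- vapply(Vs, function(v) {
    s <- st; s["V"] <- v
    compute_currents(s, p)[["I_NCX"]]
  }, 0)
  flips <- sum(diff(sign(incx)) != 0)
  expect_identical(flips, 1L)
})

test_that("clamped and frozen variables stay exactly constant", {
  p <- build_parameters("mTP06b", fix_Ki = TRUE, fix_Nai = TRUE,
                        clamp_Vm = TRUE, Vm_value = -40)
  p <- freeze_states(p, CaSR = 1.2)
  st <- steady_state_initials(params = p)
  d <- rhs(0, st, p)
  expect_identical(unname(d[c("V", "Nai", "Ki", "CaSR")]), rep(0, 4))
  out <- integrate_span(st, p, c(0, 500))
  expect_identical(unname(out[nrow(out), "V"]), -40)
  expect_identical(unname(out[nrow(out), "Ki"]), 140)
  expect_identical(unname(out[nrow(out), "CaSR"]), 1.2)
})

test_that("mTP06b with tau/gCaL scalings reverted reproduces mTP06a exactly", {
  pb <- build_parameters("mTP06b", list(tau_fL = 2, gCaL = 0.5))
  pa <- build_parameters("mTP06a")
  st <- steady_state_initials(params = pa)
  ta <- integrate_span(st, pa, seq(0, 400, by = 2), stim = 0)
  tb <- integrate_span(st, pb, seq(0, 400, by = 2), stim = 0)
  expect_identical(ta, tb)
})

test_that("resting initials respect invariants and gates sit on their curves", {
  p <- build_parameters("mTP06b")
  st <- steady_state_initials(params = p)
  gates <- st[c("m", "h", "j", "d", "f", "f2", "fCass",
                "xr1", "xr2", "xs", "r", "s", "Rbar")]
  expect_true(all(gates >= 0 & gates <= 1))
  expect_true(all(st[c("Nai", "Ki", "Cai", "Cass", "CaSR")] > 0))
  ## gate derivatives vanish at the resting potential
  d <- rhs(0, st, p)
  expect_lt(max(abs(d[c("m", "h", "j", "d", "f", "f2", "xr1",
                        "xr2", "xs", "r", "s", "Rbar")])), 1e-12)
  expect_error(steady_state_initials(-40), "resting range")
})

test_that("trajectories keep gates in [0,1] and concentrations positive", {
  p <- build_parameters("mTP06b", list(gKr = 0.6), fix_Ki = TRUE)
  tr <- simulate_paced(p, make_pacing(2000), n_beats = 3, stop = "beats",
                       record = state_names())
  gates <- tr$states[, c("m", "h", "j", "d", "f", "f2", "fCass",
                         "xr1", "xr2", "xs", "r", "s", "Rbar")]
  expect_true(all(gates >= -1e-6 & gates <= 1 + 1e-6))
  expect_true(all(tr$states[, c("Nai", "Ki", "Cai", "Cass", "CaSR")] > 0))
})
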