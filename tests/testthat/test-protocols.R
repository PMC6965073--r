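test_that("pacing protocol defaults and validation", {
  pr <- make_pacing(5000)
  expect_equal(pr$amplitude, 60)
  expect_equal(pr$width, 1)
  expect_equal(pr$CL, 5000)
  expect_error(make_pacing(50), ">= 100")
  expect_error(make_pacing(200, width = 300), "exceed")
  expect_error(make_clamp_protocol(pulse_ms = 0), "invalid clamp")
})

test_that("grids are reproducible arithmetic with recorded traversal", {
  g <- make_grid("gKr", 0, 1, 0.001)
  expect_length(g$values, 1001)
  g2 <- make_grid("CL", 750, 5250, 250)
  expect_length(g2$values, 19)
  g3 <- make_grid("gKr", 0.5, 1, 0.1, descending = TRUE)
  expect_equal(g3$values[1], 1)
  expect_error(make_grid("bogus", 0, 1, 0.1), "unknown axis")
  expect_error(make_grid("gKr", 0, 1, -0.1), "positive")
})

test_that("beta-AS scaling sets compose with variant presets", {
  s <- beta_as_scalings()
  expect_equal(unname(s[c("gCaL", "gKs")]), c(2.5, 2.0))
  s2 <- beta_as_scalings(1, 1, 1)
  expect_true(all(s2 == 1))
  p <- build_parameters("mTP06b", overrides = beta_as_scalings(1.6, 2.0, 1.67))
  eff <- effective_scales(p)
  expect_equal(eff[["gCaL"]], 2.0 * 1.6)
  expect_equal(eff[["gKs"]], 0.4 * 2.0)
  expect_equal(eff[["Pup"]], 0.6 * 1.67)
  expect_error(beta_as_scalings(-1), "> 0")
  expect_error(beta_as_scalings(extra = list(foo = 2)), "unknown scaling")
})

test_that("regression fixtures rerun to numerically identical traces", {
  pr <- make_pacing(2000)
  f1 <- regression_fixture("mTP06b", pr, n_beats = 3)
  f2 <- regression_fixture("mTP06b", pr, n_beats = 3)
  expect_identical(f1$states, f2$states)
  expect_identical(f1$beats$APD90, f2$beats$APD90)
  expect_equal(f1$provenance$variant, "mTP06b")
})
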