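test_that("zero-amplitude pacing leaves the cell within 1 mV of rest", {
  p <- build_parameters("mTP06a")
  ## settle from the nominal resting values first: the packaged initials
  ## are resting-range, not the exact equilibrium
  st <- steady_state_initials(params = p)
  settle <- simulate_free(p, st, 60000, step = 100,
                          record = state_names())
  init <- setNames(settle[nrow(settle), state_names()], state_names())
  pr <- make_pacing(2000, amplitude = 0)
  tr <- simulate_paced(p, pr, init = init, n_beats = 3, stop = "beats")
  V <- tr$states[, "V"]
  expect_lt(diff(range(V)), 1)
})

test_that("steady-state APD90 is solver-tolerance converged", {
  p <- build_parameters("mTP06b", fix_Ki = TRUE)
  run <- function(rtol, atol_fac) {
    at <- mtp06:::.default_atol() * atol_fac
    tr <- simulate_paced(p, make_pacing(1000), n_beats = 30, stop = "beats",
                         rtol = rtol, atol = at)
    utils::tail(tr$beats, 1)$APD90
  }
  a1 <- run(1e-8, 1)
  a2 <- run(5e-9, 0.5)
  expect_lt(abs(a1 - a2), 0.5)
})

test_that("re-running from a converged state reports convergence within 2 beats", {
  p <- build_parameters("mTP06b", fix_Ki = TRUE)
  tr <- simulate_paced(p, make_pacing(1000), n_beats = 200, stop = "converge")
  expect_true(tr$converged)
  tr2 <- simulate_paced(p, make_pacing(1000), init = tr$final_state,
                        n_beats = 10, stop = "converge")
  expect_true(tr2$converged)
  expect_lte(tr2$n_beats, 2)
})

test_that("classification is stable to tightening the solver tolerance", {
  p <- build_parameters("mTP06b", list(gKr = 0.6), fix_Ki = TRUE)
  tr <- simulate_paced(p, make_pacing(5000), n_beats = 20, stop = "beats")
  lab1 <- classify_behavior(tr)
  tr2 <- simulate_paced(p, make_pacing(5000), n_beats = 20, stop = "beats",
                        rtol = 1e-9)
  expect_identical(lab1, classify_behavior(tr2))
  expect_true(lab1 %in% c("fR", "RF"))
})

test_that("unstimulated run from paced state at control parameters is quiescent", {
  p <- build_parameters("mTP06b", fix_Ki = TRUE)
  tr <- simulate_paced(p, make_pacing(1000), n_beats = 10, stop = "beats")
  so <- detect_spontaneous_oscillation(p, tr$final_state, duration = 30000,
                                       window = 10000)
  expect_identical(so$outcome, "rest")
})
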