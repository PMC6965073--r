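test_that("APD90 of a constructed exponential AP matches the closed form", {
  s <- synth_ap(tau = 120)
  f <- extract_ap_features(s$time, V = s$V, stim_times = 0)
  expect_equal(f$APD90, synth_apd90(tau = 120), tolerance = 0.01)
  expect_identical(f$n_ead, 0L)
  expect_equal(f$V_peak, 40)
})

test_that("plateau oscillations are counted as EADs only past the window", {
  ## damped plateau oscillation whose envelope leaves exactly three
  ## cycles above the 1-mV prominence floor, starting 300 ms post-peak
  s <- synth_ap(tau = 4000, osc = list(t0 = 300, t1 = 3999, amp = 11,
                                       tau = 310, period = 250))
  f <- extract_ap_features(s$time, V = s$V, stim_times = 0)
  expect_identical(f$n_ead, 3L)

  ## oscillations inside the 200-ms exclusion window do not count
  s2 <- synth_ap(tau = 4000, osc = list(t0 = 60, t1 = 190, amp = 11,
                                        tau = 310, period = 60))
  f2 <- extract_ap_features(s2$time, V = s2$V, stim_times = 0)
  expect_identical(f2$n_ead, 0L)

  ## sub-prominence ripple is ignored
  s3 <- synth_ap(tau = 4000, osc = list(t0 = 300, t1 = 3999, amp = 0.3,
                                        tau = 310, period = 250))
  f3 <- extract_ap_features(s3$time, V = s3$V, stim_times = 0)
  expect_identical(f3$n_ead, 0L)
})

test_that("APD90 spanning several stimuli is resolved across beats", {
  ## beat 1 never repolarises within its own window; repolarisation occurs
  ## in beat 2's window
  t1 <- seq(0, 1999); V1 <- rep(0, 2000)
  V1[1:3] <- c(-85, 40, 20)
  t2 <- seq(2000, 3999)
  V2 <- -85 + 105 * exp(-(t2 - 2000) / 300)
  f <- extract_ap_features(c(t1, t2), V = c(V1, V2), stim_times = c(0, 2000))
  expect_false(is.na(f$APD90[1]))
  expect_gt(f$APD90[1], 2000)
})

test_that("alternating extrema pruning respects the prominence floor", {
  tt <- seq(0, 999)
  v <- sin(2 * pi * tt / 200) * 10 + sin(2 * pi * tt / 20) * 1.5
  ex <- mtp06:::.find_extrema(tt, v, 8)
  expect_identical(sum(ex$kind == 1L), 5L)   # only carrier maxima survive
  ex2 <- mtp06:::.find_extrema(tt, v, 0.5)
  expect_gt(sum(ex2$kind == 1L), 5L)         # ripple kept at low floor
})

test_that("paced-trace feature extraction matches the online per-beat values", {
  p <- build_parameters("mTP06b", fix_Ki = TRUE)
  tr <- simulate_paced(p, make_pacing(1000), n_beats = 4, stop = "beats")
  f <- extract_ap_features(tr)
  expect_equal(f$APD90, tr$beats$APD90, tolerance = 1e-10)
  expect_equal(f$V_min, tr$beats$V_min, tolerance = 1e-10)
  expect_identical(f$n_ead, tr$beats$n_ead)
})

test_that("classification labels the canonical behaviors", {
  ## regular AP -> no_EAD
  p <- build_parameters("mTP06b", fix_Ki = TRUE)
  tr <- simulate_paced(p, make_pacing(2000), n_beats = 8, stop = "converge")
  expect_identical(classify_behavior(tr), "no_EAD")
  ## EAD regime at reduced g_Kr -> fR or RF
  p2 <- build_parameters("mTP06b", list(gKr = 0.6), fix_Ki = TRUE)
  tr2 <- simulate_paced(p2, make_pacing(5000), n_beats = 20, stop = "converge")
  expect_true(classify_behavior(tr2) %in% c("fR", "RF"))
  expect_gt(sum(utils::tail(tr2$beats, 10)$n_ead), 0)
})

test_that("critical-parameter bisection validates its bracket", {
  p <- build_parameters("mTP06b", fix_Ki = TRUE)
  expect_error(
    find_critical_parameter(p, make_pacing(5000), "gKr", c(0.95, 1.0),
                            resolution = 0.05, n_beats = 6),
    "classify identically")
  expect_error(
    find_critical_parameter(p, make_pacing(5000), "nope", c(0, 1)),
    "unknown axis")
})
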