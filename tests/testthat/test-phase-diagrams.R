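test_that("degenerate 1x1 plane yields a single labeled point", {
  p <- build_parameters("mTP06b", fix_Ki = TRUE)
  pd <- sweep_plane(p, make_pacing(2000), "gKr", 1.0, "gKs", 1.0,
                    n_beats = 6, first_beats = 10)
  expect_identical(nrow(pd$grid), 1L)
  expect_identical(pd$grid$label, "no_EAD")
})

test_that("overlays merge curves and compute containment statistics", {
  p <- build_parameters("mTP06b", fix_Ki = TRUE)
  pd <- sweep_plane(p, make_pacing(2000), "gKr", 1.0, "gKs", 1.0,
                    n_beats = 6, first_beats = 10)
  pd2 <- overlay_bifurcation(pd, curves = list())
  expect_identical(pd2$grid, pd$grid)
  so <- data.frame(axis1 = 1.0, axis2 = 1.0, so = FALSE)
  pd3 <- overlay_bifurcation(pd, so_region = so)
  expect_true(is.list(pd3$stats))
  out <- export_phase_diagram(pd3, dir = tempfile("pd"))
  expect_true(file.exists(out[1]))
})

test_that("warm-start hysteresis is reported, not hidden", {
  ## at the g_Kr bistability the ascending and descending traversals may
  ## disagree; the sweep must flag rather than silently average
  p <- build_parameters("mTP06b", fix_Ki = TRUE)
  pd <- sweep_plane(p, make_pacing(5000), "gKr", c(0.80, 0.75, 0.70),
                    "gKs", 1.0, n_beats = 8, first_beats = 20,
                    both_directions = TRUE)
  expect_true(all(c("label", "bistable") %in% names(pd$grid)))
  expect_identical(nrow(pd$grid), 3L)
})
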