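fx_input_tac <- simulate_input_tac(fx_input, fx_sched)
fx_tumor_tac <- simulate_tac(fx_tumor, fx_input, fx_sched)
fx_ref_tac <- simulate_tac(fx_ref, fx_input, fx_sched)

test_that("running integral is exact for constant TACs and matches fine quadrature", {
  c0 <- 4.2
  const <- tac(fx_sched, rep(c0, 30))
  expect_equal(cumulative_integral(const), c0 * frame_midpoints(fx_sched))
  expect_equal(cumulative_integral(tac(fx_sched, rep(0, 30))), rep(0, 30))

  # fine-grid quadrature oracle on model-generated TACs
  mids <- frame_midpoints(fx_sched)
  for (crv in list(fx_tumor_tac, fx_input_tac)) {
    gen <- if (identical(crv, fx_input_tac)) {
      function(s) eval_input(fx_input, s)
    } else {
      g <- seq(0, 60, by = 0.001)
      tot <- solve_2tcm(fx_tumor, fx_input, g)$total
      function(s) stats::approx(g, tot, xout = s)$y
    }
    fine <- seq(0, 60, by = 0.001)
    fv <- gen(fine)
    exact_cum <- cumsum(c(0, (fv[-1] + fv[-length(fv)]) / 2 * diff(fine)))
    oracle <- stats::approx(fine, exact_cum, xout = mids)$y
    got <- cumulative_integral(crv)
    late <- mids >= 10
    expect_lt(max(abs(got[late] - oracle[late]) / oracle[late]), 0.01)
  }
})

test_that("a proportional tissue curve gives slope c and zero intercept", {
  c0 <- 3.7
  tissue <- tac(fx_sched, c0 * fx_input_tac$value)
  fit <- logan_plasma(tissue, fx_input_tac, tstar = 30)
  expect_equal(fit$slope, c0, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r2, 1)
})

test_that("plasma-input Logan recovers V_T of kidney-like kinetics within 2%", {
  kin524 <- tissue_kinetics(0.60, 0.30, 0.162, 0.10)
  expect_equal(vt_true(kin524), 5.24, tolerance = 1e-12)
  fit <- logan_plasma(simulate_tac(kin524, fx_input, fx_sched),
                      fx_input_tac, tstar = 30)
  expect_lt(abs(fit$slope - 5.24) / 5.24, 0.02)
  expect_gt(fit$r2, 0.99)
})

test_that("plasma-input Logan tracks ground-truth V_T on random kinetics", {
  kins <- draw_kinetics(20, seed = 202)
  for (kin in kins) {
    fit <- logan_plasma(simulate_tac(kin, fx_input, fx_sched),
                        fx_input_tac, tstar = 40)
    expect_lt(abs(fit$slope - vt_true(kin)) / vt_true(kin), 0.03)
  }
})

test_that("reference Logan: identical curves give DVR 1; matched V_ND recovers DVR", {
  self <- logan_reference(fx_ref_tac, fx_ref_tac, tstar = 30)
  expect_equal(self$slope, 1, tolerance = 1e-9)
  expect_equal(binding_potential(self), 0, tolerance = 1e-9)

  fit <- logan_reference(fx_tumor_tac, fx_ref_tac, tstar = 30)
  expect_lt(abs(fit$slope - 4.75) / 4.75, 0.05)
  expect_lt(abs(binding_potential(fit) - 3.75) / 3.75, 0.05)

  # DVR ~ ratio of the two plasma-input distribution volumes
  vt_t <- logan_plasma(fx_tumor_tac, fx_input_tac, 30)$slope
  vt_r <- logan_plasma(fx_ref_tac, fx_input_tac, 30)$slope
  expect_lt(abs(fit$slope - vt_t / vt_r) / (vt_t / vt_r), 0.03)
})

test_that("binding potential is DVR - 1", {
  expect_equal(binding_potential(4.75), 3.75)
  expect_equal(binding_potential(1), 0)
  expect_equal(binding_potential(2), 1)
})

test_that("V_T decomposition satisfies its algebraic identities", {
  mac <- decompose_vt(2.432, 3.75)
  expect_equal(mac$vs, 1.92, tolerance = 1e-10)
  expect_equal(mac$vnd, 0.512, tolerance = 1e-10)
  expect_equal(mac$vt, mac$vnd + mac$vs, tolerance = 1e-10)
  expect_equal(mac$dvr, 4.75)

  none <- decompose_vt(1.7, 0)
  expect_equal(none$vs, 0)
  expect_equal(none$vnd, 1.7)

  # exact inversion on random values
  withr::with_seed(5, {
    for (i in 1:20) {
      vt <- runif(1, 0.2, 6); bp <- runif(1, 0, 5)
      m <- decompose_vt(vt, bp)
      expect_equal(m$vnd + m$vs, vt, tolerance = 1e-10)
      expect_equal(m$vs / m$vnd, bp, tolerance = 1e-10)
    }
  })
  expect_error(decompose_vt(2, -1), "> -1")
  expect_error(decompose_vt(-0.5, 1), ">= 0")
})

test_that("t* selection: fixed mode, collinear points, and fixture onset", {
  pts <- logan_points(fx_tumor_tac, fx_ref_tac)
  expect_equal(select_tstar(pts, mode = "fixed"), 30)

  col <- tibble::tibble(mid = 1:10, x = 1:10, y = 2 * (1:10) + 1)
  expect_equal(select_tstar(col, mode = "auto"), 0)

  auto <- select_tstar(pts, max_rel_dev = 0.10, mode = "auto")
  expect_lte(auto, 30)

  expect_error(select_tstar(col[1:3, ], mode = "auto"), ">= 5")
})

test_that("Logan fit validates its inputs and drops non-positive points", {
  expect_error(logan_plasma(fx_tumor_tac, fx_input_tac, tstar = 50),
               ">= 3")
  expect_error(logan_plasma(fx_tumor_tac, fx_input_tac, tstar = 70),
               "within the scan")
  short <- frame_schedule(c(0, 1, 2), c(1, 2, 3))
  expect_error(logan_plasma(tac(short, 1:3), fx_input_tac), "schedule")

  # zero out two late frames: they are dropped, the fit still runs
  v <- fx_tumor_tac$value
  v[c(25, 27)] <- 0
  fit <- logan_plasma(tac(fx_sched, v), fx_input_tac, tstar = 30)
  expect_equal(fit$n_dropped, 2L)
  expect_equal(fit$n_points, 5L)
})
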