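test_that("lift-onset scalars match hand arithmetic and sign conventions", {
  expect_equal(compute_gf_mean(10, 10), 10)
  expect_equal(compute_gf_mean(8, 12), 10)
  expect_equal(compute_gf_mean(0, 0), 0)
  expect_error(compute_gf_mean(-1, 5), "non-negative")

  expect_equal(compute_lf_diff(6, 4), 2)   # thumb-heavy: positive
  expect_equal(compute_lf_diff(4, 6), -2)  # index-heavy: negative
  expect_equal(compute_lf_diff(5, 5), 0)   # symmetric sharing

  expect_equal(compute_cop(0, 0, 5, 8), 0)
  expect_equal(compute_cop(50, 2, 10, 8), 3.4)
  expect_error(compute_cop(10, 1, 0, 8), "grip force")

  mc <- compute_mcom(0, 10, 0, 82)
  expect_equal(mc$mcom, 0)
  mc <- compute_mcom(2, 10, 4.2, 82)
  expect_equal(mc$mcom, 124)
  expect_equal(mc$lf_torque_component, 82)
  expect_equal(mc$grip_torque_component, 42)
  expect_error(compute_mcom(1, 1, 1, 0), "d_mm")
})

test_that("torque decomposition is exact and the COP formula inverts its synthesis", {
  set.seed(5)
  for (i in 1:50) {
    lf_diff <- rnorm(1); gf <- runif(1, 1, 30); cop_diff <- rnorm(1, 0, 5)
    mc <- compute_mcom(lf_diff, gf, cop_diff, 82)
    expect_identical(mc$mcom,
                     mc$lf_torque_component + mc$grip_torque_component)
    # synthesise digit torque the way the generator does, then invert
    cop <- rnorm(1, 0, 10); lf <- runif(1, 0, 8); th <- 8
    tx <- cop * gf + lf * th
    expect_equal(compute_cop(tx, lf, gf, th), cop, tolerance = 1e-12)
  }
})

test_that("coupling peaks at r = 1, lag 0 for identical rate channels", {
  t <- seq(0, 1000, by = 2)
  pulse <- exp(-((t - 500) / 120)^2)
  cpl <- compute_coupling(t, pulse, pulse, window_ms = c(300, 700))
  expect_equal(cpl$r, 1, tolerance = 1e-9)
  expect_equal(cpl$lag_ms, 0)
  expect_equal(nrow(cpl$lags), 81L)  # 2.5 ms grid from -100 to +100
})

test_that("a 10 ms delayed grip-force rate is localised at +10 ms lag", {
  t <- seq(0, 1200, by = 2)
  lf <- exp(-((t - 600) / 100)^2)
  gf <- exp(-((t - 610) / 100)^2)  # same pulse, delayed by 10 ms
  cpl <- compute_coupling(t, gf, lf, window_ms = c(400, 800))
  # exhaustive-scan oracle over the full lag grid
  lags <- seq(-100, 100, by = 2.5)
  grid <- seq(400, 800, by = 2.5)
  r_scan <- sapply(lags, function(tau) {
    cor(exp(-((grid + tau - 610) / 100)^2), exp(-((grid - 600) / 100)^2))
  })
  expect_equal(cpl$lag_ms, lags[which.max(r_scan)])
  expect_equal(cpl$lag_ms, 10)
  expect_gt(cpl$r, 0.999)
})

test_that("a sign-flipped channel cannot reach perfect peak correlation", {
  t <- seq(0, 1000, by = 2)
  pulse <- exp(-((t - 500) / 120)^2)
  cpl <- compute_coupling(t, -pulse, pulse, window_ms = c(300, 700))
  expect_lt(cpl$r, 1)
})

test_that("coupling is invariant to affine rescaling and rejects flat channels", {
  t <- seq(0, 1000, by = 2)
  lf <- exp(-((t - 480) / 90)^2)
  gf <- exp(-((t - 520) / 110)^2)
  a <- compute_coupling(t, gf, lf, c(300, 700))
  b <- compute_coupling(t, 3.7 * gf + 11, 0.2 * lf - 4, c(300, 700))
  expect_equal(a$r, b$r, tolerance = 1e-12)
  expect_equal(a$lag_ms, b$lag_ms)
  expect_error(compute_coupling(t, gf, rep(1, length(t)), c(300, 700)),
               "zero-variance")
})

test_that("sign normalisation flips right-start subjects once and only once", {
  m <- tibble::tibble(mcom = -250, lf_diff = -2, cop_diff = -9,
                      cop_thumb = -4.5, cop_index = 4.5,
                      lf_torque_component = -82,
                      grip_torque_component = -168,
                      gf_mean = 12, coupling_r = 0.9,
                      sign_normalized = FALSE)
  r <- normalize_signs(m, "right")
  expect_equal(r$mcom, 250)
  expect_equal(r$lf_diff, 2)
  expect_equal(r$cop_diff, 9)
  expect_equal(r$lf_torque_component, 82)
  expect_equal(r$grip_torque_component, 168)
  expect_equal(r$gf_mean, 12)        # side-invariant
  expect_equal(r$coupling_r, 0.9)    # side-invariant
  expect_true(r$sign_normalized)

  l <- normalize_signs(m, "left")
  expect_equal(l$mcom, m$mcom)
  expect_error(normalize_signs(r, "right"), "already")
})

test_that("mirrored cohorts negate raw torques and coincide after normalisation", {
  sched_l <- build_schedule(schedule_spec("matched", start_side = "left",
                                          seed = 8L))
  sched_r <- build_schedule(schedule_spec("matched", start_side = "right",
                                          seed = 8L))
  obj <- object_spec()
  params <- subject_sim_params(seed = 21L)
  pl <- plan_metrics(sched_l, obj, params, "left")
  pr <- plan_metrics(sched_r, obj, params, "right")
  expect_equal(pr$planned_mcom, -pl$planned_mcom)
  expect_equal(pr$planned_lf_diff, -pl$planned_lf_diff)
  expect_equal(pr$planned_cop_diff, -pl$planned_cop_diff)
  ml <- truth_metrics(pl, obj)
  mr <- truth_metrics(pr, obj)
  expect_equal(mr$mcom, ml$mcom)
  expect_equal(mr$lf_diff, ml$lf_diff)
  expect_equal(mr$cop_diff, ml$cop_diff)
})

test_that("metrics recovered from an equilibrium lift reproduce the planned values", {
  obj <- object_spec()
  tr <- equilibrium_trial()
  m <- trial_metrics(tr, obj)
  expect_equal(m$mcom, tr$scripted$planned_mcom, tolerance = 1e-3)
  expect_equal(m$lf_diff, tr$scripted$planned_lf_diff, tolerance = 1e-3)
  expect_equal(m$cop_diff, tr$scripted$planned_cop_diff, tolerance = 1e-2)
  expect_equal(m$gf_mean, tr$scripted$planned_gf_at_lift, tolerance = 1e-2)
  expect_identical(m$mcom,
                   m$lf_torque_component + m$grip_torque_component)
  expect_gt(m$coupling_r, 0.9)
  expect_lte(abs(m$coupling_lag_ms), 100)
})
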