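test_that("gamma-variate is zero pre-arrival and peaks at amplitude", {
  expect_equal(gamma_variate(5, 400, 3, 1.5, t0 = 5), 0)
  expect_equal(gamma_variate(2, 400, 3, 1.5, t0 = 5), 0)
  # analytic maximum at t0 + alpha*beta, value = amplitude
  expect_equal(gamma_variate(9.5, 400, 3, 1.5, t0 = 5), 400)
  # dense grid search confirms it is the global maximum
  tt <- seq(0, 40, by = 0.001)
  v <- gamma_variate(tt, 400, 3, 1.5, t0 = 5)
  expect_equal(tt[which.max(v)], 9.5, tolerance = 1e-3)
  expect_lte(max(v), 400 + 1e-9)
})

test_that("gamma-variate rejects non-positive shape parameters", {
  expect_error(gamma_variate(1, -1, 3, 1), "amplitude")
  expect_error(gamma_variate(1, 400, 0, 1), "alpha")
  expect_error(gamma_variate(1, 400, 3, -2), "beta")
})

test_that("gamma-variate closed-form integral matches fine-grid numeric integration", {
  A <- 200; a <- 8; b <- 2.8; t0 <- 6
  tt <- seq(0, 40, by = 1e-3)
  v <- gamma_variate(tt, A, a, b, t0)
  numeric_int <- cumsum((v[-1] + v[-length(v)]) / 2) * 1e-3
  for (tq in c(10, 15, 20, 28, 35)) {
    i <- which.min(abs(tt[-1] - tq))
    expect_equal(gamma_variate_integral(tt[i + 1], A, a, b, t0),
                 numeric_int[i], tolerance = 1e-3)
  }
})

test_that("phantom spec validates its geometric and physiological invariants", {
  expect_s3_class(default_swine_spec(), "fpa_phantom_spec")
  expect_error(phantom_spec(dim = c(32, 32, 32), lv_inner_mm = c(99, 99, 99)),
               "inner shell")
  expect_error(phantom_spec(flows_rest = c(LAD = -1, LCx = 0.5, RCA = 0.5,
                                           LAD_distal = 0.5)), ">= 0")
  expect_error(phantom_spec(frame_times = c(3, 2, 1)), "increasing")
  expect_error(phantom_spec(stenosis_frac = 1.5), "stenosis_frac")
})

test_that("default swine spec reproduces the observed acquisition timing and flows", {
  spec <- default_swine_spec()
  dt <- estimate_delta_t(phantom_tdc(spec))
  expect_gte(dt, 4.10)
  expect_lte(dt, 8.93)
  # territory rest flows: printed means, averaging ~0.50 mL/min/g
  main <- spec$flows_rest[c("LAD", "LCx", "RCA")]
  expect_equal(unname(main), c(0.58, 0.53, 0.37))
  expect_lt(abs(mean(main) - 0.50), 0.01)
  expect_equal(unname(spec$flows_stress[c("LAD", "LAD_distal")]), c(2.07, 1.20))
})

test_that("phantom masks are non-empty, disjoint, and territories partition the myocardium", {
  sim <- simulate_acquisition(small_spec(), "rest", noise = FALSE)
  truth <- sim$truth
  expect_gt(sum(truth$myo$data), 0)
  expect_gt(sum(truth$aorta$data), 0)
  expect_false(any(truth$myo$data & truth$aorta$data))
  # labels partition: nonzero exactly on the mask
  expect_true(all((truth$territories$data > 0) == truth$myo$data))
  # perfusion nonzero only inside the mask
  expect_true(all(truth$perfusion[!truth$myo$data] == 0))
  expect_true(all(truth$perfusion[truth$myo$data] > 0))
})

test_that("phantom centerlines lie on or near the epicardial surface", {
  spec <- small_spec()
  sim <- simulate_acquisition(spec, "rest", noise = FALSE)
  myo_idx <- which(sim$truth$myo$data)
  d <- dim(sim$truth$myo$data)
  myo_mm <- cbind((arrayInd(myo_idx, d) - 1) %*% diag(spec$spacing))
  for (l in sim$truth$centerlines) {
    nd <- apply(l$points_mm, 1, function(p)
      min(sqrt(colSums((t(myo_mm) - p)^2))))
    expect_lt(max(nd), 2 * max(spec$spacing))
  }
})

test_that("identical spec and seed reproduce bit-identical noisy volumes", {
  spec <- small_spec(dim = c(24, 24, 24))
  s1 <- simulate_acquisition(spec, "stress", times = c(10, 15), ma = 50)
  s2 <- simulate_acquisition(spec, "stress", times = c(10, 15), ma = 50)
  expect_identical(s1$series[[1]]$data, s2$series[[1]]$data)
  expect_identical(s1$series[[2]]$data, s2$series[[2]]$data)
  s3 <- simulate_acquisition(spec, "stress", times = c(10, 15), ma = 50,
                             seed = spec$seed + 1L)
  expect_false(identical(s1$series[[1]]$data, s3$series[[1]]$data))
})

test_that("noise scales with tube current as an inverse square root", {
  spec <- small_spec(dim = c(24, 24, 24))
  noiseless <- simulate_acquisition(spec, "rest", times = 0, ma = 50,
                                    noise = FALSE)$series[[1]]$data
  sd_at <- function(ma) {
    noisy <- simulate_acquisition(spec, "rest", times = 0, ma = ma)$series[[1]]$data
    sd(noisy - noiseless)
  }
  expect_equal(sd_at(50), 25, tolerance = 0.02)
  expect_equal(sd_at(200), 12.5, tolerance = 0.02)
})

test_that("frames beyond the outflow-free window raise a model-validity warning", {
  spec <- small_spec(dim = c(16, 16, 16))
  t_late <- spec$tdc_t0 +
    spec$tdc_beta * (spec$tdc_alpha + 2 * sqrt(spec$tdc_alpha)) + 5
  expect_warning(simulate_acquisition(spec, "rest", times = c(0, t_late),
                                      noise = FALSE), "outflow")
})

test_that("noiseless phantom satisfies mass balance against the analytic input integral", {
  spec <- small_spec()
  sim <- simulate_acquisition(spec, "stress", noise = FALSE)
  truth <- sim$truth
  myo <- truth$myo$data
  rho <- 1.055
  # summed HU above baseline at frame k == rho * I(t_k) * sum(P_true)
  for (k in c(20, 35, length(sim$series))) {
    t <- sim$series[[k]]$time_s
    lhs <- sum(sim$series[[k]]$data[myo] - spec$hu_tissue)
    i_min <- gamma_variate_integral(t, spec$tdc_amplitude, spec$tdc_alpha,
                                    spec$tdc_beta, spec$tdc_t0) / 60
    rhs <- rho * i_min * sum(truth$perfusion[myo])
    if (rhs > 0) expect_equal(lhs, rhs, tolerance = 1e-3)
  }
})

test_that("ground-truth territory means equal the configured stenotic flows", {
  sim <- simulate_acquisition(small_spec(), "stress", noise = FALSE)
  ts <- territory_stats(sim$truth$perfusion, sim$truth$territories)
  expect_equal(ts$mean[ts$territory == "LAD-distal"], 1.20)
  expect_equal(ts$mean[ts$territory == "LAD-proximal"], 2.07)
  expect_equal(ts$sd[ts$territory == "LCx"], 0)
})

test_that("linear-ramp input mode produces the exactness-limit acquisition", {
  spec <- small_spec(tdc_shape = "linear_ramp")
  tdc <- phantom_tdc(spec, times = seq(0, 20, 0.5))
  enh <- tdc$hu - spec$hu_blood
  post <- tdc$time_s > spec$tdc_t0
  expect_equal(enh[post],
               spec$ramp_rate_hu_s * (tdc$time_s[post] - spec$tdc_t0))
})
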