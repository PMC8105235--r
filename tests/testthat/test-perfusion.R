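test_that("MIP combination equals the voxel-wise maximum", {
  v1 <- uniform_volume(10); v1$data[2, 2, 2] <- 500
  v2 <- uniform_volume(20); v2$data[5, 5, 5] <- 300
  # identity on a single volume
  expect_identical(mip_combine(list(v1))$data, v1$data)
  m <- mip_combine(list(v1, v2))
  expect_equal(m$data[2, 2, 2], 500)
  expect_equal(m$data[5, 5, 5], 300)
  # brute-force elementwise oracle over four random volumes
  set.seed(11)
  vols <- lapply(1:4, function(i) uniform_volume(0, c(5, 5, 5)))
  for (i in 1:4) vols[[i]]$data[] <- rnorm(125)
  got <- mip_combine(vols)$data
  want <- array(apply(sapply(vols, function(v) as.vector(v$data)), 1, max),
                c(5, 5, 5))
  expect_equal(got, want)
  # grid mismatch errors
  expect_error(mip_combine(list(v1, uniform_volume(0, c(4, 4, 4)))),
               "different grids")
})

test_that("C_in is the baseline-subtracted two-scan ROI average", {
  roi <- slab_mask(role = "aortic-root")
  v1 <- uniform_volume(340, time_s = 0)
  v2 <- uniform_volume(460, time_s = 5)
  expect_equal(compute_cin(v1, v2, roi, baseline_hu = 40), 360)
  expect_equal(compute_cin(v1, v2, roi, baseline_hu = 40,
                           subtract_baseline = FALSE), 400)
  # zero enhancement errors
  flat <- uniform_volume(40)
  expect_error(compute_cin(flat, flat, roi, baseline_hu = 40), "C_in")
})

test_that("C_in on the noiseless phantom matches the analytic two-point average", {
  spec <- small_spec()
  t1 <- 10; t2 <- 15
  sim <- simulate_acquisition(spec, "rest", times = c(t1, t2), noise = FALSE)
  cin <- compute_cin(sim$series[[1]], sim$series[[2]], sim$truth$aorta,
                     spec$hu_blood)
  ca <- gamma_variate(c(t1, t2), spec$tdc_amplitude, spec$tdc_alpha,
                      spec$tdc_beta, spec$tdc_t0)
  expect_equal(cin, mean(ca), tolerance = 1e-12)
})

test_that("tissue mass follows the density-times-volume rule", {
  # 100,000 voxels at the scanner voxel size -> 9.754 g
  d <- c(100, 100, 10)
  myo <- slab_mask(d, spacing = c(0.43, 0.43, 0.5))
  expect_equal(compute_tissue_mass(myo), 1.055 * 1e5 * 0.43 * 0.43 * 0.5 / 1000)
  expect_equal(compute_tissue_mass(myo), 9.753475)
  # one voxel of exactly 1 mL weighs 1.055 g
  one <- slab_mask(c(1, 1, 1), spacing = c(10, 10, 10))
  expect_equal(compute_tissue_mass(one), 1.055)
  # linearity in voxel count
  half <- array(FALSE, d); half[1:50, , ] <- TRUE
  expect_equal(compute_tissue_mass(binary_mask(half, c(0.43, 0.43, 0.5))) * 2,
               compute_tissue_mass(myo))
  expect_error(compute_tissue_mass(slab_mask(where = FALSE)), "empty")
})

test_that("two-volume perfusion inverts the first-pass relation exactly", {
  # C_in 400 HU, dt 6 s (0.1 min), uniform dHU 42.2 HU -> exactly 1 mL/min/g
  d <- c(8, 8, 8)
  myo <- slab_mask(d); myo$data[, , 7:8] <- FALSE
  aorta <- slab_mask(d, role = "aortic-root", where = FALSE)
  aorta$data[, , 8] <- TRUE
  myo$data[, , 8] <- FALSE
  v1 <- uniform_volume(100, d, time_s = 0)
  v2 <- uniform_volume(100 + 42.2, d, time_s = 6)
  v1$data[aorta$data] <- 440 - 60; v2$data[aorta$data] <- 440 + 60
  res <- compute_perfusion(v1, v2, myo, aorta, baseline_hu = 40)
  expect_equal(res$cin_hu, 400)
  expect_equal(res$p_ave, 42.2 / (0.1 * 400 * 1.055), tolerance = 1e-12)
  expect_equal(res$p_ave, 1, tolerance = 1e-12)
  expect_true(all(abs(res$map[myo$data] - 1) < 1e-12))
  expect_true(all(is.nan(res$map[!myo$data])))
})

test_that("per-voxel perfusion is proportional to dHU and conserves the mask mean", {
  d <- c(10, 10, 4)
  myo <- slab_mask(d); myo$data[, , 4] <- FALSE
  aorta <- slab_mask(d, role = "aortic-root", where = FALSE)
  aorta$data[, , 4] <- TRUE
  set.seed(3)
  v1 <- uniform_volume(80, d, time_s = 0)
  v2 <- uniform_volume(80, d, time_s = 6)
  v2$data[myo$data] <- 80 + runif(sum(myo$data), 10, 60)
  # a sub-region with zero enhancement maps to exactly zero perfusion
  v2$data[1:3, 1:3, 1] <- 80
  v1$data[aorta$data] <- 400; v2$data[aorta$data] <- 480
  res <- compute_perfusion(v1, v2, myo, aorta, baseline_hu = 40)
  expect_equal(mean(res$map[myo$data]), res$p_ave, tolerance = 1e-12)
  expect_true(all(res$map[1:3, 1:3, 1] == 0))
  # proportionality: P = P_AVE * dHU / dHU_AVE
  dhu <- v2$data - v1$data
  expect_equal(res$map[myo$data],
               res$p_ave * dhu[myo$data] / res$dhu_ave, tolerance = 1e-12)
})

test_that("perfusion is invariant to a common scaling of enhancement", {
  d <- c(8, 8, 2)
  myo <- slab_mask(d); myo$data[, , 2] <- FALSE
  aorta <- slab_mask(d, role = "aortic-root", where = FALSE); aorta$data[, , 2] <- TRUE
  base_t <- 70; base_b <- 40
  set.seed(5)
  enh1 <- array(runif(prod(d), 5, 20), d); enh2 <- enh1 + runif(prod(d), 20, 50)
  mk <- function(s) {
    v1 <- uniform_volume(0, d, time_s = 0); v2 <- uniform_volume(0, d, time_s = 5)
    v1$data <- base_t + s * enh1; v2$data <- base_t + s * enh2
    v1$data[aorta$data] <- base_b + s * 300; v2$data[aorta$data] <- base_b + s * 380
    compute_perfusion(v1, v2, myo, aorta, baseline_hu = base_b)
  }
  r1 <- mk(1); r2 <- mk(3.7)
  # the proportionality constant between HU and concentration cancels
  expect_equal(r2$cin_hu, 3.7 * r1$cin_hu, tolerance = 1e-12)
  expect_equal(r2$p_ave, r1$p_ave, tolerance = 1e-12)
  expect_equal(r2$map[myo$data], r1$map[myo$data], tolerance = 1e-12)
})

test_that("degenerate perfusion inputs raise informative errors", {
  d <- c(6, 6, 6)
  myo <- slab_mask(d)
  aorta <- slab_mask(d, role = "aortic-root")
  v1 <- uniform_volume(100, d, time_s = 10)
  v2 <- uniform_volume(150, d, time_s = 10)
  expect_error(compute_perfusion(v1, v2, myo, aorta, 40), "dt > 0")
  v2$time_s <- 16
  v2$data[] <- 90  # net de-enhancement
  v1$data[] <- 100
  expect_error(compute_perfusion(v1, v2, myo, aorta, 200), "C_in")
})

test_that("noiseless phantom with a linear input recovers truth to float precision", {
  spec <- small_spec(tdc_shape = "linear_ramp")
  t1 <- spec$tdc_t0 + 4; t2 <- spec$tdc_t0 + 9
  sim <- simulate_acquisition(spec, "stress", times = c(t1, t2), noise = FALSE)
  res <- compute_perfusion(sim$series[[1]], sim$series[[2]], sim$truth$myo,
                           sim$truth$aorta, spec$hu_blood)
  truth <- sim$truth$perfusion[sim$truth$myo$data]
  est <- res$map[sim$truth$myo$data]
  expect_lt(max(abs(est - truth) / truth), 1e-9)
})

test_that("CFR maps follow the ratio and floor rules", {
  d <- c(6, 6, 2)
  myo <- slab_mask(d); myo$data[, , 2] <- FALSE
  aorta <- slab_mask(d, role = "aortic-root", where = FALSE); aorta$data[, , 2] <- TRUE
  mk <- function(dhu) {
    v1 <- uniform_volume(80, d, time_s = 0); v2 <- uniform_volume(80, d, time_s = 6)
    v2$data[myo$data] <- 80 + dhu
    v1$data[aorta$data] <- 400; v2$data[aorta$data] <- 480
    compute_perfusion(v1, v2, myo, aorta, 40)
  }
  rest <- mk(21.1); stress <- mk(21.1)
  cfr <- compute_cfr(stress, rest)
  expect_true(all(abs(cfr$map[myo$data] - 1) < 1e-12))
  stress2 <- mk(4 * 21.1)
  cfr2 <- compute_cfr(stress2, rest)
  expect_true(all(abs(cfr2$map[myo$data] - 4) < 1e-12))
  # voxels under the rest floor are flagged undefined and excluded
  rest_low <- rest
  rest_low$map[2, 2, 1] <- 0.01
  cfr3 <- compute_cfr(stress2, rest_low, rest_floor = 0.1)
  expect_true(is.nan(cfr3$map[2, 2, 1]))
  expect_false(cfr3$defined[2, 2, 1])
})

test_that("voxel binning averages blocks and strictly reduces noise RMSE", {
  # identity at factor 1 and on uniform maps
  m <- array(2.5, c(8, 8, 8))
  expect_equal(bin_voxels(m, 1)$map, m)
  expect_true(all(bin_voxels(m, 2)$map == 2.5))
  # block-mean oracle on a small array
  m2 <- array(as.numeric(1:64), c(4, 4, 4))
  b <- bin_voxels(m2, 2)
  expect_equal(dim(b$map), c(2, 2, 2))
  expect_equal(b$map[1, 1, 1], mean(m2[1:2, 1:2, 1:2]))
  expect_equal(b$map[2, 2, 2], mean(m2[3:4, 3:4, 3:4]))
  # undefined voxels are excluded; empty blocks stay undefined
  m2[1, 1, 1] <- NaN
  b2 <- bin_voxels(m2, 2)
  expect_equal(b2$map[1, 1, 1], mean(m2[1:2, 1:2, 1:2], na.rm = TRUE))
  m3 <- array(NaN, c(4, 4, 4)); m3[3:4, 3:4, 3:4] <- 1
  expect_true(is.nan(bin_voxels(m3, 2)$map[1, 1, 1]))
  # Monte-Carlo: binning a noisy map strictly reduces voxelwise RMSE vs truth
  set.seed(42)
  truth <- array(2, c(16, 16, 16))
  noisy <- truth + array(rnorm(16^3, sd = 0.8), c(16, 16, 16))
  rmse_full <- sqrt(mean((noisy - truth)^2))
  binned <- bin_voxels(noisy, 4)$map
  truth_b <- bin_voxels(truth, 4)$map
  rmse_binned <- sqrt(mean((binned - truth_b)^2))
  expect_lt(rmse_binned, rmse_full)
})

test_that("territory CFR uses the ratio of regional means", {
  sim <- simulate_acquisition(small_spec(), "stress", noise = FALSE)
  spec <- small_spec()
  mk <- function(cond) {
    s <- simulate_acquisition(spec, cond, times = c(10, 15), noise = FALSE)
    compute_perfusion(s$series[[1]], s$series[[2]], s$truth$myo,
                      s$truth$aorta, spec$hu_blood)
  }
  stress <- mk("stress"); rest <- mk("rest")
  tc <- territory_cfr(stress, rest, sim$truth$territories)
  expect_equal(tc$cfr, tc$mean_stress / tc$mean_rest)
  # the two-point estimator bias cancels in the ratio: CFR equals true ratio
  i <- match("LAD-distal", tc$territory)
  expect_equal(tc$cfr[i], 1.20 / 0.67, tolerance = 1e-6)
})
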