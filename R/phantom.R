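#' Gamma-variate bolus curve
#'
#' Standard first-pass bolus shape used for the phantom's aortic input:
#' `A * ((t - t0)/(alpha*beta))^alpha * exp(alpha - (t - t0)/beta)` for
#' `t > t0`, zero before arrival.  Parameterised so the peak value equals
#' `amplitude`, reached at `t0 + alpha*beta`.
#'
#' @param t Time(s) in seconds (vectorised).
#' @param amplitude Peak enhancement in HU above baseline (> 0).
#' @param alpha Dimensionless shape parameter (> 0).
#' @param beta Scale parameter in seconds (> 0).
#' @param t0 Bolus arrival time in seconds.
#'
#' @return Enhancement in HU above baseline, same length as `t`.
#' @export
gamma_variate <- function(t, amplitude, alpha, beta, t0 = 0) {
  if (!is.finite(amplitude) || amplitude <= 0) abort("`amplitude` must be > 0.")
  if (!is.finite(alpha) || alpha <= 0) abort("`alpha` must be > 0.")
  if (!is.finite(beta) || beta <= 0) abort("`beta` must be > 0.")
  dt <- t - t0
  out <- numeric(length(t))
  pos <- dt > 0
  out[pos] <- amplitude * (dt[pos] / (alpha * beta))^alpha *
    exp(alpha - dt[pos] / beta)
  out
}

#' Running integral of the gamma-variate curve
#'
#' Closed form via the regularised incomplete gamma function:
#' `integral_0^t C(tau) dtau = A * beta * e^alpha * alpha^-alpha *
#' Gamma(alpha+1) * P(alpha+1, (t-t0)/beta)`.
#'
#' @inheritParams gamma_variate
#' @return Integral in HU.s from 0 to `t`.
#' @export
gamma_variate_integral <- function(t, amplitude, alpha, beta, t0 = 0) {
  if (!is.finite(amplitude) || amplitude <= 0) abort("`amplitude` must be > 0.")
  if (!is.finite(alpha) || alpha <= 0) abort("`alpha` must be > 0.")
  if (!is.finite(beta) || beta <= 0) abort("`beta` must be > 0.")
  u <- pmax(t - t0, 0) / beta
  amplitude * beta * exp(alpha) * alpha^(-alpha) * gamma(alpha + 1) *
    pgamma(u, alpha + 1)
}

#' Synthetic cardiac phantom specification
#'
#' Defines a digital LV phantom: a truncated half-ellipsoid myocardial shell,
#' an aortic-root cylinder carrying the contrast bolus, three epicardial
#' coronary centerlines, per-territory rest/stress perfusion, and the
#' acquisition (frame times, tube current, noise model).  Myocardial contrast
#' uptake follows an inflow-only single-compartment model: tissue HU at time
#' `t` is baseline plus `P * rho * integral(C_a)` with `rho` = 1.055 g/mL and
#' `C_a` the aortic enhancement above baseline.
#'
#' All world coordinates are mm, axis order (x, y, z), voxel indices 0-based;
#' masks share the volume grid exactly.
#'
#' @param dim Grid size in voxels per axis.
#' @param spacing Voxel spacing in mm, default `c(0.43, 0.43, 0.5)`.
#' @param lv_center_mm,lv_outer_mm,lv_inner_mm LV shell center and
#'   outer/inner ellipsoid semi-axes (mm).
#' @param lv_base_frac Shell kept where `z <= center_z + frac * outer_z`
#'   (basal truncation of the half-ellipsoid).
#' @param aorta_center_mm,aorta_radius_mm,aorta_height_mm Aortic-root
#'   cylinder: (x, y, z-bottom) of the axis, radius and height in mm.
#' @param hu_tissue,hu_blood Baseline tissue and blood HU.
#' @param tdc_shape `"gamma_variate"` (default) or `"linear_ramp"` (the
#'   exactness limit of the two-point estimator).
#' @param tdc_amplitude,tdc_alpha,tdc_beta,tdc_t0 Gamma-variate parameters
#'   (peak HU above baseline, shape, scale s, arrival s).
#' @param ramp_rate_hu_s Slope of the linear-ramp input in HU/s.
#' @param flows_rest,flows_stress Named true perfusion values in mL/min/g for
#'   `LAD`, `LCx`, `RCA` and optionally `LAD_distal` (sub-territory distal to
#'   a stenosis).
#' @param stenosis_frac Stenosis position as a fraction of LAD centerline
#'   arc length (`NULL` disables the distal sub-territory).
#' @param noise_sigma_ref Gaussian HU noise SD at the reference tube current.
#' @param noise_ma_ref Reference tube current (mA) for `noise_sigma_ref`.
#' @param noise_exponent Tube-current scaling exponent:
#'   `sigma(mA) = sigma_ref * (ma_ref / mA)^exponent` (quantum noise: 0.5).
#' @param frame_times Acquisition frame times in seconds, strictly ascending.
#' @param frame_ma Tube current per frame (scalar or vector).
#' @param baseline_drift_hu Constant recirculation offset added to every
#'   frame, default 0.
#' @param seed Random seed for noise reproducibility.
#'
#' @return An object of class `fpa_phantom_spec`.
#' @export
phantom_spec <- function(dim = c(96, 96, 96),
                         spacing = c(0.43, 0.43, 0.5),
                         lv_center_mm = NULL,
                         lv_outer_mm = NULL,
                         lv_inner_mm = NULL,
                         lv_base_frac = 0.25,
                         aorta_center_mm = NULL,
                         aorta_radius_mm = NULL,
                         aorta_height_mm = NULL,
                         hu_tissue = 45,
                         hu_blood = 40,
                         tdc_shape = c("gamma_variate", "linear_ramp"),
                         tdc_amplitude = 200,
                         tdc_alpha = 8,
                         tdc_beta = 2.8,
                         tdc_t0 = 6,
                         ramp_rate_hu_s = 25,
                         flows_rest = c(LAD = 0.58, LCx = 0.53, RCA = 0.37,
                                        LAD_distal = 0.67),
                         flows_stress = c(LAD = 2.07, LCx = 2.15, RCA = 1.79,
                                          LAD_distal = 1.20),
                         stenosis_frac = 0.45,
                         noise_sigma_ref = 25,
                         noise_ma_ref = 50,
                         noise_exponent = 0.5,
                         frame_times = NULL,
                         frame_ma = 200,
                         baseline_drift_hu = 0,
                         seed = 20260101L) {
  tdc_shape <- match.arg(tdc_shape)
  dim <- as.integer(dim); spacing <- as.numeric(spacing)
  if (length(dim) != 3L || any(dim < 8L)) abort("`dim` must be 3 sizes >= 8.")
  if (length(spacing) != 3L || any(spacing <= 0)) abort("spacings must be > 0.")
  extent <- dim * spacing

  # Geometry defaults scale with the field of view.
  if (is.null(lv_center_mm))
    lv_center_mm <- c(extent[1] / 2, extent[2] / 2, extent[3] / 2)
  if (is.null(lv_outer_mm))
    lv_outer_mm <- c(0.39 * extent[1], 0.39 * extent[2], 0.42 * extent[3])
  if (is.null(lv_inner_mm)) lv_inner_mm <- 0.70 * lv_outer_mm
  if (is.null(aorta_radius_mm)) aorta_radius_mm <- 0.10 * extent[1]
  if (is.null(aorta_height_mm)) aorta_height_mm <- 0.28 * extent[3]
  if (is.null(aorta_center_mm)) {
    # Corner cylinder, z-range strictly above the truncated shell.
    z0 <- lv_center_mm[3] + lv_base_frac * lv_outer_mm[3] + 2 * spacing[3]
    aorta_center_mm <- c(0.17 * extent[1], 0.17 * extent[2], z0)
  }
  if (any(lv_inner_mm >= lv_outer_mm))
    abort("inner shell must lie strictly inside the outer shell.")
  for (fl in list(flows_rest, flows_stress)) {
    if (is.null(names(fl)) || !all(c("LAD", "LCx", "RCA") %in% names(fl)))
      abort("flows must be named vectors with at least LAD, LCx, RCA.")
    if (any(fl < 0)) abort("true perfusion values must be >= 0.")
  }
  if (!is.null(stenosis_frac) &&
      (stenosis_frac <= 0 || stenosis_frac >= 1))
    abort("`stenosis_frac` must be strictly inside (0, 1).")
  if (!is.null(stenosis_frac) &&
      (!("LAD_distal" %in% names(flows_rest)) ||
       !("LAD_distal" %in% names(flows_stress))))
    abort("a stenosis requires `LAD_distal` flows at rest and stress.")
  if (is.null(frame_times)) {
    # One frame per cardiac cycle at the swine rest heart rate (~83 bpm),
    # covering baseline through just past the aortic peak.
    t_end <- if (tdc_shape == "gamma_variate")
      tdc_t0 + tdc_alpha * tdc_beta + 6 else tdc_t0 + 16
    frame_times <- seq(0, t_end, by = 0.72)
  }
  if (length(frame_times) < 2L || any(diff(frame_times) <= 0))
    abort("`frame_times` must be >= 2 strictly increasing times.")
  if (length(frame_ma) == 1L) frame_ma <- rep(frame_ma, length(frame_times))
  if (length(frame_ma) != length(frame_times))
    abort("`frame_ma` must be scalar or one value per frame.")
  if (any(frame_ma <= 0)) abort("tube currents must be > 0.")
  if (noise_sigma_ref < 0) abort("`noise_sigma_ref` must be >= 0.")

  structure(list(
    dim = dim, spacing = spacing,
    lv_center_mm = lv_center_mm, lv_outer_mm = lv_outer_mm,
    lv_inner_mm = lv_inner_mm, lv_base_frac = lv_base_frac,
    aorta_center_mm = aorta_center_mm, aorta_radius_mm = aorta_radius_mm,
    aorta_height_mm = aorta_height_mm,
    hu_tissue = hu_tissue, hu_blood = hu_blood,
    tdc_shape = tdc_shape, tdc_amplitude = tdc_amplitude,
    tdc_alpha = tdc_alpha, tdc_beta = tdc_beta, tdc_t0 = tdc_t0,
    ramp_rate_hu_s = ramp_rate_hu_s,
    flows_rest = flows_rest, flows_stress = flows_stress,
    stenosis_frac = stenosis_frac,
    noise_sigma_ref = noise_sigma_ref, noise_ma_ref = noise_ma_ref,
    noise_exponent = noise_exponent,
    frame_times = frame_times, frame_ma = frame_ma,
    baseline_drift_hu = baseline_drift_hu, seed = as.integer(seed)
  ), class = "fpa_phantom_spec")
}

#' @export
print.fpa_phantom_spec <- function(x, ...) {
  cat(sprintf("<fpa_phantom_spec> %s voxels @ %s mm, %d frames, %s input\n",
              paste(x$dim, collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              length(x$frame_times), x$tdc_shape))
  invisible(x)
}

#' Default swine phantom
#'
#' The shipped study conditions: voxel spacing 0.43 x 0.43 x 0.5 mm, one
#' frame per cardiac cycle (0.72 s), a dilute gamma-variate aortic bolus
#' whose threshold-to-peak delay falls in the observed 4.10-8.93 s range,
#' rest territory flows (LAD 0.58, LCx 0.53, RCA 0.37 mL/min/g; mean 0.49),
#' stress flows (LAD 2.07, LCx 2.15, RCA 1.79) and a stenosed LAD-distal
#' sub-territory at 1.20 mL/min/g stress.
#'
#' @param dim Grid size in voxels; 96^3 by default.
#' @param ... Overrides forwarded to [phantom_spec()].
#' @return An `fpa_phantom_spec`.
#' @export
default_swine_spec <- function(dim = c(96, 96, 96), ...) {
  phantom_spec(dim = dim, ...)
}

# Analytic aortic enhancement above baseline (HU) at times t.
phantom_ca <- function(spec, t) {
  if (spec$tdc_shape == "gamma_variate") {
    gamma_variate(t, spec$tdc_amplitude, spec$tdc_alpha, spec$tdc_beta,
                  spec$tdc_t0)
  } else {
    spec$ramp_rate_hu_s * pmax(t - spec$tdc_t0, 0)
  }
}

# Running integral of the enhancement in HU.min from time 0.
phantom_ca_integral_min <- function(spec, t) {
  if (spec$tdc_shape == "gamma_variate") {
    gamma_variate_integral(t, spec$tdc_amplitude, spec$tdc_alpha,
                           spec$tdc_beta, spec$tdc_t0) / 60
  } else {
    spec$ramp_rate_hu_s * pmax(t - spec$tdc_t0, 0)^2 / 2 / 60
  }
}

#' Noiseless aortic time-density curve of a phantom
#'
#' @param spec An [phantom_spec()].
#' @param times Sample times (defaults to the spec's frame times).
#' @return An [time_density_curve()] sampled at `times`.
#' @export
phantom_tdc <- function(spec, times = spec$frame_times) {
  stopifnot(inherits(spec, "fpa_phantom_spec"))
  time_density_curve(times, spec$hu_blood + phantom_ca(spec, times),
                     spec$hu_blood)
}

# Geometry is deterministic in (spec, condition); cache the last build so
# repeated simulations (e.g. noise realisations across seeds) don't redo the
# territory assignment.
.phantom_cache <- new.env(parent = emptyenv())

# Builds masks, centerlines, territory truth and true perfusion maps.
phantom_geometry <- function(spec, condition = c("stress", "rest")) {
  condition <- match.arg(condition)
  if (!is.null(.phantom_cache$geo) &&
      identical(.phantom_cache$spec, unclass(spec)) &&
      identical(.phantom_cache$condition, condition))
    return(.phantom_cache$geo)
  d <- spec$dim; sp <- spec$spacing
  cc <- voxel_centers_mm(d, sp)
  cx <- spec$lv_center_mm
  a_o <- spec$lv_outer_mm; a_i <- spec$lv_inner_mm

  qx_o <- ((cc$x - cx[1]) / a_o[1])^2
  qy_o <- ((cc$y - cx[2]) / a_o[2])^2
  qz_o <- ((cc$z - cx[3]) / a_o[3])^2
  qx_i <- ((cc$x - cx[1]) / a_i[1])^2
  qy_i <- ((cc$y - cx[2]) / a_i[2])^2
  qz_i <- ((cc$z - cx[3]) / a_i[3])^2
  q_o <- outer(outer(qx_o, qy_o, "+"), qz_o, "+")
  q_i <- outer(outer(qx_i, qy_i, "+"), qz_i, "+")
  zcap <- cx[3] + spec$lv_base_frac * a_o[3]
  zmask <- aperm(array(rep(cc$z <= zcap, each = d[1] * d[2]), dim = d),
                 c(1, 2, 3))
  myo <- q_o <= 1 & q_i > 1 & zmask

  ac <- spec$aorta_center_mm
  r2 <- outer((cc$x - ac[1])^2, (cc$y - ac[2])^2, "+") <=
    spec$aorta_radius_mm^2
  inz <- cc$z >= ac[3] & cc$z <= ac[3] + spec$aorta_height_mm
  aorta <- array(FALSE, d)
  aorta[, , inz] <- rep(r2, sum(inz))
  if (any(myo & aorta))
    abort("invalid phantom: aortic cylinder intersects the myocardial shell.")
  if (!any(myo)) abort("phantom myocardium mask is empty.")
  if (!any(aorta)) abort("phantom aortic ROI is empty.")

  myo_mask <- binary_mask(myo, sp, "myocardium")
  aorta_mask <- binary_mask(aorta, sp, "aortic-root")

  # Epicardial centerlines: curves on the outer shell at fixed azimuth,
  # running from the basal truncation plane towards the apex.
  mk_line <- function(label, psi_deg) {
    u <- seq(spec$lv_base_frac, -0.95, length.out = 40)
    r <- sqrt(pmax(1 - u^2, 0))
    psi <- psi_deg * pi / 180
    pts <- cbind(cx[1] + a_o[1] * r * cos(psi),
                 cx[2] + a_o[2] * r * sin(psi),
                 cx[3] + a_o[3] * u)
    centerline(label, pts)
  }
  lines <- list(mk_line("LAD", 90), mk_line("LCx", 210), mk_line("RCA", 330))

  labels <- assign_territories(myo_mask, lines, sp)
  if (!is.null(spec$stenosis_frac)) {
    lad <- lines[[1]]
    lad$stenosis_arclength_mm <- spec$stenosis_frac * centerline_length(lad)
    lines[[1]] <- lad
    labels <- partition_distal(labels, lad, myo_mask)
  }

  flows <- if (condition == "stress") spec$flows_stress else spec$flows_rest
  perf <- array(0, d)
  for (k in seq_along(labels$legend)) {
    nm <- labels$legend[k]
    key <- switch(nm,
                  "LAD-proximal" = "LAD",
                  "LAD-distal"   = "LAD_distal",
                  nm)
    if (!key %in% names(flows))
      abort(sprintf("no true flow configured for territory '%s'.", nm))
    perf[labels$data == k] <- flows[[key]]
  }

  geo <- list(myo = myo_mask, aorta = aorta_mask, centerlines = lines,
              territories = labels, perfusion = perf)
  .phantom_cache$spec <- unclass(spec)
  .phantom_cache$condition <- condition
  .phantom_cache$geo <- geo
  geo
}

#' Simulate a dynamic contrast-enhanced phantom acquisition
#'
#' Generates the CT series for the given spec: aortic voxels follow baseline
#' blood HU plus the bolus curve; each myocardial voxel accumulates contrast
#' at a rate proportional to its true perfusion (inflow-only single
#' compartment); stationary Gaussian noise scales with tube current as
#' `sigma_ref * (ma_ref/mA)^exponent`.  Identical spec + seed reproduces
#' bit-identical volumes.
#'
#' @param spec An [phantom_spec()].
#' @param condition `"rest"` or `"stress"` true-flow set.
#' @param times Frame times; defaults to the spec's frame grid.
#' @param ma Tube current per frame; defaults to the spec's.
#' @param noise Add acquisition noise? Set `FALSE` for noiseless volumes.
#' @param seed RNG seed for the noise (defaults to the spec's seed).
#'
#' @return List with `series` (list of [volume_scan()]) and `truth`, a
#'   ground-truth bundle: `perfusion` (mL/min/g, zero outside the
#'   myocardium), `myo`, `aorta`, `centerlines`, `territories` and the
#'   noiseless `tdc`.
#' @export
simulate_acquisition <- function(spec, condition = c("stress", "rest"),
                                 times = NULL, ma = NULL, noise = TRUE,
                                 seed = NULL) {
  stopifnot(inherits(spec, "fpa_phantom_spec"))
  condition <- match.arg(condition)
  if (is.null(times)) {
    times <- spec$frame_times
    if (is.null(ma)) ma <- spec$frame_ma
  }
  if (is.null(ma)) ma <- rep(spec$frame_ma[1], length(times))
  if (length(ma) == 1L) ma <- rep(ma, length(times))
  stopifnot(length(ma) == length(times))
  if (is.null(seed)) seed <- spec$seed

  # Inflow-only model validity: warn once past the bolus washout tail.
  if (spec$tdc_shape == "gamma_variate") {
    t_valid <- spec$tdc_t0 +
      spec$tdc_beta * (spec$tdc_alpha + 2 * sqrt(spec$tdc_alpha))
    if (max(times) > t_valid)
      warn(sprintf(paste0("frame times extend past %.1f s, beyond the ",
                          "outflow-free first-pass window; the inflow-only ",
                          "tissue model may not hold."), t_valid))
  }

  geo <- phantom_geometry(spec, condition)
  myo_idx <- which(geo$myo$data)
  ao_idx <- which(geo$aorta$data)
  pvals <- geo$perfusion[myo_idx]

  ca <- phantom_ca(spec, times)
  ia <- phantom_ca_integral_min(spec, times)
  sigma <- spec$noise_sigma_ref * (spec$noise_ma_ref / ma)^spec$noise_exponent
  n_vox <- prod(spec$dim)

  make_frame <- function(k) {
    arr <- array(spec$baseline_drift_hu, spec$dim)
    arr[myo_idx] <- arr[myo_idx] + spec$hu_tissue +
      pvals * MYOCARDIAL_DENSITY_G_PER_ML * ia[k]
    arr[ao_idx] <- arr[ao_idx] + spec$hu_blood + ca[k]
    arr
  }
  series <- lapply(seq_along(times), make_frame)
  if (noise && spec$noise_sigma_ref > 0) {
    withr::with_seed(seed, {
      for (k in seq_along(series))
        series[[k]] <- series[[k]] + array(rnorm(n_vox, sd = sigma[k]), spec$dim)
    })
  }
  series <- lapply(seq_along(series), function(k)
    volume_scan(series[[k]], spec$spacing, time_s = times[k],
                kvp = 100, ma = ma[k]))

  truth <- structure(list(
    perfusion = geo$perfusion, myo = geo$myo, aorta = geo$aorta,
    centerlines = geo$centerlines, territories = geo$territories,
    tdc = phantom_tdc(spec), condition = condition
  ), class = "fpa_ground_truth")

  list(series = series, truth = truth)
}

#' @export
print.fpa_ground_truth <- function(x, ...) {
  cat(sprintf("<fpa_ground_truth> %s: %d myocardial voxels, %d territories\n",
              x$condition, sum(x$myo$data), length(x$territories$legend)))
  invisible(x)
}
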