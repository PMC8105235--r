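#' Maximum intensity projection across volumes
#'
#' Voxel-wise maximum over co-registered volumes; metadata (time, tube
#' settings) inherits from the first volume.
#'
#' @param volumes List of [volume_scan()]s on identical grids (>= 1).
#' @return A [volume_scan()].
#' @export
mip_combine <- function(volumes) {
  if (inherits(volumes, "fpa_volume")) volumes <- list(volumes)
  if (length(volumes) < 1L) abort("need at least one volume.")
  for (v in volumes[-1]) check_same_grid(volumes[[1]], v, "volumes")
  out <- volumes[[1]]
  if (length(volumes) > 1L)
    out$data <- Reduce(pmax, lapply(volumes, function(v) v$data))
  out
}

#' Arterial input amplitude C_in
#'
#' Aortic-root blood-pool enhancement averaged between the two volume scans:
#' `C_in = (mean ROI HU in V1 + mean ROI HU in V2)/2 - baseline`.  The
#' baseline blood HU is subtracted so that `C_in` is the contrast-attributable
#' enhancement; set `subtract_baseline = FALSE` for the raw two-scan average.
#' An optional erosion radius shrinks the ROI to its core before averaging.
#'
#' @param v1,v2 The early and peak [volume_scan()]s.
#' @param aorta Aortic-root [binary_mask()].
#' @param baseline_hu Baseline blood-pool HU.
#' @param subtract_baseline Subtract the baseline (default `TRUE`).
#' @param erode_mm Radius (mm) by which to erode the ROI, default 0.
#'
#' @return `C_in` in HU (> 0, else an error).
#' @export
compute_cin <- function(v1, v2, aorta, baseline_hu, subtract_baseline = TRUE,
                        erode_mm = 0) {
  stopifnot(inherits(v1, "fpa_volume"), inherits(v2, "fpa_volume"),
            inherits(aorta, "fpa_mask"))
  check_same_grid(v1, v2, "V1 and V2")
  check_same_grid(v1, aorta, "volume and aortic ROI")
  roi <- aorta$data
  if (erode_mm > 0) roi <- erode_mask(roi, aorta$spacing, erode_mm)
  if (!any(roi)) abort("aortic ROI mask is empty (after erosion).")
  cin <- (mean(v1$data[roi]) + mean(v2$data[roi])) / 2 -
    if (subtract_baseline) baseline_hu else 0
  if (cin <= 0)
    abort("C_in <= 0: no contrast arrival in the aortic ROI.")
  cin
}

# Morphological erosion by a metric ball of radius r_mm (separable box
# under-approximation is not used; direct neighbourhood test).
erode_mask <- function(mask, spacing, r_mm) {
  steps <- pmax(0L, floor(r_mm / spacing))
  out <- mask
  d <- dim(mask)
  for (dz in -steps[3]:steps[3]) for (dy in -steps[2]:steps[2])
    for (dx in -steps[1]:steps[1]) {
      if (sqrt(sum((c(dx, dy, dz) * spacing)^2)) > r_mm) next
      sh <- shift_array(mask, c(dx, dy, dz))
      out <- out & sh
    }
  out
}

shift_array <- function(a, by) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (by[k] >= 0) {
      src[[k]] <- seq_len(d[k] - by[k]); dst[[k]] <- src[[k]] + by[k]
    } else {
      src[[k]] <- seq_len(d[k] + by[k]) - by[k]; dst[[k]] <- seq_len(d[k] + by[k])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Myocardial tissue mass
#'
#' `M_T = 1.055 g/mL * (voxel count * voxel volume in mL)`.
#'
#' @param myo Myocardium [binary_mask()].
#' @param spacing Voxel spacing in mm (defaults to the mask's).
#' @return Mass in grams.
#' @export
compute_tissue_mass <- function(myo, spacing = myo$spacing) {
  data <- if (inherits(myo, "fpa_mask")) myo$data else myo
  n <- sum(data)
  if (n == 0L) abort("myocardium mask is empty.")
  MYOCARDIAL_DENSITY_G_PER_ML * n * voxel_volume_ml(spacing)
}

#' Two-volume first-pass perfusion
#'
#' Single-compartment first-pass analysis from the early (V1) and peak (V2)
#' arterial volume scans.  The average perfusion is
#' `P_AVE = dHU_AVE / (dt_min * C_in * rho)` with `rho` = 1.055 g/mL, and
#' each voxel scales proportionally to its own enhancement change:
#' `P = P_AVE * dHU / dHU_AVE`.  Negative voxel values (noise) are retained;
#' clamping is a display choice, not a computation.
#'
#' @inheritParams compute_cin
#' @param myo Myocardium [binary_mask()].
#' @param ... Passed to [compute_cin()] (`subtract_baseline`, `erode_mm`).
#'
#' @return An `fpa_perfusion` object: `p_ave` (mL/min/g), `map` (voxel
#'   perfusion, `NaN` outside the myocardium), plus the constituents `cin_hu`,
#'   `mass_g`, `dhu_ave`, `dt_min`, `dmc_dt` (HU.mL/min) and the masks.
#' @export
compute_perfusion <- function(v1, v2, myo, aorta, baseline_hu, ...) {
  stopifnot(inherits(myo, "fpa_mask"))
  check_same_grid(v1, v2, "V1 and V2")
  check_same_grid(v1, myo, "volume and myocardium mask")
  dt_min <- (v2$time_s - v1$time_s) / 60
  if (!is.finite(dt_min) || dt_min <= 0)
    abort("V2 must be acquired after V1 (dt > 0).")
  if (!any(myo$data)) abort("myocardium mask is empty.")

  cin <- compute_cin(v1, v2, aorta, baseline_hu, ...)
  mass <- compute_tissue_mass(myo)
  vv <- voxel_volume_ml(myo$spacing)

  dhu <- v2$data - v1$data
  dhu_m <- dhu[myo$data]
  dhu_ave <- mean(dhu_m)
  if (dhu_ave <= 0) abort("no net myocardial enhancement between V1 and V2.")
  # Contrast-mass entry-rate proxy: summed HU change times voxel volume per time.
  dmc_dt <- sum(dhu_m) * vv / dt_min

  p_ave <- dhu_ave / (dt_min * cin * MYOCARDIAL_DENSITY_G_PER_ML)
  map <- array(NaN, dim(v1$data))
  map[myo$data] <- dhu_m / (dt_min * cin * MYOCARDIAL_DENSITY_G_PER_ML)

  structure(list(p_ave = p_ave, map = map, cin_hu = cin, mass_g = mass,
                 dhu_ave = dhu_ave, dhu = dhu, dt_min = dt_min,
                 dmc_dt = dmc_dt, myo = myo, spacing = myo$spacing),
            class = "fpa_perfusion")
}

#' @export
print.fpa_perfusion <- function(x, ...) {
  cat(sprintf("<fpa_perfusion> P_AVE %.3f mL/min/g  (C_in %.1f HU, M_T %.2f g, dHU %.2f, dt %.3f min)\n",
              x$p_ave, x$cin_hu, x$mass_g, x$dhu_ave, x$dt_min))
  invisible(x)
}

#' @describeIn compute_perfusion One-row tibble of the scalar constituents.
#' @param x An `fpa_perfusion` object.
#' @method glance fpa_perfusion
#' @export
glance.fpa_perfusion <- function(x, ...) {
  tibble(p_ave = x$p_ave, cin_hu = x$cin_hu, mass_g = x$mass_g,
         dhu_ave = x$dhu_ave, dt_min = x$dt_min, dmc_dt = x$dmc_dt,
         n_voxels = sum(x$myo$data))
}

#' Coronary flow reserve map
#'
#' Voxel-wise `CFR = P_stress / P_rest` wherever the rest map is at least
#' `rest_floor`; voxels below the floor are flagged undefined (`NaN`) and are
#' excluded from regional means.  Regional CFR should be computed as the
#' ratio of regional mean stress to regional mean rest perfusion (see
#' [territory_cfr()]), not as the mean of voxel ratios.
#'
#' @param stress,rest `fpa_perfusion` results on identical grids and masks.
#' @param rest_floor Minimum rest perfusion (mL/min/g), default 0.1.
#'
#' @return An `fpa_cfr` object: `map` (CFR, `NaN` where undefined), the
#'   `defined` mask, and the two parent results.
#' @export
compute_cfr <- function(stress, rest, rest_floor = 0.1) {
  stopifnot(inherits(stress, "fpa_perfusion"), inherits(rest, "fpa_perfusion"))
  if (!identical(dim(stress$map), dim(rest$map)))
    abort("stress and rest maps are on different grids.")
  if (!identical(stress$myo$data, rest$myo$data))
    abort("stress and rest myocardium masks differ.")
  ok <- stress$myo$data & is.finite(rest$map) & rest$map >= rest_floor
  map <- array(NaN, dim(stress$map))
  map[ok] <- stress$map[ok] / rest$map[ok]
  structure(list(map = map, defined = ok, rest_floor = rest_floor,
                 stress = stress, rest = rest, spacing = stress$spacing),
            class = "fpa_cfr")
}

#' @export
print.fpa_cfr <- function(x, ...) {
  v <- x$map[x$defined]
  cat(sprintf("<fpa_cfr> %d defined voxels, median CFR %.2f (floor %.2g mL/min/g)\n",
              length(v), stats::median(v), x$rest_floor))
  invisible(x)
}

#' Per-territory CFR from paired regional means
#'
#' Regional CFR = (territory mean stress perfusion) / (territory mean rest
#' perfusion), the averaging order used for vessel-level reporting.
#'
#' @param stress,rest `fpa_perfusion` results.
#' @param labelmap An `fpa_labelmap`.
#' @return Tibble: `territory`, `mean_stress`, `mean_rest`, `cfr`.
#' @export
territory_cfr <- function(stress, rest, labelmap) {
  ts_s <- territory_stats(stress$map, labelmap)
  ts_r <- territory_stats(rest$map, labelmap)
  tibble(territory = ts_s$territory,
         mean_stress = ts_s$mean,
         mean_rest = ts_r$mean,
         cfr = ts_s$mean / ts_r$mean)
}

#' Voxel binning of a map
#'
#' Block means over `factor^3` neighbourhoods, restricted to defined (finite)
#' in-mask voxels; blocks with no defined voxel are `NaN`.  Binning trades
#' spatial resolution for noise suppression.
#'
#' @param map 3D numeric array (NaN = undefined) or an `fpa_perfusion`
#'   (its voxel map is binned).
#' @param factor Integer >= 1 block edge per axis.
#'
#' @return List with `map` (downsampled array), `n` (defined voxels per
#'   block) and `factor`.
#' @export
bin_voxels <- function(map, factor) {
  if (inherits(map, "fpa_perfusion")) map <- map$map
  factor <- as.integer(factor)
  if (factor < 1L) abort("`factor` must be >= 1.")
  if (factor == 1L) return(list(map = map, n = array(1L, dim(map)) * is.finite(map),
                                factor = 1L))
  d <- dim(map)
  nd <- ceiling(d / factor)
  block <- function(i) (i - 1L) %/% factor + 1L
  idx <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  bix <- (block(idx$z) - 1L) * nd[1] * nd[2] + (block(idx$y) - 1L) * nd[1] +
    block(idx$x)
  v <- as.vector(map)
  ok <- is.finite(v)
  sums <- rep(0, prod(nd)); cnts <- rep(0L, prod(nd))
  agg_s <- tapply(v[ok], bix[ok], sum)
  agg_n <- tapply(rep(1L, sum(ok)), bix[ok], sum)
  sums[as.integer(names(agg_s))] <- agg_s
  cnts[as.integer(names(agg_n))] <- agg_n
  out <- ifelse(cnts > 0, sums / pmax(cnts, 1L), NaN)
  list(map = array(out, nd), n = array(cnts, nd), factor = factor)
}
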