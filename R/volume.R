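#' CT volume scan
#'
#' A `volume_scan` is a 3D grid of Hounsfield-unit values together with the
#' geometry and acquisition metadata needed for perfusion computation: voxel
#' spacing (mm), acquisition time (s) and tube settings.  Paired scans (the
#' early and peak arterial volumes, V1 and V2) must share one grid.
#'
#' @param data 3D numeric array of HU values.
#' @param spacing Numeric length-3, voxel spacing in mm per axis (x, y, z).
#' @param time_s Acquisition time in seconds (scalar).
#' @param kvp Tube voltage in kVp.
#' @param ma Tube current in mA.
#' @param phase Cardiac phase tag (percent of the R-R interval), default 75.
#'
#' @return An object of class `fpa_volume`.
#' @export
volume_scan <- function(data, spacing, time_s = NA_real_, kvp = 100, ma = 200,
                        phase = 75) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3D array of HU values.")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("`spacing` must be three positive voxel sizes in mm.")
  if (any(!is.finite(data)))
    abort("volume contains non-finite HU values.")
  structure(
    list(data = data, spacing = spacing, time_s = as.numeric(time_s)[1],
         kvp = kvp, ma = ma, phase = phase),
    class = "fpa_volume"
  )
}

#' @export
print.fpa_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fpa_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  t = %s s, %g kVp, %g mA, HU range [%.1f, %.1f]\n",
              format(x$time_s), x$kvp, x$ma, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.fpa_volume <- function(x) dim(x$data)

#' Binary mask aligned to a volume grid
#'
#' @param data Logical (or 0/1) 3D array.
#' @param spacing Voxel spacing in mm, as in [volume_scan()].
#' @param role Role tag, `"myocardium"` or `"aortic-root"` (free-form allowed).
#'
#' @return An object of class `fpa_mask`.
#' @export
binary_mask <- function(data, spacing, role = "myocardium") {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3D array.")
  if (is.numeric(data)) {
    vals <- unique(as.vector(data))
    if (!all(vals %in% c(0, 1)))
      abort("mask values must be 0/1 (or logical).")
    data <- array(data > 0, dim = dim(data))
  }
  if (!is.logical(data)) abort("mask must be logical or 0/1 numeric.")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    abort("`spacing` must be three positive voxel sizes in mm.")
  structure(list(data = data, spacing = spacing, role = role),
            class = "fpa_mask")
}

#' @export
print.fpa_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fpa_mask> role '%s', %d x %d x %d voxels, %d in mask\n",
              x$role, d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' @export
dim.fpa_mask <- function(x) dim(x$data)

# Shared-grid check used by every paired-volume operation.
check_same_grid <- function(a, b, what = "objects") {
  da <- if (inherits(a, c("fpa_volume", "fpa_mask"))) dim(a$data) else dim(a)
  db <- if (inherits(b, c("fpa_volume", "fpa_mask"))) dim(b$data) else dim(b)
  if (!identical(da, db))
    abort(sprintf("%s are on different grids: %s vs %s.", what,
                  paste(da, collapse = "x"), paste(db, collapse = "x")))
  sa <- if (is.list(a)) a$spacing else NULL
  sb <- if (is.list(b)) b$spacing else NULL
  if (!is.null(sa) && !is.null(sb) && max(abs(sa - sb)) > 1e-9)
    abort(sprintf("%s have different voxel spacing.", what))
  invisible(TRUE)
}

# Voxel volume in mL (spacing is in mm; 1 mL = 1000 mm^3).
voxel_volume_ml <- function(spacing) prod(spacing) / 1000

# World coordinates (mm) of all voxel centers, 0-based indices.
voxel_centers_mm <- function(dim3, spacing) {
  list(x = (seq_len(dim3[1]) - 1) * spacing[1],
       y = (seq_len(dim3[2]) - 1) * spacing[2],
       z = (seq_len(dim3[3]) - 1) * spacing[3])
}
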