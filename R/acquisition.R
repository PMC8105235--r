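#' Aortic time-density curve
#'
#' Enhancement of the aortic-root blood pool versus time.  The curve drives
#' bolus-tracking trigger detection, the trigger-to-peak delay estimate and
#' the systematic selection of the two perfusion volume scans.
#'
#' @param time_s Sample times in seconds, strictly ascending, length >= 3.
#' @param hu Aortic HU at each sample.
#' @param baseline_hu Baseline blood-pool HU (measured on a pre-contrast
#'   monitoring frame).
#'
#' @return An object of class `fpa_tdc`; also a valid data source for
#'   [tidy()] which returns a tibble with `time_s`, `hu` and `enhancement`.
#' @export
time_density_curve <- function(time_s, hu, baseline_hu = 0) {
  time_s <- as.numeric(time_s); hu <- as.numeric(hu)
  if (length(time_s) < 3L) abort("a time-density curve needs at least 3 samples.")
  if (length(hu) != length(time_s)) abort("`time_s` and `hu` lengths differ.")
  if (any(!is.finite(time_s)) || any(!is.finite(hu)))
    abort("time-density curve must be finite.")
  if (any(diff(time_s) <= 0)) abort("sample times must be strictly ascending.")
  structure(list(time_s = time_s, hu = hu, baseline_hu = as.numeric(baseline_hu)[1]),
            class = "fpa_tdc")
}

#' @export
print.fpa_tdc <- function(x, ...) {
  cat(sprintf("<fpa_tdc> %d samples over [%.2f, %.2f] s, baseline %.1f HU, peak %.1f HU\n",
              length(x$time_s), min(x$time_s), max(x$time_s),
              x$baseline_hu, max(x$hu)))
  invisible(x)
}

#' @method tidy fpa_tdc
#' @export
tidy.fpa_tdc <- function(x, ...) {
  tibble(time_s = x$time_s, hu = x$hu, enhancement = x$hu - x$baseline_hu)
}

#' Bolus-tracking trigger configuration
#'
#' @param threshold_hu Trigger threshold in HU above the baseline blood-pool
#'   enhancement; the protocol default is 140 HU.
#' @param latency_frames Frames between threshold crossing and the first
#'   acquired volume (scanner arm/latency); 0 means the crossing frame itself.
#'
#' @return An object of class `fpa_trigger_config`.
#' @export
trigger_config <- function(threshold_hu = 140, latency_frames = 0L) {
  if (!is.finite(threshold_hu) || threshold_hu <= 0)
    abort("`threshold_hu` must be > 0.")
  if (latency_frames < 0) abort("`latency_frames` must be >= 0.")
  structure(list(threshold_hu = threshold_hu,
                 latency_frames = as.integer(latency_frames)),
            class = "fpa_trigger_config")
}

#' Detect the bolus-tracking trigger time
#'
#' Sample-and-hold rule: the trigger is the first sample whose HU reaches
#' baseline + threshold.  No interpolation is performed, matching how a
#' scanner's monitoring scan operates on discrete frames.
#'
#' @param tdc A [time_density_curve()].
#' @param cfg A [trigger_config()].
#' @return Trigger time in seconds.
#' @export
detect_trigger <- function(tdc, cfg = trigger_config()) {
  stopifnot(inherits(tdc, "fpa_tdc"))
  idx <- which(tdc$hu >= tdc$baseline_hu + cfg$threshold_hu)
  if (length(idx) == 0L)
    abort(sprintf("trigger not reached: enhancement never exceeds %.0f HU above baseline.",
                  cfg$threshold_hu))
  i <- idx[1] + cfg$latency_frames
  if (i > length(tdc$time_s))
    abort("trigger latency runs past the end of the acquisition.")
  tdc$time_s[i]
}

#' Time of peak aortic enhancement
#'
#' Global maximum of the sampled curve; ties break to the earliest sample.
#'
#' @inheritParams detect_trigger
#' @return Peak time in seconds.
#' @export
find_peak <- function(tdc) {
  stopifnot(inherits(tdc, "fpa_tdc"))
  tdc$time_s[which.max(tdc$hu)]
}

#' Trigger-to-peak delay
#'
#' The delay between the early arterial volume (acquired at the trigger) and
#' the peak-enhancement volume.  The default (validated) strategy measures it
#' from the aortic time-density curve; the alternative `"injection"` strategy
#' predicts it as contrast injection time plus a fixed dispersion time, for
#' prospective use when no dynamic curve exists.
#'
#' @inheritParams detect_trigger
#' @param method `"tdc"` (measure from the curve, default) or `"injection"`.
#' @param injection_time_s,dispersion_time_s Injection duration and bolus
#'   dispersion time in seconds (used by `method = "injection"` only).
#' @return Delay in seconds (> 0).
#' @export
estimate_delta_t <- function(tdc, cfg = trigger_config(),
                             method = c("tdc", "injection"),
                             injection_time_s = NULL,
                             dispersion_time_s = 0) {
  method <- match.arg(method)
  if (method == "injection") {
    if (is.null(injection_time_s) || injection_time_s <= 0)
      abort("`injection_time_s` must be > 0 for the injection strategy.")
    return(injection_time_s + dispersion_time_s)
  }
  t_trig <- detect_trigger(tdc, cfg)
  t_peak <- find_peak(tdc)
  if (t_peak <= t_trig)
    abort("degenerate bolus: aortic peak at or before the trigger.")
  t_peak - t_trig
}

#' Systematic selection of the two perfusion volumes
#'
#' Builds the aortic time-density curve from per-volume ROI means, then picks
#' V1 as the first volume at/after the trigger and V2 as the volume at the
#' curve's peak.  If aortic enhancement is still rising at the last frame a
#' warning notes that the true peak may lie beyond the acquisition.
#'
#' @param series List of [volume_scan()]s with increasing `time_s`.
#' @param aorta Aortic-root [binary_mask()] on the shared grid.
#' @param baseline_hu Baseline blood-pool HU.
#' @param cfg A [trigger_config()].
#'
#' @return List with elements `v1`, `v2` (volume scans), `i1`, `i2` (indices
#'   into `series`), `tdc` and `delta_t_s`.
#' @export
select_v1_v2 <- function(series, aorta, baseline_hu, cfg = trigger_config()) {
  if (length(series) < 2L) abort("need at least two volumes.")
  stopifnot(inherits(aorta, "fpa_mask"))
  if (!any(aorta$data)) abort("aortic ROI mask is empty.")
  for (v in series) check_same_grid(v, aorta, "volume and aortic ROI")
  times <- vapply(series, function(v) v$time_s, numeric(1))
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    abort("series acquisition times must be finite and strictly ascending.")

  if (length(series) == 2L) {
    # Two-volume low-dose acquisition: already triggered, identity pass-through.
    return(list(v1 = series[[1]], v2 = series[[2]], i1 = 1L, i2 = 2L,
                tdc = NULL, delta_t_s = times[2] - times[1]))
  }

  roi_mean <- vapply(series, function(v) mean(v$data[aorta$data]), numeric(1))
  tdc <- time_density_curve(times, roi_mean, baseline_hu)
  t_trig <- detect_trigger(tdc, cfg)
  i1 <- match(TRUE, times >= t_trig)
  i2 <- which.max(roi_mean)
  if (i2 == length(series) && roi_mean[i2] > roi_mean[i2 - 1])
    warn("aortic enhancement still rising at the last frame: peak may lie beyond acquisition.")
  if (i2 <= i1)
    abort("aortic peak does not occur after the trigger volume.")
  list(v1 = series[[i1]], v2 = series[[i2]], i1 = i1, i2 = i2,
       tdc = tdc, delta_t_s = times[i2] - times[i1])
}

#' Read / write a time-density curve as CSV
#'
#' Plain two-column CSV (`time_s`, `hu`); baseline is carried in a
#' `# baseline_hu:` comment line.
#'
#' @param tdc A [time_density_curve()].
#' @param path File path.
#' @return `read_tdc_csv()` returns an `fpa_tdc`; `write_tdc_csv()` returns
#'   `path` invisibly.
#' @export
write_tdc_csv <- function(tdc, path) {
  stopifnot(inherits(tdc, "fpa_tdc"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# baseline_hu: %.10g", tdc$baseline_hu), con)
  write.csv(data.frame(time_s = tdc$time_s, hu = tdc$hu), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tdc_csv
#' @export
read_tdc_csv <- function(path) {
  first <- readLines(path, n = 1)
  baseline <- 0
  if (grepl("^# baseline_hu:", first))
    baseline <- as.numeric(sub("^# baseline_hu:", "", first))
  df <- read.csv(path, comment.char = "#")
  time_density_curve(df$time_s, df$hu, baseline)
}
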