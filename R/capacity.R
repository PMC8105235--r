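CAPACITY_CLASS_NAMES <- c("scar", "definite ischemia", "moderately reduced",
                          "mildly reduced", "minimally reduced", "normal")

#' Coronary flow-capacity thresholds
#'
#' The six-class flow-capacity scheme classifies each point of the joint
#' (CFR, stress perfusion) plane, ordered severe to normal: scar, definite
#' ischemia, moderately reduced, mildly reduced, minimally reduced, normal.
#' Each class carries lower bounds on CFR and on stress perfusion (mL/min/g);
#' bounds must be non-decreasing from severe to normal and the most severe
#' class must start at 0 on both axes so the plane is fully covered.
#'
#' Numeric cutoffs are deliberately not hard-coded science: they ship as a
#' configuration (see `system.file("extdata", "capacity_example.yaml",
#' package = "fpact")` for a clearly-labelled example) and must be chosen by
#' the user from the flow-capacity literature appropriate to their setting.
#'
#' @param classes Data frame or tibble with columns `name`, `cfr_min`,
#'   `stress_min`, ordered severe to normal.
#' @return An object of class `fpa_capacity_thresholds`.
#' @export
capacity_thresholds <- function(classes) {
  classes <- as.data.frame(classes)
  need <- c("name", "cfr_min", "stress_min")
  if (!all(need %in% names(classes)))
    abort("`classes` needs columns name, cfr_min, stress_min.")
  if (nrow(classes) != 6L || !identical(classes$name, CAPACITY_CLASS_NAMES))
    abort(sprintf("exactly the six classes %s are required, severe to normal.",
                  paste(CAPACITY_CLASS_NAMES, collapse = ", ")))
  for (col in c("cfr_min", "stress_min")) {
    b <- classes[[col]]
    if (any(!is.finite(b)) || b[1] != 0 || any(diff(b) < 0))
      abort(sprintf("`%s` must start at 0 and be non-decreasing severe to normal.",
                    col))
  }
  structure(list(classes = as_tibble(classes)), class = "fpa_capacity_thresholds")
}

#' Read flow-capacity thresholds from YAML
#'
#' @param path YAML file with a `classes` list of `{name, cfr_min, stress_min}`.
#' @return An [capacity_thresholds()] object.
#' @export
read_capacity_thresholds <- function(path) {
  y <- yaml::read_yaml(path)
  cl <- dplyr::bind_rows(lapply(y$classes, as_tibble))
  capacity_thresholds(cl)
}

#' @export
print.fpa_capacity_thresholds <- function(x, ...) {
  cat("<fpa_capacity_thresholds> (severe -> normal)\n")
  print(as.data.frame(x$classes), row.names = FALSE)
  invisible(x)
}

#' Classify flow capacity from joint (CFR, stress perfusion)
#'
#' Lower-left-dominant staircase: the class achieved on each axis is the best
#' class whose lower bound the value still meets, and the final class is the
#' more severe of the two axis classes (the worst axis governs).  Increasing
#' either CFR or stress perfusion never yields a more severe class, and every
#' point with both values >= 0 is classified.  Undefined inputs (NA/NaN)
#' stay unclassified.
#'
#' @param cfr,stress Numeric scalars, vectors or arrays (same shape).
#' @param thresholds An [capacity_thresholds()] object.
#'
#' @return An `fpa_capacity` object: `class_index` (integer, 1 = most severe,
#'   6 = normal, NA = unclassified) shaped like the input, plus the legend.
#' @export
classify_capacity <- function(cfr, stress, thresholds) {
  stopifnot(inherits(thresholds, "fpa_capacity_thresholds"))
  if (inherits(cfr, "fpa_cfr")) cfr <- cfr$map
  if (inherits(stress, "fpa_perfusion")) stress <- stress$map
  dims <- dim(cfr)
  if (!identical(dim(cfr), dim(stress)) || length(cfr) != length(stress))
    abort("`cfr` and `stress` must be aligned.")
  cl <- thresholds$classes
  axis_class <- function(v, bounds) {
    # Highest class whose lower bound is still met; bounds non-decreasing.
    k <- rowSums(outer(as.vector(v), bounds, ">=")) # counts bounds met
    k[as.vector(!is.finite(v)) | as.vector(v) < 0] <- NA_integer_
    k
  }
  kc <- axis_class(cfr, cl$cfr_min)
  ks <- axis_class(stress, cl$stress_min)
  k <- pmin(kc, ks)
  if (!is.null(dims)) k <- array(as.integer(k), dims) else k <- as.integer(k)
  structure(list(class_index = k, legend = cl$name,
                 thresholds = thresholds),
            class = "fpa_capacity")
}

#' @export
print.fpa_capacity <- function(x, ...) {
  tab <- table(factor(x$legend[x$class_index], levels = x$legend))
  cat("<fpa_capacity>\n")
  print(tab)
  invisible(x)
}

#' Export per-territory (CFR, stress perfusion) pairs as CSV
#'
#' One row per defined myocardial voxel: `territory`, `cfr`,
#' `stress_ml_min_g`; the raw material for flow-capacity scatter plots.
#'
#' @param cfr An `fpa_cfr` (or CFR array).
#' @param stress An `fpa_perfusion` (or stress map array).
#' @param labelmap An `fpa_labelmap`.
#' @param path Optional CSV output path; omit to just get the tibble.
#' @return The tibble (invisibly if `path` is given).
#' @export
capacity_scatter <- function(cfr, stress, labelmap, path = NULL) {
  if (inherits(cfr, "fpa_cfr")) cfr <- cfr$map
  if (inherits(stress, "fpa_perfusion")) stress <- stress$map
  stopifnot(inherits(labelmap, "fpa_labelmap"))
  if (!identical(dim(cfr), dim(labelmap$data)) ||
      !identical(dim(stress), dim(labelmap$data)))
    abort("maps and label map are on different grids.")
  ok <- labelmap$data > 0 & is.finite(cfr) & is.finite(stress)
  out <- tibble(territory = labelmap$legend[labelmap$data[ok]],
                cfr = cfr[ok], stress_ml_min_g = stress[ok])
  if (!is.null(path)) {
    write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Per-territory flow-capacity mass fractions
#'
#' For each territory, the fraction of classified myocardial mass falling in
#' each flow-capacity class; fractions sum to one over classified voxels.
#'
#' @param capacity An `fpa_capacity` from [classify_capacity()].
#' @param labelmap An `fpa_labelmap`.
#' @param spacing Voxel spacing in mm (defaults to the label map's).
#'
#' @return Tibble: `territory`, `class`, `n_voxels`, `mass_g`, `fraction`.
#' @export
capacity_summary <- function(capacity, labelmap, spacing = labelmap$spacing) {
  stopifnot(inherits(capacity, "fpa_capacity"), inherits(labelmap, "fpa_labelmap"))
  if (!identical(dim(capacity$class_index), dim(labelmap$data)))
    abort("capacity map and label map are on different grids.")
  vv <- voxel_volume_ml(spacing)
  rows <- list()
  for (k in seq_along(labelmap$legend)) {
    idx <- labelmap$data == k
    ci <- capacity$class_index[idx]
    ci <- ci[!is.na(ci)]
    n_tot <- length(ci)
    counts <- tabulate(ci, nbins = length(capacity$legend))
    rows[[k]] <- tibble(
      territory = labelmap$legend[k],
      class = capacity$legend,
      n_voxels = counts,
      mass_g = MYOCARDIAL_DENSITY_G_PER_ML * counts * vv,
      fraction = if (n_tot > 0) counts / n_tot else rep(NA_real_, length(counts))
    )
  }
  dplyr::bind_rows(rows)
}
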