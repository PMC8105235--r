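#' Read and write volumes, masks and maps as NIfTI
#'
#' Volumes and maps are stored as float32 (NaN-preserving), masks as uint8
#' 0/1.  Voxel spacing travels in the NIfTI pixdim; acquisition metadata
#' (time, tube settings) is not representable in NIfTI and is supplied by
#' the caller on read.
#'
#' @param vol A [volume_scan()] (or 3D array for `write_map`).
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing in mm for bare arrays.
#' @param time_s,kvp,ma Acquisition metadata attached on read.
#' @param role Mask role tag on read.
#' @name nifti-io
NULL

#' @rdname nifti-io
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "fpa_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname nifti-io
#' @export
read_volume <- function(path, time_s = NA_real_, kvp = 100, ma = 200) {
  img <- RNifti::readNifti(path)
  volume_scan(array(as.numeric(img), dim(img)), RNifti::pixdim(img),
              time_s = time_s, kvp = kvp, ma = ma)
}

#' @rdname nifti-io
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "fpa_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname nifti-io
#' @export
read_mask <- function(path, role = "myocardium") {
  img <- RNifti::readNifti(path)
  vals <- unique(as.vector(img))
  if (!all(vals %in% c(0, 1)))
    abort(sprintf("mask file '%s' has values other than 0/1: %s.", path,
                  paste(head(setdiff(vals, c(0, 1)), 3), collapse = ", ")))
  binary_mask(array(as.vector(img) > 0, dim(img)), RNifti::pixdim(img), role)
}

#' @rdname nifti-io
#' @export
write_map <- function(map, path, spacing) {
  if (inherits(map, "fpa_perfusion")) { spacing <- map$spacing; map <- map$map }
  if (inherits(map, "fpa_cfr")) { spacing <- map$spacing; map <- map$map }
  img <- RNifti::asNifti(map)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname nifti-io
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  structure(list(map = array(as.numeric(img), dim(img)),
                 spacing = RNifti::pixdim(img)), class = "fpa_map")
}

#' Read / write labelled centerlines as JSON
#'
#' Schema: an array of objects `{"label": "LAD", "points_mm": [[x,y,z], ...],
#' "stenosis_arclength_mm": <optional>}`.
#'
#' @param centerlines List of [centerline()]s.
#' @param path JSON file path.
#' @return `read_centerlines()` returns a list of `fpa_centerline`s.
#' @export
write_centerlines <- function(centerlines, path) {
  if (inherits(centerlines, "fpa_centerline")) centerlines <- list(centerlines)
  payload <- lapply(centerlines, function(l) {
    out <- list(label = l$label, points_mm = l$points_mm)
    if (!is.null(l$stenosis_arclength_mm))
      out$stenosis_arclength_mm <- l$stenosis_arclength_mm
    out
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_centerlines
#' @export
read_centerlines <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(payload)) payload <- split(payload, seq_len(nrow(payload)))
  lapply(payload, function(l) {
    pts <- l$points_mm
    if (is.list(pts) && !is.matrix(pts)) pts <- do.call(rbind, pts)
    if (is.list(pts)) pts <- pts[[1]]
    sten <- l$stenosis_arclength_mm
    if (!is.null(sten) && (length(sten) == 0 || is.na(sten))) sten <- NULL
    centerline(l$label, pts, sten)
  })
}

#' Write a territory label map (NIfTI + JSON legend)
#'
#' @param labelmap An `fpa_labelmap`.
#' @param path NIfTI path for the uint8 label volume; the legend is written
#'   next to it as `<path without extension>_legend.json`.
#' @export
write_labelmap <- function(labelmap, path) {
  stopifnot(inherits(labelmap, "fpa_labelmap"))
  img <- RNifti::asNifti(array(as.integer(labelmap$data), dim(labelmap$data)))
  RNifti::pixdim(img) <- labelmap$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  legend_path <- sub("\\.nii(\\.gz)?$", "", path)
  jsonlite::write_json(as.list(stats::setNames(seq_along(labelmap$legend),
                                               labelmap$legend)),
                       paste0(legend_path, "_legend.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read / write a phantom spec as YAML
#'
#' @param spec An [phantom_spec()].
#' @param path YAML file path.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "fpa_phantom_spec"))
  lst <- unclass(spec)
  lst$flows_rest <- as.list(lst$flows_rest)
  lst$flows_stress <- as.list(lst$flows_stress)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$flows_rest <- unlist(lst$flows_rest)
  lst$flows_stress <- unlist(lst$flows_stress)
  do.call(phantom_spec, lst[intersect(names(lst), names(formals(phantom_spec)))])
}
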