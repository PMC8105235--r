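#' Coronary centerline
#'
#' An ordered 3D polyline in world mm describing one coronary vessel, with an
#' optional stenosis position given as arc length from the ostial end.
#'
#' @param label Vessel name, conventionally `"LAD"`, `"LCx"` or `"RCA"`.
#' @param points_mm Numeric matrix, one row per point, columns (x, y, z) mm.
#' @param stenosis_arclength_mm Optional stenosis arc length (mm from the
#'   first point); must lie within the polyline's total length.
#'
#' @return An object of class `fpa_centerline`.
#' @export
centerline <- function(label, points_mm, stenosis_arclength_mm = NULL) {
  points_mm <- as.matrix(points_mm)
  if (nrow(points_mm) < 2L || ncol(points_mm) != 3L)
    abort("a centerline needs >= 2 points with columns (x, y, z).")
  seglen <- sqrt(rowSums((points_mm[-1, , drop = FALSE] -
                          points_mm[-nrow(points_mm), , drop = FALSE])^2))
  if (any(seglen == 0)) abort("consecutive centerline points must be distinct.")
  total <- sum(seglen)
  if (!is.null(stenosis_arclength_mm)) {
    if (stenosis_arclength_mm < 0 || stenosis_arclength_mm > total)
      abort("stenosis arc length outside [0, total length].")
  }
  structure(list(label = label, points_mm = unname(points_mm),
                 stenosis_arclength_mm = stenosis_arclength_mm),
            class = "fpa_centerline")
}

#' @export
print.fpa_centerline <- function(x, ...) {
  cat(sprintf("<fpa_centerline> %s: %d points, %.1f mm%s\n", x$label,
              nrow(x$points_mm), centerline_length(x),
              if (is.null(x$stenosis_arclength_mm)) "" else
                sprintf(", stenosis at %.1f mm", x$stenosis_arclength_mm)))
  invisible(x)
}

#' Total arc length of a centerline in mm
#' @param line An [centerline()].
#' @export
centerline_length <- function(line) {
  p <- line$points_mm
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# Resample a polyline at <= `step` mm intervals; returns points and their
# cumulative arc lengths.
resample_polyline <- function(points_mm, step) {
  seg <- points_mm[-1, , drop = FALSE] - points_mm[-nrow(points_mm), , drop = FALSE]
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  s <- unique(c(seq(0, cum[length(cum)], by = step), cum[length(cum)]))
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i[i >= nrow(points_mm)] <- nrow(points_mm) - 1L
  f <- (s - cum[i]) / seglen[i]
  pts <- points_mm[i, , drop = FALSE] + seg[i, , drop = FALSE] * f
  list(points = pts, arclength = s)
}

# Map world-mm points to 1-based voxel indices on the grid (clamped).
points_to_voxels <- function(points_mm, dim3, spacing) {
  ijk <- sweep(points_mm, 2, spacing, "/")
  ijk <- round(ijk) + 1
  for (a in 1:3) ijk[, a] <- pmin(pmax(ijk[, a], 1), dim3[a])
  ijk
}

ijk_to_linear <- function(ijk, dim3) {
  as.integer((ijk[, 3] - 1) * dim3[1] * dim3[2] + (ijk[, 2] - 1) * dim3[1] +
             ijk[, 1])
}

linear_to_center_mm <- function(idx, dim3, spacing) {
  idx0 <- idx - 1
  x <- idx0 %% dim3[1]
  y <- (idx0 %/% dim3[1]) %% dim3[2]
  z <- idx0 %/% (dim3[1] * dim3[2])
  cbind(x * spacing[1], y * spacing[2], z * spacing[3])
}

# Rasterize a centerline: unique source voxels (linear, 1-based) with the
# arc length of the first sample that hit each voxel.
rasterize_centerline <- function(line, dim3, spacing) {
  rs <- resample_polyline(line$points_mm, min(spacing) / 2)
  ijk <- points_to_voxels(rs$points, dim3, spacing)
  lin <- ijk_to_linear(ijk, dim3)
  keep <- !duplicated(lin)
  list(linear = lin[keep], arclength = rs$arclength[keep])
}

# Straight-corridor voxels connecting point a_mm to b_mm (inclusive).
corridor_voxels <- function(a_mm, b_mm, dim3, spacing) {
  len <- sqrt(sum((b_mm - a_mm)^2))
  n <- max(2L, ceiling(len / (min(spacing) / 2)) + 1L)
  tfrac <- seq(0, 1, length.out = n)
  pts <- outer(tfrac, b_mm - a_mm) + rep(a_mm, each = n)
  unique(ijk_to_linear(points_to_voxels(pts, dim3, spacing), dim3))
}

# Geodesic domain = myocardium plus a straight corridor from every source
# voxel to its nearest myocardial voxel.  Returns the domain and per-vessel
# source voxels.
build_assignment_domain <- function(myo_idx, source_sets, dim3, spacing,
                                    reach_cap_mm) {
  domain <- logical(prod(dim3))
  domain[myo_idx] <- TRUE
  myo_mm <- linear_to_center_mm(myo_idx, dim3, spacing)
  for (nm in names(source_sets)) {
    src <- source_sets[[nm]]
    src_mm <- linear_to_center_mm(src, dim3, spacing)
    np <- nearest_point(src_mm, myo_mm)
    if (min(np$dist) > reach_cap_mm)
      abort(sprintf("centerline '%s' lies farther than %.1f mm from the myocardium.",
                    nm, reach_cap_mm))
    outside <- which(!domain[src])
    for (i in outside) {
      corr <- corridor_voxels(src_mm[i, ], myo_mm[np$index[i], ], dim3, spacing)
      domain[corr] <- TRUE
    }
    domain[src] <- TRUE
  }
  domain
}

# Shared labelling engine: geodesic distance per source set over `domain`,
# argmin label with ties to the earlier set; straight-line fallback (with a
# warning) for voxels unreachable through the domain.
label_by_geodesics <- function(target_idx, source_sets, domain, dim3, spacing) {
  K <- length(source_sets)
  dmat <- matrix(Inf, nrow = length(target_idx), ncol = K)
  for (k in seq_len(K)) {
    dk <- grid_geodesic_dist(as.integer(dim3), spacing, domain,
                             as.integer(source_sets[[k]] - 1L))
    dmat[, k] <- dk[target_idx]
  }
  lab <- max.col(-dmat, ties.method = "first")
  unreach <- !is.finite(dmat[cbind(seq_along(target_idx), lab)])
  if (any(unreach)) {
    warn(sprintf("%d myocardial voxel(s) unreachable through the domain; assigned by straight-line distance.",
                 sum(unreach)))
    tgt_mm <- linear_to_center_mm(target_idx[unreach], dim3, spacing)
    dstraight <- matrix(Inf, nrow = nrow(tgt_mm), ncol = K)
    for (k in seq_len(K)) {
      src_mm <- linear_to_center_mm(source_sets[[k]], dim3, spacing)
      dstraight[, k] <- nearest_point(tgt_mm, src_mm)$dist
    }
    lab[unreach] <- max.col(-dstraight, ties.method = "first")
  }
  lab
}

#' Assign myocardial voxels to coronary territories
#'
#' Each centerline is rasterized to voxel sources and every myocardial voxel
#' takes the label of the vessel reachable at least geodesic cost.  Paths run
#' on the 26-connected voxel graph restricted to the myocardium plus a
#' straight corridor joining each source to its nearest myocardial voxel;
#' edge weights are Euclidean distances between voxel centers in mm.  Ties
#' break by the fixed vessel order LAD < LCx < RCA (otherwise input order).
#'
#' @param myo Myocardium [binary_mask()].
#' @param centerlines List of [centerline()]s (>= 1, unique labels).
#' @param spacing Voxel spacing in mm (defaults to the mask's).
#' @param reach_cap_mm Error if a centerline's nearest approach to the
#'   myocardium exceeds this distance (mm).
#'
#' @return An `fpa_labelmap`: integer array (`0` outside the myocardium,
#'   `1..K` territory labels) plus a `legend` mapping labels to vessel names.
#' @export
assign_territories <- function(myo, centerlines, spacing = myo$spacing,
                               reach_cap_mm = 10) {
  stopifnot(inherits(myo, "fpa_mask"))
  if (inherits(centerlines, "fpa_centerline")) centerlines <- list(centerlines)
  if (length(centerlines) < 1L) abort("need at least one centerline.")
  labels <- vapply(centerlines, function(l) l$label, character(1))
  if (anyDuplicated(labels)) abort("centerline labels must be unique.")
  canonical <- c("LAD", "LCx", "RCA")
  ord <- order(match(labels, canonical, nomatch = length(canonical) + 1),
               seq_along(labels))
  centerlines <- centerlines[ord]; labels <- labels[ord]
  if (!any(myo$data)) abort("myocardium mask is empty.")

  dim3 <- dim(myo$data)
  myo_idx <- which(myo$data)
  source_sets <- lapply(centerlines, function(l)
    rasterize_centerline(l, dim3, spacing)$linear)
  names(source_sets) <- labels
  domain <- build_assignment_domain(myo_idx, source_sets, dim3, spacing,
                                    reach_cap_mm)
  lab <- label_by_geodesics(myo_idx, source_sets, domain, dim3, spacing)

  data <- array(0L, dim3)
  data[myo_idx] <- lab
  structure(list(data = data, legend = labels, spacing = spacing),
            class = "fpa_labelmap")
}

#' @export
print.fpa_labelmap <- function(x, ...) {
  counts <- tabulate(x$data[x$data > 0], nbins = length(x$legend))
  cat("<fpa_labelmap>\n")
  for (k in seq_along(x$legend))
    cat(sprintf("  %d = %-14s %d voxels\n", k, x$legend[k], counts[k]))
  invisible(x)
}

#' Split a vessel territory at a stenosis
#'
#' Source points of the marked vessel are divided at the stenosis arc length
#' into proximal and distal subsets; voxels previously labelled to that
#' vessel are re-assigned by minimum-cost path to the nearer subset, yielding
#' `"<vessel>-proximal"` and `"<vessel>-distal"` labels.  Other territories
#' are untouched.
#'
#' @param labelmap An `fpa_labelmap` from [assign_territories()].
#' @param line The vessel's [centerline()] with `stenosis_arclength_mm` set.
#' @param myo Myocardium [binary_mask()] on the same grid.
#'
#' @return A new `fpa_labelmap` with the vessel split into two labels.
#' @export
partition_distal <- function(labelmap, line, myo) {
  stopifnot(inherits(labelmap, "fpa_labelmap"), inherits(line, "fpa_centerline"))
  s <- line$stenosis_arclength_mm
  if (is.null(s)) abort("centerline has no stenosis marker.")
  total <- centerline_length(line)
  if (s <= 0 || s >= total)
    abort("degenerate partition: stenosis marker at 0 or full length.")
  k <- match(line$label, labelmap$legend)
  if (is.na(k)) abort(sprintf("vessel '%s' not present in the legend.", line$label))

  dim3 <- dim(labelmap$data)
  spacing <- labelmap$spacing
  ras <- rasterize_centerline(line, dim3, spacing)
  prox <- ras$linear[ras$arclength <= s]
  dist <- ras$linear[ras$arclength > s]
  if (length(prox) == 0L || length(dist) == 0L)
    abort("degenerate partition: a stenosis subset has no source voxels.")

  vessel_idx <- which(labelmap$data == k)
  if (length(vessel_idx) == 0L) abort("vessel territory is empty.")
  sets <- list(prox, dist)
  names(sets) <- paste0(line$label, c("-proximal", "-distal"))
  domain <- build_assignment_domain(vessel_idx, sets, dim3, spacing,
                                    reach_cap_mm = Inf)
  sub <- label_by_geodesics(vessel_idx, sets, domain, dim3, spacing)

  data <- labelmap$data
  newk <- length(labelmap$legend) + 1L
  data[vessel_idx[sub == 2L]] <- newk
  legend <- labelmap$legend
  legend[k] <- names(sets)[1]
  legend <- c(legend, names(sets)[2])
  structure(list(data = data, legend = legend, spacing = spacing),
            class = "fpa_labelmap")
}

#' Per-territory statistics of a perfusion or CFR map
#'
#' @param values 3D numeric array (NA/NaN = undefined voxels, excluded from
#'   mean/SD but counted in territory mass).
#' @param labelmap An `fpa_labelmap`.
#' @param spacing Voxel spacing in mm (defaults to the label map's).
#'
#' @return Tibble with one row per territory: `territory`, `label`,
#'   `n_voxels`, `n_defined`, `mass_g`, `mean`, `sd`.
#' @export
territory_stats <- function(values, labelmap, spacing = labelmap$spacing) {
  stopifnot(inherits(labelmap, "fpa_labelmap"))
  if (inherits(values, "fpa_volume")) values <- values$data
  if (!identical(dim(values), dim(labelmap$data)))
    abort("value map and label map are on different grids.")
  vv <- voxel_volume_ml(spacing)
  rows <- lapply(seq_along(labelmap$legend), function(k) {
    idx <- labelmap$data == k
    n <- sum(idx)
    if (n == 0L) {
      warn(sprintf("territory '%s' is empty; statistics undefined.",
                   labelmap$legend[k]))
      return(tibble(territory = labelmap$legend[k], label = k, n_voxels = 0L,
                    n_defined = 0L, mass_g = 0,
                    mean = NA_real_, sd = NA_real_))
    }
    x <- values[idx]
    xd <- x[is.finite(x)]
    tibble(territory = labelmap$legend[k], label = k, n_voxels = n,
           n_defined = length(xd),
           mass_g = MYOCARDIAL_DENSITY_G_PER_ML * n * vv,
           mean = if (length(xd)) mean(xd) else NA_real_,
           sd = if (length(xd) > 1) sd(xd) else NA_real_)
  })
  dplyr::bind_rows(rows)
}
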