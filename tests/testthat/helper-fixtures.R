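# Shared in-code fixtures: tiny volumes, slab masks and phantom specs.

uniform_volume <- function(value, dim3 = c(8, 8, 8), spacing = c(1, 1, 1),
                           time_s = 0, ma = 200) {
  volume_scan(array(value, dim3), spacing, time_s = time_s, ma = ma)
}

slab_mask <- function(dim3 = c(8, 8, 8), spacing = c(1, 1, 1),
                      role = "myocardium", where = TRUE) {
  m <- array(FALSE, dim3)
  m[where] <- TRUE
  if (isTRUE(where)) m[] <- TRUE
  binary_mask(m, spacing, role)
}

# A small phantom spec that keeps unit tests quick.
small_spec <- function(dim = c(32, 32, 32), ...) {
  default_swine_spec(dim = dim, ...)
}

# Straight centerline along +z at (x, y), from z0 to z1 (world mm).
straight_line <- function(label, x, y, z0, z1, n = 25) {
  centerline(label, cbind(rep(x, n), rep(y, n), seq(z0, z1, length.out = n)))
}

# Independent geodesic-labelling oracle: per-voxel multi-source Dijkstra via
# igraph on an explicitly built 26-connected graph over `domain`.
igraph_label_oracle <- function(domain, spacing, source_sets) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  d <- dim(domain)
  vox <- which(domain)
  id <- array(NA_integer_, d)
  id[vox] <- seq_along(vox)
  coords <- arrayInd(vox, d)
  edges <- NULL; weights <- NULL
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    nb <- sweep(coords, 2, o, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    from <- id[vox[ok]]
    to <- id[nb[ok, , drop = FALSE]]
    keep <- !is.na(to)
    edges <- rbind(edges, cbind(from[keep], to[keep]))
    weights <- c(weights, rep(sqrt(sum((o * spacing)^2)), sum(keep)))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = weights)
  dmat <- sapply(source_sets, function(src) {
    sid <- id[src]
    sid <- sid[!is.na(sid)]
    dd <- igraph::distances(g, v = sid, weights = igraph::E(g)$weight)
    apply(dd, 2, min)
  })
  list(label = max.col(-dmat, ties.method = "first"), dist = dmat,
       voxels = vox)
}
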