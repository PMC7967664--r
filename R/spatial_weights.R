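#' Binary contiguity spatial weights
#'
#' The weight matrix used throughout is binary (1 if two units are adjacent,
#' 0 otherwise), symmetric, with a zero diagonal. It is deliberately *not*
#' row-standardized by default, matching the cross-product form of the global
#' and local Moran statistics; `row_standardize()` is available where a
#' stochastic matrix is wanted.
#'
#' @param W square numeric matrix with entries in {0,1}.
#' @param ids character vector of unit ids (defaults to W's dimnames).
#' @param islands ids that had zero row-sum before any repair (bookkeeping).
#' @param check if `TRUE`, enforce symmetry, zero diagonal, binary entries,
#'   and S0 > 0 for n >= 2.
#' @return a `spatial_weights` object with fields `n`, `W`, `S0`, `ids`,
#'   `islands`.
#' @export
spatial_weights <- function(W, ids = rownames(W), islands = character(),
                            check = TRUE) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (check) {
    if (ncol(W) != n) stop2("W must be square")
    if (length(ids) != n) stop2("ids length must match W")
    if (!all(W %in% c(0, 1))) stop2("W entries must be 0 or 1")
    if (any(diag(W) != 0)) stop2("W must have a zero diagonal")
    if (!isTRUE(all.equal(W, t(W)))) stop2("W must be symmetric")
    if (n >= 2 && sum(W) == 0)
      stop2("all units are islands (S0 = 0); supply adjacency or enable repair")
  }
  dimnames(W) <- list(ids, ids)
  structure(list(n = n, W = W, S0 = sum(W), ids = as.character(ids),
                 islands = as.character(islands)),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights> n = %d, S0 = %g, links = %d, islands = %d\n",
              x$n, x$S0, sum(x$W) / 2, length(x$islands)))
  invisible(x)
}

#' Build weights from an explicit adjacency pair list
#'
#' @param pairs two-column matrix or data.frame of unit id pairs; the
#'   symmetric closure is applied, so each link need be listed once.
#'   Self-pairs are ignored with a warning.
#' @param units ordered character vector of all unit ids.
#' @param repair if `TRUE`, link zero-neighbour units to their nearest
#'   other unit using `coords` (see [repair_islands()]).
#' @param coords optional n x 2 coordinate matrix, required when `repair`.
#' @return a [spatial_weights()] object.
#' @export
weights_from_adjacency <- function(pairs, units, repair = FALSE,
                                   coords = NULL) {
  units <- as.character(units)
  n <- length(units)
  pairs <- as.matrix(pairs)
  if (nrow(pairs) > 0L && ncol(pairs) != 2L)
    stop2("pairs must have two columns")
  W <- matrix(0, n, n, dimnames = list(units, units))
  if (nrow(pairs) > 0L) {
    a <- as.character(pairs[, 1]); b <- as.character(pairs[, 2])
    unknown <- setdiff(c(a, b), units)
    if (length(unknown))
      stop2("unknown unit(s) in pairs: ", paste(unique(unknown), collapse = ", "))
    self <- a == b
    if (any(self)) {
      warn2("ignored ", sum(self), " self-pair(s)")
      a <- a[!self]; b <- b[!self]
    }
    W[cbind(a, b)] <- 1
    W[cbind(b, a)] <- 1
  }
  islands <- units[rowSums(W) == 0]
  if (repair) {
    if (is.null(coords)) stop2("repair requires coords")
    return(repair_islands(spatial_weights(W, units, islands, check = FALSE),
                          coords))
  }
  spatial_weights(W, units, islands)
}

#' Link islands to their nearest neighbour
#'
#' Units with no neighbours (zero row-sum) are linked, symmetrically, to the
#' nearest other unit by Euclidean centroid distance. The pre-repair island
#' list is preserved on the result for reporting.
#'
#' @param w a [spatial_weights()] object (possibly unfinalized).
#' @param coords n x 2 matrix of planar unit coordinates (km), ordered as
#'   `w$ids`.
#' @return repaired [spatial_weights()]; unchanged input if no islands.
#' @export
repair_islands <- function(w, coords) {
  coords <- as.matrix(coords)
  if (w$n < 2) stop2("need at least two units to repair islands")
  if (nrow(coords) != w$n) stop2("coords must have one row per unit")
  isl <- which(rowSums(w$W) == 0)
  if (!length(isl)) return(w)
  W <- w$W
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  for (i in isl) {
    j <- which.min(D[i, ])
    W[i, j] <- W[j, i] <- 1
  }
  spatial_weights(W, w$ids, islands = w$ids[isl])
}

#' Row-standardize a weight matrix
#' @param w a [spatial_weights()] object.
#' @return plain numeric matrix with rows summing to 1 (islands keep zeros).
#' @export
row_standardize <- function(w) {
  rs <- rowSums(w$W)
  rs[rs == 0] <- 1
  w$W / rs
}

# ---- polygon support --------------------------------------------------------

#' Read unit polygons from a GeoJSON FeatureCollection
#'
#' Supports Polygon and MultiPolygon geometries; only outer rings are used
#' for contiguity. Coordinates are taken as planar (pre-projected, km).
#'
#' @param path GeoJSON file.
#' @param id_field property holding the unit id (default `"id"`; falls back
#'   to the feature's top-level `id`, then to the feature index).
#' @return a `unit_polygons` object: list of `ids` and `rings` (per unit, a
#'   list of 2-column coordinate matrices).
#' @export
read_geojson_polygons <- function(path, id_field = "id") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop2("expected a GeoJSON FeatureCollection")
  ids <- character(); rings <- list()
  for (k in seq_along(gj$features)) {
    ft <- gj$features[[k]]
    id <- ft$properties[[id_field]] %||% ft$id %||% as.character(k)
    geom <- ft$geometry
    ring_list <- switch(geom$type,
      Polygon = list(geom$coordinates[[1]]),
      MultiPolygon = lapply(geom$coordinates, function(p) p[[1]]),
      stop2("unsupported geometry type for unit ", id, ": ", geom$type))
    mats <- lapply(ring_list, function(r)
      do.call(rbind, lapply(r, function(pt) as.numeric(unlist(pt))[1:2])))
    ids <- c(ids, as.character(id))
    rings[[length(rings) + 1L]] <- mats
  }
  unit_polygons(ids, rings)
}

#' Construct a unit polygon set
#' @param ids unit ids.
#' @param rings per unit, a list of closed outer rings (2-column matrices).
#' @return a `unit_polygons` object.
#' @export
unit_polygons <- function(ids, rings) {
  ids <- as.character(ids)
  if (length(ids) != length(rings)) stop2("ids and rings lengths differ")
  for (k in seq_along(rings)) {
    for (r in rings[[k]]) {
      if (!is.matrix(r) || ncol(r) != 2 || nrow(r) < 3 || !all(is.finite(r)))
        stop2("invalid geometry for unit ", ids[k])
    }
  }
  structure(list(ids = ids, rings = rings), class = "unit_polygons")
}

poly_vertices <- function(rings, digits = 8) {
  # rounded vertex keys of all outer rings of one unit
  pts <- do.call(rbind, rings)
  unique(paste(round(pts[, 1], digits), round(pts[, 2], digits)))
}

poly_edges <- function(rings, digits = 8) {
  # undirected edge keys (sorted endpoint pair) of all outer rings
  out <- character()
  for (r in rings) {
    a <- r
    # ensure closure
    if (!all(r[1, ] == r[nrow(r), ])) a <- rbind(r, r[1, ])
    v <- paste(round(a[, 1], digits), round(a[, 2], digits))
    e <- vapply(seq_len(length(v) - 1L), function(i) {
      p <- sort(c(v[i], v[i + 1L])); paste(p, collapse = "|")
    }, character(1))
    out <- c(out, e)
  }
  unique(out)
}

#' Build contiguity weights from unit polygons
#'
#' Queen contiguity links units sharing at least one boundary point; rook
#' contiguity requires a shared edge segment. Boundaries must be
#' topologically clean (neighbouring polygons share identical vertices),
#' as is the case for lattice fixtures and typical cleaned administrative
#' layers; vertices are matched after rounding to `digits` decimals.
#'
#' @param geoms a `unit_polygons` object (see [read_geojson_polygons()]).
#' @param rule `"queen"` (default) or `"rook"`.
#' @param digits coordinate rounding used for vertex matching.
#' @param repair,coords island repair as in [weights_from_adjacency()].
#' @return a [spatial_weights()] object.
#' @export
weights_from_polygons <- function(geoms, rule = c("queen", "rook"),
                                  digits = 8, repair = FALSE, coords = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(geoms, "unit_polygons"))
  n <- length(geoms$ids)
  if (n == 0L) stop2("empty geometry set")
  keys <- if (rule == "queen")
    lapply(geoms$rings, poly_vertices, digits = digits)
  else
    lapply(geoms$rings, poly_edges, digits = digits)
  W <- matrix(0, n, n)
  # invert: map key -> unit indices, then mark co-occurring pairs
  idx <- rep(seq_len(n), lengths(keys))
  sp <- split(idx, unlist(keys))
  for (u in sp) {
    u <- unique(u)
    if (length(u) > 1L) W[t(utils::combn(u, 2))] <- 1
  }
  W <- pmax(W, t(W))
  islands <- geoms$ids[rowSums(W) == 0]
  if (repair) {
    if (is.null(coords)) coords <- t(vapply(geoms$rings, function(rs) {
      pts <- do.call(rbind, rs); colMeans(pts)
    }, numeric(2)))
    return(repair_islands(spatial_weights(W, geoms$ids, islands,
                                          check = FALSE), coords))
  }
  spatial_weights(W, geoms$ids, islands)
}

#' Export weights as a sparse triplet table
#' @param w a [spatial_weights()] object.
#' @param path optional CSV path; when given the table is also written.
#' @return data.frame with columns `unit_a`, `unit_b`, `weight` (upper
#'   triangle only).
#' @export
weights_to_triplets <- function(w, path = NULL) {
  up <- which(upper.tri(w$W) & w$W != 0, arr.ind = TRUE)
  df <- data.frame(unit_a = w$ids[up[, 1]], unit_b = w$ids[up[, 2]],
                   weight = w$W[up], stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
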