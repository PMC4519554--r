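#' Construct a land unit
#'
#' A land unit (LU) is the minimal spatial unit of analysis: a
#' (possibly multi-part) polygon in projected meters carrying sampled
#' subjects. The centroid defaults to the area-weighted polygon
#' centroid. Units assembled from several postal areas may carry
#' sub-centroids used to stabilize surface interpolation.
#'
#' @param unit_id identifier (coerced to character).
#' @param polygon two-column vertex matrix, or list of such matrices
#'   for multi-part units; coordinates in projected meters.
#' @param name display name (defaults to the id).
#' @param centroid optional (x, y) override.
#' @param sub_centroids optional matrix of (x, y) points, one per
#'   constituent postal area.
#' @param n_samples sample count carried by the unit.
#' @return object of class \code{land_unit}.
#' @export
land_unit <- function(unit_id, polygon, name = as.character(unit_id),
                      centroid = NULL, sub_centroids = NULL,
                      n_samples = 0L) {
  poly <- as_polygon(polygon)
  if (polygon_area(poly) <= 0) stop("land unit polygon has zero area")
  if (is.null(centroid)) centroid <- polygon_centroid(poly)
  centroid <- as.numeric(centroid)
  if (length(centroid) != 2L) stop("centroid must be (x, y)")
  if (!is.null(sub_centroids)) {
    sub_centroids <- as.matrix(sub_centroids)
    if (ncol(sub_centroids) != 2L) stop("sub_centroids must be (x, y) rows")
  }
  structure(list(unit_id = as.character(unit_id), name = name,
                 polygon = poly, centroid = centroid,
                 sub_centroids = sub_centroids,
                 n_samples = as.integer(n_samples)),
            class = "land_unit")
}

#' Construct a region set
#'
#' @param units list of [land_unit()] objects with unique ids.
#' @param adjacency optional named list of neighbor id vectors (made
#'   symmetric); usually built by [build_contiguity()].
#' @return object of class \code{region_set}.
#' @export
region_set <- function(units, adjacency = NULL) {
  ids <- vapply(units, function(u) u$unit_id, "")
  if (anyDuplicated(ids)) stop("unit ids must be unique")
  names(units) <- ids
  rs <- structure(list(units = units, adjacency = NULL,
                       isolates = character(0)),
                  class = "region_set")
  if (!is.null(adjacency)) rs$adjacency <- symmetrize_adjacency(adjacency, ids)
  rs
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d land units", length(x$units)))
  if (!is.null(x$adjacency)) {
    cat(sprintf(", %d contiguity edges",
                sum(lengths(x$adjacency)) / 2))
  }
  if (length(x$isolates)) {
    cat(sprintf(", isolates: %s", paste(x$isolates, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Unit ids of a region set
#'
#' @param region a \code{region_set}.
#' @return character vector of unit ids, in storage order.
#' @export
unit_ids <- function(region) {
  unname(vapply(region$units, function(u) u$unit_id, ""))
}

region_centroids <- function(region) {
  t(vapply(region$units, function(u) u$centroid, c(0, 0)))
}

symmetrize_adjacency <- function(adj, ids) {
  out <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) out[[id]] <- character(0)
  for (id in names(adj)) {
    if (!id %in% ids) stop("adjacency refers to unknown unit: ", id)
    for (nb in adj[[id]]) {
      if (!nb %in% ids) stop("adjacency refers to unknown unit: ", nb)
      if (nb == id) next
      out[[id]] <- union(out[[id]], nb)
      out[[nb]] <- union(out[[nb]], id)
    }
  }
  out
}

#' Aggregate sparsely sampled land units
#'
#' Merges each mapped unit into its target unit: polygons are combined
#' into a multi-part geometry, sample counts add, sub-centroids are
#' concatenated, and the merged unit keeps the target's id and name
#' (the location accounting for the largest number of samples). The
#' returned region has no adjacency (rebuild with
#' [build_contiguity()]).
#'
#' @param region a \code{region_set}.
#' @param mapping named character vector: names are the units to
#'   dissolve, values their targets. Chained mappings (a target being
#'   itself mapped) are rejected.
#' @return a new \code{region_set}; the mapping used is attached as
#'   attribute \code{"mapping"} for remapping subject memberships (see
#'   [remap_membership()]).
#' @export
aggregate_units <- function(region, mapping) {
  stopifnot(inherits(region, "region_set"))
  ids <- unit_ids(region)
  if (length(mapping) == 0L) return(region)
  src <- names(mapping)
  tgt <- unname(mapping)
  if (is.null(src)) stop("mapping must be a named vector (source -> target)")
  unknown <- setdiff(c(src, tgt), ids)
  if (length(unknown)) stop("mapping refers to unknown units: ",
                            paste(unknown, collapse = ", "))
  if (any(tgt %in% src)) stop("chained mapping: a target is itself mapped")
  if (anyDuplicated(src)) stop("a unit cannot be mapped twice")
  units <- region$units
  for (k in seq_along(src)) {
    from <- units[[src[k]]]
    to <- units[[tgt[k]]]
    to$polygon <- c(to$polygon, from$polygon)
    to$n_samples <- to$n_samples + from$n_samples
    to$centroid <- polygon_centroid(to$polygon)
    if (!is.null(from$sub_centroids) || !is.null(to$sub_centroids)) {
      to$sub_centroids <- rbind(to$sub_centroids, from$sub_centroids)
    }
    units[[tgt[k]]] <- to
    units[[src[k]]] <- NULL
  }
  out <- region_set(unname(units))
  attr(out, "mapping") <- mapping
  out
}

#' Remap subject membership after unit aggregation
#'
#' @param subjects data.frame with a \code{unit_id} column.
#' @param mapping the aggregation mapping (source -> target).
#' @return subjects with \code{unit_id} rewritten.
#' @export
remap_membership <- function(subjects, mapping) {
  hit <- subjects$unit_id %in% names(mapping)
  subjects$unit_id[hit] <- unname(mapping[subjects$unit_id[hit]])
  subjects
}

#' Thiessen (Voronoi) partition of a bounding region
#'
#' Tiles the bounding region into one polygon per generating centroid,
#' each the locus of points nearer to its centroid than to any other.
#' Cells are computed by successive half-plane clipping of the
#' bounding polygon with the perpendicular bisectors.
#'
#' @param centroids two-column matrix of distinct generator points.
#' @param bounding_region polygon (single ring) containing all
#'   centroids.
#' @return list of polygons (each a list of rings), one per centroid,
#'   in input order.
#' @export
voronoi_partition <- function(centroids, bounding_region) {
  centroids <- as.matrix(centroids)
  if (ncol(centroids) != 2L) stop("centroids must be (x, y) rows")
  k <- nrow(centroids)
  if (k < 1L) stop("at least one centroid required")
  d <- as.matrix(stats::dist(centroids))
  diag(d) <- Inf
  if (k > 1L && min(d) < 1e-9) stop("duplicate centroids")
  bound <- as_polygon(bounding_region)
  if (length(bound) != 1L) stop("bounding region must be a single ring")
  for (i in seq_len(k)) {
    if (!point_in_ring(centroids[i, ], bound[[1L]])) {
      stop("centroid ", i, " lies outside the bounding region")
    }
  }
  cells <- vector("list", k)
  for (i in seq_len(k)) {
    ring <- bound[[1L]]
    for (j in seq_len(k)) {
      if (j == i || is.null(ring)) next
      # half-plane of points nearer to centroid i than j:
      # (p - m) . (cj - ci) <= 0
      a <- centroids[j, ] - centroids[i, ]
      m <- (centroids[i, ] + centroids[j, ]) / 2
      ring <- clip_ring_halfplane(ring, a, sum(a * m))
    }
    if (is.null(ring)) stop("empty Voronoi cell for centroid ", i)
    cells[[i]] <- list(ring)
  }
  cells
}

#' Build a contiguity net over land units
#'
#' Queen-style contiguity: two units are neighbors when their
#' boundaries come within \code{snap_tolerance} of each other (any
#' shared boundary point counts). Units left without neighbors are
#' connected to their nearest unit when its border lies within
#' \code{connect_threshold}; explicit \code{connect_pairs} are always
#' inserted. Units farther than \code{drop_threshold} from every other
#' unit (and any unit still neighbor-less) are recorded as isolates
#' and excluded from the spatial weights.
#'
#' @param region a \code{region_set}.
#' @param connect_pairs optional 2-column matrix / list of id pairs to
#'   connect regardless of geometry.
#' @param connect_threshold meters (default 5000).
#' @param drop_threshold meters (default 10000).
#' @param snap_tolerance meters (default 1), absorbs digitization noise.
#' @return the region with \code{adjacency} and \code{isolates} filled.
#' @export
build_contiguity <- function(region, connect_pairs = NULL,
                             connect_threshold = 5000,
                             drop_threshold = 10000,
                             snap_tolerance = 1) {
  stopifnot(inherits(region, "region_set"))
  ids <- unit_ids(region)
  n <- length(ids)
  dmat <- matrix(Inf, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      dij <- polygon_boundary_distance(region$units[[i]]$polygon,
                                       region$units[[j]]$polygon)
      dmat[i, j] <- dmat[j, i] <- dij
    }
  }
  adj <- stats::setNames(lapply(ids, function(i) character(0)), ids)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (dmat[i, j] <= snap_tolerance) {
        adj[[i]] <- c(adj[[i]], ids[j])
        adj[[j]] <- c(adj[[j]], ids[i])
      }
    }
  }
  if (!is.null(connect_pairs)) {
    if (is.list(connect_pairs) && !is.data.frame(connect_pairs)) {
      connect_pairs <- do.call(rbind, connect_pairs)
    }
    connect_pairs <- as.matrix(connect_pairs)
    for (k in seq_len(nrow(connect_pairs))) {
      a <- as.character(connect_pairs[k, 1L])
      b <- as.character(connect_pairs[k, 2L])
      if (!a %in% ids || !b %in% ids) {
        stop("connect pair refers to unknown unit: ", a, "-", b)
      }
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  # auto-connect near isolates within the connect threshold
  for (i in seq_len(n)) {
    if (length(adj[[i]]) > 0L) next
    nearest <- which.min(dmat[i, ])
    if (dmat[i, nearest] <= connect_threshold) {
      adj[[i]] <- union(adj[[i]], ids[nearest])
      adj[[nearest]] <- union(adj[[nearest]], ids[i])
      message("connected isolate ", ids[i], " to nearest unit ",
              ids[nearest], sprintf(" (%.0f m)", dmat[i, nearest]))
    }
  }
  isolates <- ids[lengths(adj) == 0L]
  for (id in isolates) {
    message("unit ", id, " has no neighbor within reach; excluded as isolate")
  }
  region$adjacency <- lapply(adj, sort)
  region$isolates <- isolates
  region
}

#' Binary spatial weights from a contiguity net
#'
#' Encodes the adjacency of the non-isolate units as a symmetric 0/1
#' weight matrix (weight of unity for neighbors, zero otherwise; no
#' row standardization) together with the Cliff-Ord sums S0, S1 and S2
#' used in Moran variance formulas.
#'
#' @param region a \code{region_set} with adjacency built, or a square
#'   symmetric 0/1 matrix with unit ids as dimnames.
#' @return object of class \code{spatial_weights}: \code{ids},
#'   \code{W}, \code{S0}, \code{S1}, \code{S2}.
#' @export
binary_weights <- function(region) {
  if (is.matrix(region)) return(spatial_weights(region))
  stopifnot(inherits(region, "region_set"))
  if (is.null(region$adjacency)) stop("build contiguity first")
  keep <- setdiff(unit_ids(region), region$isolates)
  if (length(keep) < 2L) stop("fewer than two connected units")
  W <- matrix(0, length(keep), length(keep), dimnames = list(keep, keep))
  for (id in keep) {
    nbs <- intersect(region$adjacency[[id]], keep)
    W[id, nbs] <- 1
  }
  if (sum(W) == 0) stop("all units isolated: empty adjacency")
  spatial_weights(W)
}

#' Construct spatial weights from a matrix
#'
#' @param W square symmetric matrix, zero diagonal, binary entries.
#' @param ids unit ids (default dimnames or 1..n).
#' @return object of class \code{spatial_weights}.
#' @export
spatial_weights <- function(W, ids = rownames(W)) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  if (any(W != t(W))) stop("weight matrix must be symmetric")
  if (any(diag(W) != 0)) stop("weight matrix must have zero diagonal")
  if (!all(W %in% c(0, 1))) stop("weights must be binary 0/1")
  if (sum(W) == 0) stop("weight matrix has no nonzero entry")
  if (is.null(ids)) ids <- as.character(seq_len(nrow(W)))
  dimnames(W) <- list(ids, ids)
  S0 <- sum(W)
  S1 <- sum((W + t(W))^2) / 2
  S2 <- sum((rowSums(W) + colSums(W))^2)
  structure(list(ids = ids, W = W, S0 = S0, S1 = S1, S2 = S2),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d units, S0 = %g, S1 = %g, S2 = %g\n",
              length(x$ids), x$S0, x$S1, x$S2))
  invisible(x)
}

#' Export adjacency as an edge list
#'
#' @param region a \code{region_set} with adjacency.
#' @param path optional CSV path; when given the edge list is written.
#' @return data.frame with columns \code{unit_i}, \code{unit_j}
#'   (each undirected edge once).
#' @export
adjacency_edges <- function(region, path = NULL) {
  stopifnot(inherits(region, "region_set"))
  if (is.null(region$adjacency)) stop("build contiguity first")
  edges <- do.call(rbind, lapply(names(region$adjacency), function(i) {
    js <- region$adjacency[[i]]
    js <- js[js > i]
    if (length(js)) data.frame(unit_i = i, unit_j = js,
                               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) edges <- data.frame(unit_i = character(0),
                                          unit_j = character(0))
  if (!is.null(path)) utils::write.csv(edges, path, row.names = FALSE)
  edges
}

#' Write a spatial weight matrix as dense CSV
#'
#' @param w a \code{spatial_weights} object.
#' @param path CSV path.
#' @export
write_weights_csv <- function(w, path) {
  stopifnot(inherits(w, "spatial_weights"))
  utils::write.csv(as.data.frame(w$W), path, row.names = TRUE)
  invisible(path)
}

#' Read a spatial weight matrix from dense CSV
#'
#' @param path CSV path as written by [write_weights_csv()].
#' @return a \code{spatial_weights} object.
#' @export
read_weights_csv <- function(path) {
  tab <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  spatial_weights(as.matrix(tab))
}

#' Read land units from a GeoJSON FeatureCollection
#'
#' Supports Polygon and MultiPolygon features with properties
#' \code{unit_id} and \code{name}; coordinates must already be in
#' projected meters (holes are not supported and are dropped with a
#' warning).
#'
#' @param path GeoJSON file path.
#' @return a \code{region_set}.
#' @export
read_region_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection")
  }
  units <- lapply(gj$features, function(f) {
    geom <- f$geometry
    props <- f$properties
    ring_from <- function(coords) {
      m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
      ring_matrix(m)
    }
    rings <- switch(geom$type,
      Polygon = {
        if (length(geom$coordinates) > 1L) {
          warning("polygon holes are not supported; outer ring kept")
        }
        list(ring_from(geom$coordinates[[1L]]))
      },
      MultiPolygon = lapply(geom$coordinates, function(pg) {
        if (length(pg) > 1L) warning("polygon holes dropped")
        ring_from(pg[[1L]])
      }),
      stop("unsupported geometry type: ", geom$type))
    land_unit(unit_id = props$unit_id,
              name = if (!is.null(props$name)) props$name else
                as.character(props$unit_id),
              polygon = rings,
              n_samples = if (!is.null(props$n_samples))
                props$n_samples else 0L)
  })
  region_set(units)
}

#' Write land units as GeoJSON
#'
#' @param region a \code{region_set}.
#' @param path output path.
#' @export
write_region_geojson <- function(region, path) {
  stopifnot(inherits(region, "region_set"))
  feats <- lapply(region$units, function(u) {
    close_ring <- function(r) {
      r <- rbind(r, r[1L, ])
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1L], r[i, 2L]))
    }
    geom <- if (length(u$polygon) == 1L) {
      list(type = "Polygon", coordinates = list(close_ring(u$polygon[[1L]])))
    } else {
      list(type = "MultiPolygon",
           coordinates = lapply(u$polygon, function(r) list(close_ring(r))))
    }
    list(type = "Feature",
         properties = list(unit_id = u$unit_id, name = u$name,
                           n_samples = u$n_samples),
         geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection",
                            features = unname(feats)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
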