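# Planar geometry primitives used by the regionalization and landscape
# modules. All coordinates are projected meters. A "ring" is an open
# (first vertex not repeated) two-column matrix of vertices; a "polygon"
# is a list of one or more rings (multi-part, no holes).

ring_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (ncol(m) != 2L || nrow(m) < 3L) {
    stop("a ring needs a two-column matrix with at least 3 vertices")
  }
  # drop a closing vertex if present
  if (isTRUE(all.equal(m[1L, ], m[nrow(m), ], check.attributes = FALSE))) {
    m <- m[-nrow(m), , drop = FALSE]
  }
  dimnames(m) <- NULL
  m
}

as_polygon <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) return(list(ring_matrix(x)))
  if (is.list(x)) return(lapply(x, ring_matrix))
  stop("cannot interpret input as a polygon")
}

# signed shoelace area of one ring
ring_signed_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

ring_area <- function(ring) abs(ring_signed_area(ring))

polygon_area <- function(poly) sum(vapply(as_polygon(poly), ring_area, 0))

ring_centroid <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(ring))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

polygon_centroid <- function(poly) {
  poly <- as_polygon(poly)
  areas <- vapply(poly, ring_area, 0)
  cents <- t(vapply(poly, ring_centroid, c(0, 0)))
  if (sum(areas) <= 0) return(colMeans(cents))
  colSums(cents * areas) / sum(areas)
}

polygon_bbox <- function(poly) {
  v <- do.call(rbind, as_polygon(poly))
  c(xmin = min(v[, 1L]), ymin = min(v[, 2L]),
    xmax = max(v[, 1L]), ymax = max(v[, 2L]))
}

# even-odd point-in-ring test; boundary points count as inside
point_in_ring <- function(p, ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- nrow(ring)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    # on-vertex / on-edge check
    if (point_segment_distance(p, ring[i, ], ring[j, ]) < 1e-9) return(TRUE)
    if ((y[i] > p[2L]) != (y[j] > p[2L])) {
      xint <- x[i] + (p[2L] - y[i]) / (y[j] - y[i]) * (x[j] - x[i])
      if (p[1L] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

point_in_polygon <- function(p, poly) {
  any(vapply(as_polygon(poly), function(r) point_in_ring(p, r), FALSE))
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((p - (a + t * ab))^2))
}

segment_segment_distance <- function(a1, a2, b1, b2) {
  if (segments_intersect(a1, a2, b1, b2)) return(0)
  min(point_segment_distance(a1, b1, b2),
      point_segment_distance(a2, b1, b2),
      point_segment_distance(b1, a1, a2),
      point_segment_distance(b2, a1, a2))
}

segments_intersect <- function(a1, a2, b1, b2) {
  orient <- function(p, q, r) {
    v <- (q[1L] - p[1L]) * (r[2L] - p[2L]) - (q[2L] - p[2L]) * (r[1L] - p[1L])
    if (abs(v) < 1e-12) 0 else sign(v)
  }
  o1 <- orient(a1, a2, b1); o2 <- orient(a1, a2, b2)
  o3 <- orient(b1, b2, a1); o4 <- orient(b1, b2, a2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on <- function(p, q, r) {
    orient(p, q, r) == 0 &&
      r[1L] <= max(p[1L], q[1L]) + 1e-12 && r[1L] >= min(p[1L], q[1L]) - 1e-12 &&
      r[2L] <= max(p[2L], q[2L]) + 1e-12 && r[2L] >= min(p[2L], q[2L]) - 1e-12
  }
  on(a1, a2, b1) || on(a1, a2, b2) || on(b1, b2, a1) || on(b1, b2, a2)
}

ring_edges <- function(ring) {
  n <- nrow(ring)
  cbind(ring, ring[c(2:n, 1L), , drop = FALSE])
}

# minimum distance between the boundaries of two (multi-part) polygons;
# zero when they touch or overlap along an edge or point
polygon_boundary_distance <- function(p1, p2) {
  e1 <- do.call(rbind, lapply(as_polygon(p1), ring_edges))
  e2 <- do.call(rbind, lapply(as_polygon(p2), ring_edges))
  best <- Inf
  for (i in seq_len(nrow(e1))) {
    a1 <- e1[i, 1:2]; a2 <- e1[i, 3:4]
    for (j in seq_len(nrow(e2))) {
      d <- segment_segment_distance(a1, a2, e2[j, 1:2], e2[j, 3:4])
      if (d < best) best <- d
      if (best == 0) return(0)
    }
  }
  best
}

# Sutherland-Hodgman clip of a ring against the half-plane a . p <= b
clip_ring_halfplane <- function(ring, a, b) {
  n <- nrow(ring)
  out <- matrix(0, 2L * n, 2L)
  k <- 0L
  prev <- ring[n, ]
  prev_in <- sum(a * prev) <= b + 1e-9
  for (i in seq_len(n)) {
    cur <- ring[i, ]
    cur_in <- sum(a * cur) <= b + 1e-9
    if (cur_in) {
      if (!prev_in) {
        t <- (b - sum(a * prev)) / sum(a * (cur - prev))
        k <- k + 1L; out[k, ] <- prev + t * (cur - prev)
      }
      k <- k + 1L; out[k, ] <- cur
    } else if (prev_in) {
      t <- (b - sum(a * prev)) / sum(a * (cur - prev))
      k <- k + 1L; out[k, ] <- prev + t * (cur - prev)
    }
    prev <- cur
    prev_in <- cur_in
  }
  if (k < 3L) return(NULL)
  out <- out[seq_len(k), , drop = FALSE]
  # drop duplicated consecutive vertices produced by clipping
  keep <- c(TRUE, rowSums(abs(diff(out))) > 1e-9)
  out <- out[keep, , drop = FALSE]
  if (nrow(out) > 1L &&
      sum(abs(out[1L, ] - out[nrow(out), ])) < 1e-9) {
    out <- out[-nrow(out), , drop = FALSE]
  }
  if (nrow(out) < 3L) NULL else out
}
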