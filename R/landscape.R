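#' Construct a raster surface
#'
#' A regular grid of values in projected meters. Rows of the value
#' matrix run north to south (row 1 is the top row, the ESRI ASCII
#' convention); \code{origin} is the lower-left corner of the grid.
#'
#' @param values numeric matrix; NA marks nodata cells.
#' @param origin numeric (x, y), lower-left corner.
#' @param cell_size positive cell edge in meters (square cells).
#' @return object of class \code{het_surface}.
#' @export
surface <- function(values, origin, cell_size) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (cell_size <= 0) stop("cell_size must be positive")
  if (length(origin) != 2L) stop("origin must be (x, y)")
  structure(list(values = values, origin = as.numeric(origin),
                 cell_size = as.numeric(cell_size),
                 nrows = nrow(values), ncols = ncol(values)),
            class = "het_surface")
}

#' @export
print.het_surface <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("het_surface: %d x %d cells of %.0f m (%d nodata)\n",
              x$nrows, x$ncols, x$cell_size, sum(is.na(x$values))))
  if (length(v)) cat(sprintf("  range [%.4f, %.4f]\n", min(v), max(v)))
  invisible(x)
}

# cell-center coordinates; rows north to south
surface_cell_centers <- function(s) {
  xs <- s$origin[1L] + (seq_len(s$ncols) - 0.5) * s$cell_size
  ys <- s$origin[2L] + (s$nrows - seq_len(s$nrows) + 0.5) * s$cell_size
  list(x = xs, y = ys)
}

congruent_surfaces <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    a$nrows == b$nrows && a$ncols == b$ncols
}

#' Build a point layer of unit centroids carrying values
#'
#' One point per land-unit centroid; units carrying sub-centroids
#' (e.g. a city pooled from several postal areas) can replicate their
#' single value onto every sub-centroid, which smooths interpolation
#' over disproportionately large units.
#'
#' @param region a \code{region_set}.
#' @param values named per-unit values (or data.frame with
#'   \code{unit_id} and a value column).
#' @param replicate_sub_centroids replicate values onto sub-centroids
#'   (default TRUE).
#' @return data.frame: \code{x}, \code{y}, \code{value},
#'   \code{unit_id}.
#' @export
build_point_layer <- function(region, values,
                              replicate_sub_centroids = TRUE) {
  stopifnot(inherits(region, "region_set"))
  if (is.data.frame(values)) {
    vcol <- setdiff(names(values), "unit_id")[1L]
    values <- stats::setNames(values[[vcol]],
                              as.character(values$unit_id))
  }
  if (is.null(names(values))) stop("values must be named by unit id")
  rows <- list()
  for (u in region$units) {
    v <- if (u$unit_id %in% names(values)) values[[u$unit_id]] else NA_real_
    if (is.null(v) || is.na(v)) {
      warning("no value for unit ", u$unit_id, "; point omitted")
      next
    }
    pts <- if (replicate_sub_centroids && !is.null(u$sub_centroids)) {
      u$sub_centroids
    } else {
      matrix(u$centroid, 1L, 2L)
    }
    rows[[u$unit_id]] <- data.frame(x = pts[, 1L], y = pts[, 2L],
                                    value = v, unit_id = u$unit_id,
                                    stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no points: no unit has a value")
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  out
}

# radial basis of the regularized spline with tension:
# R(r) = -(ln(rho) + E1(rho) + gamma), rho = (tau r / 2)^2, R(0) = 0
rst_basis <- function(r, tau) {
  out <- numeric(length(r))
  pos <- r > 0
  rho <- (tau * r[pos] / 2)^2
  out[pos] <- -(log(rho) + pracma::expint_E1(rho) + 0.57721566490153286)
  out
}

#' Fit a regularized spline with tension to scattered points
#'
#' Thin-flexible-plate interpolant \eqn{z(p) = a_1 + \sum_j c_j
#' R(|p - p_j|)} where the radial basis uses the exponential integral,
#' \eqn{R(r) = -[\ln\rho + E_1(\rho) + \gamma_E]},
#' \eqn{\rho = (\varphi r/2)^2}. The tension \eqn{\varphi} is expressed
#' per map extent: internal distances are normalized by the larger
#' side of the data bounding box, so the default tension is
#' comparable across study areas. Coefficients solve the linear system
#' with \code{smoothing} added to the diagonal and the side condition
#' \eqn{\sum_j c_j = 0}; with zero smoothing the surface passes
#' exactly through the data points.
#'
#' @param points data.frame with \code{x}, \code{y}, \code{value}
#'   (e.g. from [build_point_layer()]).
#' @param tension positive tension parameter (default 40).
#' @param smoothing nonnegative diagonal smoothing (default 0.1).
#' @return object of class \code{rst_model} with a [predict] method.
#' @export
rst_model <- function(points, tension = 40, smoothing = 0.1) {
  points <- as.data.frame(points)
  stopifnot(all(c("x", "y", "value") %in% names(points)))
  if (tension <= 0) stop("tension must be positive")
  if (smoothing < 0) stop("smoothing must be nonnegative")
  xy <- as.matrix(points[, c("x", "y")])
  v <- as.numeric(points$value)
  if (anyNA(xy) || anyNA(v)) stop("points and values must be finite")
  n <- nrow(xy)
  if (n < 3L) stop("at least 3 points required")
  d <- as.matrix(stats::dist(xy))
  if (any(d[upper.tri(d)] < 1e-9)) {
    dup <- which(d < 1e-9 & upper.tri(d), arr.ind = TRUE)
    vals_differ <- any(abs(v[dup[, 1L]] - v[dup[, 2L]]) > 1e-12)
    if (smoothing == 0 && vals_differ) {
      stop("coincident points with different values need smoothing > 0")
    }
  }
  scale <- max(diff(range(xy[, 1L])), diff(range(xy[, 2L])))
  if (scale <= 0) stop("degenerate point layout")
  tau <- tension / scale
  K <- matrix(rst_basis(as.vector(d), tau), n, n)
  Amat <- rbind(cbind(K + smoothing * diag(n), rep(1, n)),
                c(rep(1, n), 0))
  sol <- tryCatch(solve(Amat, c(v, 0)),
                  error = function(e) stop("singular spline system"))
  structure(list(xy = xy, coef = sol[seq_len(n)], a1 = sol[n + 1L],
                 tau = tau, tension = tension, smoothing = smoothing,
                 scale = scale),
            class = "rst_model")
}

#' Predict from a regularized-spline-with-tension model
#'
#' @param object an \code{rst_model}.
#' @param newdata data.frame or matrix with columns/coords x, y.
#' @param ... unused.
#' @return numeric vector of surface values.
#' @export
predict.rst_model <- function(object, newdata, ...) {
  p <- as.matrix(as.data.frame(newdata)[, 1:2])
  n <- nrow(object$xy)
  out <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    r <- sqrt((object$xy[, 1L] - p[i, 1L])^2 +
                (object$xy[, 2L] - p[i, 2L])^2)
    out[i] <- object$a1 + sum(object$coef * rst_basis(r, object$tau))
  }
  out
}

#' Interpolate a point layer to a raster surface
#'
#' Fits [rst_model()] and evaluates it on a regular grid spanning the
#' bounding box of \code{region} (or of the points), optionally
#' clipped to the region's polygons (outside cells become nodata).
#'
#' @param points data.frame with \code{x}, \code{y}, \code{value}.
#' @param region optional \code{region_set} providing the grid extent
#'   and clip mask.
#' @param ncols grid columns across the extent (default 200; square
#'   cells).
#' @param tension,smoothing passed to [rst_model()].
#' @param clip clip to the region polygons (default TRUE when a
#'   region is given).
#' @return a \code{het_surface}.
#' @export
interpolate_rst <- function(points, region = NULL, ncols = 200,
                            tension = 40, smoothing = 0.1,
                            clip = !is.null(region)) {
  model <- rst_model(points, tension = tension, smoothing = smoothing)
  if (!is.null(region)) {
    bb <- apply(do.call(rbind, lapply(region$units, function(u)
      polygon_bbox(u$polygon))), 2L, range)
    bbox <- c(bb[1L, "xmin"], bb[1L, "ymin"], bb[2L, "xmax"], bb[2L, "ymax"])
  } else {
    bbox <- c(min(points$x), min(points$y), max(points$x), max(points$y))
  }
  cell <- (bbox[3L] - bbox[1L]) / ncols
  if (cell <= 0) stop("degenerate grid extent")
  nrows <- max(1L, ceiling((bbox[4L] - bbox[2L]) / cell))
  s <- surface(matrix(NA_real_, nrows, ncols),
               origin = bbox[1:2], cell_size = cell)
  cc <- surface_cell_centers(s)
  grid <- cbind(x = rep(cc$x, each = nrows), y = rep(cc$y, times = ncols))
  vals <- predict(model, grid)
  m <- matrix(vals, nrows, ncols)
  if (clip && !is.null(region)) {
    boxes <- lapply(region$units, function(u) polygon_bbox(u$polygon))
    for (j in seq_len(ncols)) {
      for (i in seq_len(nrows)) {
        p <- c(cc$x[j], cc$y[i])
        inside <- FALSE
        for (k in seq_along(region$units)) {
          b <- boxes[[k]]
          if (p[1L] < b["xmin"] || p[1L] > b["xmax"] ||
              p[2L] < b["ymin"] || p[2L] > b["ymax"]) next
          if (point_in_polygon(p, region$units[[k]]$polygon)) {
            inside <- TRUE
            break
          }
        }
        if (!inside) m[i, j] <- NA_real_
      }
    }
  }
  s$values <- m
  attr(s, "model") <- model
  s
}

#' Standardized divergence landscape (observed vs predicted)
#'
#' Normalizes the pixelwise absolute difference by the range of the
#' observed landscape, \eqn{max\_rg = z_{max,int} - z_{min,int}}
#' (maximum minus minimum over its valid cells), and expresses it in
#' percent: each cell is \eqn{|obs - pred| / max\_rg \times 100}.
#' Nodata propagates.
#'
#' @param observed,predicted congruent \code{het_surface} objects.
#' @return list: \code{surface} (divergence, percent of the observed
#'   range) and \code{max_rg}.
#' @export
divergence_landscape <- function(observed, predicted) {
  stopifnot(inherits(observed, "het_surface"),
            inherits(predicted, "het_surface"))
  if (!congruent_surfaces(observed, predicted)) {
    stop("surfaces are not congruent (origin, cell size, shape)")
  }
  v <- observed$values[!is.na(observed$values)]
  if (length(v) == 0L) stop("observed surface is all nodata")
  max_rg <- max(v) - min(v)
  if (max_rg == 0) stop("observed surface is constant: max_rg = 0")
  div <- abs(observed$values - predicted$values) / max_rg * 100
  out <- observed
  out$values <- div
  attr(out, "model") <- NULL
  list(surface = out, max_rg = max_rg)
}

#' Summary statistics of a surface
#'
#' Mean, standard deviation (n - 1), median, min and max over the
#' valid (non-nodata) cells.
#'
#' @param s a \code{het_surface}.
#' @return named numeric vector.
#' @export
surface_summary <- function(s) {
  stopifnot(inherits(s, "het_surface"))
  v <- s$values[!is.na(s$values)]
  if (length(v) == 0L) stop("surface is all nodata")
  c(mean = mean(v), sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
    median = stats::median(v), min = min(v), max = max(v))
}

#' Rank SAR models by divergence summaries
#'
#' Orders models by ascending mean pixelwise divergence, with
#' ascending standard deviation as the tie-break; the first model is
#' the best-fitting one.
#'
#' @param summaries data.frame with columns \code{model}, \code{mean},
#'   \code{sd} (extra columns kept).
#' @return list: \code{ranking} (reordered data.frame) and
#'   \code{best} (model id).
#' @export
rank_models <- function(summaries) {
  summaries <- as.data.frame(summaries)
  stopifnot(all(c("model", "mean", "sd") %in% names(summaries)))
  if (nrow(summaries) == 0L) stop("no summaries to rank")
  ord <- order(summaries$mean, summaries$sd)
  ranking <- summaries[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  list(ranking = ranking, best = ranking$model[1L])
}

#' Write a surface as an ESRI ASCII grid
#'
#' @param s a \code{het_surface}.
#' @param path output path (.asc).
#' @param nodata nodata marker written to the file (default -9999).
#' @export
write_ascii_grid <- function(s, path, nodata = -9999) {
  stopifnot(inherits(s, "het_surface"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", s$ncols),
               sprintf("nrows %d", s$nrows),
               sprintf("xllcorner %.6f", s$origin[1L]),
               sprintf("yllcorner %.6f", s$origin[2L]),
               sprintf("cellsize %.6f", s$cell_size),
               sprintf("NODATA_value %g", nodata)), con)
  m <- s$values
  m[is.na(m)] <- nodata
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path .asc file path.
#' @return a \code{het_surface}.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- lapply(strsplit(lines, "\\s+"), function(p) {
    stats::setNames(as.numeric(p[2L]), tolower(p[1L]))
  })
  hdr <- unlist(hdr)
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header")
  m <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(m) <- NULL
  if (!all(dim(m) == hdr[c("nrows", "ncols")])) {
    stop("grid body does not match header dimensions")
  }
  m[m == hdr[["nodata_value"]]] <- NA_real_
  surface(m, origin = hdr[c("xllcorner", "yllcorner")],
          cell_size = hdr[["cellsize"]])
}

#' Export a surface as (x, y, value) CSV
#'
#' @param s a \code{het_surface}.
#' @param path CSV path.
#' @param drop_nodata omit nodata cells (default TRUE).
#' @export
write_surface_csv <- function(s, path, drop_nodata = TRUE) {
  cc <- surface_cell_centers(s)
  df <- data.frame(x = rep(cc$x, each = s$nrows),
                   y = rep(cc$y, times = s$ncols),
                   value = as.vector(s$values))
  if (drop_nodata) df <- df[!is.na(df$value), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
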