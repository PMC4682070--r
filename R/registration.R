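#' Boundary traces
#'
#' A boundary trace is a closed outline of one compartment (nucleus or cell)
#' in image pixel coordinates: a list with `vertices` (n x 2 matrix of
#' (x, y), x = column, y = row, 0-based, first vertex not repeated),
#' `compartment` ("nucleus" or "cell"), `cell_id`, and optional `sample_id`,
#' `image_id` and `on_tile_border` flag. Vertices are ordered so the
#' shoelace signed area is positive (counterclockwise convention).
#'
#' @param vertices numeric n x 2 matrix of (x, y) vertex coordinates.
#' @param compartment `"nucleus"` or `"cell"`.
#' @param cell_id integer cell identifier.
#' @param sample_id,image_id optional identifiers carried through the
#'   pipeline.
#' @param on_tile_border logical; `TRUE` when the object touches the image
#'   border of its tile.
#' @return An object of class `boundary_trace`.
#' @export
boundary_trace <- function(vertices, compartment = c("cell", "nucleus"),
                           cell_id = 1L, sample_id = NA_character_,
                           image_id = NA_character_, on_tile_border = FALSE) {
  compartment <- match.arg(compartment)
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("vertices must be a numeric matrix with >= 3 rows and 2 columns",
         call. = FALSE)
  if (!all(is.finite(vertices)))
    stop("vertices must be finite", call. = FALSE)
  if (nrow(vertices) > 3L &&
      all(vertices[1L, ] == vertices[nrow(vertices), ]))
    vertices <- vertices[-nrow(vertices), , drop = FALSE]
  if (polygon_signed_area(vertices) < 0)
    vertices <- vertices[nrow(vertices):1L, , drop = FALSE]
  structure(list(vertices = vertices, compartment = compartment,
                 cell_id = as.integer(cell_id), sample_id = sample_id,
                 image_id = image_id, on_tile_border = isTRUE(on_tile_border)),
            class = "boundary_trace")
}

trace_vertices <- function(trace) {
  if (inherits(trace, "boundary_trace")) trace$vertices else as.matrix(trace)
}

#' Resample a boundary at equally spaced arc-length positions
#'
#' Places `n_points` points on the closed polygon with equal arc-length
#' spacing (perimeter / `n_points`), the first point at the trace's first
#' vertex, preserving the traversal order.
#'
#' @param trace a [boundary_trace()] or an n x 2 vertex matrix.
#' @param n_points number of points to place (default 50).
#' @return An `n_points` x 2 matrix of (x, y) coordinates.
#' @export
resample_boundary <- function(trace, n_points = 50L) {
  v <- trace_vertices(trace)
  if (nrow(v) < 3L) stop("trace must have >= 3 vertices", call. = FALSE)
  if (polygon_perimeter(v) <= 0)
    stop("degenerate shape: zero perimeter", call. = FALSE)
  resample_closed(v, as.integer(n_points))
}

#' Scaling factor R of a shape
#'
#' The scaling factor R is the size measure used to normalize outlines:
#' the root-mean-square Euclidean distance of the boundary points from
#' their centroid (centroid size per point). It scales linearly under
#' uniform scaling and is reported in the units of the input coordinates.
#'
#' @param points an n x 2 matrix of boundary points (typically the 50
#'   resampled points).
#' @return A positive scalar.
#' @export
compute_scaling_factor <- function(points) {
  p <- as.matrix(points)
  if (nrow(p) < 3L) stop("need >= 3 points", call. = FALSE)
  ctr <- colMeans(p)
  r <- sqrt(mean((p[, 1L] - ctr[1L])^2 + (p[, 2L] - ctr[2L])^2))
  if (r <= 0) stop("degenerate shape: coincident points", call. = FALSE)
  r
}

#' Register a boundary trace into a normalized 50-point shape
#'
#' Registration removes position, size and orientation so that only shape
#' remains: the outline is resampled at `n_points` equal arc-length
#' positions, translated so the point centroid is at the origin, divided by
#' the scaling factor R (RMS radius = 1), and rotated so the major axis of
#' the point set (leading eigenvector of the 2 x 2 second-moment matrix) is
#' horizontal. The 180-degree axis ambiguity is resolved by requiring the
#' third moment of x to be nonnegative; the starting index is the point
#' with the largest x (ties: largest y) and points run counterclockwise.
#' Mirror images are kept distinct.
#'
#' Internally the anchor point and provisional frame are derived from exact
#' arc-length line integrals over the polygon, so the result is invariant
#' (to floating-point precision) under translation, rotation, uniform
#' scaling and cyclic re-indexing of the input vertices, and re-registering
#' a registered shape reproduces it.
#'
#' @param trace a [boundary_trace()] or n x 2 vertex matrix.
#' @param n_points number of boundary points (default 50).
#' @return An object of class `registered_shape`: list with `points`
#'   (n_points x 2, centroid 0, RMS radius 1, major axis horizontal), `R`
#'   (scaling factor in input units), `rotation_applied` (radians),
#'   `centroid_original` (x, y in input units), `compartment`, `cell_id`,
#'   `sample_id`, `degenerate_axis` flag.
#' @export
register_shape <- function(trace, n_points = 50L) {
  v <- trace_vertices(trace)
  if (nrow(v) < 3L) stop("trace must have >= 3 vertices", call. = FALSE)
  n_points <- as.integer(n_points)

  ## provisional frame from exact line-integral moments (index-free)
  mom <- polygon_line_moments(v)
  if (mom$rms_radius <= 0)
    stop("degenerate shape: coincident points", call. = FALSE)
  vc <- cbind(v[, 1L] - mom$centroid[1L], v[, 2L] - mom$centroid[2L])
  degenerate_axis <- abs(mom$sxx - mom$syy) < 1e-12 && abs(mom$sxy) < 1e-12
  ang0 <- if (degenerate_axis) 0 else 0.5 * atan2(2 * mom$sxy, mom$sxx - mom$syy)
  p <- rotate_points(vc, -ang0)
  total_rot <- -ang0
  if (polygon_line_x3(p, 0) < 0) {
    p <- -p
    total_rot <- total_rot + pi
  }
  p <- p / mom$rms_radius

  ## canonical arc-length origin: boundary vertex with max x (ties: max y)
  anchor <- order(-p[, 1L], -p[, 2L])[1L]
  n <- nrow(p)
  p <- p[c(anchor:n, seq_len(anchor - 1L))[seq_len(n)], , drop = FALSE]
  if (polygon_signed_area(p) < 0)
    p <- p[c(1L, n:2L), , drop = FALSE]

  ## equal-arc-length resampling iterated to its self-consistent fixed point
  q <- resample_equalized(p, n_points)

  ## discrete finish: moments of the resampled points define the reported
  ## frame so the registered invariants hold exactly on the 50 points
  m <- colMeans(q)
  q <- cbind(q[, 1L] - m[1L], q[, 2L] - m[2L])
  sxx <- mean(q[, 1L]^2); syy <- mean(q[, 2L]^2); sxy <- mean(q[, 1L] * q[, 2L])
  ang1 <- if (abs(sxx - syy) < 1e-15 && abs(sxy) < 1e-15) 0 else
    0.5 * atan2(2 * sxy, sxx - syy)
  q <- rotate_points(q, -ang1)
  total_rot <- total_rot - ang1
  if (sum(q[, 1L]^3) < 0) {
    q <- -q
    total_rot <- total_rot + pi
  }
  rd <- sqrt(mean(q[, 1L]^2 + q[, 2L]^2))
  q <- q / rd

  ## re-anchor the start index on the final frame (cyclic shift only)
  a2 <- order(-q[, 1L], -q[, 2L])[1L]
  q <- q[c(a2:n_points, seq_len(a2 - 1L))[seq_len(n_points)], , drop = FALSE]

  R <- mom$rms_radius * rd
  ## centroid of the resampled points in original input coordinates
  centroid_original <- mom$centroid +
    mom$rms_radius * drop(rotate_points(rbind(m), ang0))

  structure(list(points = q, R = R,
                 rotation_applied = ((total_rot + pi) %% (2 * pi)) - pi,
                 centroid_original = centroid_original,
                 compartment = if (inherits(trace, "boundary_trace"))
                   trace$compartment else NA_character_,
                 cell_id = if (inherits(trace, "boundary_trace"))
                   trace$cell_id else NA_integer_,
                 sample_id = if (inherits(trace, "boundary_trace"))
                   trace$sample_id else NA_character_,
                 degenerate_axis = degenerate_axis),
            class = "registered_shape")
}

#' Shape feature vector of a registered shape
#'
#' Flattens the registered points into the 2 * n_points feature vector used
#' for PCA: all x-coordinates followed by all y-coordinates.
#'
#' @param shape a `registered_shape` (or n x 2 point matrix).
#' @return Numeric vector of length 2 * n_points.
#' @export
shape_features <- function(shape) {
  p <- if (inherits(shape, "registered_shape")) shape$points else as.matrix(shape)
  c(p[, 1L], p[, 2L])
}

#' Register a list of boundary traces into a feature table
#'
#' @param traces list of [boundary_trace()] objects.
#' @param n_points number of boundary points (default 50).
#' @return A list with `features` (n x 2*n_points matrix), and a
#'   data.frame `info` with columns cell_id, sample_id, compartment, R.
#' @export
register_boundaries <- function(traces, n_points = 50L) {
  regs <- lapply(traces, register_shape, n_points = n_points)
  features <- t(vapply(regs, shape_features, numeric(2L * n_points)))
  info <- data.frame(
    cell_id = vapply(regs, function(r) r$cell_id, integer(1)),
    sample_id = vapply(regs, function(r) r$sample_id, character(1)),
    compartment = vapply(regs, function(r) r$compartment, character(1)),
    R = vapply(regs, function(r) r$R, numeric(1)),
    rotation = vapply(regs, function(r) r$rotation_applied, numeric(1)),
    stringsAsFactors = FALSE)
  list(features = features, info = info, shapes = regs)
}

#' Conventional shape descriptors of a boundary
#'
#' Shape factor (4 pi area / perimeter^2; 1 for a circle) and aspect ratio
#' (extent of the boundary along the major principal axis divided by the
#' extent along the minor axis, >= 1).
#'
#' @param trace a [boundary_trace()] or vertex matrix.
#' @return Named numeric vector with `area`, `perimeter`, `shape_factor`,
#'   `aspect_ratio`.
#' @export
shape_descriptors <- function(trace) {
  v <- trace_vertices(trace)
  area <- abs(polygon_signed_area(v))
  per <- polygon_perimeter(v)
  p <- resample_closed(v, 200L)
  p <- cbind(p[, 1L] - mean(p[, 1L]), p[, 2L] - mean(p[, 2L]))
  sxx <- mean(p[, 1L]^2); syy <- mean(p[, 2L]^2); sxy <- mean(p[, 1L] * p[, 2L])
  ang <- if (abs(sxx - syy) < 1e-15 && abs(sxy) < 1e-15) 0 else
    0.5 * atan2(2 * sxy, sxx - syy)
  q <- rotate_points(p, -ang)
  ex <- diff(range(q[, 1L])); ey <- diff(range(q[, 2L]))
  c(area = area, perimeter = per,
    shape_factor = 4 * pi * area / per^2,
    aspect_ratio = max(ex, ey) / max(min(ex, ey), .Machine$double.eps))
}

#' Write / read boundary traces as CSV
#'
#' Long format with one row per vertex: sample_id, cell_id, compartment,
#' vertex_index, x, y.
#'
#' @param traces list of [boundary_trace()] objects.
#' @param path CSV file path.
#' @return `write_boundaries_csv` invisibly returns `path`;
#'   `read_boundaries_csv` returns a list of traces.
#' @export
write_boundaries_csv <- function(traces, path) {
  rows <- lapply(traces, function(tr)
    data.frame(sample_id = tr$sample_id, cell_id = tr$cell_id,
               compartment = tr$compartment,
               vertex_index = seq_len(nrow(tr$vertices)),
               x = tr$vertices[, 1L], y = tr$vertices[, 2L],
               stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boundaries_csv
#' @export
read_boundaries_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (sid in unique(tab$sample_id)) {
    ts <- tab[tab$sample_id == sid, , drop = FALSE]
    for (cid in unique(ts$cell_id)) for (comp in unique(ts$compartment)) {
      sel <- ts[ts$cell_id == cid & ts$compartment == comp, , drop = FALSE]
      if (nrow(sel) < 3L) next
      sel <- sel[order(sel$vertex_index), , drop = FALSE]
      out[[length(out) + 1L]] <-
        boundary_trace(cbind(sel$x, sel$y), comp, cid, sample_id = sid)
    }
  }
  out
}
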