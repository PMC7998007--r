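# Interactive seed geometries: the three drawing modes (sketch = pencil
# polyline, polygon = clicked ring filled inside, freedraw = explicit pixel
# set) drawn on axis-aligned slices, rasterized to voxel-level foreground /
# background seed sets that become hard constraints for the cut.

#' Construct a seed geometry
#'
#' Describes one user stroke on an axis-aligned slice. Vertices are 2-D
#' points in 0-based voxel-centre coordinates of the in-plane axes (for a
#' `z` slice these are the x and y axes, in that order).
#'
#' @param mode `"sketch"` (polyline, dilated by `brush_radius`), `"polygon"`
#'   (closed ring, even-odd interior fill, boundary centres included) or
#'   `"freedraw"` (explicit pixel set).
#' @param axis slice axis, one of `"x"`, `"y"`, `"z"`.
#' @param index 0-based slice index along `axis`.
#' @param vertices n x 2 numeric matrix of in-plane points (for freedraw:
#'   integer pixel coordinates).
#' @param brush_radius Chebyshev brush radius in voxels (sketch only, >= 0).
#' @param role `"foreground"` or `"background"`.
#' @param structure_id positive integer label of the target structure.
#' @return An object of class `seed_geometry`.
#' @export
seed_geometry <- function(mode = c("sketch", "polygon", "freedraw"),
                          axis = c("z", "y", "x"), index, vertices,
                          brush_radius = 0L,
                          role = c("foreground", "background"),
                          structure_id = 1L) {
  mode <- match.arg(mode)
  axis <- match.arg(axis)
  role <- match.arg(role)
  vertices <- matrix(as.numeric(vertices), ncol = 2)
  nmin <- switch(mode, sketch = 2L, polygon = 3L, freedraw = 1L)
  if (nrow(vertices) < nmin)
    stop(sprintf("%s requires at least %d vertices", mode, nmin), call. = FALSE)
  if (brush_radius < 0) stop("brush_radius must be >= 0", call. = FALSE)
  if (index < 0 || index != round(index))
    stop("slice index must be a nonnegative integer", call. = FALSE)
  structure(list(mode = mode, axis = axis, index = as.integer(index),
                 vertices = vertices, brush_radius = as.integer(brush_radius),
                 role = role, structure_id = as.integer(structure_id)),
            class = "seed_geometry")
}

# in-plane axis numbers for a slice axis (u, v), plus the slice axis
.plane_axes <- function(axis) {
  switch(axis,
         z = list(u = 1L, v = 2L, w = 3L),
         y = list(u = 1L, v = 3L, w = 2L),
         x = list(u = 2L, v = 3L, w = 1L))
}

# signed area of a ring (shoelace)
.ring_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

# even-odd point-in-polygon with boundary centres counted inside; pts integer
.polygon_pixels <- function(verts, pts) {
  n <- nrow(verts)
  jn <- c(2:n, 1)
  x <- pts[, 1]; y <- pts[, 2]
  inside <- rep(FALSE, nrow(pts))
  onedge <- rep(FALSE, nrow(pts))
  for (e in seq_len(n)) {
    x1 <- verts[e, 1]; y1 <- verts[e, 2]
    x2 <- verts[jn[e], 1]; y2 <- verts[jn[e], 2]
    # boundary test: point on segment within tolerance
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    dot <- (x - x1) * (x2 - x1) + (y - y1) * (y2 - y1)
    len2 <- (x2 - x1)^2 + (y2 - y1)^2
    onedge <- onedge | (abs(cross) < 1e-9 * max(1, sqrt(len2)) &
                          dot >= -1e-9 & dot <= len2 + 1e-9)
    # even-odd ray crossing (ray toward +x)
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < x1 + (y - y1) * (x2 - x1) / (y2 - y1))
    inside <- xor(inside, crosses)
  }
  inside | onedge
}

# 8-connected integer line trace (Bresenham-style via rounded interpolation)
.trace_line <- function(p, q) {
  p <- round(p); q <- round(q)
  nsteps <- max(abs(q - p))
  if (nsteps == 0) return(matrix(p, ncol = 2))
  t <- seq(0, 1, length.out = nsteps + 1)
  cbind(round(p[1] + t * (q[1] - p[1])), round(p[2] + t * (q[2] - p[2])))
}

#' Rasterize a seed geometry to voxel indices
#'
#' Sketch strokes become an 8-connected digital polyline on the slice,
#' dilated by a Chebyshev disc of `brush_radius`; polygons are filled by the
#' boundary-inclusive even-odd rule evaluated at voxel centres; freedraw
#' pixels are validated against the grid. All returned voxels lie on the
#' referenced slice.
#'
#' @param geom a [seed_geometry()].
#' @param grid_shape integer length-3 volume shape `(nx, ny, nz)`.
#' @return Integer matrix (n x 3) of 0-based voxel indices.
#' @export
rasterize_seed_geometry <- function(geom, grid_shape) {
  stopifnot(inherits(geom, "seed_geometry"), length(grid_shape) == 3L)
  ax <- .plane_axes(geom$axis)
  nu <- grid_shape[ax$u]; nv <- grid_shape[ax$v]
  if (geom$index >= grid_shape[ax$w])
    stop("bounds error: slice index outside the volume", call. = FALSE)
  v <- geom$vertices

  if (geom$mode == "freedraw") {
    px <- round(v)
    if (any(px[, 1] < 0 | px[, 2] < 0 | px[, 1] >= nu | px[, 2] >= nv))
      stop("bounds error: freedraw pixel outside the grid", call. = FALSE)
    px <- unique(px)
  } else if (geom$mode == "polygon") {
    if (abs(.ring_area(v)) < 1e-12)
      stop("geometry error: degenerate polygon (zero area)", call. = FALSE)
    if (any(v[, 1] < 0 | v[, 2] < 0 | v[, 1] > nu - 1 | v[, 2] > nv - 1))
      stop("bounds error: polygon vertex outside the grid", call. = FALSE)
    ulo <- max(0L, floor(min(v[, 1]))); uhi <- min(nu - 1L, ceiling(max(v[, 1])))
    vlo <- max(0L, floor(min(v[, 2]))); vhi <- min(nv - 1L, ceiling(max(v[, 2])))
    cand <- as.matrix(expand.grid(u = ulo:uhi, v = vlo:vhi))
    px <- cand[.polygon_pixels(v, cand), , drop = FALSE]
  } else {  # sketch
    if (any(v[, 1] < 0 | v[, 2] < 0 | v[, 1] > nu - 1 | v[, 2] > nv - 1))
      stop("bounds error: sketch vertex outside the grid", call. = FALSE)
    segs <- lapply(seq_len(nrow(v) - 1), function(i)
      .trace_line(v[i, ], v[i + 1, ]))
    px <- unique(do.call(rbind, segs))
    r <- geom$brush_radius
    if (r > 0) {
      disc <- as.matrix(expand.grid(-r:r, -r:r))
      px <- unique(cbind(rep(px[, 1], each = nrow(disc)) + disc[, 1],
                         rep(px[, 2], each = nrow(disc)) + disc[, 2]))
      px <- px[px[, 1] >= 0 & px[, 2] >= 0 & px[, 1] < nu & px[, 2] < nv,
               , drop = FALSE]
    }
  }

  out <- matrix(0L, nrow(px), 3)
  out[, ax$u] <- as.integer(px[, 1])
  out[, ax$v] <- as.integer(px[, 2])
  out[, ax$w] <- geom$index
  colnames(out) <- c("x", "y", "z")
  out
}

#' Build per-structure seed sets from geometries
#'
#' Unions the rasterized voxels of all geometries by role and structure,
#' de-duplicated. A voxel claimed as both foreground and background for the
#' same structure is a conflict; a structure without foreground seeds is
#' incomplete.
#'
#' @param geoms list of [seed_geometry()] objects.
#' @param grid_shape integer length-3 volume shape.
#' @return A `seed_set`: named list per structure id with `fg` and `bg`
#'   integer matrices (n x 3, 0-based voxel indices).
#' @export
build_seed_set <- function(geoms, grid_shape) {
  if (inherits(geoms, "seed_geometry")) geoms <- list(geoms)
  stopifnot(all(vapply(geoms, inherits, TRUE, "seed_geometry")))
  ids <- sort(unique(vapply(geoms, function(g) g$structure_id, 0L)))
  out <- list()
  for (sid in ids) {
    fg <- bg <- matrix(integer(0), 0, 3)
    for (g in geoms) {
      if (g$structure_id != sid) next
      px <- rasterize_seed_geometry(g, grid_shape)
      if (g$role == "foreground") fg <- rbind(fg, px) else bg <- rbind(bg, px)
    }
    fg <- unique(fg); bg <- unique(bg)
    if (nrow(fg) == 0)
      stop(sprintf("incomplete-seed error: structure %d has no foreground seeds", sid),
           call. = FALSE)
    key <- function(m) m[, 1] + grid_shape[1] * (m[, 2] + grid_shape[2] * m[, 3])
    clash <- intersect(key(fg), key(bg))
    if (length(clash) > 0) {
      cz <- clash[1] %/% (grid_shape[1] * grid_shape[2])
      cy <- (clash[1] %% (grid_shape[1] * grid_shape[2])) %/% grid_shape[1]
      cx <- clash[1] %% grid_shape[1]
      stop(sprintf(
        "conflict error: voxel (%d, %d, %d) is both foreground and background for structure %d",
        cx, cy, cz, sid), call. = FALSE)
    }
    colnames(fg) <- colnames(bg) <- c("x", "y", "z")
    out[[as.character(sid)]] <- list(fg = fg, bg = bg)
  }
  structure(out, class = "seed_set", grid_shape = as.integer(grid_shape))
}

#' Read seed geometries from JSON
#'
#' The file is a JSON list of objects mirroring [seed_geometry()] (fields
#' `mode`, `axis`, `index`, `vertices`, `brush_radius`, `role`,
#' `structure_id`); a schema ships at
#' `system.file("schema", "seeds.schema.json", package = "neuroprint")`.
#'
#' @param path JSON file.
#' @return List of [seed_geometry()] objects.
#' @export
read_seed_geometries <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(o)
    seed_geometry(mode = o$mode, axis = o$axis, index = o$index,
                  vertices = matrix(unlist(o$vertices), ncol = 2, byrow = TRUE),
                  brush_radius = if (is.null(o$brush_radius)) 0L else o$brush_radius,
                  role = o$role, structure_id = o$structure_id))
}

#' Write seed geometries to JSON
#'
#' @param geoms list of [seed_geometry()] objects.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_seed_geometries <- function(geoms, path) {
  if (inherits(geoms, "seed_geometry")) geoms <- list(geoms)
  objs <- lapply(geoms, function(g)
    list(mode = g$mode, axis = g$axis, index = g$index,
         vertices = lapply(seq_len(nrow(g$vertices)),
                           function(i) as.numeric(g$vertices[i, ])),
         brush_radius = g$brush_radius, role = g$role,
         structure_id = g$structure_id))
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
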