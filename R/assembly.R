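# From label map to printable kit: voxel-level boolean overlap resolution,
# watertight surface extraction, binary/ASCII STL export and external mold
# generation. Boolean work happens on masks before meshing, so adjacent
# structures meet exactly with no tolerance gaps.

#' Resolve structure overlaps by priority
#'
#' Assigns every claimed voxel to the highest-priority (lowest rank number)
#' claiming structure, so the output masks are pairwise disjoint — the
#' mask-subtraction step performed before independent printing. The
#' lowest-priority envelope (parenchyma) thereby loses every voxel claimed
#' by an internal structure.
#'
#' @param masks named list of congruent logical masks, one per structure
#'   label (names = label integers).
#' @param priorities named numeric vector of ranks (same names); smaller
#'   rank wins. Ranks must be unique.
#' @param structures optional descriptor `data.frame`
#'   ([structure_descriptor()] rows); defaults to bare descriptors.
#' @param spacing,origin,direction grid geometry.
#' @return A [label_map()] with disjoint structures; the disjointness
#'   certificate (max voxel multiplicity, always 1) is attached as attribute
#'   `disjoint_certificate`.
#' @export
resolve_overlaps <- function(masks, priorities, structures = NULL,
                             spacing = c(1, 1, 1), origin = c(0, 0, 0),
                             direction = diag(3)) {
  stopifnot(is.list(masks), length(masks) >= 1)
  labs <- as.integer(names(masks))
  if (anyNA(labs)) stop("masks must be named by integer labels", call. = FALSE)
  dims <- dim(masks[[1]])
  for (m in masks)
    if (!identical(dim(m), dims)) stop("masks must be congruent", call. = FALSE)
  pr <- priorities[names(masks)]
  if (anyNA(pr) || anyDuplicated(pr))
    stop("configuration error: priorities must cover all masks and be unique ranks",
         call. = FALSE)

  labels <- array(0L, dims)
  assigned_rank <- array(Inf, dims)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    take <- m & pr[[nm]] < assigned_rank
    labels[take] <- as.integer(nm)
    assigned_rank[take] <- pr[[nm]]
  }
  if (is.null(structures)) {
    structures <- do.call(rbind, lapply(seq_along(labs), function(i)
      structure_descriptor(labs[i], sprintf("structure_%d", labs[i]),
                           priority = as.integer(rank(pr))[i])))
  }
  lm <- label_map(labels, structures, spacing = spacing, origin = origin,
                  direction = direction)
  attr(lm, "disjoint_certificate") <- 1L  # one label per voxel by construction
  lm
}

#' Crop a skull-base structure to the tumor neighbourhood
#'
#' Keeps only the part of `mask` inside the axis-aligned bounding box of the
#' tumor, dilated by `margin` mm per axis — the portion of a large structure
#' adjacent to the tumor that is worth printing.
#'
#' @param mask,tumor_mask congruent logical masks.
#' @param margin mm, >= 0.
#' @param spacing voxel spacing in mm.
#' @return Cropped logical mask.
#' @export
crop_skull_base <- function(mask, tumor_mask, margin, spacing = c(1, 1, 1)) {
  stopifnot(identical(dim(mask), dim(tumor_mask)), margin >= 0)
  if (!any(tumor_mask))
    stop("empty-selection error: tumor mask has no voxels", call. = FALSE)
  dims <- dim(mask)
  idx <- which(tumor_mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  pad <- floor(margin / spacing + 1e-9)
  lo <- pmax(1, lo - pad); hi <- pmin(dims, hi + pad)
  keep <- array(FALSE, dims)
  keep[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  mask & keep
}

#' Construct a structure mesh
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param descriptor one-row `data.frame` ([structure_descriptor()]).
#' @return An object of class `structure_mesh`.
#' @export
structure_mesh <- function(vertices, triangles, descriptor = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1 || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range", call. = FALSE)
  structure(list(vertices = vertices, triangles = triangles,
                 descriptor = descriptor), class = "structure_mesh")
}

#' @export
print.structure_mesh <- function(x, ...) {
  nm <- if (!is.null(x$descriptor)) x$descriptor$name else "mesh"
  cat(sprintf("<structure_mesh> %s: %d vertices, %d triangles, volume %.1f mm^3\n",
              nm, nrow(x$vertices), nrow(x$triangles), mesh_volume(x)))
  invisible(x)
}

#' Signed mesh volume
#'
#' Sum of signed tetrahedra against the origin; positive for consistently
#' outward-oriented closed meshes.
#'
#' @param mesh a `structure_mesh`.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; t <- mesh$triangles
  if (nrow(t) == 0) return(0)
  a <- v[t[, 1], , drop = FALSE]
  b <- v[t[, 2], , drop = FALSE]
  c_ <- v[t[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Check mesh watertightness and orientation
#'
#' A mesh is accepted when every undirected edge is shared by exactly two
#' triangles with opposite orientation, no triangle has (near-)zero area,
#' and the signed volume is positive.
#'
#' @param mesh a `structure_mesh`.
#' @return Logical; details as attribute `checks`.
#' @export
is_watertight <- function(mesh) {
  t <- mesh$triangles
  if (nrow(t) == 0) return(FALSE)
  nv <- nrow(mesh$vertices)
  dir_edges <- rbind(t[, c(1, 2)], t[, c(2, 3)], t[, c(3, 1)])
  key_und <- pmin(dir_edges[, 1], dir_edges[, 2]) * (nv + 1) +
    pmax(dir_edges[, 1], dir_edges[, 2])
  cnt <- table(key_und)
  manifold <- all(cnt == 2)
  key_dir <- dir_edges[, 1] * (nv + 1) + dir_edges[, 2]
  opposed <- !any(duplicated(key_dir))   # each directed edge used once
  v <- mesh$vertices
  a <- v[t[, 1], , drop = FALSE]; b <- v[t[, 2], , drop = FALSE]
  c_ <- v[t[, 3], , drop = FALSE]
  u <- b - a; w <- c_ - a
  areas <- 0.5 * sqrt((u[, 2] * w[, 3] - u[, 3] * w[, 2])^2 +
                      (u[, 3] * w[, 1] - u[, 1] * w[, 3])^2 +
                      (u[, 1] * w[, 2] - u[, 2] * w[, 1])^2)
  nonzero <- all(areas > 1e-12)
  vol_ok <- mesh_volume(mesh) > 0
  ok <- manifold && opposed && nonzero && vol_ok
  attr(ok, "checks") <- c(manifold = manifold, oriented = opposed,
                          nonzero_area = nonzero, positive_volume = vol_ok)
  ok
}

# Laplacian smoothing: x <- x + lambda * (neighbour mean - x)
#' Laplacian mesh smoothing
#'
#' @param mesh a `structure_mesh`.
#' @param iterations number of smoothing passes, >= 0.
#' @param lambda per-pass step toward the neighbour mean, in `(0, 1]`.
#' @return The smoothed `structure_mesh` (connectivity unchanged).
#' @export
smooth_mesh <- function(mesh, iterations, lambda = 0.5) {
  if (iterations < 1) return(mesh)
  t <- mesh$triangles
  edges <- unique(rbind(t[, c(1, 2)], t[, c(2, 3)], t[, c(3, 1)],
                        t[, c(2, 1)], t[, c(3, 2)], t[, c(1, 3)]))
  deg <- tabulate(edges[, 1], nbins = nrow(mesh$vertices))
  v <- mesh$vertices
  for (it in seq_len(iterations)) {
    sums <- rowsum(v[edges[, 2], , drop = FALSE], edges[, 1])
    nb_mean <- sums / deg[as.integer(rownames(sums))]
    vi <- as.integer(rownames(sums))
    v[vi, ] <- v[vi, ] + lambda * (nb_mean - v[vi, , drop = FALSE])
  }
  structure_mesh(v, t, mesh$descriptor)
}

#' Extract a watertight surface for one label
#'
#' Isosurface of the binary mask at level 0.5 (tetrahedral marching on the
#' lattice, face-consistent, hence watertight and outward-oriented), mapped
#' to mm through the grid geometry, optionally Laplacian-smoothed
#' (`lambda = 0.5` per iteration).
#'
#' @param labelmap a [label_map()] (or a logical mask via `mask`).
#' @param label integer label to extract.
#' @param smoothing_iterations >= 0.
#' @param mask alternative input: a logical mask (then `labelmap`/`label`
#'   are ignored but geometry must be passed via `spacing`/`origin`).
#' @param spacing,origin geometry when meshing a bare mask.
#' @return A [structure_mesh()].
#' @export
extract_surface <- function(labelmap = NULL, label = NULL,
                            smoothing_iterations = 0L, mask = NULL,
                            spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.null(mask)) {
    stopifnot(inherits(labelmap, "label_map"), !is.null(label))
    mask <- labelmap$labels == label
    spacing <- labelmap$spacing
    origin <- labelmap$origin
    descr <- labelmap$structures[labelmap$structures$label == label, ]
    if (nrow(descr) == 0) descr <- NULL
  } else descr <- NULL
  if (!any(mask))
    stop("empty-structure error: no voxels carry the requested label",
         call. = FALSE)
  res <- cpp_marching_tets(as.logical(mask), dim(mask))
  verts <- sweep(sweep(res$vertices, 2, spacing, "*"), 2, origin, "+")
  mesh <- structure_mesh(verts, res$triangles, descr)
  if (smoothing_iterations > 0)
    mesh <- smooth_mesh(mesh, smoothing_iterations, lambda = 0.5)
  mesh
}

#' Write a mesh to STL
#'
#' Binary STL is the printer-facing format: an 80-byte header, a 4-byte
#' little-endian triangle count, then 50 bytes per triangle (normal, three
#' vertices as float32, 2-byte attribute). Facet normals are recomputed from
#' the vertex winding. Units are mm.
#'
#' @param mesh a `structure_mesh`.
#' @param path output file.
#' @param format `"binary"` or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  v <- mesh$vertices; t <- mesh$triangles
  a <- v[t[, 1], , drop = FALSE]; b <- v[t[, 2], , drop = FALSE]
  c_ <- v[t[, 3], , drop = FALSE]
  u <- b - a; w <- c_ - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "neuroprint binary STL (mm)"))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(t)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(t))) {
      writeBin(as.numeric(c(n[i, ], a[i, ], b[i, ], c_[i, ])), con, size = 4,
               endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    nm <- if (!is.null(mesh$descriptor)) mesh$descriptor$name else "mesh"
    writeLines(sprintf("solid %s", nm), con)
    for (i in seq_len(nrow(t))) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[i,1], n[i,2], n[i,3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g", a[i,1], a[i,2], a[i,3]),
                   sprintf("      vertex %.9g %.9g %.9g", b[i,1], b[i,2], b[i,3]),
                   sprintf("      vertex %.9g %.9g %.9g", c_[i,1], c_[i,2], c_[i,3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", nm), con)
  }
  invisible(path)
}

#' Read a binary STL file
#'
#' @param path binary STL file.
#' @return A `structure_mesh` (vertices welded by exact coordinate match).
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nt <- readBin(con, "integer", size = 4, endian = "little")
  tri <- matrix(0L, nt, 3)
  pts <- matrix(0, 3 * nt, 3)
  for (i in seq_len(nt)) {
    rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "raw", n = 2)
    pts[3 * i - 2, ] <- rec[4:6]
    pts[3 * i - 1, ] <- rec[7:9]
    pts[3 * i, ] <- rec[10:12]
  }
  key <- apply(pts, 1, paste, collapse = "/")
  uid <- match(key, unique(key))
  verts <- pts[!duplicated(key), , drop = FALSE]
  tri <- matrix(uid, ncol = 3, byrow = TRUE)
  structure_mesh(verts, tri)
}

# per-axis (Chebyshev-in-mm) or Euclidean dilation of a mask by `radius_mm`
#' Dilate a binary mask
#'
#' @param mask logical 3-D array.
#' @param radius_mm dilation radius in mm.
#' @param spacing voxel spacing in mm.
#' @param metric `"chebyshev"` (per-axis box kernel with radius
#'   `floor(radius_mm / spacing)` voxels) or `"euclidean"`
#'   (distance-transform ball).
#' @return The dilated logical mask.
#' @export
dilate_mask <- function(mask, radius_mm, spacing,
                        metric = c("chebyshev", "euclidean")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    d2 <- array(cpp_edt_sq(as.logical(mask), dim(mask), spacing), dim(mask))
    return(d2 <= radius_mm^2 + 1e-9)
  }
  out <- mask
  for (ax in 1:3) {
    r <- floor(radius_mm / spacing[ax] + 1e-9)
    if (r < 1) next
    acc <- out
    for (s in seq_len(r)) {
      acc <- acc | .shift_pad_false(out, ax, s) | .shift_pad_false(out, ax, -s)
    }
    out <- acc
  }
  out
}

.shift_pad_false <- function(a, axis, by) {
  dims <- dim(a)
  out <- array(FALSE, dims)
  n <- dims[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  idx <- function(x, i) switch(axis, x[i, , , drop = FALSE],
                               x[, i, , drop = FALSE], x[, , i, drop = FALSE])
  if (axis == 1) out[dst, , ] <- a[src, , ]
  else if (axis == 2) out[, dst, ] <- a[, src, ]
  else out[, , dst] <- a[, , src]
  out
}

#' Generate an external two-part mold
#'
#' The mold region is the brain mask dilated by `wall_thickness` mm minus the
#' brain mask itself, split into two parts by the plane through the mask
#' centroid orthogonal to `split_axis`, each part meshed watertight. The
#' voxel partition is exact: `|dilated| = |brain| + |part1| + |part2|`.
#'
#' @param brain_mask nonempty logical mask.
#' @param wall_thickness mm; must be at least one voxel.
#' @param split_axis `"x"`, `"y"` or `"z"`.
#' @param spacing,origin grid geometry.
#' @param metric dilation metric: `"chebyshev"` (per-axis mm radii; a box
#'   kernel) or `"euclidean"` (distance-transform ball).
#' @return List with `part1`, `part2` ([structure_mesh()]s), the logical
#'   `mold_mask`, and `counts` (dilated/brain/part voxel counts).
#' @export
generate_mold <- function(brain_mask, wall_thickness, split_axis = c("x", "y", "z"),
                          spacing = c(1, 1, 1), origin = c(0, 0, 0),
                          metric = c("chebyshev", "euclidean")) {
  split_axis <- match.arg(split_axis)
  metric <- match.arg(metric)
  if (!any(brain_mask)) stop("brain mask is empty", call. = FALSE)
  if (wall_thickness < min(spacing))
    stop("parameter error: wall thinner than one voxel", call. = FALSE)
  dil <- dilate_mask(brain_mask, wall_thickness, spacing, metric)
  mold <- dil & !brain_mask
  ax <- match(split_axis, c("x", "y", "z"))
  idx <- which(brain_mask, arr.ind = TRUE)
  centroid <- mean(idx[, ax])
  coord <- slice.index(mold, ax)
  m1 <- mold & coord <= centroid
  m2 <- mold & coord > centroid
  p1 <- extract_surface(mask = m1, spacing = spacing, origin = origin)
  p2 <- extract_surface(mask = m2, spacing = spacing, origin = origin)
  list(part1 = p1, part2 = p2, mold_mask = mold,
       counts = c(dilated = sum(dil), brain = sum(brain_mask),
                  part1 = sum(m1), part2 = sum(m2)))
}
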