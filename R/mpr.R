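# Multiplanar reconstruction: resample arbitrary planes through the volume
# and overlay segmentation contours so the cut can be verified visually
# against the source image.

#' Define an oblique resampling plane
#'
#' The slice grid is spanned by `u_axis` and `normal x u_axis`: sample
#' `(i, j)` sits at `origin + i * sample_spacing * u_axis +
#' j * sample_spacing * (normal x u_axis)` (0-based `i`, `j`).
#'
#' @param origin mm point on the plane.
#' @param normal unit plane normal.
#' @param u_axis unit in-plane direction orthogonal to `normal`.
#' @param extent `(width, height)` in mm.
#' @param sample_spacing sample step in mm, > 0; a scalar, or a length-2
#'   vector giving separate steps along `u_axis` and `v_axis`.
#' @return An object of class `oblique_plane`.
#' @export
oblique_plane <- function(origin, normal, u_axis, extent, sample_spacing = 1) {
  normal <- as.numeric(normal); u_axis <- as.numeric(u_axis)
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-6 || abs(sqrt(sum(u_axis^2)) - 1) > 1e-6)
    stop("normal and u_axis must be unit vectors (within 1e-6)", call. = FALSE)
  if (abs(sum(normal * u_axis)) > 1e-6)
    stop("u_axis must be orthogonal to normal (within 1e-6)", call. = FALSE)
  if (any(sample_spacing <= 0)) stop("sample_spacing must be > 0", call. = FALSE)
  sample_spacing <- rep(as.numeric(sample_spacing), length.out = 2)
  extent <- as.numeric(extent)
  if (length(extent) != 2 || any(extent <= 0))
    stop("extent must be two positive lengths (mm)", call. = FALSE)
  structure(list(origin = as.numeric(origin), normal = normal, u_axis = u_axis,
                 v_axis = c(normal[2] * u_axis[3] - normal[3] * u_axis[2],
                            normal[3] * u_axis[1] - normal[1] * u_axis[3],
                            normal[1] * u_axis[2] - normal[2] * u_axis[1]),
                 extent = extent, sample_spacing = sample_spacing),
            class = "oblique_plane")
}

# sample grid (i, j) of a plane in world mm; returns list(points, ni, nj)
.plane_grid <- function(plane) {
  ss <- rep(plane$sample_spacing, length.out = 2)
  ni <- floor(plane$extent[1] / ss[1] + 1e-9) + 1L
  nj <- floor(plane$extent[2] / ss[2] + 1e-9) + 1L
  ij <- expand.grid(i = 0:(ni - 1L), j = 0:(nj - 1L))
  pts <- t(plane$origin +
             outer(plane$u_axis, ij$i * ss[1]) +
             outer(plane$v_axis, ij$j * ss[2]))
  list(points = pts, ni = ni, nj = nj)
}

#' Extract an oblique slice
#'
#' @param vol an [image_volume()].
#' @param plane an [oblique_plane()].
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param fill value used outside the volume support.
#' @return 2-D numeric matrix (`ni x nj`).
#' @export
extract_oblique_slice <- function(vol, plane,
                                  interpolation = c("trilinear", "nearest"),
                                  fill = 0) {
  stopifnot(is_image_volume(vol), inherits(plane, "oblique_plane"))
  interpolation <- match.arg(interpolation)
  g <- .plane_grid(plane)
  vals <- sample_world(vol, g$points, interpolation = interpolation, fill = fill)
  matrix(vals, g$ni, g$nj)
}

#' Axis-aligned plane helper
#'
#' Convenience constructor for the plane that reproduces stored slice `k`
#' (0-based) of an axis-aligned volume exactly.
#'
#' @param vol an [image_volume()].
#' @param axis slice axis `"x"`, `"y"` or `"z"`.
#' @param index 0-based slice index.
#' @return An [oblique_plane()].
#' @export
axis_plane <- function(vol, axis = c("z", "y", "x"), index) {
  axis <- match.arg(axis)
  dims <- dim(vol$data)
  ax <- .plane_axes(axis)
  normal <- vol$direction[, ax$w]
  u <- vol$direction[, ax$u]
  # orient the normal so the implied v axis (normal x u) matches the stored
  # second in-plane axis rather than its negation
  v_want <- vol$direction[, ax$v]
  v_got <- c(normal[2] * u[3] - normal[3] * u[2],
             normal[3] * u[1] - normal[1] * u[3],
             normal[1] * u[2] - normal[2] * u[1])
  if (sum(v_got * v_want) < 0) normal <- -normal
  origin <- vol$origin + vol$direction[, ax$w] * index * vol$spacing[ax$w]
  oblique_plane(origin, normal = normal, u_axis = u,
                extent = c((dims[ax$u] - 1) * vol$spacing[ax$u],
                           (dims[ax$v] - 1) * vol$spacing[ax$v]),
                sample_spacing = c(vol$spacing[ax$u], vol$spacing[ax$v]))
}

# Marching squares at level 0.5 on a binary matrix; returns list of closed
# polylines (n x 2, 0-based cell coordinates). Segments are generated per
# 2x2 cell and chained into loops.
#' Trace binary contours with 2-D marching squares
#'
#' @param bin logical matrix.
#' @return List of closed polylines (`n x 2`, 0-based pixel coordinates;
#'   first row equals last row). Empty list when `bin` has no TRUE pixel.
#' @export
marching_squares <- function(bin) {
  ni <- nrow(bin); nj <- ncol(bin)
  pad <- matrix(FALSE, ni + 2, nj + 2)
  pad[2:(ni + 1), 2:(nj + 1)] <- bin
  segs <- list()
  # edge midpoint coordinates relative to cell corner (i, j):
  # top (between (i,j) and (i+1,j)), right, bottom, left in padded space
  for (i in 1:(ni + 1)) {
    for (j in 1:(nj + 1)) {
      a <- pad[i, j]; b <- pad[i + 1, j]; c_ <- pad[i + 1, j + 1]; d <- pad[i, j + 1]
      code <- a + 2 * b + 4 * c_ + 8 * d
      if (code == 0 || code == 15) next
      # midpoints (in padded coords, cell corner = (i, j))
      mT <- c(i + 0.5, j);     mR <- c(i + 1, j + 0.5)
      mB <- c(i + 0.5, j + 1); mL <- c(i, j + 0.5)
      add <- function(p, q) segs[[length(segs) + 1]] <<- c(p, q)
      switch(as.character(code),
        "1"  = add(mL, mT), "2"  = add(mT, mR), "3"  = add(mL, mR),
        "4"  = add(mR, mB), "5"  = { add(mL, mT); add(mR, mB) },
        "6"  = add(mT, mB), "7"  = add(mL, mB),
        "8"  = add(mB, mL), "9"  = add(mB, mT),
        "10" = { add(mT, mR); add(mB, mL) },
        "11" = add(mB, mR), "12" = add(mR, mL), "13" = add(mR, mT),
        "14" = add(mT, mL))
    }
  }
  if (length(segs) == 0) return(list())
  sm <- do.call(rbind, segs)
  key1 <- sprintf("%.1f_%.1f", sm[, 1], sm[, 2])
  key2 <- sprintf("%.1f_%.1f", sm[, 3], sm[, 4])
  # direction-agnostic chaining: follow whichever endpoint matches
  lookup <- split(rep(seq_len(nrow(sm)), 2), c(key1, key2))
  used <- rep(FALSE, nrow(sm))
  loops <- list()
  for (s0 in seq_len(nrow(sm))) {
    if (used[s0]) next
    pts <- list(sm[s0, 1:2], sm[s0, 3:4])
    used[s0] <- TRUE
    repeat {
      cur <- pts[[length(pts)]]
      k <- sprintf("%.1f_%.1f", cur[1], cur[2])
      nxt <- lookup[[k]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0) break
      e <- nxt[1]
      used[e] <- TRUE
      p1 <- sm[e, 1:2]; p2 <- sm[e, 3:4]
      nextp <- if (all(abs(p1 - cur) < 1e-9)) p2 else p1
      pts[[length(pts) + 1]] <- nextp
      if (all(abs(nextp - pts[[1]]) < 1e-9)) break
    }
    loop <- do.call(rbind, pts) - 2  # un-pad to 0-based pixel coordinates
    loops[[length(loops) + 1]] <- loop
  }
  loops
}

#' Overlay label contours on an extracted slice
#'
#' Each label is resampled on the plane with nearest-neighbour interpolation
#' (labels must not blend) and its boundary traced by 2-D marching squares
#' at level 0.5. Labels absent from the plane yield no contour.
#'
#' @param slice_grid matrix from [extract_oblique_slice()].
#' @param plane the [oblique_plane()] that produced it.
#' @param labelmap a [label_map()] congruent with the source volume.
#' @param fill_value scalar recorded for out-of-volume samples.
#' @return An `mpr_slice`: `image`, `overlays` (per-label list of polylines
#'   in slice coordinates) and `fill_value`.
#' @export
overlay_labels <- function(slice_grid, plane, labelmap, fill_value = 0) {
  stopifnot(inherits(plane, "oblique_plane"), inherits(labelmap, "label_map"))
  lvol <- image_volume(labelmap$labels + 0, spacing = labelmap$spacing,
                       origin = labelmap$origin, direction = labelmap$direction)
  g <- .plane_grid(plane)
  lab <- matrix(sample_world(lvol, g$points, interpolation = "nearest",
                             fill = 0), g$ni, g$nj)
  overlays <- list()
  for (lb in labelmap$structures$label) {
    bin <- lab == lb
    overlays[[as.character(lb)]] <- if (any(bin)) marching_squares(bin) else list()
  }
  structure(list(image = slice_grid, overlays = overlays,
                 fill_value = fill_value),
            class = "mpr_slice")
}

#' Render an MPR slice with contour overlays to PNG
#'
#' Grayscale windowed image with contours rasterized in each structure's
#' color.
#'
#' @param mpr an `mpr_slice` from [overlay_labels()].
#' @param labelmap the [label_map()] supplying structure colors.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_mpr_png <- function(mpr, labelmap, path) {
  img <- mpr$image
  rng <- range(img)
  gray <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  ni <- nrow(gray); nj <- ncol(gray)
  rgb_arr <- array(0, c(nj, ni, 3))                  # png rows = y
  for (ch in 1:3) rgb_arr[, , ch] <- t(gray)
  for (lb in names(mpr$overlays)) {
    s <- labelmap$structures[labelmap$structures$label == as.integer(lb), ]
    col <- if (nrow(s)) c(s$r, s$g, s$b) else c(1, 0, 0)
    for (loop in mpr$overlays[[lb]]) {
      px <- unique(round(loop))
      keep <- px[, 1] >= 0 & px[, 1] < ni & px[, 2] >= 0 & px[, 2] < nj
      px <- px[keep, , drop = FALSE]
      for (ch in 1:3) rgb_arr[cbind(px[, 2] + 1, px[, 1] + 1, ch)] <- col[ch]
    }
  }
  png::writePNG(rgb_arr, path)
  invisible(path)
}
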