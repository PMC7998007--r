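#' @useDynLib neuroprint, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm sd setNames
#' @importFrom utils head tail
NULL

#' Construct an MR image volume
#'
#' An `image_volume` is a 3-D scalar intensity grid together with its physical
#' geometry: voxel spacing in mm, the physical (LPS) coordinate of voxel
#' `(0,0,0)`, and a 3x3 orthonormal direction matrix whose columns are the
#' physical directions of the three array axes. Voxel centres sit at
#' `origin + direction %*% (index * spacing)` with 0-based indices, x fastest.
#'
#' @param data 3-D numeric array of intensities (stored as double).
#' @param spacing numeric length-3, voxel spacing in mm, all > 0.
#' @param origin numeric length-3, physical position of voxel (0,0,0) in mm.
#' @param direction 3x3 orthonormal axis-cosine matrix (columns = axes).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("every axis must be nonempty", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)", call. = FALSE)
  if (!all(is.finite(data)))
    stop("intensities must all be finite", call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  direction <- matrix(as.numeric(direction), 3, 3)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("`direction` must be orthonormal within 1e-6", call. = FALSE)
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.3g, %.3g, %.3g) mm; intensity range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

is_image_volume <- function(x) inherits(x, "image_volume")

#' Bundle co-registered MR sequences
#'
#' Groups the contrast-enhanced T1 volume (the segmentation substrate) with
#' optional T2 and FLAIR volumes acquired on the same grid. All present
#' volumes must share shape, spacing, origin and direction.
#'
#' @param t1ce required `image_volume`.
#' @param t2,flair optional `image_volume`s on the identical grid.
#' @return An object of class `sequence_bundle`.
#' @export
sequence_bundle <- function(t1ce, t2 = NULL, flair = NULL) {
  stopifnot(is_image_volume(t1ce))
  same_grid <- function(a, b) {
    identical(dim(a$data), dim(b$data)) &&
      max(abs(a$spacing - b$spacing)) < 1e-9 &&
      max(abs(a$origin - b$origin)) < 1e-9 &&
      max(abs(a$direction - b$direction)) < 1e-9
  }
  for (v in list(t2, flair)) {
    if (!is.null(v)) {
      if (!is_image_volume(v)) stop("sequences must be image_volume objects", call. = FALSE)
      if (!same_grid(t1ce, v))
        stop("all sequences must share grid shape, spacing, origin and direction",
             call. = FALSE)
    }
  }
  structure(list(t1ce = t1ce, t2 = t2, flair = flair), class = "sequence_bundle")
}

# RAS (NIfTI world) <-> LPS (internal/DICOM world) conversion
.ras_flip <- diag(c(-1, -1, 1))

#' Read an MR volume from disk
#'
#' Reads either a NIfTI file or a DICOM series directory into the canonical
#' internal representation (LPS world coordinates, axis-aligned grid, slices
#' ascending along the slice normal). Non-axis-aligned input is resampled to
#' canonical axes at read time.
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @param format `"nifti"` or `"dicom_series"`.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, format = c("nifti", "dicom_series")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("path does not exist: %s", path), call. = FALSE)
  vol <- switch(format,
    nifti = read_nifti_volume(path),
    dicom_series = read_dicom_series(path))
  canonicalize_volume(vol)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim(arr))   # drop image-class attributes
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1, drop = TRUE]
  xf <- RNifti::xform(img)              # index -> RAS mm, 0-based indices
  m <- unclass(xf)[1:3, , drop = FALSE]
  spacing <- sqrt(colSums(m[, 1:3, drop = FALSE]^2))
  dir_ras <- sweep(m[, 1:3, drop = FALSE], 2, spacing, "/")
  dir_lps <- .ras_flip %*% dir_ras
  origin_lps <- as.numeric(.ras_flip %*% m[, 4])
  image_volume(arr, spacing = spacing, origin = origin_lps, direction = dir_lps)
}

#' Write a volume to NIfTI
#'
#' Data are written as 64-bit floats and the header in NIfTI-2 form (double
#' precision geometry fields) so a write/read round trip is exact. The
#' internal LPS geometry is converted to the NIfTI RAS convention.
#'
#' @param vol an [image_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_image_volume(vol))
  m <- .ras_flip %*% (vol$direction %*% diag(vol$spacing))
  origin_ras <- as.numeric(.ras_flip %*% vol$origin)
  xf <- rbind(cbind(m, origin_ras), c(0, 0, 0, 1))
  arr <- vol$data
  attr(arr, "pixdim") <- vol$spacing   # must precede asNifti; fixed afterwards
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::qform(img) <- structure(xf, code = 2L)
  # NIfTI-2: double-precision header fields, so geometry round trips exactly
  RNifti::writeNifti(img, path, datatype = "double", version = 2)
  invisible(path)
}

# Reorient a volume whose direction matrix is an axis permutation/flip to the
# identity; resample trilinearly if genuinely oblique.
canonicalize_volume <- function(vol) {
  d <- vol$direction
  if (max(abs(d - diag(3))) < 1e-6) return(vol)
  rd <- round(d)
  if (max(abs(d - rd)) < 1e-6 && all(colSums(abs(rd)) == 1) && all(rowSums(abs(rd)) == 1)) {
    # permutation with flips: relocate axes without interpolation
    perm <- apply(abs(rd), 2, which.max)   # world axis served by each array axis
    inv <- order(perm)
    arr <- aperm(vol$data, inv)
    spacing <- vol$spacing[inv]
    sign_ax <- rd[cbind(perm, seq_len(3))][inv]
    for (ax in 1:3) {
      if (sign_ax[ax] < 0) {
        idx <- rev(seq_len(dim(arr)[ax]))
        arr <- switch(ax, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
      }
    }
    # with identity direction the origin is the minimal world corner per axis
    dims0 <- dim(vol$data)
    corners_idx <- as.matrix(expand.grid(c(0, dims0[1] - 1), c(0, dims0[2] - 1),
                                         c(0, dims0[3] - 1)))
    world <- t(vol$direction %*% (t(corners_idx) * vol$spacing) + vol$origin)
    origin <- apply(world, 2, min)
    return(image_volume(arr, spacing = spacing, origin = origin, direction = diag(3)))
  }
  # oblique: resample onto an axis-aligned grid covering the volume extent
  dims <- dim(vol$data)
  corners_idx <- as.matrix(expand.grid(c(0, dims[1] - 1), c(0, dims[2] - 1),
                                       c(0, dims[3] - 1)))
  world <- t(vol$direction %*% (t(corners_idx) * vol$spacing) + vol$origin)
  sp <- rep(min(vol$spacing), 3)
  lo <- apply(world, 2, min); hi <- apply(world, 2, max)
  n <- pmax(2L, as.integer(floor((hi - lo) / sp)) + 1L)
  grid <- as.matrix(expand.grid(x = lo[1] + sp[1] * (seq_len(n[1]) - 1),
                                y = lo[2] + sp[2] * (seq_len(n[2]) - 1),
                                z = lo[3] + sp[3] * (seq_len(n[3]) - 1)))
  vals <- sample_world(vol, grid, interpolation = "trilinear", fill = 0)
  image_volume(array(vals, n), spacing = sp, origin = lo, direction = diag(3))
}

#' Denoise a volume
#'
#' Preprocessing step applied before segmentation. Two methods are offered:
#' a median filter over the 6-neighbour cross (arm length `radius`, replicate
#' padding at faces), and Perona-Malik anisotropic diffusion with exponential
#' conduction, which smooths homogeneous regions while preserving the
#' intensity edges the boundary energies depend on.
#'
#' @param vol an [image_volume()].
#' @param method `"anisotropic_diffusion"` (default) or `"median"`.
#' @param radius median arm length in voxels (>= 1).
#' @param iterations diffusion iterations (>= 1).
#' @param kappa diffusion conduction scale in intensity units.
#' @param dt diffusion time step; must be <= 1/6 for stability.
#' @return A denoised [image_volume()] on the same grid.
#' @export
denoise_volume <- function(vol, method = c("anisotropic_diffusion", "median"),
                           radius = 1L, iterations = 5L, kappa = 30,
                           dt = 0.1) {
  stopifnot(is_image_volume(vol))
  method <- match.arg(method)
  if (method == "median") {
    if (radius < 1) stop("median `radius` must be >= 1", call. = FALSE)
    out <- median_filter(vol$data, radius = radius)
  } else {
    if (iterations < 1) stop("diffusion `iterations` must be >= 1", call. = FALSE)
    if (kappa <= 0 || dt <= 0 || dt > 1 / 6)
      stop("require kappa > 0 and 0 < dt <= 1/6", call. = FALSE)
    out <- anisotropic_diffusion(vol$data, iterations, kappa, dt)
  }
  image_volume(out, spacing = vol$spacing, origin = vol$origin,
               direction = vol$direction)
}

#' Median filter on a raw array (6-neighbour cross)
#'
#' @param arr 3-D numeric array.
#' @param radius arm length of the cross in voxels.
#' @return Filtered array of the same shape.
#' @export
median_filter <- function(arr, radius = 1L) {
  arr <- as.array(arr)
  stopifnot(length(dim(arr)) == 3L, radius >= 1)
  out <- cpp_median_cross(as.numeric(arr), dim(arr), as.integer(radius))
  array(out, dim(arr))
}

# shift array by one voxel along `axis` with replicate boundary
.shift1 <- function(a, axis, by) {
  n <- dim(a)[axis]
  idx <- pmin(pmax(seq_len(n) + by, 1L), n)
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

anisotropic_diffusion <- function(arr, iterations, kappa, dt) {
  u <- arr
  for (it in seq_len(iterations)) {
    acc <- array(0, dim(u))
    for (axis in 1:3) {
      for (s in c(-1L, 1L)) {
        g <- .shift1(u, axis, s) - u
        acc <- acc + exp(-(g / kappa)^2) * g
      }
    }
    u <- u + dt * acc
  }
  u
}

#' Resample a volume to a new spacing
#'
#' Preserves physical extent within one voxel. Label-type data must use
#' nearest-neighbour interpolation so the value set is preserved.
#'
#' @param vol an [image_volume()].
#' @param target_spacing length-3 spacing in mm, all > 0.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return Resampled [image_volume()].
#' @export
resample_volume <- function(vol, target_spacing,
                            interpolation = c("trilinear", "nearest")) {
  stopifnot(is_image_volume(vol))
  interpolation <- match.arg(interpolation)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0))
    stop("`target_spacing` must be 3 positive numbers", call. = FALSE)
  if (max(abs(target_spacing - vol$spacing)) < 1e-12) return(vol)
  dims <- dim(vol$data)
  extent <- (dims - 1) * vol$spacing
  n <- pmax(2L, as.integer(round(extent / target_spacing)) + 1L)
  grid <- as.matrix(expand.grid(
    x = target_spacing[1] * (seq_len(n[1]) - 1),
    y = target_spacing[2] * (seq_len(n[2]) - 1),
    z = target_spacing[3] * (seq_len(n[3]) - 1)))
  world <- t(vol$direction %*% t(grid) + vol$origin)
  vals <- sample_world(vol, world, interpolation = interpolation, fill = 0)
  image_volume(array(vals, n), spacing = target_spacing, origin = vol$origin,
               direction = vol$direction)
}

# Sample a volume at arbitrary world (LPS mm) points. Returns `fill` outside
# the support. Used by resampling, canonicalization and MPR.
sample_world <- function(vol, points, interpolation = c("trilinear", "nearest"),
                         fill = 0) {
  interpolation <- match.arg(interpolation)
  dims <- dim(vol$data)
  rel <- t(vol$direction) %*% (t(points) - vol$origin)
  ix <- rel[1, ] / vol$spacing[1]
  iy <- rel[2, ] / vol$spacing[2]
  iz <- rel[3, ] / vol$spacing[3]
  n <- length(ix)
  out <- rep(as.numeric(fill), n)
  if (interpolation == "nearest") {
    jx <- round(ix); jy <- round(iy); jz <- round(iz)
    ok <- jx >= 0 & jy >= 0 & jz >= 0 & jx <= dims[1] - 1 & jy <= dims[2] - 1 &
      jz <= dims[3] - 1
    out[ok] <- vol$data[cbind(jx[ok] + 1, jy[ok] + 1, jz[ok] + 1)]
    return(out)
  }
  ok <- ix >= 0 & iy >= 0 & iz >= 0 & ix <= dims[1] - 1 & iy <= dims[2] - 1 &
    iz <= dims[3] - 1
  if (!any(ok)) return(out)
  x <- ix[ok]; y <- iy[ok]; z <- iz[ok]
  x0 <- pmax(pmin(floor(x), dims[1] - 2), 0); y0 <- pmax(pmin(floor(y), dims[2] - 2), 0)
  z0 <- pmax(pmin(floor(z), dims[3] - 2), 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  g <- function(dx, dy, dz)
    vol$data[cbind(pmin(x0 + dx, dims[1] - 1) + 1,
                   pmin(y0 + dy, dims[2] - 1) + 1,
                   pmin(z0 + dz, dims[3] - 1) + 1)]
  v <- g(0,0,0) * (1-fx)*(1-fy)*(1-fz) + g(1,0,0) * fx*(1-fy)*(1-fz) +
       g(0,1,0) * (1-fx)*fy*(1-fz)     + g(1,1,0) * fx*fy*(1-fz) +
       g(0,0,1) * (1-fx)*(1-fy)*fz     + g(1,0,1) * fx*(1-fy)*fz +
       g(0,1,1) * (1-fx)*fy*fz         + g(1,1,1) * fx*fy*fz
  out[ok] <- v
  out
}
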