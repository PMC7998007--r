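# Synthetic MR-like phantoms with ground truth: a brain-shaped envelope with
# sinusoidal radial undulation (gyri-like surface non-convexity), a
# hyperintense tumor, paired ventricles and a deep nucleus, on a 1-mm
# isotropic grid with additive Gaussian noise. Every downstream module is
# testable against these volumes without any patient data.

#' Phantom specification
#'
#' Defaults describe the nominal study volume: 64^3 voxels at 1.0 mm
#' isotropic spacing, class mean intensities separated from their neighbours
#' by at least three noise standard deviations.
#'
#' @param seed integer RNG seed; the phantom is bit-reproducible per seed.
#' @param shape grid shape, default `c(64, 64, 64)`.
#' @param spacing mm, default `c(1, 1, 1)`.
#' @param noise_sigma additive Gaussian noise SD in intensity units.
#' @param brain_radius mean envelope radius, mm.
#' @param gyri_amplitude,gyri_frequency radial sinusoid of the envelope.
#' @param tumor list: `center` offset from the grid centre (mm), `radius`
#'   (mm), `mean` intensity.
#' @param intensities named means for `background`, `parenchyma`,
#'   `ventricle`, `nucleus` (tumor mean lives in `tumor$mean`).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L, shape = c(64, 64, 64),
                         spacing = c(1, 1, 1), noise_sigma = 5,
                         brain_radius = 26, gyri_amplitude = 2,
                         gyri_frequency = 8,
                         tumor = list(center = c(9, 6, 2), radius = 9,
                                      mean = 160),
                         intensities = c(background = 10, parenchyma = 100,
                                         ventricle = 40, nucleus = 130)) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (brain_radius + gyri_amplitude > min((shape - 1) * spacing) / 2)
    stop("specification error: brain envelope exceeds the grid", call. = FALSE)
  if (sqrt(sum(tumor$center^2)) + tumor$radius >
      brain_radius - gyri_amplitude)
    stop("specification error: tumor exceeds the brain envelope", call. = FALSE)
  structure(list(seed = as.integer(seed), shape = as.integer(shape),
                 spacing = as.numeric(spacing), noise_sigma = noise_sigma,
                 brain_radius = brain_radius,
                 gyri_amplitude = gyri_amplitude,
                 gyri_frequency = gyri_frequency,
                 tumor = tumor, intensities = intensities),
            class = "phantom_spec")
}

# run fn with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Default phantom structure descriptors
#'
#' Tumor, ventricles, deep nucleus and parenchyma with the default priority
#' order (tumor wins overlaps, parenchyma loses them).
#'
#' @return A descriptor `data.frame`.
#' @export
phantom_structures <- function() {
  rbind(structure_descriptor(1, "tumor", c(0.9, 0.3, 0.3, 1), 0, priority = 1),
        structure_descriptor(2, "ventricles", c(0.8, 0.8, 0.8, 1), 0.2, priority = 2),
        structure_descriptor(3, "nucleus", c(0.6, 0.8, 0.4, 1), 0.2, priority = 3),
        structure_descriptor(4, "parenchyma", c(0.95, 0.9, 0.85, 1), 0.8, priority = 4))
}

#' Generate a synthetic MR phantom
#'
#' Deterministic for a fixed spec seed. Ground-truth labels are assigned by
#' priority, hence pairwise disjoint by construction. The bundle carries
#' T1ce (segmentation substrate) plus T2 and FLAIR volumes with different
#' class contrasts on the identical grid.
#'
#' @param spec a [phantom_spec()].
#' @return List with `bundle` ([sequence_bundle()]) and `truth`
#'   ([label_map()]).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$shape
  ctr <- (dims - 1) / 2 * spec$spacing
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spec$spacing[a] - ctr[a])
  X <- array(rep(ax[[1]], times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ax[[2]], each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(ax[[3]], each = dims[1] * dims[2]), dims)

  r <- sqrt(X^2 + Y^2 + Z^2)
  theta <- acos(ifelse(r > 0, Z / pmax(r, 1e-12), 1))
  phi <- atan2(Y, X)
  renv <- spec$brain_radius +
    spec$gyri_amplitude * sin(spec$gyri_frequency * theta) *
    cos(spec$gyri_frequency * phi)
  brain <- r <= renv

  ball <- function(center, radius) {
    (X - center[1])^2 + (Y - center[2])^2 + (Z - center[3])^2 <= radius^2
  }
  ellipsoid <- function(center, semi) {
    ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
      ((Z - center[3]) / semi[3])^2 <= 1
  }
  tumor <- ball(spec$tumor$center, spec$tumor$radius)
  vent <- ellipsoid(c(-6, 6, 0), c(3, 5, 7)) | ellipsoid(c(-6, -6, 0), c(3, 5, 7))
  nucl <- ball(c(-2, 0, -10), 4)

  labels <- array(0L, dims)
  labels[brain] <- 4L           # parenchyma
  labels[brain & nucl] <- 3L
  labels[brain & vent] <- 2L
  labels[brain & tumor] <- 1L

  mk_vol <- function(means) {
    I <- array(means[["background"]], dims)
    I[labels == 4L] <- means[["parenchyma"]]
    I[labels == 2L] <- means[["ventricle"]]
    I[labels == 3L] <- means[["nucleus"]]
    I[labels == 1L] <- means[["tumor"]]
    if (spec$noise_sigma > 0)
      I <- I + array(rnorm(prod(dims), 0, spec$noise_sigma), dims)
    image_volume(I, spacing = spec$spacing)
  }

  m1 <- c(spec$intensities, tumor = spec$tumor$mean)
  m2 <- c(background = 10, parenchyma = 90, ventricle = 170, nucleus = 110,
          tumor = 140)
  m3 <- c(background = 10, parenchyma = 110, ventricle = 30, nucleus = 120,
          tumor = 150)
  vols <- .with_seed(spec$seed, function() {
    list(t1ce = mk_vol(m1), t2 = mk_vol(m2), flair = mk_vol(m3))
  })

  truth <- label_map(labels, phantom_structures(), spacing = spec$spacing)
  list(bundle = sequence_bundle(vols$t1ce, vols$t2, vols$flair), truth = truth)
}

#' Auto-place foreground/background seeds for a phantom structure
#'
#' Emulates the interactive strokes: foreground freedraw discs deep inside
#' the structure on three slices, background strokes on full slices beyond
#' the structure's axial extent plus a surrounding ring on the central
#' slice.
#'
#' @param truth ground-truth [label_map()].
#' @param structure_id label to seed.
#' @param interior_mm minimum interior depth for foreground pixels.
#' @param gap_mm,band_mm background ring: distance band
#'   `[gap_mm, gap_mm + band_mm]` from the structure.
#' @return List of [seed_geometry()] objects.
#' @export
auto_seed_geometries <- function(truth, structure_id, interior_mm = 2,
                                 gap_mm = 4, band_mm = 2) {
  stopifnot(inherits(truth, "label_map"))
  mask <- truth$labels == structure_id
  if (!any(mask)) stop("structure absent from the label map", call. = FALSE)
  dims <- dim(mask)
  d_in <- sqrt(array(cpp_edt_sq(!mask, dims, truth$spacing), dims))   # depth inside
  d_out <- sqrt(array(cpp_edt_sq(mask, dims, truth$spacing), dims))   # distance to structure
  zs <- which(apply(mask, 3, any))
  zpick <- unique(round(stats::quantile(zs, c(0.3, 0.5, 0.7))))
  geoms <- list()
  mkfree <- function(px, z, role) {
    seed_geometry("freedraw", axis = "z", index = z - 1L, vertices = px,
                  role = role, structure_id = structure_id)
  }
  for (z in zpick) {
    fg_px <- which(mask[, , z] & d_in[, , z] >= interior_mm, arr.ind = TRUE) - 1L
    if (nrow(fg_px) > 0) geoms[[length(geoms) + 1]] <- mkfree(fg_px, z, "foreground")
  }
  zc <- round(stats::median(zs))
  ring <- which(d_out[, , zc] >= gap_mm & d_out[, , zc] <= gap_mm + band_mm,
                arr.ind = TRUE) - 1L
  if (nrow(ring) > 0) geoms[[length(geoms) + 1]] <- mkfree(ring, zc, "background")
  zlo <- max(1L, min(zs) - as.integer(ceiling(gap_mm / truth$spacing[3])))
  zhi <- min(dims[3], max(zs) + as.integer(ceiling(gap_mm / truth$spacing[3])))
  for (z in c(zlo, zhi)) {
    bg_px <- which(!mask[, , z], arr.ind = TRUE) - 1L
    geoms[[length(geoms) + 1]] <- mkfree(bg_px, z, "background")
  }
  geoms
}

#' Generate a craniotomy mask pair with target overlap and size change
#'
#' Builds two rectangles of equal height on a 360 x 160 raster whose widths
#' and horizontal shift realize the requested Jaccard overlap and percent
#' size change within 0.02 / 1 percentage point. Deterministic per seed
#' (the seed only jitters placement).
#'
#' @param seed integer.
#' @param target_overlap Jaccard index in `[0, 1]`.
#' @param target_size_change percent change of the second mask's area
#'   relative to the first, >= 0.
#' @return List of two logical matrices `mr` and `model`; achieved values
#'   as attributes `overlap` and `size_change`.
#' @export
generate_craniotomy_pair <- function(seed, target_overlap,
                                     target_size_change = 0) {
  if (target_overlap < 0 || target_overlap > 1)
    stop("target_overlap must be in [0, 1]", call. = FALSE)
  if (target_size_change < 0)
    stop("target_size_change must be >= 0", call. = FALSE)
  H <- 100L; wa <- 100L
  nr <- 360L; nc <- 160L
  a <- H * wa
  wb <- as.integer(round(wa * (1 + target_size_change / 100)))
  b <- H * wb
  if (target_overlap == 0) {
    wi <- 0L
  } else {
    i <- target_overlap * (a + b) / (1 + target_overlap)
    wi <- as.integer(round(i / H))
  }
  if (wi > min(wa, wb))
    stop("infeasible target combination: required overlap exceeds a mask",
         call. = FALSE)
  achieved_j <- if (wa + wb - wi > 0) wi / (wa + wb - wi) else 1
  if (abs(achieved_j - target_overlap) > 0.02)
    stop("infeasible target combination on this raster", call. = FALSE)
  x0 <- 3L + (abs(seed) %% 7L)           # deterministic jitter
  y0 <- 3L + (abs(seed) %% 11L)
  gap <- if (wi == 0L) 2L else 0L        # disjoint masks get a gap
  mr <- matrix(FALSE, nr, nc)
  model <- matrix(FALSE, nr, nc)
  mr[x0:(x0 + wa - 1L), y0:(y0 + H - 1L)] <- TRUE
  xb <- x0 + wa - wi + gap
  model[xb:(xb + wb - 1L), y0:(y0 + H - 1L)] <- TRUE
  inter <- sum(mr & model)
  res <- list(mr = mr, model = model)
  attr(res, "overlap") <- inter / sum(mr | model)
  attr(res, "size_change") <- 100 * abs(sum(model) - sum(mr)) / sum(mr)
  res
}
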