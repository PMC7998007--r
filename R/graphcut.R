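# Seeded binary segmentation by minimum s-t cut on the voxel graph, in the
# classical foreground/background-seed formulation: Gaussian boundary weights
# on neighbour links, hard terminal constraints on seed voxels, optional
# regional terms from Gaussian intensity likelihoods fitted to the seeds.

#' Graph-cut parameters
#'
#' @param sigma intensity scale (same units as the volume) of the boundary
#'   term: neighbour weight `exp(-(Ip - Iq)^2 / (2 sigma^2))`. Larger sigma
#'   tolerates larger edges before the link becomes cheap to cut.
#' @param lambda_regional weight of the regional terms (0 disables them:
#'   pure boundary energy with hard seeds).
#' @param connectivity 6, 18 or 26 neighbourhood.
#' @param spacing_aware if `TRUE`, neighbour weights are divided by the
#'   physical distance in mm between the voxel centres, so the cut is
#'   measured in actual distance rather than voxel steps.
#' @return An object of class `graphcut_params`.
#' @export
graphcut_params <- function(sigma = 30, lambda_regional = 0,
                            connectivity = 6, spacing_aware = TRUE) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (lambda_regional < 0) stop("lambda_regional must be >= 0", call. = FALSE)
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  structure(list(sigma = sigma, lambda_regional = lambda_regional,
                 connectivity = as.integer(connectivity),
                 spacing_aware = isTRUE(spacing_aware)),
            class = "graphcut_params")
}

# neighbour offsets (positive half-space only, so each pair appears once)
.neighbour_offsets <- function(connectivity) {
  all_off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  all_off <- all_off[rowSums(abs(all_off)) > 0, , drop = FALSE]
  ord <- rowSums(abs(all_off))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3)
  half <- all_off[, 3] > 0 | (all_off[, 3] == 0 & all_off[, 2] > 0) |
    (all_off[, 3] == 0 & all_off[, 2] == 0 & all_off[, 1] > 0)
  all_off[keep & half, , drop = FALSE]
}

# 0-based (x,y,z) matrix -> 0-based linear ids, x fastest
.lin_id <- function(m, dims) m[, 1] + dims[1] * (m[, 2] + dims[2] * m[, 3])

#' Build the energy graph for one structure
#'
#' Neighbour links carry `B(p,q) = exp(-(Ip-Iq)^2/(2 sigma^2))`, divided by
#' the physical centre distance when `spacing_aware`. Seed voxels are tied to
#' their terminal with the hard-constraint capacity
#' `K = 1 + max_p sum of incident n-links`. With `lambda_regional > 0`,
#' non-seed voxels get terminal links `lambda * (-log)` of Gaussian intensity
#' likelihoods fitted to the foreground/background seed intensities
#' (variance floored at 1e-6), clamped to `[0, K]`.
#'
#' @param vol an [image_volume()].
#' @param fg,bg integer matrices (n x 3) of 0-based foreground/background
#'   seed voxel indices.
#' @param params a [graphcut_params()].
#' @return An `energy_graph`: edge list (`from`, `to`, 0-based linear voxel
#'   ids; `weight`), terminal capacities (`src_idx`/`src_cap`,
#'   `sink_idx`/`sink_cap`) and the constant `K`.
#' @export
build_energy_graph <- function(vol, fg, bg, params = graphcut_params()) {
  stopifnot(is_image_volume(vol), inherits(params, "graphcut_params"))
  dims <- dim(vol$data)
  nvox <- prod(dims)
  I <- as.numeric(vol$data)

  offs <- .neighbour_offsets(params$connectivity)
  from <- to <- integer(0)
  weight <- numeric(0)
  idx_grid <- array(seq_len(nvox) - 1L, dims)   # 0-based linear ids
  for (o in seq_len(nrow(offs))) {
    dx <- offs[o, 1]; dy <- offs[o, 2]; dz <- offs[o, 3]
    xs <- seq_len(dims[1] - abs(dx)) + max(0, -dx)
    ys <- seq_len(dims[2] - abs(dy)) + max(0, -dy)
    zs <- seq_len(dims[3] - abs(dz)) + max(0, -dz)
    a <- idx_grid[xs, ys, zs]
    b <- idx_grid[xs + dx, ys + dy, zs + dz]
    dI <- I[b + 1L] - I[a + 1L]
    w <- exp(-dI^2 / (2 * params$sigma^2))
    if (params$spacing_aware) {
      dist_mm <- sqrt(sum((c(dx, dy, dz) * vol$spacing)^2))
      w <- w / dist_mm
    }
    from <- c(from, as.integer(a)); to <- c(to, as.integer(b))
    weight <- c(weight, w)
  }

  # K = 1 + max over voxels of the sum of incident n-links
  inc <- numeric(nvox)
  inc <- inc + as.numeric(tapply_sum(from + 1L, weight, nvox))
  inc <- inc + as.numeric(tapply_sum(to + 1L, weight, nvox))
  K <- 1 + max(inc)

  fg_id <- unique(.lin_id(fg, dims)); bg_id <- unique(.lin_id(bg, dims))
  src_idx <- fg_id; src_cap <- rep(K, length(fg_id))
  sink_idx <- bg_id; sink_cap <- rep(K, length(bg_id))

  if (params$lambda_regional > 0) {
    gauss_nll <- function(x, mu, v) 0.5 * log(2 * pi * v) + (x - mu)^2 / (2 * v)
    fi <- I[fg_id + 1L]; bi <- I[bg_id + 1L]
    vf <- max(stats::var(fi), 1e-6); vb <- max(stats::var(bi), 1e-6)
    if (is.na(vf)) vf <- 1e-6
    if (is.na(vb)) vb <- 1e-6
    nonseed <- setdiff(seq_len(nvox) - 1L, c(fg_id, bg_id))
    x <- I[nonseed + 1L]
    cap_src <- pmin(pmax(params$lambda_regional * gauss_nll(x, mean(bi), vb), 0), K)
    cap_snk <- pmin(pmax(params$lambda_regional * gauss_nll(x, mean(fi), vf), 0), K)
    src_idx <- c(src_idx, nonseed); src_cap <- c(src_cap, cap_src)
    sink_idx <- c(sink_idx, nonseed); sink_cap <- c(sink_cap, cap_snk)
  }

  structure(list(n_voxels = nvox, dims = dims, from = from, to = to,
                 weight = weight, src_idx = src_idx, src_cap = src_cap,
                 sink_idx = sink_idx, sink_cap = sink_cap, K = K),
            class = "energy_graph")
}

# sum `w` grouped by integer ids 1..nbins (dense result)
tapply_sum <- function(ids, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, ids)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# energy of a binary labeling under an energy_graph: n-links cut across the
# boundary plus terminal capacities on the violated side
#' Cut energy of a labeling
#'
#' @param graph an energy graph from [build_energy_graph()].
#' @param labels logical/0-1 vector over voxels (TRUE = foreground).
#' @return The total capacity the labeling cuts.
#' @export
cut_energy <- function(graph, labels) {
  labels <- as.logical(labels)
  e_n <- sum(graph$weight[labels[graph$from + 1L] != labels[graph$to + 1L]])
  e_src <- sum(graph$src_cap[!labels[graph$src_idx + 1L]])
  e_snk <- sum(graph$sink_cap[labels[graph$sink_idx + 1L]])
  e_n + e_src + e_snk
}

#' Solve one binary minimum cut
#'
#' @param graph an energy graph from [build_energy_graph()].
#' @return Logical 3-D foreground mask with the attained cut energy attached
#'   as attribute `energy`.
#' @export
solve_cut <- function(graph) {
  lab <- cpp_mincut(graph$n_voxels,
                    graph$from, graph$to, graph$weight,
                    graph$src_idx, graph$src_cap,
                    graph$sink_idx, graph$sink_cap)
  mask <- array(lab == 1L, graph$dims)
  attr(mask, "energy") <- cut_energy(graph, as.logical(lab))
  mask
}

#' Structure descriptor
#'
#' Display and assembly metadata for one labeled structure.
#'
#' @param label positive integer label.
#' @param name structure name.
#' @param color RGBA in `[0,1]` (length 3 or 4).
#' @param transparency in `[0,1]`.
#' @param priority positive integer rank; smaller = wins overlaps.
#' @return A one-row `data.frame`.
#' @export
structure_descriptor <- function(label, name, color = c(0.8, 0.2, 0.2, 1),
                                 transparency = 0, priority = label) {
  if (length(color) == 3) color <- c(color, 1)
  stopifnot(label >= 1, priority >= 1, transparency >= 0, transparency <= 1)
  data.frame(label = as.integer(label), name = name,
             r = color[1], g = color[2], b = color[3], a = color[4],
             transparency = transparency, priority = as.integer(priority),
             stringsAsFactors = FALSE)
}

#' Construct a label map
#'
#' @param labels integer 3-D array (0 = unassigned/background).
#' @param structures `data.frame` of [structure_descriptor()] rows covering
#'   every nonzero label.
#' @param spacing,origin,direction grid geometry (as in [image_volume()]).
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, structures, spacing = c(1, 1, 1),
                      origin = c(0, 0, 0), direction = diag(3)) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  present <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (!all(present %in% structures$label))
    stop("every nonzero label needs a structure descriptor", call. = FALSE)
  structure(list(labels = labels, structures = structures,
                 spacing = as.numeric(spacing), origin = as.numeric(origin),
                 direction = matrix(as.numeric(direction), 3, 3)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_map> %d x %d x %d voxels, %d structure(s)\n",
              d[1], d[2], d[3], nrow(x$structures)))
  for (i in seq_len(nrow(x$structures))) {
    s <- x$structures[i, ]
    cat(sprintf("  [%d] %-12s %d voxels (priority %d)\n", s$label, s$name,
                sum(x$labels == s$label), s$priority))
  }
  invisible(x)
}

#' Seeded graph-cut segmentation (draw-cut)
#'
#' Runs one independent binary min-cut per structure in the seed set, each
#' constrained so every foreground seed is labeled and every background seed
#' is not, and attaining the minimum cut energy among all labelings
#' consistent with the seeds. Structures are then assembled into a label map
#' with overlaps resolved by priority.
#'
#' @param vol an [image_volume()].
#' @param seeds a `seed_set` from [build_seed_set()].
#' @param params a [graphcut_params()].
#' @param structures optional descriptor `data.frame`; defaults to one
#'   descriptor per structure id.
#' @return A [label_map()]; per-structure binary masks and cut energies are
#'   attached as attributes `masks` and `energies`.
#' @export
draw_cut <- function(vol, seeds, params = graphcut_params(),
                     structures = NULL) {
  stopifnot(is_image_volume(vol), inherits(seeds, "seed_set"))
  dims <- dim(vol$data)
  if (!identical(as.integer(attr(seeds, "grid_shape")), as.integer(dims)))
    stop("seed set grid shape does not match the volume", call. = FALSE)
  ids <- as.integer(names(seeds))
  if (is.null(structures)) {
    structures <- do.call(rbind, lapply(ids, function(sid)
      structure_descriptor(sid, name = sprintf("structure_%d", sid),
                           color = grDevices::col2rgb(
                             grDevices::palette.colors(9)[(sid %% 9) + 1]) / 255,
                           priority = sid)))
  }
  masks <- list(); energies <- numeric(0)
  for (sid in ids) {
    s <- seeds[[as.character(sid)]]
    if (nrow(s$fg) == 0 || nrow(s$bg) == 0)
      stop(sprintf("structure %d needs both foreground and background seeds", sid),
           call. = FALSE)
    g <- build_energy_graph(vol, s$fg, s$bg, params)
    m <- solve_cut(g)
    masks[[as.character(sid)]] <- m
    energies[as.character(sid)] <- attr(m, "energy")
  }
  prio <- setNames(structures$priority, as.character(structures$label))
  lm <- resolve_overlaps(masks, prio[as.character(ids)], structures,
                         spacing = vol$spacing, origin = vol$origin,
                         direction = vol$direction)
  attr(lm, "masks") <- masks
  attr(lm, "energies") <- energies
  lm
}

#' Seeded region growing
#'
#' Breadth-first flood fill accepting voxels whose intensity lies within
#' `tolerance` of the running mean of the accepted region (updated per
#' frontier generation). The result always contains all seeds.
#'
#' @param vol an [image_volume()].
#' @param seed_voxels integer matrix (n x 3) of 0-based seed indices.
#' @param tolerance intensity units, >= 0.
#' @param connectivity 6, 18 or 26.
#' @return Logical 3-D mask.
#' @export
region_grow <- function(vol, seed_voxels, tolerance, connectivity = 6) {
  stopifnot(is_image_volume(vol), tolerance >= 0)
  dims <- dim(vol$data)
  seed_voxels <- matrix(as.integer(seed_voxels), ncol = 3)
  if (any(seed_voxels < 0) || any(sweep(seed_voxels, 2, dims - 1L) > 0))
    stop("bounds error: seed voxel outside the grid", call. = FALSE)
  half <- .neighbour_offsets(connectivity)
  offs <- rbind(half, -half)
  m <- cpp_region_grow(as.numeric(vol$data), dims,
                       as.integer(.lin_id(seed_voxels, dims)),
                       as.numeric(tolerance), offs)
  array(m, dims)
}

#' Threshold segmentation
#'
#' @param vol an [image_volume()].
#' @param method `"otsu"` (256-bin between-class-variance maximization) or
#'   `"fixed"`.
#' @param level threshold for `method = "fixed"`.
#' @return Logical mask of voxels with intensity >= threshold; the threshold
#'   used is attached as attribute `threshold`.
#' @export
threshold_segment <- function(vol, method = c("otsu", "fixed"), level = NULL) {
  stopifnot(is_image_volume(vol))
  method <- match.arg(method)
  I <- as.numeric(vol$data)
  if (method == "fixed") {
    if (is.null(level)) stop("fixed thresholding requires `level`", call. = FALSE)
    thr <- level
  } else {
    lo <- min(I); hi <- max(I)
    if (hi - lo < 1e-12)
      stop("degenerate-histogram error: constant volume has no Otsu threshold",
           call. = FALSE)
    nb <- 256L
    h <- tabulate(pmin(as.integer((I - lo) / (hi - lo) * nb) + 1L, nb), nbins = nb)
    p <- h / sum(h)
    omega <- cumsum(p)
    mids <- lo + (seq_len(nb) - 0.5) * (hi - lo) / nb
    mu <- cumsum(p * mids)
    mu_t <- mu[nb]
    denom <- omega * (1 - omega)
    bcv <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, -Inf)
    kstar <- which.max(bcv[-nb])
    thr <- lo + kstar * (hi - lo) / nb   # upper edge of the chosen bin
  }
  mask <- array(I >= thr, dim(vol$data))
  attr(mask, "threshold") <- thr
  mask
}
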