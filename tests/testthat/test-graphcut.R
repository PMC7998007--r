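.vol1d <- function(values) image_volume(array(values, c(length(values), 1, 1)))

test_that("the cut on a step profile falls on the intensity jump", {
  vol <- .vol1d(c(0, 0, 100, 100))
  g <- build_energy_graph(vol,
                          fg = matrix(c(3L, 0L, 0L), 1),
                          bg = matrix(c(0L, 0L, 0L), 1))
  m <- solve_cut(g)
  expect_equal(as.logical(m), c(FALSE, FALSE, TRUE, TRUE))
  # the minimum cuts exactly one n-link, the weakest one
  expect_equal(attr(m, "energy"),
               exp(-100^2 / (2 * 30^2)), tolerance = 1e-12)
})

test_that("boundary n-link weights follow the Gaussian contrast model", {
  vol <- image_volume(array(c(10, 40, 10, 40, 10, 40, 10, 40), c(2, 2, 2)),
                      spacing = c(2, 1, 1))
  p <- graphcut_params(sigma = 20, spacing_aware = TRUE)
  g <- build_energy_graph(vol, matrix(0L, 1, 3), matrix(c(1L, 0L, 0L), 1), p)
  # x-neighbours differ by 30 over 2 mm; y/z neighbours are equal-intensity
  wx <- g$weight[abs(g$to - g$from) == 1]
  expect_equal(unique(round(wx, 12)),
               round(exp(-30^2 / (2 * 20^2)) / 2, 12))
  wyz <- g$weight[abs(g$to - g$from) > 1]
  expect_true(all(abs(wyz - 1) < 1e-12))
  # without spacing awareness the 2 mm division disappears
  g2 <- build_energy_graph(vol, matrix(0L, 1, 3), matrix(c(1L, 0L, 0L), 1),
                           graphcut_params(sigma = 20, spacing_aware = FALSE))
  wx2 <- g2$weight[abs(g2$to - g2$from) == 1]
  expect_equal(unique(round(wx2, 12)), round(exp(-30^2 / (2 * 20^2)), 12))
})

test_that("hard seed capacity exceeds any voxel's incident n-link budget", {
  set.seed(5)
  vol <- image_volume(array(runif(4 * 4 * 4, 0, 50), c(4, 4, 4)))
  g <- build_energy_graph(vol, matrix(0L, 1, 3), matrix(c(3L, 3L, 3L), 1))
  inc <- numeric(g$n_voxels)
  for (e in seq_along(g$from)) {
    inc[g$from[e] + 1] <- inc[g$from[e] + 1] + g$weight[e]
    inc[g$to[e] + 1] <- inc[g$to[e] + 1] + g$weight[e]
  }
  expect_gt(min(g$src_cap), max(inc))
  expect_gt(min(g$sink_cap), max(inc))
})

test_that("solve_cut attains the exhaustive minimum over seed-consistent labelings", {
  set.seed(17)
  dims <- c(2L, 2L, 3L)
  nvox <- prod(dims)
  for (trial in 1:12) {
    vol <- image_volume(array(runif(nvox, 0, 120), dims))
    picks <- sample(nvox, 2)
    coord <- function(id) {
      id0 <- id - 1
      c(id0 %% 2, (id0 %/% 2) %% 2, id0 %/% 4)
    }
    fg <- matrix(coord(picks[1]), 1)
    bg <- matrix(coord(picks[2]), 1)
    g <- build_energy_graph(vol, fg, bg,
                            graphcut_params(sigma = sample(c(10, 30, 60), 1)))
    m <- solve_cut(g)
    expect_true(m[fg[1] + 1, fg[2] + 1, fg[3] + 1])
    expect_false(m[bg[1] + 1, bg[2] + 1, bg[3] + 1])
    # brute force over all 2^(nvox-2) free labelings
    free <- setdiff(seq_len(nvox), picks)
    best <- Inf
    for (code in 0:(2^length(free) - 1)) {
      lab <- logical(nvox)
      lab[picks[1]] <- TRUE
      lab[free] <- bitwAnd(bitwShiftR(code, seq_along(free) - 1), 1) == 1
      best <- min(best, cut_energy(g, lab))
    }
    expect_equal(attr(m, "energy"), best, tolerance = 1e-9, info = trial)
  }
})

test_that("segmentation is deterministic for identical inputs", {
  ph <- cached_phantom(seed = 42, noise_sigma = 5)
  vol <- denoise_volume(ph$bundle$t1ce)
  geoms <- auto_seed_geometries(ph$truth, 1L)
  ss <- build_seed_set(geoms, dim(vol$data))
  m1 <- draw_cut(vol, ss)
  m2 <- draw_cut(vol, ss)
  expect_identical(m1$labels, m2$labels)
  expect_identical(attr(m1, "energies"), attr(m2, "energies"))
})

test_that("draw-cut recovers the phantom tumor against ground truth", {
  ph <- cached_phantom(seed = 42, noise_sigma = 5)
  vol <- denoise_volume(ph$bundle$t1ce)
  ss <- build_seed_set(auto_seed_geometries(ph$truth, 1L), dim(vol$data))
  lm <- draw_cut(vol, ss)
  expect_gt(dice_coefficient(lm$labels == 1, ph$truth$labels == 1), 0.95)
})

test_that("a regional term keeps seed constraints and a sensible result", {
  vol <- .vol1d(c(0, 5, 95, 100, 98, 2))
  fg <- matrix(c(3L, 0L, 0L), 1); bg <- matrix(c(0L, 0L, 0L), 1)
  g <- build_energy_graph(vol, fg, bg,
                          graphcut_params(sigma = 30, lambda_regional = 0.5))
  expect_true(all(g$src_cap <= g$K + 1e-12))
  expect_true(all(g$src_cap >= 0))
  m <- solve_cut(g)
  expect_true(m[4, 1, 1]); expect_false(m[1, 1, 1])
})

test_that("region growing floods a plateau and always keeps its seeds", {
  arr <- array(0, c(8, 8, 3))
  arr[3:6, 3:6, 2] <- 100
  vol <- image_volume(arr)
  m <- region_grow(vol, matrix(c(3L, 3L, 1L), 1), tolerance = 10)
  expect_equal(which(m), which(arr == 100))
  # tolerance 0 on a lone bright voxel keeps only the seed
  m0 <- region_grow(vol, matrix(c(0L, 0L, 0L), 1), tolerance = 0)
  expect_true(m0[1, 1, 1])
  expect_equal(sum(m0), sum(arr == 0))   # all the zeros are connected
  expect_error(region_grow(vol, matrix(c(8L, 0L, 0L), 1), 1), "bounds error")
})

test_that("Otsu thresholding separates a clean bimodal volume", {
  arr <- array(c(rep(10, 40), rep(200, 24)), c(4, 4, 4))
  vol <- image_volume(arr)
  m <- threshold_segment(vol, "otsu")
  expect_equal(sum(m), 24)
  expect_true(all(arr[m] == 200))
  thr <- attr(m, "threshold")
  expect_true(thr > 10 && thr <= 200)
  mf <- threshold_segment(vol, "fixed", level = 100)
  expect_identical(as.logical(mf), as.logical(m))
  expect_error(threshold_segment(image_volume(array(5, c(3, 3, 3))), "otsu"),
               "degenerate-histogram")
})
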