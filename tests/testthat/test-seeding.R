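grid10 <- c(10L, 10L, 10L)

test_that("polygon fill is boundary-inclusive even-odd at voxel centres", {
  sq <- seed_geometry("polygon", "z", 0,
                      rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4)),
                      role = "foreground")
  px <- rasterize_seed_geometry(sq, grid10)
  expect_equal(nrow(px), 25)
  expect_true(all(px[, 3] == 0))
  # triangle with a center exactly on the hypotenuse counts inside
  tri <- seed_geometry("polygon", "z", 2, rbind(c(0, 0), c(4, 0), c(0, 4)))
  pxt <- rasterize_seed_geometry(tri, grid10)
  expect_true(any(pxt[, 1] == 2 & pxt[, 2] == 2))
})

test_that("rasterization is invariant to rotation of the vertex ring", {
  ring <- rbind(c(1, 1), c(6, 2), c(7, 6), c(2, 7))
  key <- function(px) sort(px[, 1] + 100 * px[, 2])
  base <- rasterize_seed_geometry(seed_geometry("polygon", "z", 0, ring), grid10)
  for (s in 1:3) {
    rot <- ring[c((s + 1):4, 1:s), , drop = FALSE]
    px <- rasterize_seed_geometry(seed_geometry("polygon", "z", 0, rot), grid10)
    expect_equal(key(px), key(base))
  }
})

test_that("convex polygon counts match the half-plane oracle", {
  set.seed(21)
  for (trial in 1:10) {
    # random convex ring: points on a circle at sorted angles
    k <- sample(3:6, 1)
    ang <- sort(runif(k, 0, 2 * pi))
    cx <- runif(1, 3, 6); cy <- runif(1, 3, 6); r <- runif(1, 1.5, 2.8)
    ring <- cbind(cx + r * cos(ang), cy + r * sin(ang))
    px <- rasterize_seed_geometry(seed_geometry("polygon", "z", 0, ring), grid10)
    expect_equal(nrow(px), convex_fill_oracle(ring, 10, 10), info = trial)
  }
})

test_that("sketch strokes trace digital polylines and dilate by the brush", {
  line <- seed_geometry("sketch", "z", 1, rbind(c(0, 0), c(0, 4)))
  expect_equal(nrow(rasterize_seed_geometry(line, grid10)), 5)
  # diagonal is 8-connected: 5 voxels, not 9
  diag_ <- seed_geometry("sketch", "z", 1, rbind(c(0, 0), c(4, 4)))
  expect_equal(nrow(rasterize_seed_geometry(diag_, grid10)), 5)
  # Chebyshev disc of radius 1 around a single straight stroke
  fat <- seed_geometry("sketch", "z", 1, rbind(c(2, 2), c(2, 6)),
                       brush_radius = 1)
  expect_equal(nrow(rasterize_seed_geometry(fat, grid10)), 21)  # 3 x 7 box
})

test_that("degenerate and out-of-bounds geometries are rejected", {
  expect_error(rasterize_seed_geometry(
    seed_geometry("polygon", "z", 0, rbind(c(1, 1), c(3, 3), c(5, 5))),
    grid10), "zero area")
  expect_error(rasterize_seed_geometry(
    seed_geometry("freedraw", "z", 0, rbind(c(2, 2), c(11, 3))), grid10),
    "bounds error")
  expect_error(rasterize_seed_geometry(
    seed_geometry("sketch", "y", 12, rbind(c(0, 0), c(2, 2))), grid10),
    "bounds error")
})

test_that("seed sets union by role, deduplicate, and flag conflicts", {
  fg1 <- seed_geometry("sketch", "z", 0, rbind(c(0, 0), c(3, 0)),
                       role = "foreground")
  fg2 <- seed_geometry("sketch", "z", 0, rbind(c(2, 0), c(5, 0)),
                       role = "foreground")   # shares voxels 2,3 with fg1
  bg <- seed_geometry("polygon", "z", 0, rbind(c(0, 5), c(4, 5), c(4, 8), c(0, 8)),
                      role = "background")
  ss <- build_seed_set(list(fg1, fg2, bg), grid10)
  expect_s3_class(ss, "seed_set")
  expect_equal(nrow(ss[["1"]]$fg), 6)   # x = 0..5 once each
  expect_gt(nrow(ss[["1"]]$bg), 0)

  clash <- seed_geometry("sketch", "z", 0, rbind(c(3, 0), c(3, 2)),
                         role = "background")
  expect_error(build_seed_set(list(fg1, clash), grid10), "conflict error")
  expect_error(build_seed_set(list(bg), grid10), "incomplete-seed")
})

test_that("seed geometries survive a JSON round trip", {
  geoms <- list(
    seed_geometry("polygon", "z", 3, rbind(c(1, 1), c(5, 1), c(5, 5), c(1, 5)),
                  role = "foreground", structure_id = 2L),
    seed_geometry("sketch", "y", 1, rbind(c(0, 0), c(4, 4)), brush_radius = 1,
                  role = "background", structure_id = 2L))
  path <- tempfile(fileext = ".json")
  write_seed_geometries(geoms, path)
  back <- read_seed_geometries(path)
  expect_equal(length(back), 2)
  for (i in 1:2) {
    expect_equal(back[[i]]$mode, geoms[[i]]$mode)
    expect_equal(back[[i]]$vertices, geoms[[i]]$vertices)
    expect_equal(back[[i]]$role, geoms[[i]]$role)
    expect_equal(back[[i]]$structure_id, geoms[[i]]$structure_id)
  }
  expect_true(file.exists(system.file("schema", "seeds.schema.json",
                                      package = "neuroprint")))
})
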