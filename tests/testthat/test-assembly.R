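.cube_mask <- function(n, side, at = 3) {
  m <- array(FALSE, c(n, n, n))
  m[at:(at + side - 1), at:(at + side - 1), at:(at + side - 1)] <- TRUE
  m
}

test_that("overlaps resolve strictly by priority and certify disjointness", {
  a <- array(FALSE, c(6, 6, 6)); a[2:4, 2:4, 2:4] <- TRUE
  b <- array(FALSE, c(6, 6, 6)); b[3:5, 3:5, 3:5] <- TRUE
  lm <- resolve_overlaps(list("1" = a, "2" = b), c("1" = 1, "2" = 2))
  expect_s3_class(lm, "label_map")
  # every voxel of a keeps label 1; b only gets the non-overlapping rest
  expect_true(all(lm$labels[a] == 1L))
  expect_equal(sum(lm$labels == 2L), sum(b & !a))
  expect_equal(sum(lm$labels != 0L), sum(a | b))
  expect_equal(attr(lm, "disjoint_certificate"), 1L)
  # swapping ranks swaps the winner on the overlap
  lm2 <- resolve_overlaps(list("1" = a, "2" = b), c("1" = 2, "2" = 1))
  expect_true(all(lm2$labels[b] == 2L))
  expect_error(resolve_overlaps(list("1" = a, "2" = b), c("1" = 1, "2" = 1)),
               "configuration error")
})

test_that("skull-base cropping keeps only the tumor bounding box plus margin", {
  big <- array(TRUE, c(20, 20, 20))
  tum <- array(FALSE, c(20, 20, 20)); tum[9:11, 9:11, 9:11] <- TRUE
  got <- crop_skull_base(big, tum, margin = 2)
  idx <- which(got, arr.ind = TRUE)
  expect_equal(unname(apply(idx, 2, range)),
               matrix(c(7, 13, 7, 13, 7, 13), 2))
  # margin in mm is divided by spacing
  got2 <- crop_skull_base(big, tum, margin = 2, spacing = c(2, 2, 2))
  expect_equal(unname(apply(which(got2, arr.ind = TRUE), 2, min)), c(8, 8, 8))
  expect_error(crop_skull_base(big, array(FALSE, c(20, 20, 20)), 1),
               "empty-selection")
})

test_that("extracted surfaces are watertight and volume-faithful for a ball", {
  ball <- digital_ball(10)
  mesh <- extract_surface(mask = ball, spacing = c(1, 1, 1))
  expect_true(is_watertight(mesh))
  v <- mesh_volume(mesh)
  expect_gt(v, 0)                                   # outward orientation
  expect_lt(abs(v - sum(ball)) / sum(ball), 0.02)   # within 2 % of voxel count
})

test_that("surface volume scales with the cube of the voxel spacing", {
  ball <- digital_ball(6)
  v1 <- mesh_volume(extract_surface(mask = ball, spacing = c(1, 1, 1)))
  v2 <- mesh_volume(extract_surface(mask = ball, spacing = c(2, 2, 2)))
  expect_equal(v2, 8 * v1, tolerance = 1e-9)
  # origin translation does not change the enclosed volume
  v3 <- mesh_volume(extract_surface(mask = ball, spacing = c(1, 1, 1),
                                    origin = c(50, -20, 7)))
  expect_equal(v3, v1, tolerance = 1e-9)
})

test_that("watertightness check exposes holes and orientation flips sign", {
  ball <- digital_ball(5)
  mesh <- extract_surface(mask = ball)
  expect_true(is_watertight(mesh))
  holed <- structure_mesh(mesh$vertices, mesh$triangles[-1, , drop = FALSE])
  expect_false(is_watertight(holed))
  flipped <- structure_mesh(mesh$vertices, mesh$triangles[, c(1, 3, 2)])
  expect_equal(mesh_volume(flipped), -mesh_volume(mesh), tolerance = 1e-9)
  expect_error(extract_surface(mask = array(FALSE, c(4, 4, 4))),
               "empty-structure")
})

test_that("Laplacian smoothing keeps topology and mildly shrinks a ball", {
  mesh <- extract_surface(mask = digital_ball(8))
  sm <- smooth_mesh(mesh, 5)
  expect_equal(dim(sm$vertices), dim(mesh$vertices))
  expect_identical(sm$triangles, mesh$triangles)
  expect_true(is_watertight(sm))
  v0 <- mesh_volume(mesh); v1 <- mesh_volume(sm)
  expect_lt(v1, v0)
  expect_gt(v1, 0.85 * v0)
})

test_that("binary STL layout is exact and round trips the mesh", {
  tri <- structure_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        rbind(c(1, 2, 3)))
  p <- tempfile(fileext = ".stl")
  write_stl(tri, p)
  expect_equal(file.size(p), 80 + 4 + 50)   # header + count + one facet
  back <- read_stl(p)
  expect_equal(back$vertices, tri$vertices)
  expect_equal(back$triangles, tri$triangles)

  ball <- extract_surface(mask = digital_ball(6))
  p2 <- tempfile(fileext = ".stl")
  write_stl(ball, p2)
  expect_equal(file.size(p2), 80 + 4 + 50 * nrow(ball$triangles))
  back2 <- read_stl(p2)
  expect_true(is_watertight(back2))
  expect_equal(mesh_volume(back2), mesh_volume(ball), tolerance = 1e-5)

  pa <- tempfile(fileext = ".stl")
  write_stl(tri, pa, format = "ascii")
  lines <- readLines(pa)
  expect_match(lines[1], "^solid ")
  expect_match(lines[length(lines)], "^endsolid ")
})

test_that("dilation metrics behave as a box and a ball respectively", {
  one <- array(FALSE, c(9, 9, 9)); one[5, 5, 5] <- TRUE
  cheb <- dilate_mask(one, 2, c(1, 1, 1), "chebyshev")
  expect_equal(sum(cheb), 125)        # 5^3 box
  eucl <- dilate_mask(one, 2, c(1, 1, 1), "euclidean")
  expect_equal(sum(eucl), 33)         # digital ball of radius 2
  # anisotropic spacing shrinks the voxel radius along coarse axes
  cheb2 <- dilate_mask(one, 2, c(1, 1, 2), "chebyshev")
  expect_equal(sum(cheb2), 5 * 5 * 3)
})

test_that("the two-part mold partitions the dilated shell exactly", {
  brain <- .cube_mask(20, 10, at = 6)
  mold <- generate_mold(brain, wall_thickness = 2, split_axis = "x")
  expect_equal(sum(mold$mold_mask), 14^3 - 10^3)     # 1744 shell voxels
  expect_equal(unname(mold$counts["dilated"]),
               unname(mold$counts["brain"] + mold$counts["part1"] +
                        mold$counts["part2"]))
  expect_true(is_watertight(mold$part1))
  expect_true(is_watertight(mold$part2))
  expect_gt(mesh_volume(mold$part1), 0)
  expect_gt(mesh_volume(mold$part2), 0)
  # cube is symmetric about the split plane: halves have equal voxel counts
  expect_equal(unname(mold$counts["part1"]), unname(mold$counts["part2"]))
  expect_error(generate_mold(brain, wall_thickness = 0.5),
               "parameter error")
})
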