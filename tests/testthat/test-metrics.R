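.plan_mask <- function(rows, cols, n = 40) {
  m <- matrix(FALSE, n, n); m[rows, cols] <- TRUE
  m
}

test_that("tumor depth is the spacing-aware distance to the cortical surface", {
  labels <- array(0L, c(30, 30, 30))
  labels[5:25, 5:25, 5:25] <- 2L               # brain block
  labels[14:16, 14:16, 10:12] <- 1L            # small tumor inside it
  st <- rbind(structure_descriptor(1, "tumor"),
              structure_descriptor(2, "brain"))
  lm <- label_map(labels, st)
  d <- tumor_depth_mm(lm, 1, 2)
  # nearest face of the block is 5 voxels from the closest tumor voxel
  expect_equal(as.numeric(d), 5)
  expect_false(attr(d, "touches_surface"))
  # doubling the z spacing makes the x/y route the shortest one
  lm2 <- label_map(labels, st, spacing = c(1, 1, 2))
  expect_equal(as.numeric(tumor_depth_mm(lm2, 1, 2)), 9)
})

test_that("a ball tumor under a flat brain face sits at center depth minus radius", {
  n <- 72
  labels <- array(0L, c(n, n, n))
  labels[6:67, 6:67, 6:67] <- 2L               # brain block, top face at z=67
  ctr <- c(36, 36, 67 - 30)                    # center 30 voxels below the face
  idx <- which(labels == 2L, arr.ind = TRUE)
  d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 + (idx[, 3] - ctr[3])^2
  labels[idx[d2 <= 100, ]] <- 1L               # radius-10 ball
  st <- rbind(structure_descriptor(1, "tumor"),
              structure_descriptor(2, "brain"))
  d <- tumor_depth_mm(label_map(labels, st), 1, 2)
  expect_equal(as.numeric(d), 20)
  expect_equal(categorize_depth(d, attr(d, "touches_surface")), "deep")
})

test_that("a tumor reaching the surface has depth zero and category cortex", {
  labels <- array(0L, c(20, 20, 20))
  labels[5:15, 5:15, 5:15] <- 2L
  labels[5:7, 9:11, 9:11] <- 1L                # touches the x face of the brain
  st <- rbind(structure_descriptor(1, "tumor"),
              structure_descriptor(2, "brain"))
  d <- tumor_depth_mm(label_map(labels, st), 1, 2)
  expect_equal(as.numeric(d), 0)
  expect_true(attr(d, "touches_surface"))
  expect_equal(categorize_depth(d, attr(d, "touches_surface")), "cortex")
})

test_that("depth categories use 20 and 40 mm bounds, 40 inclusive to deep", {
  expect_equal(categorize_depth(15), "intermediate")
  expect_equal(categorize_depth(19.99), "intermediate")
  expect_equal(categorize_depth(20), "deep")
  expect_equal(categorize_depth(30), "deep")
  expect_equal(categorize_depth(40), "deep")
  expect_equal(categorize_depth(45), "very_deep")
  expect_error(categorize_depth(-1), "depth")
})

test_that("size-change scores bin percent change relative to the MR plan", {
  expect_equal(score_size_change(100, 100), 0L)
  expect_equal(score_size_change(100, 130), 1L)
  expect_equal(score_size_change(100, 160), 2L)
  expect_equal(score_size_change(100, 180), 3L)
  expect_equal(score_size_change(100, 124.9), 0L)
  expect_equal(score_size_change(100, 125), 1L)
  expect_equal(score_size_change(100, 50), 2L)    # 50% shrink -> lower bin edge
  expect_equal(score_size_change(100, 400), 3L)   # beyond 100% clamps to 3
  expect_equal(score_size_change(100, 0), 3L)
  expect_error(score_size_change(0, 10), "> 0")
  # monotone in |area change| for a fixed reference
  sc <- vapply(seq(100, 300, by = 10),
               function(a3) score_size_change(100, a3), 0L)
  expect_true(all(diff(sc) >= 0))
})

test_that("location-change scores bin the Jaccard overlap", {
  a <- .plan_mask(1:20, 1:20)
  expect_equal(as.integer(score_location_change(a, a)), 0L)
  b <- .plan_mask(1:20, 3:22)         # inter 360, union 440 -> J = 9/11
  s1 <- score_location_change(a, b)
  expect_equal(as.integer(s1), 1L)
  expect_equal(attr(s1, "overlap"), 360 / 440)
  c_ <- .plan_mask(1:20, 11:30)       # inter 200, union 600 -> J = 1/3
  expect_equal(as.integer(score_location_change(a, c_)), 2L)
  # nested rectangles with areas 70 and 100 give exactly J = 0.70
  outer_ <- .plan_mask(1:10, 1:10)
  inner_ <- .plan_mask(1:10, 1:7)
  s7 <- score_location_change(outer_, inner_)
  expect_equal(attr(s7, "overlap"), 0.70)
  expect_equal(as.integer(s7), 1L)
  # translation of both masks together leaves the score unchanged
  expect_equal(attr(score_location_change(.plan_mask(5:24, 5:24),
                                          .plan_mask(5:24, 7:26)), "overlap"),
               attr(s1, "overlap"))
  # relative-to-first overlap is never below Jaccard
  s_rel <- score_location_change(a, b, method = "relative_first")
  expect_gte(attr(s_rel, "overlap"), attr(s1, "overlap"))
  expect_error(score_location_change(a, matrix(FALSE, 40, 40)), "nonempty")
})

test_that("plan comparison flags posture, rotation and goal changes", {
  r1 <- .plan_mask(1:10, 1:10)
  p1 <- craniotomy_plan("supine", "right", 30, r1, "GTR")
  p2 <- craniotomy_plan("supine", "left", 45, .plan_mask(1:10, 2:11), "STR")
  cmp <- compare_plans(p1, p2)
  expect_true(cmp$posture_changed)     # side flip counts as repositioning
  expect_true(cmp$rotation_changed)
  expect_true(cmp$goal_changed)
  expect_equal(cmp$size_score, 0L)
  same <- compare_plans(p1, p1)
  expect_false(same$posture_changed || same$rotation_changed || same$goal_changed)
  expect_equal(as.integer(same$location_score), 0L)
  expect_error(craniotomy_plan("supine", "right", 15, r1), "rotation")
  expect_error(craniotomy_plan("supine", "right", 0, r1, "ALL"), "goal")
})

test_that("squared distance transform agrees with brute force on random grids", {
  set.seed(33)
  for (trial in 1:5) {
    dims <- c(sample(3:6, 1), sample(3:6, 1), sample(3:6, 1))
    sp <- runif(3, 0.5, 2)
    m <- array(runif(prod(dims)) < 0.15, dims)
    if (!any(m)) m[1, 1, 1] <- TRUE
    d2 <- array(neuroprint:::cpp_edt_sq(as.logical(m), dims, sp), dims)
    idx <- which(m, arr.ind = TRUE)
    for (rep in 1:10) {
      q <- c(sample(dims[1], 1), sample(dims[2], 1), sample(dims[3], 1))
      bf <- min(((idx[, 1] - q[1]) * sp[1])^2 + ((idx[, 2] - q[2]) * sp[2])^2 +
                  ((idx[, 3] - q[3]) * sp[3])^2)
      expect_equal(d2[q[1], q[2], q[3]], bf, tolerance = 1e-9)
    }
  }
  # no feature voxels anywhere -> infinite distance
  none <- array(FALSE, c(3, 3, 3))
  expect_true(all(is.infinite(
    neuroprint:::cpp_edt_sq(as.logical(none), c(3L, 3L, 3L), c(1, 1, 1)))))
})

test_that("craniotomy pair generator hits its overlap and size targets", {
  for (seed in c(1, 9, 123)) {
    pr <- generate_craniotomy_pair(seed, target_overlap = 0.6,
                                   target_size_change = 30)
    expect_lte(abs(attr(pr, "overlap") - 0.6), 0.02)
    expect_lte(abs(attr(pr, "size_change") - 30), 1)
    expect_equal(sum(pr$mr), 100 * 100)
  }
  pr7 <- generate_craniotomy_pair(4, target_overlap = 0.70)
  expect_equal(as.integer(score_location_change(pr7$mr, pr7$model)), 1L)
  p0 <- generate_craniotomy_pair(2, target_overlap = 0)
  expect_equal(attr(p0, "overlap"), 0)
  expect_equal(as.integer(score_location_change(p0$mr, p0$model)), 2L)
  expect_error(generate_craniotomy_pair(1, 0.99, 100), "infeasible")
})
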