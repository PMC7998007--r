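# Surgical-planning quantifications: tumor depth below the cortical surface
# with its 2 cm / 4 cm category boundaries, encoded posture/rotation answer
# sets, and the craniotomy size-change (0-3) and location-change (0-2)
# scores comparing the MR-based plan with the printed-model-based plan.

.rotation_set <- c(0, 10, 30, 45, 60, 90, 100)
.resection_goals <- c("PR", "STR", "GTR", "supra_TR")

#' Construct a craniotomy plan
#'
#' @param posture `"supine"`, `"prone"` or `"lateral"`.
#' @param side `"right"` or `"left"`.
#' @param rotation_deg head rotation, one of 0, 10, 30, 45, 60, 90, 100.
#' @param craniotomy_region nonempty 2-D logical mask on the fixed
#'   skull-projection raster.
#' @param resection_goal `"PR"`, `"STR"`, `"GTR"` or `"supra_TR"`.
#' @return An object of class `craniotomy_plan`.
#' @export
craniotomy_plan <- function(posture = c("supine", "prone", "lateral"),
                            side = c("right", "left"), rotation_deg = 0,
                            craniotomy_region, resection_goal = "GTR") {
  posture <- match.arg(posture)
  side <- match.arg(side)
  if (!rotation_deg %in% .rotation_set)
    stop(sprintf("rotation must be one of {%s} degrees",
                 paste(.rotation_set, collapse = ", ")), call. = FALSE)
  if (!resection_goal %in% .resection_goals)
    stop("unknown resection goal", call. = FALSE)
  craniotomy_region <- as.matrix(craniotomy_region) != 0
  if (!any(craniotomy_region))
    stop("craniotomy region must be nonempty", call. = FALSE)
  structure(list(posture = posture, side = side,
                 rotation_deg = rotation_deg,
                 craniotomy_region = craniotomy_region,
                 resection_goal = resection_goal),
            class = "craniotomy_plan")
}

#' Tumor depth below the cortical surface
#'
#' Minimum spacing-aware Euclidean distance (mm) from any tumor voxel to the
#' brain-mask outer surface (brain voxels with a 6-neighbour outside the
#' mask); 0 when the tumor reaches the surface.
#'
#' @param labelmap a [label_map()].
#' @param tumor_label,brain_label labels of tumor and whole-brain masks. The
#'   brain mask is taken as all voxels carrying `brain_label` *or* any other
#'   nonzero label (internal structures are inside the brain).
#' @return Depth in mm; attribute `touches_surface` flags contact.
#' @export
tumor_depth_mm <- function(labelmap, tumor_label, brain_label) {
  stopifnot(inherits(labelmap, "label_map"))
  tumor <- labelmap$labels == tumor_label
  brain <- labelmap$labels != 0L
  if (!any(tumor) || !any(labelmap$labels == brain_label))
    stop("tumor and brain labels must both be present", call. = FALSE)
  outside <- !brain
  surface <- brain & (
    .shift_pad_true(outside, 1, 1) | .shift_pad_true(outside, 1, -1) |
    .shift_pad_true(outside, 2, 1) | .shift_pad_true(outside, 2, -1) |
    .shift_pad_true(outside, 3, 1) | .shift_pad_true(outside, 3, -1))
  d2 <- array(cpp_edt_sq(as.logical(surface), dim(tumor), labelmap$spacing),
              dim(tumor))
  depth <- sqrt(min(d2[tumor]))
  touches <- any(tumor & surface)
  if (touches) depth <- 0
  attr(depth, "touches_surface") <- touches
  depth
}

# shift with TRUE padding (out-of-grid counts as outside the brain)
.shift_pad_true <- function(a, axis, by) {
  out <- !.shift_pad_false(!a, axis, by)
  out
}

#' Categorize tumor depth
#'
#' Cortex when the tumor reaches the surface; otherwise intermediate below
#' 20 mm, deep from 20 to 40 mm inclusive, very deep beyond 40 mm.
#'
#' @param depth mm, >= 0.
#' @param touches_surface logical.
#' @return One of `"cortex"`, `"intermediate"`, `"deep"`, `"very_deep"`.
#' @export
categorize_depth <- function(depth, touches_surface = FALSE) {
  if (depth < 0) stop("depth must be >= 0", call. = FALSE)
  if (isTRUE(touches_surface)) return("cortex")
  if (depth < 20) "intermediate" else if (depth <= 40) "deep" else "very_deep"
}

#' Score the change in craniotomy size
#'
#' Percent change is measured relative to the MR-based plan:
#' `100 * |area_3d - area_mr| / area_mr`. Scores: 0 below 25%, 1 for
#' 25-50%, 2 for 50-75%, 3 at or above 75% (changes beyond 100% clamp to 3).
#'
#' @param area_mr craniotomy area of the MR-based plan, mm^2, > 0.
#' @param area_3d craniotomy area of the model-based plan, mm^2, >= 0.
#' @return Integer score 0-3.
#' @export
score_size_change <- function(area_mr, area_3d) {
  if (area_mr <= 0) stop("reference area must be > 0", call. = FALSE)
  if (area_3d < 0) stop("area must be >= 0", call. = FALSE)
  change <- 100 * abs(area_3d - area_mr) / area_mr
  if (change < 25) 0L else if (change < 50) 1L else if (change < 75) 2L else 3L
}

#' Score the change in craniotomy location
#'
#' Overlap defaults to the Jaccard index of the two regions. Scores: 0 for
#' overlap above 0.90, 1 for overlap in (0.50, 0.90], 2 at or below 0.50.
#'
#' @param region_mr,region_3d congruent nonempty 2-D logical masks.
#' @param method `"jaccard"` (intersection over union) or
#'   `"relative_first"` (intersection over the MR-plan area).
#' @return Integer score 0-2; the overlap used is attached as attribute
#'   `overlap`.
#' @export
score_location_change <- function(region_mr, region_3d,
                                  method = c("jaccard", "relative_first")) {
  method <- match.arg(method)
  region_mr <- as.matrix(region_mr) != 0
  region_3d <- as.matrix(region_3d) != 0
  if (!identical(dim(region_mr), dim(region_3d)))
    stop("masks must be congruent", call. = FALSE)
  if (!any(region_mr) || !any(region_3d))
    stop("masks must be nonempty", call. = FALSE)
  inter <- sum(region_mr & region_3d)
  ov <- switch(method,
               jaccard = inter / sum(region_mr | region_3d),
               relative_first = inter / sum(region_mr))
  score <- if (ov > 0.90) 0L else if (ov > 0.50) 1L else 2L
  attr(score, "overlap") <- ov
  score
}

#' Compare two craniotomy plans
#'
#' @param plan_mr,plan_3d [craniotomy_plan()]s on the same raster.
#' @param pixel_area_mm2 area of one raster pixel, mm^2.
#' @return List with posture/side/rotation/goal change flags and the two
#'   scores.
#' @export
compare_plans <- function(plan_mr, plan_3d, pixel_area_mm2 = 1) {
  stopifnot(inherits(plan_mr, "craniotomy_plan"),
            inherits(plan_3d, "craniotomy_plan"))
  a_mr <- sum(plan_mr$craniotomy_region) * pixel_area_mm2
  a_3d <- sum(plan_3d$craniotomy_region) * pixel_area_mm2
  list(posture_changed = plan_mr$posture != plan_3d$posture ||
         plan_mr$side != plan_3d$side,
       rotation_changed = plan_mr$rotation_deg != plan_3d$rotation_deg,
       goal_changed = plan_mr$resection_goal != plan_3d$resection_goal,
       size_score = score_size_change(a_mr, a_3d),
       location_score = score_location_change(plan_mr$craniotomy_region,
                                              plan_3d$craniotomy_region))
}
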