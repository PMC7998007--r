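# Shared fixtures, built in code at test time.

dice_coefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# digital ball mask: voxel centres within `radius` of the centre
digital_ball <- function(radius, n = 2 * radius + 5, center = rep((n + 1) / 2, 3)) {
  idx <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  d2 <- (idx$i - center[1])^2 + (idx$j - center[2])^2 + (idx$k - center[3])^2
  array(d2 <= radius^2, c(n, n, n))
}

# cached default phantoms so several tests can share one generation
.phantom_cache <- new.env(parent = emptyenv())
cached_phantom <- function(seed = 42, noise_sigma = 5) {
  key <- sprintf("s%d_n%g", seed, noise_sigma)
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom(
      phantom_spec(seed = seed, noise_sigma = noise_sigma))
  .phantom_cache[[key]]
}

# a small fast phantom for pipeline-level tests
small_phantom_spec <- function(seed = 7, noise_sigma = 4) {
  phantom_spec(seed = seed, shape = c(48, 48, 48), noise_sigma = noise_sigma,
               brain_radius = 18, gyri_amplitude = 1.5, gyri_frequency = 8,
               tumor = list(center = c(6, 4, 2), radius = 6, mean = 160))
}

# independent convex-polygon rasterization oracle: a centre is inside a
# convex ring iff it lies on the inner side of (or on) every edge
convex_fill_oracle <- function(verts, nu, nv) {
  or <- 0
  n <- nrow(verts)
  jn <- c(2:n, 1)
  area2 <- sum(verts[, 1] * verts[jn, 2] - verts[jn, 1] * verts[, 2])
  s <- sign(area2)
  pts <- as.matrix(expand.grid(u = 0:(nu - 1), v = 0:(nv - 1)))
  keep <- rep(TRUE, nrow(pts))
  for (e in 1:n) {
    ex <- verts[jn[e], 1] - verts[e, 1]
    ey <- verts[jn[e], 2] - verts[e, 2]
    cr <- ex * (pts[, 2] - verts[e, 2]) - ey * (pts[, 1] - verts[e, 1])
    keep <- keep & (s * cr >= -1e-9)
  }
  sum(keep)
}
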