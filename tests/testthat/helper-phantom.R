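# Small geometries used across tests: default study geometry and a coarse
# variant whose distal zone exceeds 10^4 voxels for large-sample checks.
test_geom <- function() phantom_geometry()

big_distal_geom <- function() {
  phantom_geometry(grid_shape = c(24L, 24L, 48L), bone_axis = 3L,
                   n_slices_proximal = 8L, n_slices_transition = 8L,
                   n_slices_distal = 32L, marrow_radius_voxels = 10L)
}

# Independent brute-force oracle for the trimmed-variance score:
# sort, linearly interpolate the percentile between order statistics,
# filter, then a two-pass variance.
oracle_trimmed_variance <- function(values, trim = 90) {
  x <- sort(values)
  n <- length(x)
  h <- (n - 1) * trim / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  threshold <- x[lo] + (h - lo) * (x[hi] - x[lo])
  kept <- x[x <= threshold]
  m <- sum(kept) / length(kept)
  sum((kept - m)^2) / (length(kept) - 1)
}

# Beta shape parameters for a mean/variance on the percent scale,
# written out independently of the package internals.
oracle_beta_shapes <- function(mean_pdff, variance) {
  mu <- mean_pdff / 100; s2 <- variance / 1e4
  nu <- mu * (1 - mu) / s2 - 1
  c(alpha = mu * nu, beta = (1 - mu) * nu)
}
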