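# Shared fixtures, built once per test run.

# canonical 2.5-um spherical 2C nucleus at 0.1-um isotropic voxels
sphere_img <- make_nucleus(nucleus_spec())
sphere_field <- boundary_distance_field(sphere_img$mask, sphere_img$voxel_size_um)

# analytic fraction of a sphere's volume within `cut` of its surface
shell_fraction <- function(R, cut) 1 - ((R - cut) / R)^3

# independent exhaustive nearest-outside-voxel distance oracle (space beyond
# the array border counts as outside, matching edt_um's convention)
brute_force_edt <- function(mask, vox) {
  d <- dim(mask)
  dp <- d + 2L
  pm <- array(FALSE, dp)
  pm[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  co <- function(i) {
    i <- i - 1L
    cbind(i %% dp[1], (i %/% dp[1]) %% dp[2], i %/% (dp[1] * dp[2]))
  }
  A <- co(which(pm))
  B <- co(which(!pm))
  D2 <- outer(A[, 1] * vox[1], B[, 1] * vox[1], "-")^2 +
    outer(A[, 2] * vox[2], B[, 2] * vox[2], "-")^2 +
    outer(A[, 3] * vox[3], B[, 3] * vox[3], "-")^2
  res <- array(0, dp)
  res[which(pm)] <- sqrt(apply(D2, 1, min))
  res[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

# rasterise an axis-aligned ellipsoid mask centred in its grid
ellipsoid_mask <- function(semi_axes_um, voxel_um, margin_vox = 4L) {
  dims <- ceiling(2 * semi_axes_um / voxel_um) + 2L * margin_vox
  ctr <- dims * voxel_um / 2
  ax <- function(k) (seq_len(dims[k]) - 0.5) * voxel_um[k]
  r2 <- outer(outer(((ax(1) - ctr[1]) / semi_axes_um[1])^2,
                    ((ax(2) - ctr[2]) / semi_axes_um[2])^2, "+"),
              ((ax(3) - ctr[3]) / semi_axes_um[3])^2, "+")
  r2 <= 1
}

# simulate one paired-nucleus P0.5 table from radial models (green, red)
sim_p05_pairs <- function(n_nuclei, model_green, model_red, seed0,
                          n_spots = 200L) {
  do.call(rbind, lapply(seq_len(n_nuclei), function(i) {
    g <- sample_interior_points(sphere_field, sphere_img$mask,
                                sphere_img$voxel_size_um, n_spots,
                                model_green, seed = seed0 + 2L * i)
    r <- sample_interior_points(sphere_field, sphere_img$mask,
                                sphere_img$voxel_size_um, n_spots,
                                model_red, seed = seed0 + 2L * i + 1L)
    data.frame(p05_green = painting_profile(g$d_um)$p05,
               p05_red = painting_profile(r$d_um)$p05)
  }))
}

# default planted-domain layout for island-caller simulations: ten 10-kb
# domains evenly spaced on a 2-Mb chromosome
planted_domain_layout <- function() {
  s <- seq(1e5, 1.9e6, by = 2e5)
  data.frame(chrom = "chr1", start = s, end = s + 1e4)
}
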