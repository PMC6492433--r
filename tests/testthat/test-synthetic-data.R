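test_that("rasterised nuclei have the right geometry and are reproducible", {
  # sphere volume
  vol <- sum(sphere_img$mask) * prod(sphere_img$voxel_size_um)
  expect_lt(abs(vol - 4 / 3 * pi * 2.5^3) / (4 / 3 * pi * 2.5^3), 0.05)

  # zero background: every nonzero DAPI voxel satisfies the ellipsoid equation
  sp <- nucleus_spec(semi_axes_um = c(2, 1.5, 1), background_level = 0)
  img <- make_nucleus(sp)
  expect_true(all((img$channels$dapi > 0) == img$mask))

  # same seed twice -> bit-identical noisy images
  spn <- nucleus_spec(poisson_noise = TRUE, seed = 11)
  expect_identical(make_nucleus(spn)$channels$dapi,
                   make_nucleus(spn)$channels$dapi)

  # ellipsoid exceeding an explicit grid errors naming the axis
  expect_error(make_nucleus(nucleus_spec(dims_vox = c(60, 60, 30))),
               "axis 3")
})

test_that("uniform scattering follows the shell-volume law", {
  pts <- sample_interior_points(sphere_field, sphere_img$mask,
                                sphere_img$voxel_size_um, 10000,
                                radial_model("uniform"), seed = 21)
  d_all <- sphere_field[sphere_img$mask]
  # voxel-enumeration reference for the 0.5-um shell, then the analytic law
  p_ref <- mean(d_all <= 0.5)
  expect_lt(abs(p_ref - shell_fraction(2.5, 0.5)), 0.02)
  sd3 <- 3 * sqrt(p_ref * (1 - p_ref) / 10000)
  expect_lt(abs(mean(pts$d_um <= 0.5) - p_ref), sd3)
  # whole empirical distance distribution matches the enumeration law
  xs <- sort(unique(d_all))
  ks <- max(abs(stats::ecdf(pts$d_um)(xs) - stats::ecdf(d_all)(xs)))
  expect_lt(ks, 0.02)
})

test_that("boundary bias has the correct small- and large-beta limits", {
  p_small <- sample_interior_points(sphere_field, sphere_img$mask,
                                    sphere_img$voxel_size_um, 500,
                                    radial_model("boundary_bias", 0.01),
                                    seed = 5)
  expect_gte(mean(p_small$d_um <= 0.2), 0.99)

  p_large <- sample_interior_points(sphere_field, sphere_img$mask,
                                    sphere_img$voxel_size_um, 2000,
                                    radial_model("boundary_bias", 1e6),
                                    seed = 6)
  p_unif <- sample_interior_points(sphere_field, sphere_img$mask,
                                   sphere_img$voxel_size_um, 2000,
                                   radial_model("uniform"), seed = 7)
  ks <- suppressWarnings(stats::ks.test(p_large$d_um, p_unif$d_um))
  expect_gt(ks$p.value, 0.01)
})

test_that("scattered spots land in the channel with recorded truth", {
  img <- scatter_channel(make_nucleus(nucleus_spec()), 20,
                         radial_model("uniform"), "green", seed = 31)
  expect_equal(sum(img$channels$green), 20, tolerance = 0.02)
  expect_equal(nrow(img$spots_truth$green), 20)
  # empty channel for zero spots, no error
  img0 <- scatter_channel(make_nucleus(nucleus_spec()), 0,
                          radial_model("uniform"), "red", seed = 1)
  expect_true(all(img0$channels$red == 0))
})

test_that("simulated contact matrices carry the prescribed block structure", {
  labs <- rep(rep(c("A", "B"), each = 10), length.out = 100)
  same <- outer(labs, labs, "==")
  sep <- abs(outer(1:100, 1:100, "-"))

  # s = 0.5: expected same/cross ratio at fixed separation is exactly 3
  mu <- contact_expectation(hic_sim_config(n_bins = 100, labels = labs,
                                           strength_s = 0.5))
  pick <- sep == 5
  expect_equal(mean(mu[pick & same]) / mean(mu[pick & !same]), 3)

  # s = 1: expected cross-label counts are exactly zero
  mu1 <- contact_expectation(hic_sim_config(n_bins = 100, labels = labs,
                                            strength_s = 1))
  expect_true(all(mu1[!same] == 0))

  # s = 0: sampled same- vs cross-label ratio near 1 at fixed separations
  cm <- simulate_contact_matrix(hic_sim_config(n_bins = 100, labels = labs,
                                               strength_s = 0,
                                               mean_depth = 50, seed = 8))
  ratios <- vapply(1:5, function(d) {
    pick <- sep == d
    mean(cm$counts[pick & same]) / mean(cm$counts[pick & !same])
  }, numeric(1))
  expect_gt(mean(ratios), 0.95)
  expect_lt(mean(ratios), 1.05)

  # expected total calibrated to mean_depth * n^2
  expect_equal(sum(mu), 50 * 100^2, tolerance = 1e-10)

  # row sums concentrate around expectation
  expect_lt(stats::sd(rowSums(cm$counts)) / mean(rowSums(cm$counts)),
            3 / sqrt(mean(cm$counts[cm$counts > 0])))

  expect_error(hic_sim_config(strength_s = 1.2), "strength_s")
})

test_that("rechip response generator is linear, noisy and reproducible", {
  X <- matrix(rnorm(200 * 4), ncol = 4)
  # noiseless unit coefficient returns column 1 exactly
  expect_equal(simulate_rechip_response(X, c(1, 0, 0, 0), noise_sd = 0), X[, 1])
  # pure noise has mean near 0
  y <- simulate_rechip_response(X, rep(0, 4), noise_sd = 1, seed = 3)
  expect_lt(abs(mean(y)), 4 / sqrt(200))
  # reproducible under a fixed seed
  expect_identical(simulate_rechip_response(X, rep(1, 4), 1, seed = 9),
                   simulate_rechip_response(X, rep(1, 4), 1, seed = 9))
  expect_error(simulate_rechip_response(X, c(1, 2)), "does not match")
})

test_that("ChIP track simulation plants enrichment where asked", {
  # a 300-bp domain inside one 500-bp window elevates exactly that window
  dom <- data.frame(start = 10100, end = 10400)
  rates <- rowMeans(vapply(1:200, function(s) {
    tr <- simulate_chip_tracks(track_sim_config(genome_length_bp = 5e4,
                                                planted_domains = dom,
                                                enrichment_fold = 8,
                                                depth = 20, seed = s))
    tr$treatment$values
  }, numeric(100)))
  expect_identical(which(rates > 60), 21L)  # window 21 covers [10000, 10500)
  # control is flat at depth
  tr <- simulate_chip_tracks(track_sim_config(seed = 2))
  expect_equal(mean(tr$control$values), 20, tolerance = 0.05)
  expect_error(track_sim_config(planted_domains = data.frame(start = -5, end = 10)),
               "within")
})
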