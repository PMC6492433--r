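test_that("ICE balancing converges, inverts constructed biases and is idempotent", {
  # constant off-diagonal matrix is already balanced
  M <- matrix(5, 30, 30); diag(M) <- 0
  b0 <- ice_balance(contact_matrix(M, 1000), mask_fraction = 0)
  expect_true(b0$converged)
  ratio <- b0$values / M
  expect_lt(diff(range(ratio[is.finite(ratio)])), 1e-12)

  # diag(bias) %*% M %*% diag(bias) recovers M up to scale, bias up to scale
  cm <- simulate_contact_matrix(hic_sim_config(n_bins = 80, strength_s = 0.4,
                                               mean_depth = 200, seed = 2))
  bal <- ice_balance(cm, mask_fraction = 0, eps = 1e-10, max_iter = 2000)
  M0 <- bal$values
  bias <- withr::with_seed(3, exp(stats::runif(80, -0.5, 0.5)))
  rebal <- ice_balance(contact_matrix(diag(bias) %*% M0 %*% diag(bias), 20000),
                       mask_fraction = 0, eps = 1e-8, max_iter = 2000)
  rat <- rebal$values / M0
  rat <- rat[is.finite(rat)]
  expect_lt(max(abs(rat / mean(rat) - 1)), 1e-3)
  brat <- rebal$bias_vector / bias
  expect_lt(max(abs(brat / mean(brat) - 1)), 1e-3)

  # converged marginals deviate by less than eps = 1e-4
  b1 <- ice_balance(cm, mask_fraction = 0)
  keep <- !b1$masked
  s <- rowSums(b1$values[keep, keep])
  expect_lt(max(abs(s / mean(s) - 1)), 1e-4)
  expect_true(b1$converged)

  # idempotence: balancing a balanced matrix changes it by < eps
  again <- ice_balance(contact_matrix(b1$values[keep, keep] * 1e4, 20000),
                       mask_fraction = 0)
  expect_lt(again$final_eps, 1e-4)

  expect_error(ice_balance(contact_matrix(matrix(0, 5, 5), 1000)), "all-zero")
})

test_that("observed/expected removes distance decay exactly", {
  # pure distance-decay input: all O/E entries are 1
  n <- 20
  sep <- abs(outer(1:n, 1:n, "-"))
  vals <- 3 * (sep + 1)^-1.2
  diag(vals) <- 0
  b <- structure(list(values = vals, bias_vector = rep(1, n),
                      masked = rep(FALSE, n), converged = TRUE,
                      final_eps = 0, bin_size_bp = 1000L,
                      bins = data.frame(chrom = "chr1", start = 0:(n - 1) * 1000)),
                 class = "balanced_matrix")
  oe <- observed_over_expected(b)
  off <- oe[sep > 0]
  expect_equal(off, rep(1, length(off)), tolerance = 1e-12)

  # hand 6x6 oracle: per-diagonal means computed independently
  set.seed(10)
  v6 <- matrix(stats::runif(36, 1, 5), 6)
  v6 <- (v6 + t(v6)) / 2; diag(v6) <- 0
  b6 <- b; b6$values <- v6; b6$masked <- rep(FALSE, 6)
  b6$bins <- data.frame(chrom = "chr1", start = 0:5 * 1000)
  oe6 <- observed_over_expected(b6)
  s6 <- abs(outer(1:6, 1:6, "-"))
  for (d in 1:5) {
    exp_d <- mean(v6[s6 == d])
    expect_equal(oe6[s6 == d], v6[s6 == d] / exp_d, tolerance = 1e-12)
    expect_equal(mean(oe6[s6 == d]), 1, tolerance = 1e-12)
  }
})

test_that("correlation matrices expose block structure and match hand values", {
  # s = 1 synthetic: within-block positive, cross-block negative
  labs <- rep(rep(c("A", "B"), each = 10), length.out = 100)
  cm <- simulate_contact_matrix(hic_sim_config(n_bins = 100, labels = labs,
                                               strength_s = 1,
                                               mean_depth = 100, seed = 4))
  oe <- observed_over_expected(ice_balance(cm))
  co <- correlation_matrix(oe)
  same <- outer(labs, labs, "==")
  off <- row(co) != col(co) & !is.na(co)
  expect_gt(mean(co[off & same]), 0.5)
  expect_lt(mean(co[off & !same]), -0.5)

  # 4x4 hand oracle: Pearson by the explicit formula
  m4 <- matrix(c(NA, 1.2, 0.8, 1.1,
                 1.2, NA, 1.3, 0.7,
                 0.8, 1.3, NA, 0.9,
                 1.1, 0.7, 0.9, NA), 4, 4)
  diag(m4) <- 1
  co4 <- correlation_matrix(m4)
  hand_pearson <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  expect_equal(co4[1, 2], hand_pearson(m4[1, ], m4[2, ]), tolerance = 1e-12)
  expect_equal(co4[3, 4], hand_pearson(m4[3, ], m4[4, ]), tolerance = 1e-12)
  expect_equal(diag(co4), rep(1, 4))
  expect_equal(co4, t(co4))
})

test_that("compartment calls recover truth at high strength and orient by the track", {
  labs <- rep(rep(c("A", "B"), each = 10), length.out = 100)
  truth_track <- as.numeric(labs == "A")
  cm <- simulate_contact_matrix(hic_sim_config(n_bins = 100, labels = labs,
                                               strength_s = 1,
                                               mean_depth = 100, seed = 4))
  call <- call_compartments(
    correlation_matrix(observed_over_expected(ice_balance(cm))), truth_track)
  um <- call$label != "masked"
  expect_gte(mean(call$label[um] == labs[um]), 0.95)
  # orientation rule: A bins have positive eigenvector entries
  expect_true(all(call$eigenvector[um][call$label[um] == "A"] > 0))

  # s = 0: agreement with the fixed labeling is chance-level
  cm0 <- simulate_contact_matrix(hic_sim_config(n_bins = 100, labels = labs,
                                                strength_s = 0,
                                                mean_depth = 100, seed = 5))
  call0 <- call_compartments(
    correlation_matrix(observed_over_expected(ice_balance(cm0))), truth_track)
  um0 <- call0$label != "masked"
  agree0 <- mean(call0$label[um0] == labs[um0])
  expect_gte(agree0, 0.4)
  expect_lte(agree0, 0.6)
})

test_that("compartment agreement is 1 on self, 0 on flip, high across replicates", {
  labs <- rep(rep(c("A", "B"), each = 10), length.out = 120)
  track <- as.numeric(labs == "A")
  calls <- lapply(c(11, 12), function(s) {
    cm <- simulate_contact_matrix(hic_sim_config(n_bins = 120, labels = labs,
                                                 strength_s = 0.8,
                                                 mean_depth = 100, seed = s))
    call_compartments(correlation_matrix(observed_over_expected(ice_balance(cm))),
                      track)
  })
  expect_equal(compartment_agreement(calls[[1]], calls[[1]]), 1.0)
  flipped <- calls[[1]]
  flipped$label <- c(A = "B", B = "A", masked = "masked")[flipped$label]
  expect_equal(compartment_agreement(calls[[1]], flipped), 0.0)
  expect_gte(compartment_agreement(calls[[1]], calls[[2]]), 0.9)
})

test_that("compartment strength tracks the simulated attenuation", {
  labs <- rep(rep(c("A", "B"), each = 10), length.out = 200)
  run <- function(s, seed) {
    cm <- simulate_contact_matrix(hic_sim_config(n_bins = 200, labels = labs,
                                                 strength_s = s,
                                                 mean_depth = 100, seed = seed))
    oe <- observed_over_expected(ice_balance(cm))
    call <- call_compartments(correlation_matrix(oe), as.numeric(labs == "A"))
    list(oe = oe, call = call,
         st = compartment_strength(oe, call, bin_size_bp = 20000))
  }
  # no compartments, truth labeling: mean AB O/E ~ 1
  r0 <- run(0, 21)
  truth_call <- r0$call
  truth_call$label <- ifelse(truth_call$label == "masked", "masked", labs)
  st0 <- compartment_strength(r0$oe, truth_call, bin_size_bp = 20000)
  expect_gt(st0$mean_AB_relative, 0.95)
  expect_lt(st0$mean_AB_relative, 1.05)

  # attenuation direction: lower s -> higher cross-compartment O/E
  r_wt <- run(0.6, 22)
  r_mut <- run(0.3, 23)
  cmp <- compare_compartment_strength(r_wt$st, r_mut$st)
  expect_gt(cmp$mean_AB_b, cmp$mean_AB_a)
  expect_lt(cmp$mw_p, 0.01)

  # single cross-compartment pair is returned verbatim
  oe2 <- matrix(c(NA, 1.3, 1.3, NA), 2, 2)
  call2 <- structure(list(eigenvector = c(1, -1), label = c("A", "B"),
                          eigen_gap = 1, degenerate = FALSE),
                     class = "compartment_call")
  st2 <- compartment_strength(oe2, call2, max_sep_bp = 1e6, bin_size_bp = 20000)
  expect_equal(st2$oe_values_AB, 1.3)
})

test_that("trans-contact fractions count inter-chromosomal mass", {
  bins <- data.frame(chrom = rep(c("chr1", "chr2"), each = 3),
                     start = rep(0:2 * 1000, 2))
  blockdiag <- matrix(0, 6, 6)
  blockdiag[1:3, 1:3] <- 4; blockdiag[4:6, 4:6] <- 4
  diag(blockdiag) <- 0
  m1 <- contact_matrix(blockdiag, 1000, bins = bins)
  expect_equal(trans_contact_fraction(m1)$trans_fraction, 0)

  offblock <- matrix(0, 6, 6)
  offblock[1:3, 4:6] <- 2; offblock[4:6, 1:3] <- 2
  m2 <- contact_matrix(offblock, 1000, bins = bins)
  expect_equal(trans_contact_fraction(m2)$trans_fraction, 1)

  # hand toy: cis 80, trans 20 -> 0.20
  toy <- matrix(0, 6, 6)
  toy[1, 2] <- 10; toy[2, 1] <- 10; toy[4, 5] <- 10; toy[5, 4] <- 10
  toy[1, 4] <- 5; toy[4, 1] <- 5
  m3 <- contact_matrix(toy, 1000, bins = bins)
  res <- trans_contact_fraction(m3)
  expect_equal(res$trans_fraction, 0.2)
  expect_equal(res$per_pair$fraction, 0.2)
})
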