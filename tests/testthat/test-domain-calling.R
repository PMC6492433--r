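test_that("window counting matches brute-force binning for reads and coverage", {
  reads <- data.frame(chrom = "chr1", start = c(10, 200, 499))
  wc <- window_counts(reads, W_bp = 500, chrom_length_bp = 2000)
  expect_equal(wc$chr1$values, c(3, 0, 0, 0))

  cov <- data.frame(chrom = "chr1", start = 0, end = 5000, value = 2.0)
  expect_equal(window_counts(cov, 500, mode = "mass")$chr1$values,
               rep(1000, 10))
  expect_equal(window_counts(cov, 500, mode = "mean")$chr1$values,
               rep(2, 10))

  withr::with_seed(5, {
    r <- data.frame(chrom = "chr1", start = sample(0:9999, 300, TRUE))
    got <- suppressWarnings(
      window_counts(r, 500, chrom_length_bp = 10000))$chr1$values
    oracle <- vapply(0:19, function(w) {
      sum(r$start >= w * 500 & r$start < (w + 1) * 500)
    }, numeric(1))
    expect_equal(got, oracle)
  })
})

test_that("the island merge rule honours the gap parameter G exactly", {
  n <- 60
  mk <- function(spikes) {
    t <- rep(20, n); t[spikes] <- 200
    list(treatment = signal_track(t, 500), control = signal_track(rep(20, n), 500))
  }
  # 1500-bp gap (three quiet windows): one island
  one <- call_islands(mk(c(10, 14))$treatment, mk(c(10, 14))$control,
                      G = 1500, fdr = 0.01)
  expect_equal(nrow(one$islands), 1)
  expect_equal(one$islands$start, (10 - 1) * 500)
  expect_equal(one$islands$end, 14 * 500)
  # 2000-bp gap: two islands
  two <- call_islands(mk(c(10, 15))$treatment, mk(c(10, 15))$control,
                      G = 1500, fdr = 0.01)
  expect_equal(nrow(two$islands), 2)
})

test_that("planted domains are recovered and the null yields nothing", {
  dom <- planted_domain_layout()
  tr <- simulate_chip_tracks(track_sim_config(planted_domains = dom[, -1],
                                              enrichment_fold = 8, depth = 20,
                                              seed = 3))
  ic <- call_islands(tr$treatment, tr$control)
  expect_gte(domain_overlap(dom, ic$islands)$jaccard, 0.9)

  null_tr <- simulate_chip_tracks(track_sim_config(enrichment_fold = 1,
                                                   depth = 20, seed = 4))
  expect_equal(nrow(call_islands(null_tr$treatment, null_tr$control)$islands), 0)

  # monotone recovery in enrichment fold
  jac <- vapply(c(2, 8), function(f) {
    t2 <- simulate_chip_tracks(track_sim_config(planted_domains = dom[, -1],
                                                enrichment_fold = f,
                                                depth = 20, seed = 7))
    domain_overlap(dom, call_islands(t2$treatment, t2$control)$islands)$jaccard
  }, numeric(1))
  expect_lte(jac[1], jac[2])
})

test_that("replicate intersection and overlap follow interval algebra", {
  a <- data.frame(chrom = "chr1", start = c(100, 1000), end = c(500, 1500))
  b <- data.frame(chrom = "chr1", start = 300, end = 800)
  expect_equal(intersect_replicates(a, a), perilad:::.normalize_intervals(a))
  expect_equal(nrow(intersect_replicates(
    a, data.frame(chrom = "chr1", start = 5000, end = 6000))), 0)
  got <- intersect_replicates(a, b)
  expect_equal(got$start, 300)
  expect_equal(got$end, 500)

  # intersection is a base-pair subset of both inputs
  withr::with_seed(9, {
    for (rep in 1:3) {
      ra <- data.frame(chrom = "chr1", start = sort(sample(0:1e5, 5)) * 10)
      ra$end <- ra$start + sample(500:5000, 5)
      rb <- data.frame(chrom = "chr1", start = sort(sample(0:1e5, 5)) * 10)
      rb$end <- rb$start + sample(500:5000, 5)
      it <- intersect_replicates(ra, rb)
      if (nrow(it) > 0) {
        expect_equal(domain_overlap(it, ra)$fraction_of_a_covered, 1)
        expect_equal(domain_overlap(it, rb)$fraction_of_a_covered, 1)
      }
    }
  })

  expect_equal(domain_overlap(a, a), list(jaccard = 1,
                                          fraction_of_a_covered = 1,
                                          fraction_of_b_covered = 1))
  ov <- domain_overlap(data.frame(chrom = "chr1", start = 0, end = 100),
                       data.frame(chrom = "chr1", start = 50, end = 150))
  expect_equal(ov$jaccard, 1 / 3)
  expect_equal(ov$fraction_of_a_covered, 0.5)
  expect_equal(ov$fraction_of_b_covered, 0.5)
})

test_that("log-ratio tracks behave at the identity, fold-4 and hand cases", {
  t1 <- signal_track(c(40, 40, 40, 40), 500)
  expect_equal(log_ratio_track(t1, t1)$values, rep(0, 4))

  # fold-4 treatment over depth-matched input (explicit scale 1) comes out ~2
  t4 <- signal_track(rep(4000, 4), 500)
  i4 <- signal_track(rep(1000, 4), 500)
  expect_equal(log_ratio_track(t4, i4, scale = 1)$values, rep(2, 4),
               tolerance = 1e-3)
  # with the computed depth ratio the global fold is absorbed
  expect_equal(log_ratio_track(t4, i4)$values, rep(0, 4), tolerance = 1e-3)
  # hand 5-window oracle with pc = 1
  tv <- signal_track(c(40, 10, 0, 25, 5), 500)
  iv <- signal_track(c(20, 20, 20, 10, 10), 500)
  s <- 80 / 80
  expect_equal(log_ratio_track(tv, iv)$values,
               log2((tv$values + 1) / (s * iv$values + 1)))

  # both-zero windows masked
  tz <- signal_track(c(0, 10), 500); iz <- signal_track(c(0, 5), 500)
  expect_true(is.na(log_ratio_track(tz, iz)$values[1]))
  expect_error(log_ratio_track(t1, signal_track(1:5, 500)), "grid")
})

test_that("inside-vs-flank comparison detects accessibility contrasts", {
  dom <- data.frame(chrom = "chr1", start = 20000, end = 30000)
  n <- 100
  # constant track: no contrast
  flat <- signal_track(rep(5, n), 500)
  r0 <- signal_in_and_flank(flat, dom)
  expect_equal(r0$mean_inside, r0$mean_flank)
  expect_gt(r0$p, 0.9)

  # inside 0, flank 1
  v <- rep(NA_real_, n)
  v[41:60] <- 0                      # windows covering [20000, 30000)
  v[c(39, 40, 61, 62)] <- 1          # 1-kb flanks
  contrast <- signal_track(ifelse(is.na(v), 3, v), 500)
  r1 <- signal_in_and_flank(contrast, dom)
  expect_lt(r1$mean_inside, r1$mean_flank)
  expect_lt(r1$p, 0.02)

  # domain at the chromosome start: left flank empty, no error
  dom0 <- data.frame(chrom = "chr1", start = 0, end = 5000)
  expect_no_error(signal_in_and_flank(flat, dom0))
})

test_that("peak-overlap stratification respects half-open coordinates", {
  reg <- data.frame(chrom = "chr1", start = 0, end = 50000)
  n <- 100
  peaks <- data.frame(chrom = "chr1", start = c(10000, 30000),
                      end = c(12000, 31000))
  # chip values: 1 minus peak indicator per window
  ws <- (seq_len(n) - 1) * 500
  we <- ws + 500
  hit <- (ws < 12000 & we > 10000) | (ws < 31000 & we > 30000)
  chip <- signal_track(as.numeric(!hit), 500)
  r <- stratify_by_peak_overlap(chip, reg, peaks)
  expect_equal(r$mean_overlap, 0)
  expect_equal(r$mean_no_overlap, 1)
  expect_lt(r$p, 1e-6)

  # a window exactly abutting a peak end is non-overlapping
  ab <- stratify_by_peak_overlap(chip, data.frame(chrom = "chr1",
                                                  start = 12000, end = 12500),
                                 peaks)
  expect_equal(ab$n_overlap, 0)
  expect_true(ab$undefined)

  # empty peaks: one group, flagged undefined
  r2 <- stratify_by_peak_overlap(chip, reg,
                                 data.frame(chrom = character(0),
                                            start = numeric(0),
                                            end = numeric(0)))
  expect_true(r2$undefined)
})

test_that("qPCR fold enrichment follows the delta-delta-Ct rule", {
  tab <- data.frame(
    locus = rep(c("TUB2", "L1", "L2"), each = 2),
    template = rep(c("IP", "input"), 3),
    Ct = c(28, 24, 26, 24, 27, 27))
  res <- qpcr_fold_enrichment(tab)
  expect_equal(res$fold_enrichment[res$locus == "TUB2"], 1)
  # L1: dCt = 2, two cycles smaller than TUB2's 4 -> fold 4
  expect_equal(res$fold_enrichment[res$locus == "L1"], 4)
  # L2: dCt = 0 -> 2^4 = 16
  expect_equal(res$fold_enrichment[res$locus == "L2"], 16)

  expect_error(qpcr_fold_enrichment(tab[tab$locus != "TUB2", ]), "reference")
  expect_error(qpcr_fold_enrichment(tab[-3, ]), "L1")
})
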