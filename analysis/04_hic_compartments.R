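#!/usr/bin/env Rscript
# Hi-C compartmentalization: wild-type-like vs lamin-mutant-like genotypes.
#
# Two contact-matrix simulations share the same A/B labels (alternating
# 10-bin blocks, 250 bins of 20 kb) and differ only in compartment strength
# (s = 0.6 vs s = 0.3). Each is ICE-balanced to eps < 1e-4, O/E-transformed,
# and compartments are called from the leading eigenvector of the O/E row
# correlation matrix. Cross-compartment interaction strength within 1 Mb
# quantifies the attenuation; a two-chromosome simulation illustrates the
# trans-contact fraction.

suppressMessages(library(perilad))
dir.create("results", showWarnings = FALSE)

labs <- rep(rep(c("A", "B"), each = 10), length.out = 250)
track <- as.numeric(labs == "A")
run <- function(s, seed) {
  cm <- simulate_contact_matrix(hic_sim_config(n_bins = 250, labels = labs,
                                               strength_s = s,
                                               mean_depth = 100, seed = seed))
  bal <- ice_balance(cm)
  oe <- observed_over_expected(bal)
  call <- call_compartments(correlation_matrix(oe), track)
  list(bal = bal, oe = oe, call = call,
       st = compartment_strength(oe, call, bin_size_bp = 20000))
}
wt <- run(0.6, 101)
mut <- run(0.3, 102)

cat(sprintf("ICE converged: wt %s (eps %.2g), mutant %s (eps %.2g)\n",
            wt$bal$converged, wt$bal$final_eps,
            mut$bal$converged, mut$bal$final_eps))
agree <- compartment_agreement(mut$call, wt$call)
cat(sprintf("mutant A/B labels agree with wild type at %.1f%% of bins\n",
            100 * agree))
cmp <- compare_compartment_strength(wt$st, mut$st)
cat(sprintf("mean cross-compartment O/E within 1 Mb: wt %.3f, mutant %.3f (MW p = %.3g)\n",
            cmp$mean_AB_a, cmp$mean_AB_b, cmp$mw_p))

write.csv(data.frame(bin = seq_along(labs), true_label = labs,
                     wt_eigen = wt$call$eigenvector, wt_label = wt$call$label,
                     mut_eigen = mut$call$eigenvector,
                     mut_label = mut$call$label),
          "results/hic_compartment_calls.csv", row.names = FALSE)
write.csv(data.frame(genotype = c("wild_type", "crwn_like"),
                     strength_s = c(0.6, 0.3),
                     mean_ab_oe = c(cmp$mean_AB_a, cmp$mean_AB_b),
                     mw_p = c(NA, cmp$mw_p)),
          "results/hic_compartment_strength.csv", row.names = FALSE)

# trans contacts on a toy two-chromosome genome: the mutant-like genotype
# gets 3x the inter-chromosomal rate
trans_demo <- function(trans_rate, seed) {
  cis <- lapply(c(seed, seed + 1), function(sd) {
    simulate_contact_matrix(hic_sim_config(n_bins = 100, strength_s = 0.5,
                                           mean_depth = 50, seed = sd))$counts
  })
  n <- 200
  counts <- matrix(0, n, n)
  counts[1:100, 1:100] <- cis[[1]]
  counts[101:200, 101:200] <- cis[[2]]
  tr <- withr::with_seed(seed + 2, matrix(rpois(100 * 100, trans_rate), 100))
  counts[1:100, 101:200] <- tr
  counts[101:200, 1:100] <- t(tr)
  bins <- data.frame(chrom = rep(c("chr1", "chr2"), each = 100),
                     start = rep(0:99 * 20000, 2))
  trans_contact_fraction(contact_matrix(counts, 20000, bins = bins))
}
tf_wt <- trans_demo(2, 201)$trans_fraction
tf_mut <- trans_demo(6, 301)$trans_fraction
cat(sprintf("trans-contact fraction: wt-like %.3f, mutant-like %.3f\n",
            tf_wt, tf_mut))
write.csv(data.frame(genotype = c("wild_type", "crwn_like"),
                     trans_fraction = c(tf_wt, tf_mut)),
          "results/hic_trans_fraction.csv", row.names = FALSE)
cat("Attenuated compartment strength with preserved A/B identity and more\n",
    "frequent trans contacts — the mutant signature.\n")
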