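#!/usr/bin/env Rscript
# Chromosome-painting profiles and the paired P0.5 contrast.
#
# For each simulated nucleus, both painting channels are rendered (~500 spots
# each), the cumulative signal profile vs distance to the periphery is
# computed with the bottom two z-slices excluded, and P0.5 — the fraction of
# signal within 0.5 um of the boundary — is read off. Per-nucleus Green/Red
# pairs are compared with the Wilcoxon signed-rank test.

suppressMessages(library(perilad))
dir.create("results", showWarnings = FALSE)

genotypes <- list(
  wild_type = list(green = radial_model("boundary_bias", 0.3),
                   red = radial_model("uniform")),
  crwn1_like = list(green = radial_model("uniform"),
                    red = radial_model("uniform"))
)

profiles <- list()
p05_rows <- list()
for (g in names(genotypes)) {
  for (i in 1:15) {
    s0 <- match(g, names(genotypes)) * 20000 + i * 10
    img <- make_nucleus(nucleus_spec(seed = s0))
    img <- scatter_channel(img, 500, genotypes[[g]]$green, "green", seed = s0 + 1)
    img <- scatter_channel(img, 500, genotypes[[g]]$red, "red", seed = s0 + 2)
    field <- boundary_distance_field(img$mask, img$voxel_size_um)
    pg <- cumulative_signal_profile(img, "green", field, nucleus_id = i)
    pr <- cumulative_signal_profile(img, "red", field, nucleus_id = i)
    p05_rows[[length(p05_rows) + 1]] <-
      data.frame(genotype = g, nucleus = i,
                 p05_green = pg$p05, p05_red = pr$p05)
    profiles[[length(profiles) + 1]] <-
      data.frame(genotype = g, nucleus = i,
                 channel = rep(c("green", "red"),
                               c(length(pg$distances_um), length(pr$distances_um))),
                 d_um = c(pg$distances_um, pr$distances_um),
                 cum_fraction = c(pg$cumulative_fraction, pr$cumulative_fraction))
  }
}
p05 <- do.call(rbind, p05_rows)
write.csv(do.call(rbind, profiles), "results/painting_profiles.csv",
          row.names = FALSE)
write.csv(p05, "results/painting_p05.csv", row.names = FALSE)

for (g in names(genotypes)) {
  res <- paired_p05_test(p05[p05$genotype == g, c("p05_green", "p05_red")])
  cat(sprintf(
    "%-10s mean P0.5 green %.3f red %.3f | green>red in %d/%d | Wilcoxon p = %.3g\n",
    g, res$mean_green, res$mean_red, res$n_green_gt_red, res$n_pairs,
    res$p_value))
}
cat("The wild-type contrast collapses when both channels share one radial\n",
    "model, the crwn1-like pattern.\n")
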