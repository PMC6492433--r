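#' Build a cumulative painting profile from distances and weights
#'
#' Given per-signal distances to the nuclear periphery and intensity weights,
#' returns the intensity-weighted cumulative distribution on a regular distance
#' grid together with P0.5, the fraction of signal within 0.5 um of the
#' periphery.
#'
#' @param distances_um numeric distances to the NP (um).
#' @param weights nonnegative intensity weights (default equal).
#' @param step_um distance grid step (um).
#' @param cutoff_um distance at which the headline statistic is read off.
#' @param nucleus_id,channel identifiers carried through to the result.
#' @return an object of class `painting_profile` with `distances_um`,
#'   `cumulative_fraction` (nondecreasing, ending at 1) and `p05`.
#' @export
painting_profile <- function(distances_um, weights = NULL, step_um = 0.05,
                             cutoff_um = 0.5, nucleus_id = NA, channel = NA) {
  stopifnot(length(distances_um) > 0)
  if (is.null(weights)) weights <- rep(1, length(distances_um))
  stopifnot(length(weights) == length(distances_um), all(weights >= 0))
  tot <- sum(weights)
  if (tot <= 0) stop("zero total signal")
  dmax <- max(distances_um)
  grid <- seq(0, dmax + step_um, by = step_um)
  ord <- order(distances_um)
  cum <- cumsum(weights[ord]) / tot
  cf <- vapply(grid, function(g) {
    k <- findInterval(g, distances_um[ord])
    if (k == 0) 0 else cum[k]
  }, numeric(1))
  p05 <- if (cutoff_um >= dmax) 1 else stats::approx(grid, cf, xout = cutoff_um,
                                                     rule = 2)$y
  structure(list(nucleus_id = nucleus_id, channel = channel,
                 distances_um = grid, cumulative_fraction = cf, p05 = p05,
                 cutoff_um = cutoff_um),
            class = "painting_profile")
}

#' @export
print.painting_profile <- function(x, ...) {
  cat(sprintf("<painting_profile> %s/%s: P%.1f = %.3f\n",
              x$nucleus_id, x$channel, x$cutoff_um, x$p05))
  invisible(x)
}

#' Cumulative painting signal vs distance to the nuclear periphery
#'
#' For one channel of a segmented nucleus, accumulates voxel intensity as a
#' function of distance to the periphery, over mask voxels in the retained
#' z-slices. The lowest `exclude_bottom_slices` z-slices of the mask's
#' bounding box are dropped, because the nuclear part flattened against the
#' slide distorts distances there.
#'
#' @param img segmented `nucleus_image`.
#' @param channel `"green"` or `"red"`.
#' @param field a [boundary_distance_field()] for the mask (computed if NULL).
#' @param exclude_bottom_slices number of bottom z-slices to drop (default 2).
#' @param step_um distance grid step.
#' @param cutoff_um cutoff for the headline fraction (default 0.5 um).
#' @param binarize if TRUE weight voxels equally instead of by intensity.
#' @param nucleus_id identifier carried into the profile.
#' @return a [painting_profile()].
#' @export
cumulative_signal_profile <- function(img, channel = c("green", "red"),
                                      field = NULL, exclude_bottom_slices = 2L,
                                      step_um = 0.05, cutoff_um = 0.5,
                                      binarize = FALSE, nucleus_id = NA) {
  channel <- match.arg(channel)
  stopifnot(!is.null(img$mask))
  ch <- img$channels[[channel]]
  if (is.null(ch)) stop(sprintf("channel '%s' missing", channel))
  if (is.null(field)) {
    field <- boundary_distance_field(img$mask, img$voxel_size_um)
  }
  zs <- which(apply(img$mask, 3, any))
  drop_z <- utils::head(zs, exclude_bottom_slices)
  keep <- img$mask
  if (length(drop_z) > 0) keep[, , drop_z] <- FALSE
  idx <- which(keep)
  w <- ch[idx]
  if (binarize) w <- as.numeric(w > 0)
  if (sum(w) <= 0) stop("zero total signal in retained slices")
  painting_profile(unclass(field)[idx], w, step_um = step_um,
                   cutoff_um = cutoff_um, nucleus_id = nucleus_id,
                   channel = channel)
}

#' Paired per-nucleus comparison of Green vs Red P0.5
#'
#' Two-sided Wilcoxon signed-rank test on the per-nucleus differences
#' `p05_green - p05_red` (zero differences dropped), plus the count of nuclei
#' whose Green signal is the more peripheral.
#'
#' @param pairs data.frame with columns `p05_green` and `p05_red` (one row per
#'   nucleus), or a list of `list(green = , red = )` painting profiles.
#' @return list with `n_pairs`, `n_green_gt_red`, `wilcoxon_statistic`,
#'   `p_value`, `mean_green`, `mean_red` and `all_zero` (TRUE when every
#'   difference is zero, in which case the p-value is NA).
#' @export
paired_p05_test <- function(pairs) {
  if (!is.data.frame(pairs)) {
    pairs <- do.call(rbind, lapply(pairs, function(p) {
      data.frame(p05_green = p$green$p05, p05_red = p$red$p05)
    }))
  }
  stopifnot(nrow(pairs) >= 5)
  diffs <- pairs$p05_green - pairs$p05_red
  nz <- diffs[diffs != 0]
  if (length(nz) == 0) {
    return(list(n_pairs = nrow(pairs), n_green_gt_red = 0L,
                wilcoxon_statistic = NA_real_, p_value = NA_real_,
                mean_green = mean(pairs$p05_green),
                mean_red = mean(pairs$p05_red), all_zero = TRUE))
  }
  ht <- suppressWarnings(stats::wilcox.test(nz, exact = FALSE, correct = TRUE))
  list(n_pairs = nrow(pairs), n_green_gt_red = sum(diffs > 0),
       wilcoxon_statistic = unname(ht$statistic), p_value = ht$p.value,
       mean_green = mean(pairs$p05_green), mean_red = mean(pairs$p05_red),
       all_zero = FALSE)
}
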