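#' Binned Hi-C contact matrix
#'
#' @param counts symmetric nonnegative matrix of contact counts.
#' @param bin_size_bp bin width in bp.
#' @param bins data.frame with one row per bin, columns `chrom` and `start`.
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, bin_size_bp, bins = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  stopifnot(ncol(counts) == n, all(counts >= 0))
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(counts))) {
    stop("contact matrix must be symmetric")
  }
  if (is.null(bins)) {
    bins <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * bin_size_bp)
  }
  stopifnot(nrow(bins) == n)
  diag(counts) <- 0
  structure(list(counts = counts, bin_size_bp = as.integer(bin_size_bp),
                 bins = bins),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d bins of %d bp (%s); total counts %.4g\n",
              nrow(x$counts), x$bin_size_bp,
              paste(unique(x$bins$chrom), collapse = ","), sum(x$counts)))
  invisible(x)
}

#' Iterative correction (ICE) of a contact matrix
#'
#' Removes multiplicative per-bin biases by repeatedly dividing each entry by
#' its row and column marginals (normalised to mean 1) until the maximum
#' relative change of the retained marginals falls below `eps`. Bins in the
#' lowest `mask_fraction` of raw coverage are masked before balancing, the
#' usual guard against noisy low-coverage rows.
#'
#' @param m a [contact_matrix()].
#' @param eps convergence threshold on the maximum relative marginal deviation.
#' @param max_iter iteration cap; hitting it sets `converged = FALSE` without
#'   raising an error.
#' @param mask_fraction fraction of lowest-coverage bins to mask, in `[0, 0.5)`.
#' @return an object of class `balanced_matrix` with fields `values` (balanced
#'   matrix, masked rows/columns `NA`), `bias_vector` (per-bin factors, `NA`
#'   when masked), `masked` (logical), `converged`, `final_eps`, plus the bin
#'   table and bin size of the input.
#' @export
ice_balance <- function(m, eps = 1e-4, max_iter = 200L, mask_fraction = 0.02) {
  stopifnot(inherits(m, "contact_matrix"),
            mask_fraction >= 0, mask_fraction < 0.5)
  counts <- m$counts
  n <- nrow(counts)
  if (sum(counts) == 0) stop("cannot balance an all-zero contact matrix")
  cov <- rowSums(counts)
  masked <- cov == 0
  if (mask_fraction > 0) {
    thr <- stats::quantile(cov[!masked], mask_fraction, names = FALSE)
    masked <- masked | cov <= thr
    if (all(masked)) stop("masking removed every bin")
  }
  keep <- which(!masked)
  w <- counts[keep, keep, drop = FALSE]
  bias <- rep(1, length(keep))
  converged <- FALSE
  final_eps <- Inf
  for (it in seq_len(max_iter)) {
    s <- rowSums(w)
    if (any(s == 0)) stop("retained bin lost all coverage during balancing")
    final_eps <- max(abs(s / mean(s) - 1))
    if (final_eps < eps) { converged <- TRUE; break }
    # square-root damping prevents the 2-cycle oscillation that plain
    # marginal division exhibits on near-bipartite contact structures
    f <- sqrt(s / mean(s))
    w <- w / outer(f, f)
    bias <- bias * f
  }
  values <- matrix(NA_real_, n, n)
  values[keep, keep] <- w
  bias_full <- rep(NA_real_, n)
  bias_full[keep] <- bias
  structure(list(values = values, bias_vector = bias_full, masked = masked,
                 converged = converged, final_eps = final_eps,
                 bin_size_bp = m$bin_size_bp, bins = m$bins),
            class = "balanced_matrix")
}

#' @export
print.balanced_matrix <- function(x, ...) {
  cat(sprintf("<balanced_matrix> %d bins (%d masked); converged=%s (eps %.3g)\n",
              nrow(x$values), sum(x$masked), x$converged, x$final_eps))
  invisible(x)
}

#' Observed-over-expected transform
#'
#' Divides each entry of a balanced matrix by the mean retained value at the
#' same genomic separation, removing the distance decay; by construction every
#' diagonal of the output averages to 1.
#'
#' @param b a `balanced_matrix` from [ice_balance()].
#' @param allow_unconverged set TRUE to accept an unconverged balance.
#' @return numeric O/E matrix with masked rows/columns `NA`; separations with
#'   no retained entries are `NA`.
#' @export
observed_over_expected <- function(b, allow_unconverged = FALSE) {
  stopifnot(inherits(b, "balanced_matrix"))
  if (!b$converged && !allow_unconverged) {
    stop("balancing did not converge; pass allow_unconverged = TRUE to override")
  }
  v <- b$values
  n <- nrow(v)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  expected <- vapply(0:(n - 1), function(d) {
    vals <- v[sep == d]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) NA_real_ else mean(vals)
  }, numeric(1))
  oe <- v / matrix(expected[sep + 1], n, n)
  oe[is.na(v)] <- NA_real_
  oe
}

#' Correlation matrix of O/E rows
#'
#' Pearson correlation between rows of an O/E matrix (pairwise deletion of
#' masked entries), the standard input to compartment eigenanalysis. Rows with
#' zero variance come out masked.
#'
#' @param oe O/E matrix, masked entries `NA`.
#' @return symmetric correlation matrix with unit diagonal; masked bins `NA`.
#' @export
correlation_matrix <- function(oe) {
  n <- nrow(oe)
  unmasked <- which(colSums(!is.na(oe)) > 0)
  if (length(unmasked) < 3) stop("need at least 3 unmasked bins")
  cm <- matrix(NA_real_, n, n)
  sub <- suppressWarnings(
    stats::cor(t(oe[unmasked, unmasked, drop = FALSE]),
               use = "pairwise.complete.obs"))
  cm[unmasked, unmasked] <- sub
  diag(cm)[unmasked] <- 1
  # constant rows yield NA whole rows; mask them fully
  bad <- unmasked[apply(is.na(sub), 1, all)]
  cm[bad, ] <- NA_real_
  cm[, bad] <- NA_real_
  cm
}

#' Call A/B compartments from a correlation matrix
#'
#' Takes the leading eigenvector of the (unmasked) correlation matrix, orients
#' its sign to correlate positively with `orientation_track` (e.g. gene density
#' or an active mark; ground-truth labels in simulations) and labels bins A
#' where the oriented eigenvector is positive, B where negative.
#'
#' @param corr correlation matrix from [correlation_matrix()].
#' @param orientation_track per-bin numeric values used only to fix the sign.
#' @return an object of class `compartment_call` with `eigenvector` (NA at
#'   masked bins), `label` (`"A"`, `"B"` or `"masked"`), `eigen_gap` and a
#'   `degenerate` flag when the top eigenvalue gap is below 1e-8.
#' @export
call_compartments <- function(corr, orientation_track) {
  n <- nrow(corr)
  stopifnot(length(orientation_track) == n)
  keep <- which(!apply(is.na(corr), 1, all))
  sub <- corr[keep, keep, drop = FALSE]
  sub[is.na(sub)] <- 0
  es <- eigen((sub + t(sub)) / 2, symmetric = TRUE)
  ev <- es$vectors[, 1]
  gap <- es$values[1] - es$values[2]
  ot <- orientation_track[keep]
  if (stats::sd(ot) > 0 && stats::sd(ev) > 0) {
    r <- stats::cor(ev, ot)
    if (!is.na(r) && r < 0) ev <- -ev
  }
  e_full <- rep(NA_real_, n)
  e_full[keep] <- ev
  label <- rep("masked", n)
  label[keep] <- ifelse(ev > 0, "A", "B")
  structure(list(eigenvector = e_full, label = label,
                 eigen_gap = gap, degenerate = gap < 1e-8),
            class = "compartment_call")
}

#' @export
print.compartment_call <- function(x, ...) {
  cat(sprintf("<compartment_call> %d bins: %d A, %d B, %d masked%s\n",
              length(x$label), sum(x$label == "A"), sum(x$label == "B"),
              sum(x$label == "masked"),
              if (x$degenerate) " (degenerate eigen gap)" else ""))
  invisible(x)
}

#' Agreement between two compartment calls
#'
#' @param call,reference `compartment_call`s on the same bin grid.
#' @return fraction of bins unmasked in both calls that carry the same label.
#' @export
compartment_agreement <- function(call, reference) {
  stopifnot(length(call$label) == length(reference$label))
  both <- call$label != "masked" & reference$label != "masked"
  if (!any(both)) stop("no bins unmasked in both calls")
  mean(call$label[both] == reference$label[both])
}

#' Cross- vs within-compartment interaction strength
#'
#' Collects O/E values for all unmasked bin pairs separated by at most
#' `max_sep_bp` and splits them into cross-compartment (A-B) and
#' within-compartment (A-A or B-B) sets. Because each diagonal of the O/E
#' matrix averages to 1, these values are already distance-normalised
#' interaction strengths relative to the average; `mean_AB_relative` rises
#' toward 1 as compartmentalization weakens.
#'
#' @param oe O/E matrix.
#' @param call a `compartment_call` on the same grid.
#' @param max_sep_bp separation cap in bp (default 1 Mb).
#' @param bin_size_bp bin size in bp used to convert the cap to bins.
#' @return list with `oe_values_AB`, `oe_values_within`, `mean_AB_relative`,
#'   `mean_within_relative`.
#' @export
compartment_strength <- function(oe, call, max_sep_bp = 1e6,
                                 bin_size_bp = 20000L) {
  n <- nrow(oe)
  stopifnot(length(call$label) == n)
  max_sep <- floor(max_sep_bp / bin_size_bp)
  ab <- numeric(0)
  within <- numeric(0)
  for (d in 1:max_sep) {
    if (d >= n) break
    i <- seq_len(n - d)
    j <- i + d
    vals <- oe[cbind(i, j)]
    li <- call$label[i]
    lj <- call$label[j]
    ok <- !is.na(vals) & li != "masked" & lj != "masked"
    ab <- c(ab, vals[ok & li != lj])
    within <- c(within, vals[ok & li == lj])
  }
  if (length(ab) == 0) stop("no cross-compartment pairs within the separation cap")
  list(oe_values_AB = ab, oe_values_within = within,
       mean_AB_relative = mean(ab),
       mean_within_relative = mean(within))
}

#' Compare cross-compartment strength between two genotypes
#'
#' Two-sided Mann-Whitney U test on the A-B O/E value sets of two
#' [compartment_strength()] results (e.g. wild type vs a lamin-like mutant).
#'
#' @param a,b results of [compartment_strength()].
#' @return list with the two means, their difference and `mw_p`.
#' @export
compare_compartment_strength <- function(a, b) {
  ht <- stats::wilcox.test(a$oe_values_AB, b$oe_values_AB,
                           exact = FALSE, correct = TRUE)
  list(mean_AB_a = a$mean_AB_relative, mean_AB_b = b$mean_AB_relative,
       delta = b$mean_AB_relative - a$mean_AB_relative,
       mw_p = ht$p.value)
}

#' Fraction of inter-chromosomal (trans) contacts
#'
#' @param m a genome-wide [contact_matrix()] whose bin table spans at least two
#'   chromosomes.
#' @return list with `trans_fraction` (overall) and `per_pair`, a data.frame of
#'   chromosome pairs with their contact sums and the fraction of the total.
#' @export
trans_contact_fraction <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  chroms <- unique(m$bins$chrom)
  if (length(chroms) < 2) stop("need at least 2 chromosomes")
  ch <- m$bins$chrom
  total <- sum(m$counts)
  pairs <- utils::combn(chroms, 2, simplify = FALSE)
  per_pair <- do.call(rbind, lapply(pairs, function(p) {
    s <- 2 * sum(m$counts[ch == p[1], ch == p[2], drop = FALSE])
    data.frame(chrom_a = p[1], chrom_b = p[2], contacts = s,
               fraction = s / total)
  }))
  cis <- sum(vapply(chroms, function(cc) {
    sum(m$counts[ch == cc, ch == cc, drop = FALSE])
  }, numeric(1)))
  list(trans_fraction = (total - cis) / total, per_pair = per_pair,
       total_contacts = total)
}
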