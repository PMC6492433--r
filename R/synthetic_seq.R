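#' Configuration for a synthetic Hi-C contact matrix
#'
#' The expected count between bins i and j (i != j) is
#' `c * (|i-j| + 1)^(-decay_alpha) * (1 + s)` when the bins share an A/B label
#' and `... * (1 - s)` otherwise, with `c` chosen so the expected total equals
#' `mean_depth * n_bins^2`. `strength_s = 0` removes all label dependence;
#' `strength_s = 1` forbids cross-compartment contacts. Counts are Poisson.
#'
#' @param n_bins number of bins.
#' @param bin_size_bp bin width in bp.
#' @param labels character vector of per-bin labels (`"A"`/`"B"`), length
#'   `n_bins`; default alternating 10-bin blocks.
#' @param strength_s compartmentalization strength in `[0, 1]`.
#' @param decay_alpha power-law distance-decay exponent (> 0).
#' @param mean_depth expected mean count per matrix entry.
#' @param seed integer seed.
#' @return an object of class `hic_sim_config`.
#' @export
hic_sim_config <- function(n_bins = 200L, bin_size_bp = 20000L, labels = NULL,
                           strength_s = 0.5, decay_alpha = 1, mean_depth = 50,
                           seed = 1L) {
  if (is.null(labels)) {
    labels <- rep(rep(c("A", "B"), each = 10L), length.out = n_bins)
  }
  stopifnot(length(labels) == n_bins, decay_alpha > 0, mean_depth > 0)
  if (strength_s < 0 || strength_s > 1) {
    stop("strength_s must lie in [0, 1]")
  }
  structure(list(n_bins = as.integer(n_bins),
                 bin_size_bp = as.integer(bin_size_bp),
                 labels = labels, strength_s = strength_s,
                 decay_alpha = decay_alpha, mean_depth = mean_depth,
                 seed = as.integer(seed)),
            class = "hic_sim_config")
}

#' Expected (noise-free) contact matrix for a simulation config
#'
#' @param cfg a [hic_sim_config()].
#' @return numeric matrix of expected counts (zero diagonal).
#' @export
contact_expectation <- function(cfg) {
  stopifnot(inherits(cfg, "hic_sim_config"))
  n <- cfg$n_bins
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  same <- outer(cfg$labels, cfg$labels, "==")
  mu <- (sep + 1)^(-cfg$decay_alpha) *
    ifelse(same, 1 + cfg$strength_s, 1 - cfg$strength_s)
  diag(mu) <- 0
  mu * (cfg$mean_depth * n^2 / sum(mu))
}

#' Simulate a Hi-C contact matrix with block A/B structure
#'
#' Poisson-samples the upper triangle of [contact_expectation()] and mirrors it,
#' giving a symmetric count matrix with zero diagonal.
#'
#' @param cfg a [hic_sim_config()].
#' @return a [contact_matrix()] whose bins carry the true labels as an
#'   attribute `true_labels`.
#' @export
simulate_contact_matrix <- function(cfg) {
  mu <- contact_expectation(cfg)
  n <- cfg$n_bins
  counts <- matrix(0, n, n)
  up <- upper.tri(mu)
  counts[up] <- withr::with_seed(cfg$seed, stats::rpois(sum(up), mu[up]))
  counts <- counts + t(counts)
  cm <- contact_matrix(counts, cfg$bin_size_bp,
                       bins = data.frame(
                         chrom = "chr1",
                         start = (seq_len(n) - 1L) * cfg$bin_size_bp))
  attr(cm, "true_labels") <- cfg$labels
  cm
}

#' Binned signal track
#'
#' Per-window values on a fixed grid of `window_bp`-wide windows along one
#' chromosome; window i covers `[(i-1)*window_bp, i*window_bp)`.
#'
#' @param values numeric per-window values.
#' @param window_bp window width in bp.
#' @param chrom chromosome name.
#' @return an object of class `signal_track`.
#' @export
signal_track <- function(values, window_bp, chrom = "chr1") {
  stopifnot(window_bp > 0)
  structure(list(chrom = chrom, window_bp = as.integer(window_bp),
                 values = as.numeric(values)),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %s: %d windows of %d bp; total %.4g\n",
              x$chrom, length(x$values), x$window_bp, sum(x$values)))
  invisible(x)
}

#' Configuration for synthetic ChIP treatment/control tracks
#'
#' @param genome_length_bp chromosome length (bp).
#' @param planted_domains data.frame with columns `start`, `end`
#'   (0-based half-open, within the genome) marking enriched domains.
#' @param enrichment_fold fold enrichment inside domains (>= 1).
#' @param window_bp counting window (bp).
#' @param depth expected reads per window outside domains.
#' @param seed integer seed.
#' @param overdispersion optional Gamma-mixing variance multiplier; 0 keeps
#'   pure Poisson counts.
#' @return an object of class `track_sim_config`.
#' @export
track_sim_config <- function(genome_length_bp = 2e6, planted_domains = NULL,
                             enrichment_fold = 8, window_bp = 500L,
                             depth = 20, seed = 1L, overdispersion = 0) {
  if (is.null(planted_domains)) {
    planted_domains <- data.frame(start = numeric(0), end = numeric(0))
  }
  stopifnot(enrichment_fold >= 1, depth > 0, window_bp > 0,
            all(planted_domains$start < planted_domains$end))
  if (nrow(planted_domains) > 0 &&
      (min(planted_domains$start) < 0 ||
       max(planted_domains$end) > genome_length_bp)) {
    stop("planted domains must lie within [0, genome_length_bp)")
  }
  structure(list(genome_length_bp = genome_length_bp,
                 planted_domains = planted_domains,
                 enrichment_fold = enrichment_fold,
                 window_bp = as.integer(window_bp), depth = depth,
                 seed = as.integer(seed), overdispersion = overdispersion),
            class = "track_sim_config")
}

#' Simulate ChIP treatment and control read-count tracks
#'
#' Treatment windows are Poisson with rate `depth` outside planted domains and
#' `depth * enrichment_fold` inside (partial overlaps scale linearly with the
#' covered fraction); the control is Poisson(`depth`) everywhere.
#'
#' @param cfg a [track_sim_config()].
#' @return list with elements `treatment` and `control` ([signal_track()]s).
#' @export
simulate_chip_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "track_sim_config"))
  W <- cfg$window_bp
  nwin <- ceiling(cfg$genome_length_bp / W)
  frac <- numeric(nwin)
  if (nrow(cfg$planted_domains) > 0) {
    starts <- (seq_len(nwin) - 1) * W
    ends <- pmin(starts + W, cfg$genome_length_bp)
    for (r in seq_len(nrow(cfg$planted_domains))) {
      ov <- pmax(0, pmin(ends, cfg$planted_domains$end[r]) -
                    pmax(starts, cfg$planted_domains$start[r]))
      frac <- frac + ov / W
    }
    frac <- pmin(frac, 1)
  }
  rate_t <- cfg$depth * (1 + (cfg$enrichment_fold - 1) * frac)
  withr::with_seed(cfg$seed, {
    if (cfg$overdispersion > 0) {
      shape <- 1 / cfg$overdispersion
      rate_t <- rate_t * stats::rgamma(nwin, shape, shape)
      rate_c <- cfg$depth * stats::rgamma(nwin, shape, shape)
    } else {
      rate_c <- rep(cfg$depth, nwin)
    }
    list(treatment = signal_track(stats::rpois(nwin, rate_t), W),
         control = signal_track(stats::rpois(nwin, rate_c), W))
  })
}

#' Simulate RE-ChIP-like interaction signal from a feature matrix
#'
#' Generates `y = X %*% coefficients + N(0, noise_sd)` per genomic window,
#' the generative model assumed by the chromatin-NP regression stage.
#'
#' @param X numeric feature matrix (windows x features).
#' @param coefficients numeric vector, one per feature.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return numeric response vector.
#' @export
simulate_rechip_response <- function(X, coefficients, noise_sd = 1, seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) != length(coefficients)) {
    stop(sprintf("coefficient length (%d) does not match feature count (%d)",
                 length(coefficients), ncol(X)))
  }
  mu <- drop(X %*% coefficients)
  if (noise_sd == 0) return(mu)
  mu + withr::with_seed(seed, stats::rnorm(nrow(X), 0, noise_sd))
}
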