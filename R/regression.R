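# Interval sets are handled as data.frames (chrom, start, end) in 0-based
# half-open coordinates; GenomicRanges does the actual interval arithmetic.
.as_gr <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  stopifnot(all(x$start < x$end))
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

.gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr))
}

#' Distance from genomic windows to the nearest pericentromeric region
#'
#' Windows overlapping a PR get distance 0; any other window gets the gap from
#' its midpoint to the nearest PR boundary on the same chromosome. Windows on
#' chromosomes with no PR are returned as `NA` with a warning.
#'
#' @param windows,pr interval sets: data.frames with `chrom`, `start`, `end`
#'   (0-based half-open) or `GRanges`.
#' @return numeric vector of distances in bp, one per window.
#' @export
distance_to_pr <- function(windows, pr) {
  win <- .as_gr(windows)
  prg <- .as_gr(pr)
  n <- length(win)
  out <- rep(NA_real_, n)
  ov <- GenomicRanges::findOverlaps(win, prg)
  out[unique(S4Vectors::queryHits(ov))] <- 0
  todo <- which(is.na(out))
  if (length(todo) > 0) {
    mids <- floor((GenomicRanges::start(win[todo]) - 1 +
                     GenomicRanges::end(win[todo])) / 2)
    midgr <- GenomicRanges::GRanges(GenomicRanges::seqnames(win[todo]),
                                    IRanges::IRanges(mids + 1, width = 1))
    nd <- GenomicRanges::distanceToNearest(midgr, prg)
    out[todo[S4Vectors::queryHits(nd)]] <- S4Vectors::mcols(nd)$distance
  }
  if (anyNA(out)) warning("windows on chromosomes with no PR: distance NA")
  out
}

#' Spearman correlation of signal with distance to PRs
#'
#' @param signal per-window signal values.
#' @param distances per-window distances (bp) as from [distance_to_pr()].
#' @return list with `rho` and `p` (NA with a warning for constant input).
#' @export
spearman_vs_pr <- function(signal, distances) {
  stopifnot(length(signal) == length(distances))
  ok <- !is.na(signal) & !is.na(distances)
  if (sum(ok) < 10) stop("need at least 10 complete pairs")
  if (stats::sd(signal[ok]) == 0 || stats::sd(distances[ok]) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = sum(ok)))
  }
  ht <- suppressWarnings(stats::cor.test(signal[ok], distances[ok],
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p = ht$p.value, n = sum(ok))
}

#' LASSO fit with tenfold cross-validation and the one-standard-error rule
#'
#' Fits a Gaussian LASSO over a log-spaced lambda grid, estimates the CV mean
#' squared error curve, and reports coefficients at `lambda.1se` — the largest
#' lambda whose CV error is within one standard error of the minimum —
#' following standard glmnet practice. Features are standardized internally;
#' coefficients are reported on the original scale.
#'
#' @param X numeric feature matrix (n x K) with column names.
#' @param y numeric response (length n).
#' @param n_folds number of CV folds (default 10).
#' @param lambda_grid optional lambda sequence (decreasing); by default glmnet's
#'   100-point grid from lambda_max down to 1e-4 * lambda_max.
#' @param seed integer seed fixing the fold assignment.
#' @param fold_method `"random"` (seeded random folds, the glmnet default) or
#'   `"contiguous"` (folds are contiguous blocks of windows, which respects
#'   genomic autocorrelation).
#' @param ... further arguments to [glmnet::glmnet()] (e.g. `thresh`).
#' @return an object of class `lasso_model` with `coefficients`, `intercept`,
#'   `lambda_grid`, `cv_mean_mse`, `cv_se_mse`, `lambda_min`, `lambda_1se`,
#'   `n_nonzero` and the underlying `cv_fit`.
#' @export
fit_lasso_cv <- function(X, y, n_folds = 10L, lambda_grid = NULL, seed = 1L,
                         fold_method = c("random", "contiguous"), ...) {
  fold_method <- match.arg(fold_method)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (n_folds > n) stop("n_folds exceeds the number of observations")
  keep <- which(apply(X, 2, stats::sd) > 0)
  if (length(keep) < ncol(X)) {
    warning(sprintf("dropping %d degenerate (constant) feature column(s)",
                    ncol(X) - length(keep)))
    X <- X[, keep, drop = FALSE]
  }
  foldid <- if (fold_method == "contiguous") {
    as.integer(cut(seq_len(n), n_folds, labels = FALSE))
  } else {
    withr::with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  }
  cv <- glmnet::cv.glmnet(X, y, family = "gaussian", foldid = foldid,
                          lambda = lambda_grid, nlambda = 100,
                          lambda.min.ratio = 1e-4, standardize = TRUE, ...)
  cf <- as.matrix(stats::coef(cv, s = "lambda.1se"))
  structure(list(coefficients = cf[-1, 1], intercept = cf[1, 1],
                 lambda_grid = cv$lambda, cv_mean_mse = cv$cvm,
                 cv_se_mse = cv$cvsd, lambda_min = cv$lambda.min,
                 lambda_1se = cv$lambda.1se,
                 n_nonzero = sum(cf[-1, 1] != 0), cv_fit = cv),
            class = "lasso_model")
}

#' @export
print.lasso_model <- function(x, ...) {
  cat(sprintf(
    "<lasso_model> %d features, %d nonzero at lambda.1se = %.4g (lambda.min %.4g)\n",
    length(x$coefficients), x$n_nonzero, x$lambda_1se, x$lambda_min))
  invisible(x)
}

#' Chromosome-held-out comparison of two feature sets
#'
#' Fits the full and the reduced LASSO model on windows of the training
#' chromosomes (lambda chosen by tenfold CV with the one-standard-error rule,
#' standardization learned on the training windows only) and evaluates both on
#' the held-out test chromosomes. A lower `mse_full` indicates that the
#' additional feature(s) — distance to the pericentromere, in the chromatin-NP
#' analysis — carry real predictive signal.
#'
#' @param X_full,X_reduced feature matrices on the same windows; `X_reduced`
#'   is `X_full` minus the feature(s) under test.
#' @param y response per window.
#' @param chrom chromosome of each window.
#' @param train_chroms,test_chroms chromosome name sets.
#' @param seed seed for the CV fold assignment.
#' @return list with `mse_full`, `mse_reduced`, `delta` (reduced - full; > 0
#'   favours the full model) and the two fitted models.
#' @export
compare_feature_sets <- function(X_full, X_reduced, y, chrom,
                                 train_chroms, test_chroms, seed = 1L) {
  X_full <- as.matrix(X_full)
  X_reduced <- as.matrix(X_reduced)
  stopifnot(nrow(X_full) == length(y), nrow(X_reduced) == length(y),
            length(chrom) == length(y))
  tr <- chrom %in% train_chroms
  te <- chrom %in% test_chroms
  if (!any(te)) stop("empty test set")
  if (!any(tr)) stop("empty training set")
  if (stats::sd(y[tr]) == 0) {
    # constant response: both models predict the constant
    return(list(mse_full = mean((y[te] - y[tr][1])^2),
                mse_reduced = mean((y[te] - y[tr][1])^2), delta = 0,
                fit_full = NULL, fit_reduced = NULL))
  }
  eval_one <- function(X) {
    fit <- fit_lasso_cv(X[tr, , drop = FALSE], y[tr], seed = seed)
    pred <- drop(X[te, names(fit$coefficients), drop = FALSE] %*%
                   fit$coefficients) + fit$intercept
    list(mse = mean((y[te] - pred)^2), fit = fit)
  }
  full <- eval_one(X_full)
  red <- eval_one(X_reduced)
  list(mse_full = full$mse, mse_reduced = red$mse,
       delta = red$mse - full$mse,
       fit_full = full$fit, fit_reduced = red$fit)
}

#' Generate synthetic genomic windows with epigenomic-style features
#'
#' Lays out fixed-width windows on a set of chromosomes, each chromosome with a
#' central pericentromeric region, and draws `n_features` standard-normal
#' feature columns plus the `dist_to_pr_bp` column computed from the layout.
#'
#' @param n_chroms number of chromosomes.
#' @param windows_per_chrom windows per chromosome.
#' @param window_bp window width (bp).
#' @param n_features number of random feature columns.
#' @param pr_fraction fraction of each chromosome covered by its PR.
#' @param seed integer seed.
#' @return list with `windows` (data.frame chrom/start/end), `pr`
#'   (data.frame of PR intervals), `X` (feature matrix whose last column is
#'   `dist_to_pr_bp`) and `chrom` (per-window chromosome).
#' @export
make_feature_windows <- function(n_chroms = 5L, windows_per_chrom = 600L,
                                 window_bp = 20000L, n_features = 10L,
                                 pr_fraction = 0.1, seed = 1L) {
  chroms <- paste0("chr", seq_len(n_chroms))
  win <- do.call(rbind, lapply(chroms, function(cc) {
    s <- (seq_len(windows_per_chrom) - 1) * window_bp
    data.frame(chrom = cc, start = s, end = s + window_bp)
  }))
  len <- windows_per_chrom * window_bp
  half <- pr_fraction * len / 2
  pr <- data.frame(chrom = chroms,
                   start = floor(len / 2 - half), end = ceiling(len / 2 + half))
  X <- withr::with_seed(seed,
                        matrix(stats::rnorm(nrow(win) * n_features),
                               ncol = n_features,
                               dimnames = list(NULL,
                                               paste0("feat", seq_len(n_features)))))
  d <- distance_to_pr(win, pr)
  X <- cbind(X, dist_to_pr_bp = d)
  list(windows = win, pr = pr, X = X, chrom = win$chrom)
}
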