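#' Specification of a synthetic 2C nucleus
#'
#' Defines an axis-aligned ellipsoidal nucleus to be rasterised onto an
#' anisotropic voxel grid. Sorted 2C Arabidopsis nuclei are close to spherical,
#' so the default shape is a 2.5-um-radius sphere.
#'
#' @param semi_axes_um numeric length-3 ellipsoid semi-axes (um).
#' @param voxel_size_um numeric length-3 voxel size (um); each semi-axis must
#'   be at least twice the voxel size on its axis.
#' @param dapi_level DAPI intensity inside the nucleus.
#' @param background_level intensity outside the nucleus.
#' @param seed integer seed controlling Poisson shot noise.
#' @param margin_um margin of background added around the ellipsoid.
#' @param dims_vox optional explicit grid size (3 integers); an ellipsoid that
#'   does not fit raises an error naming the offending axis.
#' @param poisson_noise if TRUE, voxel intensities are Poisson draws around
#'   their noiseless level.
#' @return an object of class `nucleus_spec`.
#' @export
nucleus_spec <- function(semi_axes_um = c(2.5, 2.5, 2.5),
                         voxel_size_um = c(0.1, 0.1, 0.1),
                         dapi_level = 200,
                         background_level = 5,
                         seed = 1L,
                         margin_um = 0.4,
                         dims_vox = NULL,
                         poisson_noise = FALSE) {
  stopifnot(length(semi_axes_um) == 3, all(semi_axes_um > 0),
            length(voxel_size_um) == 3, all(voxel_size_um > 0),
            is.finite(dapi_level), dapi_level > 0,
            is.finite(background_level), background_level >= 0)
  if (any(semi_axes_um < 2 * voxel_size_um)) {
    stop("each semi-axis must be >= 2 voxels on its axis")
  }
  structure(list(semi_axes_um = semi_axes_um, voxel_size_um = voxel_size_um,
                 dapi_level = dapi_level, background_level = background_level,
                 seed = as.integer(seed), margin_um = margin_um,
                 dims_vox = dims_vox, poisson_noise = poisson_noise),
            class = "nucleus_spec")
}

#' Radial placement model for FISH / painting signal
#'
#' `uniform` places signal uniformly in the nuclear interior. `boundary_bias`
#' accepts a uniformly drawn candidate with probability `exp(-d / beta_um)`,
#' where `d` is the candidate voxel's distance to the nuclear boundary, so
#' small `beta_um` concentrates signal at the nuclear periphery (NP-enriched
#' chromatin) and large `beta_um` recovers the uniform model.
#'
#' @param kind `"uniform"` or `"boundary_bias"`.
#' @param beta_um positive decay length in um (boundary_bias only).
#' @return an object of class `radial_model`.
#' @export
radial_model <- function(kind = c("uniform", "boundary_bias"), beta_um = NULL) {
  kind <- match.arg(kind)
  if (kind == "boundary_bias") {
    stopifnot(!is.null(beta_um), beta_um > 0)
  }
  structure(list(kind = kind, beta_um = beta_um), class = "radial_model")
}

.new_nucleus_image <- function(dims, voxel_size_um, channels, mask = NULL) {
  structure(list(dims = dims, voxel_size_um = voxel_size_um,
                 channels = channels, mask = mask,
                 spots_truth = list()),
            class = "nucleus_image")
}

#' @export
print.nucleus_image <- function(x, ...) {
  cat("<nucleus_image> ", paste(x$dims, collapse = " x "),
      " voxels @ ", paste(signif(x$voxel_size_um, 3), collapse = "/"),
      " um; channels: ", paste(names(x$channels), collapse = ", "),
      if (!is.null(x$mask)) sprintf("; mask (%d voxels)", sum(x$mask)) else "",
      "\n", sep = "")
  invisible(x)
}

# voxel centre coordinates (um) along one axis
.axis_coords <- function(n, h) (seq_len(n) - 0.5) * h

#' Rasterise a synthetic nucleus
#'
#' Produces a `nucleus_image` whose DAPI channel equals `dapi_level` inside the
#' axis-aligned ellipsoid and `background_level` outside (optionally with
#' Poisson shot noise); the analytic interior mask is stored on the image.
#'
#' @param spec a [nucleus_spec()].
#' @return a `nucleus_image` with channels `dapi`, `green`, `red`.
#' @export
make_nucleus <- function(spec) {
  stopifnot(inherits(spec, "nucleus_spec"))
  vox <- spec$voxel_size_um
  if (is.null(spec$dims_vox)) {
    dims <- as.integer(ceiling(2 * (spec$semi_axes_um + spec$margin_um) / vox))
  } else {
    dims <- as.integer(spec$dims_vox)
    need <- 2 * spec$semi_axes_um / vox
    for (ax in 1:3) {
      if (dims[ax] < need[ax]) {
        stop(sprintf("ellipsoid exceeds grid on axis %d (%d voxels, needs %.0f)",
                     ax, dims[ax], ceiling(need[ax])))
      }
    }
  }
  ctr <- dims * vox / 2
  xs <- ((.axis_coords(dims[1], vox[1]) - ctr[1]) / spec$semi_axes_um[1])^2
  ys <- ((.axis_coords(dims[2], vox[2]) - ctr[2]) / spec$semi_axes_um[2])^2
  zs <- ((.axis_coords(dims[3], vox[3]) - ctr[3]) / spec$semi_axes_um[3])^2
  r2 <- outer(outer(xs, ys, "+"), zs, "+")
  mask <- r2 <= 1
  dapi <- ifelse(mask, spec$dapi_level, spec$background_level)
  if (spec$poisson_noise) {
    dapi <- withr::with_seed(spec$seed,
                             array(stats::rpois(length(dapi), dapi), dims))
  }
  zero <- array(0, dims)
  img <- .new_nucleus_image(dims, vox,
                            list(dapi = dapi, green = zero, red = zero),
                            mask = mask)
  img$center_um <- ctr
  img$semi_axes_um <- spec$semi_axes_um
  img
}

#' Sample signal positions inside a nucleus under a radial model
#'
#' Rejection sampler shared by [scatter_channel()] and the statistical
#' calibration runs: candidate voxels are drawn uniformly from the interior and
#' accepted with probability `exp(-d / beta_um)` (boundary_bias) or always
#' (uniform), where `d` is the voxel's distance to the boundary.
#'
#' @param field distance field of the mask (um), as from [edt_um()].
#' @param mask logical interior mask.
#' @param voxel_size_um voxel size (um).
#' @param n number of points.
#' @param model a [radial_model()].
#' @param seed integer seed.
#' @param max_tries cap on total candidate draws.
#' @return data.frame with voxel indices `i, j, k`, continuous coordinates
#'   `x_um, y_um, z_um` (jittered within the voxel) and boundary distance `d_um`.
#' @export
sample_interior_points <- function(field, mask, voxel_size_um, n, model, seed,
                                   max_tries = 1000L * max(n, 1L)) {
  stopifnot(inherits(model, "radial_model"))
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty interior mask")
  d_all <- field[idx]
  withr::with_seed(seed, {
    if (n == 0L) {
      take <- integer(0)
    } else if (model$kind == "uniform") {
      take <- sample.int(length(idx), n, replace = TRUE)
    } else {
      take <- integer(0)
      tries <- 0L
      # scale the acceptance envelope by its interior maximum so acceptance
      # stays proportional to exp(-d / beta) while the sampler remains
      # practical for very small beta
      dmin <- min(d_all)
      while (length(take) < n) {
        m <- min(4L * (n - length(take)), max_tries - tries)
        if (m <= 0L) stop("rejection sampling exceeded retry cap")
        tries <- tries + m
        cand <- sample.int(length(idx), m, replace = TRUE)
        acc <- stats::runif(m) < exp(-(d_all[cand] - dmin) / model$beta_um)
        take <- c(take, cand[acc])
      }
      take <- take[seq_len(n)]
    }
    dims <- dim(mask)
    lin <- idx[take] - 1L
    i <- lin %% dims[1] + 1L
    j <- (lin %/% dims[1]) %% dims[2] + 1L
    k <- lin %/% (dims[1] * dims[2]) + 1L
    jit <- matrix(stats::runif(3 * length(take), -0.5, 0.5), ncol = 3)
    data.frame(
      i = i, j = j, k = k,
      x_um = (i - 0.5 + jit[, 1]) * voxel_size_um[1],
      y_um = (j - 0.5 + jit[, 2]) * voxel_size_um[2],
      z_um = (k - 0.5 + jit[, 3]) * voxel_size_um[3],
      d_um = d_all[take]
    )
  })
}

#' Scatter synthetic FISH / painting spots into a channel
#'
#' Spot centres are sampled with [sample_interior_points()]; each spot is
#' rendered as a 3D Gaussian blob of total intensity 1. The sampled centres and
#' their boundary distances are recorded in `img$spots_truth[[channel]]`.
#'
#' @param img a `nucleus_image` with a nonempty interior mask.
#' @param n_spots number of spots (0 gives an empty channel).
#' @param model a [radial_model()].
#' @param channel `"green"` or `"red"`.
#' @param spot_sigma_um Gaussian spot width (um).
#' @param seed integer seed.
#' @return the image with the channel filled in.
#' @export
scatter_channel <- function(img, n_spots, model, channel = c("green", "red"),
                            spot_sigma_um = 0.15, seed = 1L) {
  channel <- match.arg(channel)
  stopifnot(inherits(img, "nucleus_image"), !is.null(img$mask),
            sum(img$mask) > 0)
  field <- attr(img, "edt_cache")
  if (is.null(field)) {
    field <- edt_um(img$mask, img$voxel_size_um)
    attr(img, "edt_cache") <- field
  }
  pts <- sample_interior_points(field, img$mask, img$voxel_size_um,
                                n_spots, model, seed)
  vox <- img$voxel_size_um
  dims <- img$dims
  arr <- array(0, dims)
  rad <- pmax(1L, ceiling(3 * spot_sigma_um / vox))
  for (s in seq_len(nrow(pts))) {
    ctr <- c(pts$x_um[s], pts$y_um[s], pts$z_um[s])
    cv <- ctr / vox + 0.5              # continuous voxel coordinate
    i0 <- pmax(1L, floor(cv) - rad)
    i1 <- pmin(dims, floor(cv) + rad)
    gx <- stats::dnorm(.axis_coords(dims[1], vox[1])[i0[1]:i1[1]], ctr[1], spot_sigma_um)
    gy <- stats::dnorm(.axis_coords(dims[2], vox[2])[i0[2]:i1[2]], ctr[2], spot_sigma_um)
    gz <- stats::dnorm(.axis_coords(dims[3], vox[3])[i0[3]:i1[3]], ctr[3], spot_sigma_um)
    blob <- outer(outer(gx, gy), gz)
    tot <- sum(blob)
    if (tot > 0) {
      arr[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <-
        arr[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] + blob / tot
    }
  }
  img$channels[[channel]] <- arr
  img$spots_truth[[channel]] <- pts
  img
}
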