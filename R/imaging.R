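#' Segment a nucleus from its DAPI channel
#'
#' Otsu threshold on the DAPI intensities, followed by keeping the largest 3D
#' connected component and filling holes within each z-slice. This replaces the
#' interactive boundary tracing of typical confocal workflows with a
#' deterministic, testable rule.
#'
#' @param img a `nucleus_image` with a nonconstant DAPI channel.
#' @return the image with `img$mask` set to the segmented nucleus.
#' @export
segment_nucleus <- function(img) {
  stopifnot(inherits(img, "nucleus_image"))
  dapi <- img$channels$dapi
  if (is.null(dapi)) stop("DAPI channel missing")
  rng <- range(dapi)
  if (diff(rng) == 0) stop("no nucleus found: constant DAPI channel")
  norm <- (dapi - rng[1]) / diff(rng)
  # single global Otsu threshold over the full voxel histogram (otsu on a 3D
  # Image would return one threshold per z-frame)
  thr <- EBImage::otsu(EBImage::Image(matrix(norm, ncol = 1)), range = c(0, 1))
  fg <- norm > thr
  if (!any(fg)) stop("no nucleus found: empty foreground")
  mask <- largest_component(fg)
  img$mask <- .fill_holes_slices(mask)
  attr(img, "edt_cache") <- NULL
  img
}

#' Distance-to-periphery field of a nucleus mask
#'
#' Anisotropy-aware Euclidean distance (um) from each interior voxel to the
#' nearest voxel outside the mask — the "edge of DAPI staining" that all
#' perinuclear distances are measured against.
#'
#' @param mask logical 3D mask (nonempty).
#' @param voxel_size_um voxel size (um).
#' @return numeric 3D array (class `distance_field`), 0 outside the mask.
#' @export
boundary_distance_field <- function(mask, voxel_size_um) {
  if (!any(mask)) stop("empty mask")
  structure(edt_um(mask, voxel_size_um), class = "distance_field")
}

#' Detect FISH signal spots and their distances to the periphery
#'
#' Thresholds a channel at `min_fraction_of_max` of its within-mask maximum,
#' keeps 3D connected components of at least `min_voxels` voxels, and records
#' each component's intensity-weighted barycenter and its distance to the
#' nuclear periphery (trilinear interpolation of the distance field at the
#' barycenter). A barycenter interpolating to a non-positive distance is
#' reported with distance 0 and `outside_flag = TRUE`, never negative.
#'
#' @param img segmented `nucleus_image`.
#' @param channel `"green"` or `"red"`.
#' @param field optional precomputed [boundary_distance_field()].
#' @param min_fraction_of_max detection threshold as a fraction of the channel
#'   maximum within the mask.
#' @param min_voxels minimum component size.
#' @param distance_mode `"3d"` (default) measures the true 3D distance to the
#'   periphery; `"2d"` measures within the barycenter's focal plane only, as
#'   when distances are read off a single confocal section.
#' @return data.frame with one row per spot: `channel`, `x_um`, `y_um`, `z_um`,
#'   `total_intensity`, `distance_to_np_um`, `n_voxels`, `outside_flag`.
#'   No spots gives a zero-row frame.
#' @export
detect_spots <- function(img, channel = c("green", "red"), field = NULL,
                         min_fraction_of_max = 0.2, min_voxels = 4L,
                         distance_mode = c("3d", "2d")) {
  channel <- match.arg(channel)
  distance_mode <- match.arg(distance_mode)
  stopifnot(!is.null(img$mask))
  ch <- img$channels[[channel]]
  if (is.null(ch)) stop(sprintf("channel '%s' missing", channel))
  empty <- data.frame(channel = character(0), x_um = numeric(0),
                      y_um = numeric(0), z_um = numeric(0),
                      total_intensity = numeric(0),
                      distance_to_np_um = numeric(0),
                      n_voxels = integer(0), outside_flag = logical(0))
  inmask <- ch * img$mask
  mx <- max(inmask)
  if (mx <= 0) return(empty)
  if (is.null(field)) {
    field <- boundary_distance_field(img$mask, img$voxel_size_um)
  }
  labs <- label_components_3d(inmask >= min_fraction_of_max * mx)
  k <- max(labs)
  if (k == 0) return(empty)
  vox <- img$voxel_size_um
  dims <- img$dims
  slice_fields <- new.env(parent = emptyenv())
  slice_distance <- function(bc_vox) {
    z <- min(max(1L, round(bc_vox[3])), dims[3])
    key <- as.character(z)
    if (is.null(slice_fields[[key]])) {
      sl <- array(img$mask[, , z], c(dims[1], dims[2], 1L))
      # huge z spacing keeps the adjacent (padded) planes from contributing:
      # the distance is measured within the focal plane only
      slice_fields[[key]] <- edt_um(sl, c(vox[1], vox[2], 1e6))
    }
    interp_trilinear(slice_fields[[key]], c(bc_vox[1], bc_vox[2], 1))
  }
  rows <- lapply(seq_len(k), function(l) {
    idx <- which(labs == l)
    if (length(idx) < min_voxels) return(NULL)
    w <- ch[idx]
    lin <- idx - 1L
    i <- lin %% dims[1] + 1L
    j <- (lin %/% dims[1]) %% dims[2] + 1L
    z <- lin %/% (dims[1] * dims[2]) + 1L
    bc_vox <- c(sum(w * i), sum(w * j), sum(w * z)) / sum(w)
    d <- if (distance_mode == "2d") slice_distance(bc_vox)
         else interp_trilinear(unclass(field), bc_vox)
    data.frame(channel = channel,
               x_um = (bc_vox[1] - 0.5) * vox[1],
               y_um = (bc_vox[2] - 0.5) * vox[2],
               z_um = (bc_vox[3] - 0.5) * vox[3],
               total_intensity = sum(w),
               distance_to_np_um = max(d, 0),
               n_voxels = length(idx),
               outside_flag = d <= 0)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Compare NP distances of two probe classes (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test (normal approximation with tie correction) of
#' green- vs red-probe distances to the nuclear periphery, with per-group
#' summaries formatted "mean ± sd, n".
#'
#' @param green_dists,red_dists numeric distance vectors (um), nonempty.
#' @return an object of class `distance_comparison` with per-group `mean`,
#'   `sd`, `n`, formatted `summary` strings, `u_statistic`, `p_value`,
#'   significance `code` (`"**"` p < 0.01, `"*"` 0.01 <= p < 0.05, `"ns"`
#'   otherwise) and a `small_n` flag when either group has n < 3.
#' @export
compare_probe_distances <- function(green_dists, red_dists) {
  stopifnot(length(green_dists) > 0, length(red_dists) > 0)
  small_n <- length(green_dists) < 3 || length(red_dists) < 3
  if (small_n) warning("fewer than 3 observations in a group")
  summ <- function(x) {
    list(mean = mean(x), sd = stats::sd(x), n = length(x),
         summary = format_distance_summary(mean(x), stats::sd(x), length(x)))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(green_dists, red_dists, exact = FALSE, correct = TRUE))
  p <- ht$p.value
  if (is.nan(p)) p <- 1  # all values tied: no evidence of a shift
  structure(list(green = summ(green_dists), red = summ(red_dists),
                 u_statistic = unname(ht$statistic), p_value = p,
                 code = if (p < 0.01) "**" else if (p < 0.05) "*" else "ns",
                 small_n = small_n),
            class = "distance_comparison")
}

#' Format a distance summary as "mean ± sd, n"
#'
#' @param mean,sd,n group summary values.
#' @return character scalar, e.g. `"0.60 ± 0.41, 60"`.
#' @export
format_distance_summary <- function(mean, sd, n) {
  sprintf("%.2f ± %.2f, %d", mean, sd, as.integer(n))
}

#' @export
print.distance_comparison <- function(x, ...) {
  cat("Green:", x$green$summary, "| Red:", x$red$summary,
      sprintf("| U = %.1f, p = %.3g (%s)\n", x$u_statistic, x$p_value, x$code))
  invisible(x)
}

#' Nuclear morphology: volume, surface area, sphericity
#'
#' Volume is voxel count times voxel volume; surface area is estimated from
#' the gradient magnitude of a smoothed mask indicator (co-area formula);
#' sphericity is Wadell's `pi^(1/3) * (6 V)^(2/3) / A`, capped at 1.
#'
#' @param mask logical 3D mask (nonempty).
#' @param voxel_size_um voxel size (um).
#' @return list with `volume_um3`, `surface_area_um2`, `sphericity` and a
#'   `border_warning` flag (TRUE when the mask touches the array border, where
#'   the area is underestimated).
#' @export
nuclear_morphology <- function(mask, voxel_size_um) {
  if (!any(mask)) stop("empty mask")
  d <- dim(mask)
  border <- any(mask[1, , ]) || any(mask[d[1], , ]) ||
    any(mask[, 1, ]) || any(mask[, d[2], ]) ||
    any(mask[, , 1]) || any(mask[, , d[3]])
  if (border) warning("mask touches the image border; surface area underestimated")
  V <- sum(mask) * prod(voxel_size_um)
  A <- .surface_area_um2(mask, voxel_size_um)
  list(volume_um3 = V, surface_area_um2 = A,
       sphericity = min(1, pi^(1 / 3) * (6 * V)^(2 / 3) / A),
       border_warning = border)
}
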