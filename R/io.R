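#' Write a contact matrix as sparse triplets
#'
#' Upper-triangle entries as `bin_i<TAB>bin_j<TAB>count` (0-based bins), with a
#' companion bins table `<path>.bins.tsv` (`chrom`, `start`, `end`, `bin_id`).
#'
#' @param m a [contact_matrix()].
#' @param path output path.
#' @export
write_triplet_matrix <- function(m, path) {
  stopifnot(inherits(m, "contact_matrix"))
  up <- which(upper.tri(m$counts, diag = TRUE) & m$counts > 0, arr.ind = TRUE)
  df <- data.frame(bin_i = up[, 1] - 1L, bin_j = up[, 2] - 1L,
                   count = m$counts[up])
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  bins <- data.frame(chrom = m$bins$chrom, start = m$bins$start,
                     end = m$bins$start + m$bin_size_bp,
                     bin_id = seq_len(nrow(m$bins)) - 1L)
  utils::write.table(bins, paste0(path, ".bins.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sparse triplet contact matrix
#'
#' @param path triplet file written by [write_triplet_matrix()] (a bins table
#'   at `<path>.bins.tsv` is used when present).
#' @param n_bins,bin_size_bp required when no bins table is found.
#' @return a [contact_matrix()].
#' @export
read_triplet_matrix <- function(path, n_bins = NULL, bin_size_bp = NULL) {
  tri <- utils::read.table(path, sep = "\t",
                           col.names = c("bin_i", "bin_j", "count"))
  bins_path <- paste0(path, ".bins.tsv")
  if (file.exists(bins_path)) {
    bins <- utils::read.table(bins_path, header = TRUE, sep = "\t")
    n_bins <- nrow(bins)
    bin_size_bp <- bins$end[1] - bins$start[1]
  } else {
    stopifnot(!is.null(n_bins), !is.null(bin_size_bp))
    bins <- data.frame(chrom = "chr1",
                       start = (seq_len(n_bins) - 1) * bin_size_bp)
  }
  counts <- matrix(0, n_bins, n_bins)
  counts[cbind(tri$bin_i + 1L, tri$bin_j + 1L)] <- tri$count
  counts[cbind(tri$bin_j + 1L, tri$bin_i + 1L)] <- tri$count
  contact_matrix(counts, bin_size_bp,
                 bins = bins[, c("chrom", "start"), drop = FALSE])
}

#' Write a signal track as bedGraph
#'
#' @param track a [signal_track()].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  n <- length(track$values)
  df <- data.frame(chrom = track$chrom,
                   start = (seq_len(n) - 1) * track$window_bp,
                   end = seq_len(n) * track$window_bp,
                   value = track$values)
  df <- df[!is.na(df$value), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path bedGraph path.
#' @return data.frame with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  utils::read.table(path, sep = "\t",
                    col.names = c("chrom", "start", "end", "value"))
}

#' Write intervals as BED
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `score`.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "score"), names(intervals))
  df <- intervals[, cols, drop = FALSE]
  if ("score" %in% cols) df <- cbind(df[1:3], name = ".", score = df$score)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED file (first three or more columns)
#'
#' @param path BED path.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t")
  names(df)[1:3] <- c("chrom", "start", "end")
  df[, 1:3]
}

#' Write a nucleus image as per-channel multi-page TIFFs with a JSON sidecar
#'
#' One TIFF per channel (one page per z-slice, intensities scaled to [0, 1]
#' by the stored `intensity_scale`), plus `<prefix>.json` recording
#' `voxel_size_um`, dims, channels and the scale.
#'
#' @param img a `nucleus_image`.
#' @param prefix output path prefix.
#' @return the sidecar path, invisibly.
#' @export
write_nucleus_tiff <- function(img, prefix) {
  stopifnot(inherits(img, "nucleus_image"))
  scale <- vapply(img$channels, function(a) max(1e-12, max(a)), numeric(1))
  for (ch in names(img$channels)) {
    pages <- lapply(seq_len(img$dims[3]),
                    function(z) img$channels[[ch]][, , z] / scale[[ch]])
    tiff::writeTIFF(pages, sprintf("%s_%s.tif", prefix, ch),
                    bits.per.sample = 16)
  }
  side <- paste0(prefix, ".json")
  jsonlite::write_json(list(voxel_size_um = img$voxel_size_um,
                            dims = img$dims, channels = names(img$channels),
                            intensity_scale = as.list(scale)),
                       side, auto_unbox = FALSE, digits = NA)
  invisible(side)
}

#' Read a nucleus image written by [write_nucleus_tiff()]
#'
#' @param prefix path prefix used when writing.
#' @return a `nucleus_image`.
#' @export
read_nucleus_tiff <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  channels <- lapply(meta$channels, function(ch) {
    pages <- tiff::readTIFF(sprintf("%s_%s.tif", prefix, ch), all = TRUE)
    arr <- array(0, dims)
    for (z in seq_len(dims[3])) {
      arr[, , z] <- pages[[z]] * meta$intensity_scale[[ch]]
    }
    arr
  })
  names(channels) <- meta$channels
  .new_nucleus_image(dims, meta$voxel_size_um, channels)
}
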