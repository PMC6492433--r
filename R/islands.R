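#' Bin reads or coverage onto a fixed window grid
#'
#' @param x either a data.frame of read starts (`chrom`, `start`; bp, 0-based)
#'   or a coverage bedGraph data.frame (`chrom`, `start`, `end`, `value`).
#' @param W_bp window width in bp (default 500).
#' @param chrom_length_bp optional chromosome length(s); defaults to the
#'   largest coordinate seen, rounded up to a window.
#' @param mode for bedGraph input, `"mass"` sums value x covered bp per window,
#'   `"mean"` averages the value over the window.
#' @return a named list of [signal_track()]s, one per chromosome.
#' @export
window_counts <- function(x, W_bp = 500L, chrom_length_bp = NULL,
                          mode = c("mass", "mean")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(x), "chrom" %in% names(x), "start" %in% names(x))
  is_cov <- all(c("end", "value") %in% names(x))
  if (is.unsorted(order(x$chrom, x$start))) {
    warning("input not sorted; sorting internally")
  }
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  out <- list()
  for (cc in unique(x$chrom)) {
    xi <- x[x$chrom == cc, , drop = FALSE]
    clen <- if (is.null(chrom_length_bp)) {
      max(if (is_cov) xi$end else xi$start + 1)
    } else if (is.null(names(chrom_length_bp))) chrom_length_bp
    else chrom_length_bp[[cc]]
    nwin <- ceiling(clen / W_bp)
    vals <- numeric(nwin)
    if (is_cov) {
      ws <- (seq_len(nwin) - 1) * W_bp
      we <- ws + W_bp
      for (r in seq_len(nrow(xi))) {
        ov <- pmax(0, pmin(we, xi$end[r]) - pmax(ws, xi$start[r]))
        vals <- vals + xi$value[r] * ov
      }
      if (mode == "mean") vals <- vals / W_bp
    } else {
      tab <- table(factor(xi$start %/% W_bp + 1L, levels = seq_len(nwin)))
      vals <- as.numeric(tab)
    }
    out[[cc]] <- signal_track(vals, W_bp, chrom = cc)
  }
  out
}

#' Call broad enrichment islands with a window/gap scorer
#'
#' A SICER-style caller for broad ChIP enrichment. Each treatment window is
#' screened against a Poisson background whose rate is the depth-scaled
#' control value, floored at the depth-scaled genome-wide control mean (the
#' floor keeps chance dips of the control from manufacturing significance).
#' Windows with screening p below `screen_p` are eligible; eligible windows
#' separated by at most `G` bp are merged into candidate islands; each island
#' is scored by the upper-tail Poisson probability of its summed treatment
#' counts against its summed background rate, and islands are retained at
#' Benjamini-Hochberg `q < fdr`.
#'
#' @param treatment,control [signal_track()]s on the same window grid.
#' @param G maximum gap (bp) bridged when merging eligible windows.
#' @param fdr island-level FDR threshold.
#' @param screen_p window-level screening p-value defining eligibility.
#' @return an object of class `island_call`: data.frame `islands` with
#'   `chrom`, `start`, `end` (0-based half-open), `score` (summed treatment
#'   counts), `expected`, `p_value`, `q_value`; parameters are echoed.
#' @export
call_islands <- function(treatment, control, G = 1500L, fdr = 0.01,
                         screen_p = 0.2) {
  stopifnot(inherits(treatment, "signal_track"), inherits(control, "signal_track"))
  if (treatment$window_bp != control$window_bp ||
      length(treatment$values) != length(control$values)) {
    stop("treatment and control must share the window grid")
  }
  if (sum(control$values) <= 0) stop("control track has no signal")
  W <- treatment$window_bp
  t <- treatment$values
  cv <- control$values
  r <- sum(t) / sum(cv)
  lambda <- r * pmax(cv, mean(cv))
  p_win <- stats::ppois(t - 1, lambda, lower.tail = FALSE)
  elig <- which(p_win < screen_p)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), score = numeric(0),
                      expected = numeric(0), p_value = numeric(0),
                      q_value = numeric(0))
  params <- list(W = W, G = G, fdr = fdr, screen_p = screen_p)
  if (length(elig) == 0) {
    return(structure(list(islands = empty, params = params),
                     class = "island_call"))
  }
  # merge eligible windows whose gap (bp between successive eligible
  # windows) is at most G
  brk <- c(TRUE, (elig[-1] - elig[-length(elig)] - 1L) * W > G)
  grp <- cumsum(brk)
  isl <- do.call(rbind, lapply(split(elig, grp), function(ix) {
    span <- min(ix):max(ix)
    data.frame(chrom = treatment$chrom,
               start = (min(ix) - 1) * W, end = max(ix) * W,
               score = sum(t[span]), expected = sum(lambda[span]))
  }))
  isl$p_value <- stats::ppois(isl$score - 1, isl$expected, lower.tail = FALSE)
  # BH with the full window count as family size: candidate islands exist only
  # because their windows passed screening, so correcting over islands alone
  # would understate the number of implicit tests
  isl$q_value <- stats::p.adjust(isl$p_value, method = "BH",
                                 n = max(nrow(isl), length(t)))
  isl <- isl[isl$q_value < fdr, , drop = FALSE]
  rownames(isl) <- NULL
  structure(list(islands = isl, params = params), class = "island_call")
}

#' @export
print.island_call <- function(x, ...) {
  cat(sprintf("<island_call> %d islands (W=%d, G=%d, FDR<%g)\n",
              nrow(x$islands), x$params$W, x$params$G, x$params$fdr))
  invisible(x)
}

# normalize an interval data.frame: sort and merge overlaps
.normalize_intervals <- function(x) {
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(.as_gr(x))
  df <- .gr_to_df(gr)
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Intersect two replicate island calls into reproducible domains
#'
#' Base-pair intersection of two island sets; regions enriched in both
#' replicates are the reproducible domains (PLADs, for CRWN1 ChIP).
#'
#' @param a,b `island_call`s or interval data.frames.
#' @return normalized interval data.frame (`chrom`, `start`, `end`).
#' @export
intersect_replicates <- function(a, b) {
  ia <- if (inherits(a, "island_call")) a$islands else a
  ib <- if (inherits(b, "island_call")) b$islands else b
  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  if (nrow(ia) == 0 || nrow(ib) == 0) return(empty)
  gr <- GenomicRanges::intersect(.as_gr(ia), .as_gr(ib))
  if (length(gr) == 0) return(empty)
  .normalize_intervals(.gr_to_df(gr))
}

#' Base-pair overlap between two interval sets
#'
#' @param a,b interval data.frames (`chrom`, `start`, `end`).
#' @return list with `jaccard` (shared bp / union bp), `fraction_of_a_covered`
#'   and `fraction_of_b_covered`. Empty inputs give zeros.
#' @export
domain_overlap <- function(a, b) {
  wa <- if (nrow(a) > 0) sum(a$end - a$start) else 0
  wb <- if (nrow(b) > 0) sum(b$end - b$start) else 0
  if (wa == 0 || wb == 0) {
    return(list(jaccard = 0, fraction_of_a_covered = 0,
                fraction_of_b_covered = 0))
  }
  inter <- GenomicRanges::intersect(.as_gr(a), .as_gr(b))
  wi <- sum(GenomicRanges::width(inter))
  list(jaccard = wi / (wa + wb - wi),
       fraction_of_a_covered = wi / wa,
       fraction_of_b_covered = wi / wb)
}

#' Log2 ratio track of treatment over input
#'
#' `log2((t + pc) / (s * input + pc))` per window, where `s` is the
#' treatment/input depth ratio; windows where both raw values are zero are
#' masked (`NA`).
#'
#' @param treatment,input_ [signal_track()]s on the same grid.
#' @param pseudocount positive pseudocount (default 1).
#' @param scale depth scale `s`; `NULL` (default) uses the ratio of track
#'   totals, or pass 1 when the two libraries are already depth-matched.
#' @return a [signal_track()] of log2 ratios.
#' @export
log_ratio_track <- function(treatment, input_, pseudocount = 1, scale = NULL) {
  stopifnot(pseudocount > 0)
  if (treatment$window_bp != input_$window_bp ||
      length(treatment$values) != length(input_$values)) {
    stop("treatment and input must share the window grid")
  }
  s <- if (is.null(scale)) sum(treatment$values) / sum(input_$values) else scale
  v <- log2((treatment$values + pseudocount) /
              (s * input_$values + pseudocount))
  v[treatment$values == 0 & input_$values == 0] <- NA_real_
  signal_track(v, treatment$window_bp, chrom = treatment$chrom)
}

# window index sets covered by an interval set, on a track's grid
.windows_touching <- function(track, intervals) {
  n <- length(track$values)
  W <- track$window_bp
  hit <- logical(n)
  iv <- intervals[intervals$chrom == track$chrom, , drop = FALSE]
  for (r in seq_len(nrow(iv))) {
    lo <- floor(iv$start[r] / W) + 1
    hi <- ceiling(iv$end[r] / W)
    hit[max(1, lo):min(n, hi)] <- TRUE
  }
  hit
}

#' Compare signal inside domains with their flanking regions
#'
#' Partitions track windows into domain windows and windows of the `flank_bp`
#' regions on either side (clipped at chromosome ends and at neighbouring
#' domains) and compares the two value sets with a two-sided Mann-Whitney U
#' test — the accessibility-inside-vs-outside contrast used for PLADs.
#'
#' @param track a [signal_track()] (e.g. ATAC coverage or a log ratio).
#' @param domains interval data.frame.
#' @param flank_bp flank width in bp (default 1000).
#' @return list with `mean_inside`, `mean_flank`, `n_inside`, `n_flank`, `p`.
#' @export
signal_in_and_flank <- function(track, domains, flank_bp = 1000L) {
  stopifnot(inherits(track, "signal_track"))
  dom <- .normalize_intervals(domains)
  dom <- dom[dom$chrom == track$chrom, , drop = FALSE]
  if (nrow(dom) == 0) stop("no domains on the track's chromosome")
  clen <- length(track$values) * track$window_bp
  fl <- data.frame(chrom = rep(dom$chrom, 2),
                   start = c(pmax(0, dom$start - flank_bp), dom$end),
                   end = c(dom$start, pmin(clen, dom$end + flank_bp)))
  fl <- fl[fl$start < fl$end, , drop = FALSE]
  inside <- .windows_touching(track, dom)
  flank <- .windows_touching(track, fl) & !inside
  if (!any(flank)) stop("no flank windows anywhere")
  vi <- track$values[inside]
  vf <- track$values[flank]
  vi <- vi[!is.na(vi)]; vf <- vf[!is.na(vf)]
  ht <- suppressWarnings(stats::wilcox.test(vi, vf, exact = FALSE))
  p <- ht$p.value
  if (is.nan(p)) p <- 1
  list(mean_inside = mean(vi), mean_flank = mean(vf),
       n_inside = length(vi), n_flank = length(vf), p = p)
}

#' Stratify ChIP signal by overlap with accessibility peaks
#'
#' Restricts a track to windows inside `regions`, splits them by any base-pair
#' overlap with `peaks` (half-open intervals: abutting does not overlap), and
#' compares the two ChIP-signal distributions with a two-sided Mann-Whitney U
#' test.
#'
#' @param chip_track a [signal_track()].
#' @param regions interval data.frame restricting the windows considered.
#' @param peaks interval data.frame of peaks.
#' @return list with `mean_overlap`, `mean_no_overlap`, group sizes, `p`, and
#'   `undefined = TRUE` (p = NA) when either group is empty.
#' @export
stratify_by_peak_overlap <- function(chip_track, regions, peaks) {
  stopifnot(inherits(chip_track, "signal_track"))
  reg <- .normalize_intervals(regions)
  reg <- reg[reg$chrom == chip_track$chrom, , drop = FALSE]
  if (nrow(reg) == 0) stop("regions empty on the track's chromosome")
  inreg <- .windows_touching(chip_track, reg)
  W <- chip_track$window_bp
  n <- length(chip_track$values)
  overlap <- logical(n)
  pk <- peaks[peaks$chrom == chip_track$chrom, , drop = FALSE]
  if (nrow(pk) > 0) {
    ws <- (seq_len(n) - 1) * W
    we <- ws + W
    for (r in seq_len(nrow(pk))) {
      overlap <- overlap | (ws < pk$end[r] & we > pk$start[r])
    }
  }
  g1 <- chip_track$values[inreg & overlap]
  g0 <- chip_track$values[inreg & !overlap]
  g1 <- g1[!is.na(g1)]; g0 <- g0[!is.na(g0)]
  if (length(g1) == 0 || length(g0) == 0) {
    return(list(mean_overlap = if (length(g1)) mean(g1) else NA_real_,
                mean_no_overlap = if (length(g0)) mean(g0) else NA_real_,
                n_overlap = length(g1), n_no_overlap = length(g0),
                p = NA_real_, undefined = TRUE))
  }
  ht <- suppressWarnings(stats::wilcox.test(g1, g0, exact = FALSE))
  p <- ht$p.value
  if (is.nan(p)) p <- 1
  list(mean_overlap = mean(g1), mean_no_overlap = mean(g0),
       n_overlap = length(g1), n_no_overlap = length(g0),
       p = p, undefined = FALSE)
}

#' qPCR fold enrichment by the delta-delta-Ct method
#'
#' `dCt(locus) = Ct_IP - Ct_input`; fold enrichment relative to the reference
#' locus is `2^-(dCt(locus) - dCt(reference))`, assuming doubling per cycle.
#' The reference locus (TUB2 in the CRWN1 ChIP assays) has fold 1 by
#' construction.
#'
#' @param table data.frame with columns `locus`, `template` (`"IP"`/`"input"`)
#'   and `Ct`.
#' @param reference reference locus name (default `"TUB2"`).
#' @return data.frame with `locus`, `dCt` and `fold_enrichment`.
#' @export
qpcr_fold_enrichment <- function(table, reference = "TUB2") {
  stopifnot(all(c("locus", "template", "Ct") %in% names(table)))
  loci <- unique(table$locus)
  if (!reference %in% loci) stop(sprintf("reference locus '%s' missing", reference))
  dct <- vapply(loci, function(l) {
    ip <- table$Ct[table$locus == l & table$template == "IP"]
    inp <- table$Ct[table$locus == l & table$template == "input"]
    if (length(ip) == 0) stop(sprintf("locus '%s' has no IP Ct", l))
    if (length(inp) == 0) stop(sprintf("locus '%s' has no input Ct", l))
    mean(ip) - mean(inp)
  }, numeric(1))
  data.frame(locus = loci, dCt = unname(dct),
             fold_enrichment = 2^-(unname(dct) - dct[[reference]]))
}
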