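# Peak-to-region assignment and distance-decay scoring.
#
# A peak contributes to a region when its center lies within `window` bp of
# the region's reference point (TSS-style 5' end or interval center).  Each
# contributing peak gets a score S_p = exp(-(0.5 + 4 * delta)) where
# delta = |distance| / window in [0, 1], and a region's regulatory potential
# S_g is the sum of its peak scores.  All distance arithmetic is done in
# BED 0-based coordinates.

# Shared association kernel: returns a data.frame of (peak index,
# region index) pairs where |peak center - region reference| <= window on
# the same chromosome.  Uses IRanges overlap machinery; the O(n*m)
# brute-force equivalent lives in the test suite as an oracle.
.find_pairs <- function(peaks, regions, window, ref_point = "center") {
  if (!is.numeric(window) || length(window) != 1 || window <= 0) {
    stop_contract("window must be a single positive number of bp")
  }
  centers0 <- .bed_center(peaks)
  refs0 <- .region_reference(regions, ref_point)
  # Harmonize seqlevels so findOverlaps accepts disjoint chromosome sets
  lev <- union(GenomeInfoDb::seqlevels(peaks), GenomeInfoDb::seqlevels(regions))
  q <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(peaks),
    IRanges::IRanges(start = centers0 + 1L, width = 1L)
  )
  s <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(regions),
    # window is inclusive at both ends: 0-based [ref - w, ref + w]
    IRanges::IRanges(start = pmax(refs0 - window, 0) + 1L,
                     end = refs0 + window + 1L)
  )
  GenomeInfoDb::seqlevels(q) <- lev
  GenomeInfoDb::seqlevels(s) <- lev
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  data.frame(peak = S4Vectors::queryHits(hits),
             region = S4Vectors::subjectHits(hits))
}

#' Pair peaks with nearby regions
#'
#' Returns every (peak, region) pair on the same chromosome whose
#' center-to-reference distance is at most \code{window} bp (boundary
#' inclusive).  A peak may pair with several regions and vice versa.
#'
#' @param peaks,regions \code{GRanges} with an \code{id} metadata column,
#'   e.g. from [read_bed()].  Region ids must be unique.
#' @param window Association window in bp (default 100 kb).
#' @param ref_point Region reference point: \code{"center"} (interval
#'   midpoint, the default) or \code{"start"} (strand-aware 5' end).
#' @return data.frame with columns \code{peak_id}, \code{region_id}, sorted
#'   by region id then peak id (C-locale order); zero rows when nothing
#'   pairs.
#' @export
merge_ranges <- function(peaks, regions, window = 1e5,
                         ref_point = c("center", "start")) {
  ref_point <- match.arg(ref_point)
  region_ids <- .assert_unique_region_ids(.interval_ids(regions))
  peak_ids <- .interval_ids(peaks)
  idx <- .find_pairs(peaks, regions, window, ref_point)
  out <- data.frame(peak_id = peak_ids[idx$peak],
                    region_id = region_ids[idx$region],
                    stringsAsFactors = FALSE)
  out[.order_radix(out$region_id, out$peak_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Signed distance from peak centers to region reference points
#'
#' Distance is \code{peak_center - region_reference} in bp, computed in
#' 0-based coordinates with centers taken as the floor of the interval
#' midpoint.  With \code{ref_point = "start"} the reference is the
#' strand-aware 5' end (start for \code{+}/unstranded regions, the last
#' base for \code{-} regions).
#'
#' @param peaks,regions Parallel \code{GRanges} (equal length, or one of
#'   length 1 to be recycled).  Elements must be pairwise on the same
#'   chromosome.
#' @param ref_point \code{"center"} or \code{"start"}.
#' @return Integer vector of signed distances in bp.
#' @export
find_distance <- function(peaks, regions, ref_point = c("center", "start")) {
  ref_point <- match.arg(ref_point)
  n <- max(length(peaks), length(regions))
  if (length(peaks) == 1L) peaks <- rep(peaks, n)
  if (length(regions) == 1L) regions <- rep(regions, n)
  if (length(peaks) != length(regions)) {
    stop_contract("peaks and regions must be parallel (lengths %d vs %d)",
                  length(peaks), length(regions))
  }
  same <- as.character(GenomeInfoDb::seqnames(peaks)) ==
    as.character(GenomeInfoDb::seqnames(regions))
  if (any(!same)) {
    stop_contract("peak and region on different chromosomes at position %d",
                  which(!same)[1])
  }
  as.integer(.bed_center(peaks) - .region_reference(regions, ref_point))
}

#' Exponential distance-decay peak scores
#'
#' Computes \code{S_p = exp(-(0.5 + 4 * delta))} with
#' \code{delta = |distance| / window}, a monotonically decreasing kernel
#' ranging from \code{exp(-0.5)} at the reference point to
#' \code{exp(-4.5)} at the window edge.
#'
#' @param distances Signed distances in bp; every \code{|distance|} must be
#'   at most \code{window} (filter with [merge_ranges()] first).
#' @param window Association window in bp.
#' @return Numeric vector of peak scores, order-preserving.
#' @export
score_peaks <- function(distances, window = 1e5) {
  if (!is.numeric(window) || length(window) != 1 || window <= 0) {
    stop_contract("window must be a single positive number of bp")
  }
  if (any(!is.finite(distances))) {
    stop_contract("distances must be finite")
  }
  if (any(abs(distances) > window)) {
    stop_contract("|distance| exceeds window at position %d",
                  which(abs(distances) > window)[1])
  }
  exp(-(0.5 + 4 * abs(distances) / window))
}

#' Sum peak scores into per-region regulatory potentials
#'
#' The regulatory potential of a region is the plain sum of the decay
#' scores of all peaks assigned to it.  Regions without any contributing
#' peak are absent from the output.
#'
#' @param peak_scores Numeric vector of peak scores.
#' @param region_ids Parallel character vector of region ids.
#' @return data.frame with columns \code{region_id}, \code{potential},
#'   \code{n_peaks}, one row per distinct region id, sorted by region id.
#' @export
score_regions <- function(peak_scores, region_ids) {
  if (length(peak_scores) != length(region_ids)) {
    stop_contract("peak_scores and region_ids must be parallel (%d vs %d)",
                  length(peak_scores), length(region_ids))
  }
  if (length(peak_scores) == 0) {
    return(data.frame(region_id = character(), potential = numeric(),
                      n_peaks = integer(), stringsAsFactors = FALSE))
  }
  region_ids <- as.character(region_ids)
  uid <- sort(unique(region_ids), method = "radix")
  f <- factor(region_ids, levels = uid)
  pot <- as.numeric(rowsum(peak_scores, f))
  n <- as.integer(tabulate(f, nbins = length(uid)))
  data.frame(region_id = uid, potential = pot, n_peaks = n,
             stringsAsFactors = FALSE)
}

#' Assign peaks to regions and score each assignment
#'
#' Composition of [merge_ranges()], [find_distance()] and [score_peaks()]:
#' every peak within \code{window} of a region's reference point becomes a
#' row carrying its signed distance, normalized distance \code{delta} and
#' decay score.
#'
#' @inheritParams merge_ranges
#' @return data.frame with columns \code{peak_id}, \code{chrom},
#'   \code{peak_start}, \code{peak_end} (BED 0-based half-open),
#'   \code{region_id}, \code{distance_bp}, \code{delta}, \code{peak_score},
#'   sorted by region id then peak id.
#' @export
associated_peaks <- function(peaks, regions, window = 1e5,
                             ref_point = c("center", "start")) {
  ref_point <- match.arg(ref_point)
  region_ids <- .assert_unique_region_ids(.interval_ids(regions))
  peak_ids <- .interval_ids(peaks)
  idx <- .find_pairs(peaks, regions, window, ref_point)
  d <- as.integer(.bed_center(peaks)[idx$peak] -
                    .region_reference(regions, ref_point)[idx$region])
  out <- data.frame(
    peak_id = peak_ids[idx$peak],
    chrom = as.character(GenomeInfoDb::seqnames(peaks))[idx$peak],
    peak_start = .bed_start(peaks)[idx$peak],
    peak_end = .bed_end(peaks)[idx$peak],
    region_id = region_ids[idx$region],
    distance_bp = d,
    delta = abs(d) / window,
    peak_score = score_peaks(d, window),
    stringsAsFactors = FALSE
  )
  out[.order_radix(out$region_id, out$peak_id, out$distance_bp), ,
      drop = FALSE] |>
    `rownames<-`(NULL)
}
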