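# Rank-product integration of binding potential and expression statistics,
# plus the two-factor regulatory-interaction (RI) term.

#' Rank regions by binding potential and expression statistic
#'
#' Binding ranks order regulatory potentials descending (largest potential
#' gets rank 1); expression ranks order the absolute statistic descending
#' (strongest change gets rank 1, the sign being kept aside for grouping).
#' Ties get midranks.  The rank product
#' \code{RP = binding_rank * stat_rank / n^2}, with n the number of ranked
#' regions, lies in [1/n^2, 1]; small values mark likely direct targets.
#'
#' @param potentials Numeric vector of regulatory potentials.
#' @param stats Parallel numeric vector of signed statistics (or RI terms).
#' @param ids Parallel character vector of unique region ids.
#' @return data.frame with columns \code{region_id}, \code{potential},
#'   \code{stat}, \code{binding_rank}, \code{stat_rank},
#'   \code{rank_product}, sorted by rank product ascending (ties broken by
#'   region id).
#' @export
rank_product <- function(potentials, stats, ids) {
  n <- length(ids)
  if (n == 0) {
    stop_empty("no regions to rank")
  }
  if (length(potentials) != n || length(stats) != n) {
    stop_contract("potentials, stats and ids must be parallel")
  }
  ids <- as.character(ids)
  .assert_unique_region_ids(ids)
  bad <- which(!is.finite(stats))
  if (length(bad) > 0) {
    stop_contract("non-finite statistic for region '%s'", ids[bad[1]])
  }
  if (any(!is.finite(potentials))) {
    stop_contract("non-finite regulatory potential")
  }
  binding_rank <- rank(-potentials, ties.method = "average")
  stat_rank <- rank(-abs(stats), ties.method = "average")
  rp <- binding_rank * stat_rank / n^2
  out <- data.frame(region_id = ids, potential = potentials, stat = stats,
                    binding_rank = binding_rank, stat_rank = stat_rank,
                    rank_product = rp, stringsAsFactors = FALSE)
  out[.order_radix(out$rank_product, out$region_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Regulatory-interaction term for two factors
#'
#' The elementwise product of the two factors' signed perturbation
#' statistics for each region.  A positive product means the factors push
#' the target in the same direction (cooperative); a negative product means
#' opposing directions (competitive); zero when either statistic is zero.
#'
#' @param stats_x,stats_y Parallel numeric vectors of finite signed
#'   statistics, one per region.
#' @return Numeric vector of RI values, order-preserving.
#' @export
regulatory_interaction <- function(stats_x, stats_y) {
  if (length(stats_x) != length(stats_y)) {
    stop_contract("stats_x and stats_y must be parallel (%d vs %d)",
                  length(stats_x), length(stats_y))
  }
  if (any(!is.finite(stats_x)) || any(!is.finite(stats_y))) {
    stop_contract("statistics must be finite")
  }
  stats_x * stats_y
}

# Join region scores with expression records; message the number dropped
# for lack of an expression record.
.join_expression <- function(scores, expression) {
  m <- match(scores$region_id, expression$region_id)
  dropped <- sum(is.na(m))
  if (dropped > 0) {
    message(sprintf("dropped %d region(s) with peaks but no expression record",
                    dropped))
  }
  keep <- !is.na(m)
  cbind(scores[keep, , drop = FALSE],
        expression[m[keep], setdiff(names(expression), "region_id"),
                   drop = FALSE])
}

#' Rank a factor's direct targets
#'
#' The full single- or two-factor pipeline: assign peaks to regions and
#' score them ([associated_peaks()]), sum scores into regulatory
#' potentials ([score_regions()]), join the perturbation statistics, and
#' rank by rank product ([rank_product()]).  In \code{two_factor} mode the
#' expression rank is taken on the absolute regulatory interaction
#' \code{RI = stat_x * stat_y} ([regulatory_interaction()]).  Only regions
#' with at least one associated peak and an expression record are ranked;
#' n in the rank product is the number of such regions.  Each target also
#' receives a regulatory group from [assign_groups()]: by default tertiles
#' of the signed statistic (Down/None/Up) for a single factor, and the RI
#' sign (Competitive/None/Cooperative) for two factors.
#'
#' @inheritParams merge_ranges
#' @param expression data.frame from [read_expression()] with column
#'   \code{stat} (single mode) or \code{stat_x}, \code{stat_y}
#'   (two-factor mode).
#' @param mode \code{"single"} or \code{"two_factor"}.
#' @param grouping Grouping method passed to [assign_groups()]; default
#'   \code{"quantile"} for single mode, \code{"sign"} for two-factor mode.
#' @param quantiles Lower/upper probabilities for quantile grouping.
#' @return data.frame with one row per ranked region: \code{region_id},
#'   \code{chrom}, \code{start}, \code{end} (BED 0-based half-open),
#'   \code{strand}, \code{n_peaks}, \code{potential}, \code{binding_rank},
#'   the statistic column(s) (\code{stat}, or \code{stat_x}, \code{stat_y},
#'   \code{ri}), \code{stat_rank}, \code{rank_product} and \code{group},
#'   sorted by rank product ascending.
#' @export
direct_targets <- function(peaks, regions, expression, window = 1e5,
                           ref_point = c("center", "start"),
                           mode = c("single", "two_factor"),
                           grouping = NULL, quantiles = c(1 / 3, 2 / 3)) {
  ref_point <- match.arg(ref_point)
  mode <- match.arg(mode)
  ap <- associated_peaks(peaks, regions, window, ref_point)
  message(sprintf("%d peak-region pairs from %d peaks and %d regions",
                  nrow(ap), length(peaks), length(regions)))
  scores <- score_regions(ap$peak_score, ap$region_id)
  need <- if (mode == "single") "stat" else c("stat_x", "stat_y")
  if (!all(need %in% names(expression))) {
    stop_contract("expression table must carry column(s): %s",
                  paste(need, collapse = ", "))
  }
  joined <- .join_expression(scores, expression)
  if (nrow(joined) == 0) {
    stop_empty("no region has both peaks and an expression record")
  }
  if (mode == "single") {
    ranking_stat <- joined$stat
    grouping_value <- joined$stat
    if (is.null(grouping)) grouping <- "quantile"
    labels <- c("Down", "None", "Up")
  } else {
    joined$ri <- regulatory_interaction(joined$stat_x, joined$stat_y)
    ranking_stat <- joined$ri
    grouping_value <- joined$ri
    if (is.null(grouping)) grouping <- "sign"
    labels <- c("Competitive", "None", "Cooperative")
  }
  rp <- rank_product(joined$potential, ranking_stat, joined$region_id)
  ord <- match(rp$region_id, joined$region_id)
  joined <- joined[ord, , drop = FALSE]
  grp <- assign_groups(grouping_value[ord], method = grouping,
                       quantiles = quantiles, labels = labels)
  ridx <- match(joined$region_id, .interval_ids(regions))
  out <- data.frame(
    region_id = joined$region_id,
    chrom = as.character(GenomeInfoDb::seqnames(regions))[ridx],
    start = .bed_start(regions)[ridx],
    end = .bed_end(regions)[ridx],
    strand = as.character(GenomicRanges::strand(regions))[ridx],
    n_peaks = joined$n_peaks,
    potential = joined$potential,
    binding_rank = rp$binding_rank,
    stringsAsFactors = FALSE
  )
  if (mode == "single") {
    out$stat <- joined$stat
  } else {
    out$stat_x <- joined$stat_x
    out$stat_y <- joined$stat_y
    out$ri <- joined$ri
  }
  out$stat_rank <- rp$stat_rank
  out$rank_product <- rp$rank_product
  out$group <- as.character(grp)
  message(sprintf("ranked %d regions", nrow(out)))
  out
}

#' Rank the shared targets of two factors
#'
#' Two-factor pipeline over two peak sets.  A region is a shared target
#' when it has at least one associated peak from each factor
#' (\code{shared = "region"}, the default); with \code{shared = "overlap"}
#' only peaks whose intervals overlap a peak of the other factor are used.
#' The regulatory potential of a shared region sums the decay scores of
#' the retained peaks of both factors, and targets are ranked by the
#' regulatory interaction as in [direct_targets()] two-factor mode.
#'
#' @inheritParams direct_targets
#' @param peaks_x,peaks_y \code{GRanges} of the two factors' peaks.
#' @param shared \code{"region"} (co-occupancy of the same region) or
#'   \code{"overlap"} (peak intervals must overlap).
#' @return As [direct_targets()] (two-factor mode).
#' @export
combined_targets <- function(peaks_x, peaks_y, regions, expression,
                             window = 1e5, ref_point = c("center", "start"),
                             shared = c("region", "overlap"),
                             grouping = "sign", quantiles = c(1 / 3, 2 / 3)) {
  ref_point <- match.arg(ref_point)
  shared <- match.arg(shared)
  if (shared == "overlap") {
    nx <- length(peaks_x)
    ny <- length(peaks_y)
    hits <- GenomicRanges::findOverlaps(peaks_x, peaks_y, ignore.strand = TRUE)
    peaks_x <- peaks_x[unique(S4Vectors::queryHits(hits))]
    peaks_y <- peaks_y[unique(S4Vectors::subjectHits(hits))]
    message(sprintf("overlap mode: retained %d/%d factor-x and %d/%d factor-y peaks",
                    length(peaks_x), nx, length(peaks_y), ny))
  }
  ap_x <- associated_peaks(peaks_x, regions, window, ref_point)
  ap_y <- associated_peaks(peaks_y, regions, window, ref_point)
  shared_ids <- intersect(unique(ap_x$region_id), unique(ap_y$region_id))
  message(sprintf("%d shared region(s) with peaks from both factors",
                  length(shared_ids)))
  if (length(shared_ids) == 0) {
    stop_empty("no region has peaks from both factors")
  }
  ap <- rbind(ap_x[ap_x$region_id %in% shared_ids, , drop = FALSE],
              ap_y[ap_y$region_id %in% shared_ids, , drop = FALSE])
  scores <- score_regions(ap$peak_score, ap$region_id)
  if (!all(c("stat_x", "stat_y") %in% names(expression))) {
    stop_contract("expression table must carry columns stat_x, stat_y")
  }
  joined <- .join_expression(scores, expression)
  if (nrow(joined) == 0) {
    stop_empty("no shared region has an expression record")
  }
  joined$ri <- regulatory_interaction(joined$stat_x, joined$stat_y)
  rp <- rank_product(joined$potential, joined$ri, joined$region_id)
  ord <- match(rp$region_id, joined$region_id)
  joined <- joined[ord, , drop = FALSE]
  grp <- assign_groups(joined$ri, method = grouping, quantiles = quantiles,
                       labels = c("Competitive", "None", "Cooperative"))
  ridx <- match(joined$region_id, .interval_ids(regions))
  data.frame(
    region_id = joined$region_id,
    chrom = as.character(GenomeInfoDb::seqnames(regions))[ridx],
    start = .bed_start(regions)[ridx],
    end = .bed_end(regions)[ridx],
    strand = as.character(GenomicRanges::strand(regions))[ridx],
    n_peaks = joined$n_peaks,
    potential = joined$potential,
    binding_rank = rp$binding_rank,
    stat_x = joined$stat_x,
    stat_y = joined$stat_y,
    ri = joined$ri,
    stat_rank = rp$stat_rank,
    rank_product = rp$rank_product,
    group = as.character(grp),
    stringsAsFactors = FALSE
  )
}
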