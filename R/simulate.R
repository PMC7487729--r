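# Synthetic peaks and two-factor expression statistics with planted
# cooperative or competitive structure, for validating the pipeline.

#' Simulation configuration
#'
#' Study conditions for the planted-signal simulation: transcripts on a
#' single abstract chromosome (default length = 195,471,971 bp, the size
#' of mouse chromosome 1), random peaks near their TSSs, i.i.d. standard
#' normal perturbation statistics for two factors, and a planted bias on
#' \code{n_biased} transcripts where the second factor's statistic is
#' replaced by \code{bias_factor} times the first's (+3 plants a
#' cooperative signal, -3 a competitive one).
#'
#' @param n_regions Number of transcripts (default 5000).
#' @param chrom_length Chromosome length in bp.
#' @param chrom Chromosome name.
#' @param n_peaks Number of peaks (default 10000).
#' @param peak_width Peak width in bp (default 200; only the center enters
#'   the score).
#' @param window Association window in bp (default 100 kb).
#' @param n_biased Number of biased transcripts (default 1000).
#' @param bias_factor Signed multiplier for the planted bias (default +3).
#' @param seed Integer seed; every stage derives its substream from it.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_regions = 5000, chrom_length = 195471971,
                       chrom = "chr1", n_peaks = 10000, peak_width = 200,
                       window = 1e5, n_biased = 1000, bias_factor = 3,
                       seed = 42) {
  if (n_biased > n_regions) {
    stop_contract("n_biased (%d) exceeds n_regions (%d)", n_biased, n_regions)
  }
  if (bias_factor == 0) {
    stop_contract("bias_factor must be non-zero")
  }
  if (chrom_length <= window) {
    stop_contract("chrom_length must exceed window")
  }
  structure(list(n_regions = n_regions, chrom_length = chrom_length,
                 chrom = chrom, n_peaks = n_peaks, peak_width = peak_width,
                 window = window, n_biased = n_biased,
                 bias_factor = bias_factor, seed = seed),
            class = "sim_config")
}

#' Simulate transcript regions
#'
#' Draws \code{n_regions} distinct TSS positions uniformly without
#' replacement from the chromosome interior and expands each into a
#' window-wide promoter centered on the TSS, so the region's center
#' reference point equals the TSS exactly.  Strands are random; ids are
#' \code{g1..gN}.  Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return \code{GRanges} with metadata columns \code{id} and \code{tss}
#'   (0-based TSS coordinate).
#' @export
simulate_regions <- function(config) {
  half <- floor(config$window / 2)
  lo <- half
  hi <- config$chrom_length - half - 1
  if (hi - lo + 1 < config$n_regions) {
    stop_contract("chromosome too short for %d distinct TSSs",
                  config$n_regions)
  }
  set.seed(config$seed)
  tss <- sort(sample.int(hi - lo + 1, config$n_regions, replace = FALSE)) +
    lo - 1L
  strand <- sample(c("+", "-"), config$n_regions, replace = TRUE)
  gr <- .granges_from_bed(rep(config$chrom, config$n_regions),
                          start0 = tss - half, end0 = tss + half,
                          id = paste0("g", seq_len(config$n_regions)),
                          strand = strand)
  S4Vectors::mcols(gr)$tss <- tss
  gr
}

#' Simulate binding peaks near TSSs
#'
#' Generates \code{n_peaks} fixed-width peaks.  Each peak picks a
#' transcript uniformly at random and centers itself at the transcript's
#' TSS plus an offset drawn uniformly from \code{[-window, window]}, so by
#' construction every peak center lies within the association window of at
#' least one TSS.  Ids are \code{p1..pM}.  Deterministic given the config
#' seed.
#'
#' @param config A [sim_config()].
#' @param regions Regions from [simulate_regions()].
#' @return \code{GRanges} with metadata columns \code{id} and
#'   \code{target_region} (the id of the transcript the offset was drawn
#'   around).
#' @export
simulate_peaks <- function(config, regions) {
  if (length(regions) == 0) {
    stop_contract("regions must be non-empty")
  }
  set.seed(config$seed + 1L)
  tss <- S4Vectors::mcols(regions)$tss
  pick <- sample.int(length(regions), config$n_peaks, replace = TRUE)
  offset <- sample.int(2L * config$window + 1L, config$n_peaks,
                       replace = TRUE) - config$window - 1L
  center <- tss[pick] + offset
  half <- floor(config$peak_width / 2)
  start0 <- pmax(center - half, 0)
  gr <- .granges_from_bed(rep(config$chrom, config$n_peaks),
                          start0 = start0,
                          end0 = start0 + config$peak_width,
                          id = paste0("p", seq_len(config$n_peaks)))
  S4Vectors::mcols(gr)$target_region <- .interval_ids(regions)[pick]
  gr
}

#' Simulate two-factor expression statistics with a planted bias
#'
#' Draws i.i.d. standard normal statistics \code{stat_x}, \code{stat_y}
#' for every transcript, then samples \code{n_biased} transcripts among
#' those with at least one associated peak (under the configured window,
#' center reference) and replaces their \code{stat_y} with
#' \code{bias_factor * stat_x}.  With a positive bias factor every biased
#' transcript has RI = bias_factor * stat_x^2 > 0 (cooperative); with a
#' negative one, RI < 0 (competitive).  Deterministic given the config
#' seed, and the same transcripts are biased for +b and -b.
#'
#' @param config A [sim_config()].
#' @param regions Regions from [simulate_regions()].
#' @param peaks Peaks from [simulate_peaks()].
#' @return data.frame with columns \code{region_id}, \code{stat_x},
#'   \code{stat_y}; attribute \code{"biased"} holds the biased region ids.
#' @export
simulate_stats <- function(config, regions, peaks) {
  set.seed(config$seed + 2L)
  n <- length(regions)
  ids <- .interval_ids(regions)
  stat_x <- stats::rnorm(n)
  stat_y <- stats::rnorm(n)
  pairs <- merge_ranges(peaks, regions, window = config$window,
                        ref_point = "center")
  with_peaks <- which(ids %in% unique(pairs$region_id))
  if (length(with_peaks) < config$n_biased) {
    stop_contract("only %d region(s) have nearby peaks; need %d to bias",
                  length(with_peaks), config$n_biased)
  }
  biased <- sort(sample(with_peaks, config$n_biased, replace = FALSE))
  stat_y[biased] <- config$bias_factor * stat_x[biased]
  out <- data.frame(region_id = ids, stat_x = stat_x, stat_y = stat_y,
                    stringsAsFactors = FALSE)
  attr(out, "biased") <- ids[biased]
  out
}

#' Simulate a complete planted-signal dataset
#'
#' Runs [simulate_regions()], [simulate_peaks()] and [simulate_stats()] in
#' that fixed order.
#'
#' @param config A [sim_config()].
#' @return List with elements \code{regions}, \code{peaks}, \code{stats},
#'   \code{config}.
#' @export
simulate_dataset <- function(config = sim_config()) {
  regions <- simulate_regions(config)
  peaks <- simulate_peaks(config, regions)
  stats <- simulate_stats(config, regions, peaks)
  list(regions = regions, peaks = peaks, stats = stats, config = config)
}
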