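# Internal helpers: classed error conditions, coordinate arithmetic,
# locale-independent ordering.

# Error classes map to CLI exit codes: parse -> 2, contract -> 3, empty -> 4.
.stop_classed <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "tftarget_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_parse    <- function(fmt, ...) .stop_classed("tftarget_parse_error", fmt, ...)
stop_contract <- function(fmt, ...) .stop_classed("tftarget_contract_error", fmt, ...)
stop_empty    <- function(fmt, ...) .stop_classed("tftarget_empty_error", fmt, ...)

# BED 0-based half-open is the canonical coordinate system; GRanges objects
# (1-based closed) are converted at the boundary.  For a GRanges row the
# 0-based interval is [start - 1, end).
.bed_start <- function(gr) GenomicRanges::start(gr) - 1L
.bed_end <- function(gr) GenomicRanges::end(gr)

# Center in 0-based coordinates: floor of the interval midpoint.
.bed_center <- function(gr) {
  (.bed_start(gr) + .bed_end(gr)) %/% 2L
}

# Reference point of a region in 0-based coordinates.
# center: floor midpoint; start: strand-aware 5' end (start for +/*,
# end - 1 for -).
.region_reference <- function(gr, ref_point = c("center", "start")) {
  ref_point <- match.arg(ref_point)
  if (ref_point == "center") {
    return(.bed_center(gr))
  }
  s <- as.character(GenomicRanges::strand(gr))
  ifelse(s == "-", .bed_end(gr) - 1L, .bed_start(gr))
}

.interval_ids <- function(gr) {
  ids <- S4Vectors::mcols(gr)$id
  if (is.null(ids)) {
    stop_contract("interval collection carries no 'id' metadata column")
  }
  as.character(ids)
}

# radix = C-locale ordering, stable across platforms
.order_radix <- function(...) order(..., method = "radix")

.assert_unique_region_ids <- function(ids) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop_contract(
      "region ids must be unique; duplicated: %s",
      paste(utils::head(dup, 5), collapse = ", ")
    )
  }
  invisible(ids)
}

# Construct a GRanges from 0-based half-open coordinates.
.granges_from_bed <- function(chrom, start0, end0, id,
                              strand = NULL, seqlengths = NULL) {
  if (is.null(strand)) strand <- rep("*", length(chrom))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand,
    seqlengths = seqlengths
  )
  S4Vectors::mcols(gr)$id <- as.character(id)
  gr
}
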