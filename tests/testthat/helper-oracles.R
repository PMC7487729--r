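# Fixture builders and independent brute-force oracles.  The oracles are
# deliberately naive (explicit loops, counting definitions) and share no
# code with the implementation paths they check.

# GRanges from BED 0-based half-open coordinates
gr_bed <- function(chrom, start0, end0, id, strand = NULL) {
  if (is.null(strand)) strand <- rep("*", length(chrom))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0),
                               strand = strand)
  S4Vectors::mcols(gr)$id <- id
  gr
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                             max_width = 5000, prefix = "iv") {
  chrom <- sample(chroms, n, replace = TRUE)
  start0 <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  gr_bed(chrom, start0, start0 + width, paste0(prefix, seq_len(n)),
         strand = sample(c("+", "-", "*"), n, replace = TRUE))
}

# 0-based centers/references computed independently of the package helpers
oracle_center <- function(chrom_start0, chrom_end0) {
  floor((chrom_start0 + chrom_end0) / 2)
}

oracle_reference <- function(gr, ref_point) {
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  if (ref_point == "center") {
    return(oracle_center(s0, e0))
  }
  ifelse(as.character(GenomicRanges::strand(gr)) == "-", e0 - 1L, s0)
}

# O(n*m) all-pairs association oracle: returns sorted (peak_id, region_id)
oracle_pairs <- function(peaks, regions, window, ref_point = "center") {
  pc <- oracle_center(GenomicRanges::start(peaks) - 1L,
                      GenomicRanges::end(peaks))
  rr <- oracle_reference(regions, ref_point)
  pch <- as.character(GenomicRanges::seqnames(peaks))
  rch <- as.character(GenomicRanges::seqnames(regions))
  pid <- S4Vectors::mcols(peaks)$id
  rid <- S4Vectors::mcols(regions)$id
  rows <- list()
  for (i in seq_along(peaks)) {
    for (j in seq_along(regions)) {
      if (pch[i] == rch[j] && abs(pc[i] - rr[j]) <= window) {
        rows[[length(rows) + 1]] <- c(pid[i], rid[j])
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(peak_id = character(), region_id = character()))
  }
  df <- data.frame(peak_id = vapply(rows, `[`, "", 1),
                   region_id = vapply(rows, `[`, "", 2))
  df[order(df$region_id, df$peak_id, method = "radix"), , drop = FALSE] |>
    `rownames<-`(NULL)
}

# Grouped-sum oracle via an environment accumulator
oracle_region_sums <- function(scores, ids) {
  acc <- new.env()
  cnt <- new.env()
  for (i in seq_along(scores)) {
    k <- ids[i]
    assign(k, mget(k, acc, ifnotfound = 0)[[1]] + scores[i], acc)
    assign(k, mget(k, cnt, ifnotfound = 0L)[[1]] + 1L, cnt)
  }
  ids_u <- sort(ls(acc), method = "radix")
  data.frame(region_id = ids_u,
             potential = vapply(ids_u, function(k) get(k, acc), 0),
             n_peaks = vapply(ids_u, function(k) get(k, cnt), 0L),
             row.names = NULL)
}

# Naive re-ranking oracle: sort-based ranks with explicit midrank handling
oracle_rank_desc <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(x > x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

oracle_rank_product <- function(potentials, stats) {
  n <- length(potentials)
  oracle_rank_desc(potentials) * oracle_rank_desc(abs(stats)) / n^2
}

# Counting ECDF oracle
oracle_ecdf <- function(sample, x) {
  vapply(x, function(p) sum(sample <= p) / length(sample), 0)
}

# Brute-force two-sample KS statistics evaluated over the pooled support
oracle_ks_D <- function(a, b, alternative = "two_sided") {
  probes <- sort(unique(c(a, b)))
  d <- oracle_ecdf(a, probes) - oracle_ecdf(b, probes)
  # sup over all reals: attained at a probe point or at the flat 0 tail
  switch(alternative,
         two_sided = max(abs(d)),
         greater = max(c(0, d)),
         less = max(c(0, -d)))
}

write_tmp_lines <- function(lines, ext = ".bed") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
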