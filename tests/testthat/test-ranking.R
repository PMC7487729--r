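test_that("rank_product reproduces the two-region worked case", {
  rp <- rank_product(c(0.7, 0.1), c(-2, 1), c("gA", "gB"))
  expect_equal(rp$region_id, c("gA", "gB"))
  expect_equal(rp$rank_product, c(0.25, 1.0))
  expect_equal(rp$binding_rank, c(1, 2))
  expect_equal(rp$stat_rank, c(1, 2))
})

test_that("ties receive midranks", {
  rp <- rank_product(c(1, 1, 1), c(3, -3, 0.5), c("a", "b", "c"))
  expect_equal(sort(rp$binding_rank), c(2, 2, 2))
  # |3| and |-3| tie for the top expression rank
  expect_equal(rp$stat_rank[match(c("a", "b"), rp$region_id)], c(1.5, 1.5))
})

test_that("rank products match a naive sort-based recomputation and bounds", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    pot <- round(runif(n), sample(1:3, 1))  # rounding induces ties
    stat <- round(rnorm(n), 1)
    ids <- paste0("g", seq_len(n))
    rp <- rank_product(pot, stat, ids)
    want <- oracle_rank_product(pot, stat)[match(rp$region_id, ids)]
    expect_equal(rp$rank_product, want)
    expect_true(all(rp$rank_product >= 1 / n^2 - 1e-15))
    expect_true(all(rp$rank_product <= 1 + 1e-15))
    # sorted ascending, most important target first
    expect_true(!is.unsorted(rp$rank_product))
  }
})

test_that("the minimal rank product marks a doubly top-ranked region", {
  rp <- rank_product(c(5, 1, 2), c(-9, 0.1, 3), c("top", "mid", "low"))
  expect_equal(rp$region_id[1], "top")
  expect_equal(rp$rank_product[1], 1 / 9)
})

test_that("rank_product rejects degenerate inputs", {
  expect_error(rank_product(numeric(), numeric(), character()),
               class = "tftarget_empty_error")
  expect_error(rank_product(1:2, c(1, NaN), c("a", "b")), "b",
               class = "tftarget_contract_error")
  expect_error(rank_product(1:2, 1:2, c("a", "a")),
               class = "tftarget_contract_error")
  expect_error(rank_product(1:3, 1:2, c("a", "b")),
               class = "tftarget_contract_error")
})

test_that("rank products are invariant to input row order", {
  set.seed(13)
  n <- 40
  pot <- runif(n)
  stat <- rnorm(n)
  ids <- paste0("g", 1:n)
  perm <- sample(n)
  a <- rank_product(pot, stat, ids)
  b <- rank_product(pot[perm], stat[perm], ids[perm])
  expect_equal(a, b)
})

test_that("stat ranks are scale invariant; negation flips RI signs only", {
  set.seed(17)
  n <- 30
  pot <- runif(n)
  x <- rnorm(n)
  y <- rnorm(n)
  ids <- paste0("g", 1:n)
  base <- rank_product(pot, regulatory_interaction(x, y), ids)
  scaled <- rank_product(pot, regulatory_interaction(x * 2.5, y), ids)
  expect_equal(base$stat_rank, scaled$stat_rank)
  expect_equal(base$rank_product, scaled$rank_product)
  flipped <- rank_product(pot, regulatory_interaction(x, -3 * y), ids)
  expect_equal(base$rank_product, flipped$rank_product)
  expect_equal(sign(flipped$stat), -sign(base$stat))
})

test_that("regulatory_interaction multiplies signed statistics elementwise", {
  expect_equal(regulatory_interaction(2, 3), 6)       # cooperative sign
  expect_equal(regulatory_interaction(2, -3), -6)     # competitive sign
  expect_equal(regulatory_interaction(0, 5), 0)
  ri <- regulatory_interaction(c(1, -2), c(4, 0.5))
  expect_equal(ri, c(4, -1))
  expect_error(regulatory_interaction(1:3, 1:2),
               class = "tftarget_contract_error")
  expect_error(regulatory_interaction(c(1, Inf), c(1, 1)),
               class = "tftarget_contract_error")
})

test_that("direct_targets composes the worked single-factor example", {
  # two regions whose peak layouts produce potentials ~{0.7, 0.1}
  regions <- gr_bed("chr1", c(0, 50000), c(2000, 52000), c("g1", "g2"))
  # g1 center 1000: two peaks at delta 0 and 0.5 (w = 1000)
  # g2 center 51000: one remote peak at delta 1
  peaks <- gr_bed("chr1",
                  c(950, 1450, 51950),
                  c(1050, 1550, 52050),
                  c("p1", "p2", "p3"))
  expr <- data.frame(region_id = c("g1", "g2"), stat = c(-2, 1))
  dt <- suppressMessages(
    direct_targets(peaks, regions, expr, window = 1000, grouping = "sign")
  )
  expect_equal(dt$region_id, c("g1", "g2"))
  expect_equal(dt$potential, c(exp(-0.5) + exp(-2.5), exp(-4.5)),
               tolerance = 1e-12)
  expect_equal(dt$rank_product, c(0.25, 1.0))
  expect_equal(dt$group, c("Down", "Up"))
  expect_equal(dt$n_peaks, c(2L, 1L))
  expect_equal(dt$start, c(0, 50000))  # BED coordinates round-trip
})

test_that("two-factor mode with identical stats ranks like |stat| squared", {
  set.seed(19)
  regions <- random_intervals(30, chroms = "chr1", prefix = "g")
  peaks <- random_intervals(120, chroms = "chr1", prefix = "p")
  stat <- rnorm(30)
  expr <- data.frame(region_id = paste0("g", 1:30),
                     stat_x = stat, stat_y = stat)
  dt <- suppressMessages(
    direct_targets(peaks, regions, expr, mode = "two_factor")
  )
  expect_true(all(dt$ri >= 0))
  expect_true(all(dt$group %in% c("Cooperative", "None")))
  # rank of stat^2 equals rank of |stat| on the joined subset
  sub <- match(dt$region_id, expr$region_id)
  expect_equal(rank(-dt$ri), rank(-abs(stat[sub])))
})

test_that("direct_targets equals the step-by-step composed oracle", {
  set.seed(29)
  regions <- random_intervals(100, chroms = c("chr1", "chr2"), prefix = "g")
  peaks <- random_intervals(300, chroms = c("chr1", "chr2"), prefix = "p")
  expr <- data.frame(region_id = paste0("g", 1:100),
                     stat_x = rnorm(100), stat_y = rnorm(100))
  w <- 1e5
  dt <- suppressMessages(
    direct_targets(peaks, regions, expr, window = w, mode = "two_factor")
  )
  # oracle composition: brute-force pairs -> per-pair decay scores ->
  # grouped sums -> RI -> naive ranks
  pairs <- oracle_pairs(peaks, regions, w)
  pc <- oracle_center(GenomicRanges::start(peaks) - 1L,
                      GenomicRanges::end(peaks))
  rr <- oracle_reference(regions, "center")
  d <- pc[match(pairs$peak_id, S4Vectors::mcols(peaks)$id)] -
    rr[match(pairs$region_id, S4Vectors::mcols(regions)$id)]
  sums <- oracle_region_sums(exp(-(0.5 + 4 * abs(d) / w)), pairs$region_id)
  m <- match(sums$region_id, expr$region_id)
  ri <- expr$stat_x[m] * expr$stat_y[m]
  want_rp <- oracle_rank_product(sums$potential, ri)
  got <- dt[match(sums$region_id, dt$region_id), ]
  expect_equal(got$potential, sums$potential, tolerance = 1e-12)
  expect_equal(got$rank_product, want_rp, tolerance = 1e-12)
  expect_equal(got$ri, ri)
})

test_that("regions with peaks but no expression are dropped with a count", {
  regions <- gr_bed("chr1", c(0, 3000), c(2000, 5000), c("g1", "g2"))
  peaks <- gr_bed("chr1", c(900, 3900), c(1100, 4100), c("p1", "p2"))
  expr <- data.frame(region_id = "g1", stat = 1.5)
  expect_message(
    dt <- direct_targets(peaks, regions, expr, window = 1e4,
                         grouping = "sign"),
    "dropped 1 region"
  )
  expect_equal(dt$region_id, "g1")
  none <- data.frame(region_id = "gX", stat = 1)
  expect_error(
    suppressMessages(direct_targets(peaks, regions, none, window = 1e4)),
    class = "tftarget_empty_error"
  )
})

test_that("combined_targets keeps only regions bound by both factors", {
  regions <- gr_bed("chr1", c(0, 30000, 60000), c(2000, 32000, 62000),
                    c("g1", "g2", "g3"))
  # factor x binds g1 and g2; factor y binds g2 and g3
  px <- gr_bed("chr1", c(900, 30900), c(1100, 31100), c("x1", "x2"))
  py <- gr_bed("chr1", c(30400, 60900), c(30600, 61100), c("y1", "y2"))
  expr <- data.frame(region_id = c("g1", "g2", "g3"),
                     stat_x = c(1, 2, 3), stat_y = c(1, -1, 2))
  dt <- suppressMessages(
    combined_targets(px, py, regions, expr, window = 5000)
  )
  expect_equal(dt$region_id, "g2")
  # potential sums contributions from both factors' peaks
  d_x <- abs((30900 + 31100) %/% 2 - (30000 + 32000) %/% 2)
  d_y <- abs((30400 + 30600) %/% 2 - (30000 + 32000) %/% 2)
  expect_equal(dt$potential,
               exp(-(0.5 + 4 * d_x / 5000)) + exp(-(0.5 + 4 * d_y / 5000)),
               tolerance = 1e-12)
  expect_equal(dt$group, "Competitive")
  expect_error(
    suppressMessages(combined_targets(px, py, regions, expr, window = 100)),
    class = "tftarget_empty_error"
  )
})
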