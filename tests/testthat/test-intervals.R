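test_that("overlap, reciprocal overlap and containment handle the canonical cases", {
  a <- genomic_intervals("1", 100, 200)
  b <- genomic_intervals("1", 150, 250)
  expect_equal(overlap_bp(a, b), 50)
  expect_equal(overlap_bp(a, genomic_intervals("2", 100, 200)), 0)
  expect_equal(reciprocal_overlap(a, a), 1.0)
  expect_equal(reciprocal_overlap(a, b), 0.5)

  outer <- genomic_intervals("1", 100, 500)
  expect_true(contains_fully(outer, genomic_intervals("1", 200, 300)))
  expect_false(contains_fully(outer, genomic_intervals("1", 400, 600)))
  # partial encompassment: positive overlap without containment
  partial <- genomic_intervals("1", 400, 600)
  expect_gt(overlap_bp(outer, partial), 0)
  expect_false(contains_fully(outer, partial))

  expect_error(genomic_intervals("1", 200, 200), "invariants")
  expect_error(genomic_intervals("1", -5, 100), "invariants")
})

test_that("interval arithmetic matches a base-enumeration oracle and is symmetric", {
  set.seed(42)
  for (i in 1:200) {
    a <- random_interval(); b <- random_interval()
    ov <- overlap_bp(a, b)
    expect_identical(as.numeric(ov), as.numeric(oracle_overlap(a, b)))
    expect_equal(ov, overlap_bp(b, a))
    ro <- reciprocal_overlap(a, b)
    expect_equal(ro, oracle_ro(a, b))
    expect_equal(ro, reciprocal_overlap(b, a))
    # bound: reciprocal overlap never exceeds overlap over the shorter length
    expect_lte(ro, ov / min(a$end - a$start, b$end - b$start) + 1e-12)
  }
})

test_that("interval overlap agrees with an independent interval library", {
  set.seed(7)
  a <- do.call(rbind, lapply(1:50, function(i) random_interval()))
  b <- do.call(rbind, lapply(1:50, function(i) random_interval()))
  ir_ov <- IRanges::width(IRanges::pintersect(
    IRanges::IRanges(a$start + 1, a$end), IRanges::IRanges(b$start + 1, b$end),
    resolve.empty = "max.start"))
  expect_equal(overlap_bp(a, b), pmax(0, ir_ov))
})

test_that("chromosome labels are normalized at construction", {
  x <- genomic_intervals(c("chr8", "8", "chrX"), c(0, 0, 0), c(10, 10, 10))
  expect_equal(x$chrom, c("8", "8", "X"))
})

test_that("adjacent same-type calls merge; different types do not", {
  calls <- cnv_calls(c("s1", "s1"), c("1", "1"), c(1000, 2100), c(2000, 3000),
                     c(3, 3), c("duplication", "duplication"))
  m <- merge_adjacent(calls, max_gap = 500)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 1000)
  expect_equal(m$end, 3000)

  mixed <- cnv_calls(c("s1", "s1"), c("1", "1"), c(1000, 2100), c(2000, 3000),
                     c(1, 3), c("deletion", "duplication"))
  expect_equal(nrow(merge_adjacent(mixed, max_gap = 500)), 2L)
  expect_error(merge_adjacent(calls, max_gap = -1), "non-negative")
})

test_that("merge_adjacent is idempotent and matches the pairwise-closure oracle", {
  set.seed(11)
  for (rep in 1:25) {
    calls <- random_calls(sample(3:14, 1L), max_pos = 3e5)
    gap <- sample(c(0, 1e4, 5e4), 1L)
    m1 <- merge_adjacent(calls, max_gap = gap)
    m2 <- merge_adjacent(m1, max_gap = gap)
    expect_equal(m1[, c("sample_id", "chrom", "start", "end", "cnv_type")],
                 m2[, c("sample_id", "chrom", "start", "end", "cnv_type")])
    orc <- oracle_merge(calls, max_gap = gap)
    got <- m1[, c("sample_id", "chrom", "start", "end", "cnv_type")]
    rownames(orc) <- rownames(got) <- NULL
    expect_equal(got, orc)
  }
})

toy_band_map <- function() {
  cytoband_map(chrom = c("8", "8", "3", "3", "3"),
               start = c(0, 5000, 0, 4000, 9000),
               end = c(5000, 9000, 4000, 9000, 15000),
               band = c("p23.1", "p22", "q11", "q13.33", "q21.2"))
}

test_that("cytoband labels render single bands, spans and boundaries", {
  bands <- toy_band_map()
  expect_equal(cytoband_label(genomic_intervals("8", 1000, 3000), bands),
               "8p23.1")
  expect_equal(cytoband_label(genomic_intervals("3", 5000, 12000), bands),
               "3q13.33 - 3q21.2")
  # start exactly at a band boundary belongs to the following band
  expect_equal(cytoband_label(genomic_intervals("8", 5000, 6000), bands),
               "8p22")
  expect_error(cytoband_label(genomic_intervals("8", 8000, 12000), bands),
               "outside")
  expect_error(cytoband_label(genomic_intervals("7", 0, 10), bands),
               "outside")
  # agreement with a linear-scan oracle at random positions
  set.seed(3)
  for (i in 1:50) {
    pos <- sample.int(8999, 1L) - 1L
    lab <- cytoband_label(genomic_intervals("8", pos, pos + 1), bands)
    expect_equal(lab, paste0("8", oracle_band("8", pos, bands)))
  }
})

test_that("overlapping bands on one chromosome are rejected", {
  expect_error(cytoband_map(c("1", "1"), c(0, 500), c(1000, 1500),
                            c("p1", "p2")), "overlapping")
})
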