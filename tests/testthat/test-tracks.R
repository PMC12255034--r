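test_that("BED round-trips and rejects malformed coordinates", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("track name=test", "chr1\t10\t20\tpk1\t5\t+",
               "chr2\t0\t100\tpk2\t0\t-"), bed)
  pk <- read_bed(bed)
  expect_equal(pk$chrom, c("chr1", "chr2"))
  expect_equal(pk$start, c(10L, 0L))
  expect_equal(pk$end, c(20L, 100L))
  expect_equal(pk$strand, c("+", "-"))

  out <- tempfile(fileext = ".bed")
  write_bed(pk, out)
  expect_equal(read_bed(out), pk)

  empty <- tempfile(fileext = ".bed")
  writeLines(character(), empty)
  expect_equal(nrow(read_bed(empty)), 0L)

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t5\t8", "chr1\t20\t10"), bad)
  expect_error(read_bed(bad), "line 2")
})

test_that("bedGraph reading sorts runs and rejects overlaps/negatives", {
  bg <- tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t50\t60\t1.5", "chr1\t0\t10\t2.5"), bg)
  tr <- read_bedgraph(bg)
  expect_equal(tr$start, c(0L, 50L))
  expect_equal(tr$value, c(2.5, 1.5))

  out <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, out)
  expect_equal(as.data.frame(read_bedgraph(out)), as.data.frame(tr))

  ovl <- tempfile()
  writeLines(c("chr1\t0\t10\t1", "chr1\t5\t15\t1"), ovl)
  expect_error(read_bedgraph(ovl), "overlap")

  neg <- tempfile()
  writeLines("chr1\t0\t10\t-1", neg)
  expect_error(read_bedgraph(neg), "negative")
})

test_that("BPM normalization rescales values and conserves scaled mass", {
  tr <- signal_track("chr1", c(0L, 100L), c(50L, 130L), c(3, 6))
  expect_equal(bpm_normalize(tr, 1e6)$value, c(3, 6))
  expect_equal(bpm_normalize(tr, 2e6)$value, c(1.5, 3))
  expect_error(bpm_normalize(tr, 0), "positive")
  expect_equal(nrow(bpm_normalize(signal_track(), 1e6)), 0L)

  set.seed(11)
  for (i in 1:5) {
    rt <- random_track(8)
    total <- runif(1, 1e5, 1e8)
    mass <- function(t) sum((t$end - t$start) * t$value)
    expect_equal(mass(bpm_normalize(rt, total)),
                 mass(rt) * 1e6 / total)
  }
})

test_that("background subtraction is a per-base floored difference", {
  s <- signal_track("chr1", 0L, 100L, 5)
  b <- signal_track("chr1", 0L, 100L, 2)
  expect_equal(subtract_background(s, b)$value, 3)
  # background exceeding signal floors at zero
  expect_equal(nrow(subtract_background(b, s)), 0L)
  # empty background leaves the signal unchanged
  expect_equal(subtract_background(s, signal_track()), s)

  set.seed(21)
  for (i in 1:8) {
    s <- random_track(6)
    b <- random_track(6)
    res <- subtract_background(s, b)
    for (pos in sample.int(480, 25)) {
      sv <- oracle_mean_signal(s, "chr1", pos, pos + 1L)
      bv <- oracle_mean_signal(b, "chr1", pos, pos + 1L)
      rv <- oracle_mean_signal(res, "chr1", pos, pos + 1L)
      expect_equal(rv, max(0, sv - bv))
    }
  }
})

test_that("mean signal is base-weighted with uncovered bases as zero", {
  tr <- signal_track("chr1", 10L, 50L, 4)
  expect_equal(mean_signal(tr, "chr1", 10, 50), 4)
  # half the region covered at 4, half uncovered
  expect_equal(mean_signal(tr, "chr1", 30, 70), 2)
  expect_equal(mean_signal(signal_track(), "chr1", 0, 10), 0)

  set.seed(31)
  for (i in 1:8) {
    rt <- random_track(7)
    st <- sample.int(400, 1)
    en <- st + sample.int(80, 1)
    expect_equal(mean_signal(rt, "chr1", st, en),
                 oracle_mean_signal(rt, "chr1", st, en))
  }
  # constant coverage c over the whole region returns c for any c
  for (cc in c(0.5, 1, 7.25)) {
    tr <- signal_track("chr1", 0L, 200L, cc)
    expect_equal(mean_signal(tr, "chr1", 20, 180), cc)
  }
})

test_that("overlap flags agree with an all-pairs brute force", {
  q <- genome_intervals("chr1", 10L, 20L)
  expect_true(overlaps_any(q, genome_intervals("chr1", 19L, 30L)))
  # half-open adjacency is not an overlap
  expect_false(overlaps_any(q, genome_intervals("chr1", 20L, 30L)))
  expect_false(overlaps_any(q, genome_intervals("chr2", 10L, 20L)))
  expect_equal(overlaps_any(q, genome_intervals(character(), integer(),
                                                integer())), FALSE)

  set.seed(41)
  for (i in 1:5) {
    nq <- sample(50:200, 1); ns <- sample(50:200, 1)
    q <- genome_intervals(sample(c("chr1", "chr2"), nq, TRUE),
                          s <- sample.int(1000, nq, TRUE),
                          s + sample.int(50, nq, TRUE))
    s2 <- genome_intervals(sample(c("chr1", "chr2"), ns, TRUE),
                           t <- sample.int(1000, ns, TRUE),
                           t + sample.int(50, ns, TRUE))
    expect_equal(overlaps_any(q, s2), oracle_overlaps(q, s2))
  }
})

test_that("threshold peak caller merges across gaps and filters length", {
  flat <- signal_track("chr1", 0L, 1000L, 0.5)
  expect_equal(nrow(call_peaks_threshold(flat, 1)), 0L)

  one <- signal_track("chr1", c(0L, 100L), c(50L, 160L), c(0.5, 3))
  pk <- call_peaks_threshold(one, 1, min_len = 30L)
  expect_equal(pk[, c("start", "end")],
               data.frame(start = 100L, end = 160L))

  # two above-threshold runs separated by a bridgeable gap merge
  two <- signal_track("chr1", c(0L, 40L), c(20L, 60L), c(3, 4))
  merged <- call_peaks_threshold(two, 1, min_len = 10L, merge_gap = 25L)
  expect_equal(merged[, c("start", "end")],
               data.frame(start = 0L, end = 60L))
  apart <- call_peaks_threshold(two, 1, min_len = 10L, merge_gap = 10L)
  expect_equal(nrow(apart), 2L)

  # brute-force scan oracle on random tracks
  set.seed(51)
  for (i in 1:6) {
    rt <- random_track(10, max_pos = 300L, max_val = 4)
    thr <- 2; gap <- 8L; ml <- 5L
    base <- vapply(0:299, function(p)
      oracle_mean_signal(rt, "chr1", p, p + 1L), 0)
    above <- which(base >= thr) - 1L
    pk <- call_peaks_threshold(rt, thr, min_len = ml, merge_gap = gap)
    if (!length(above)) {
      expect_equal(nrow(pk), 0L)
    } else {
      grp <- cumsum(c(TRUE, diff(above) > gap + 1L))
      exp_start <- tapply(above, grp, min)
      exp_end <- tapply(above, grp, max) + 1L
      keep <- (exp_end - exp_start) >= ml
      expect_equal(pk$start, unname(as.integer(exp_start[keep])))
      expect_equal(pk$end, unname(as.integer(exp_end[keep])))
    }
  }
})

test_that("signal track constructor enforces its invariants", {
  expect_error(signal_track("chr1", 20L, 10L, 1), "start < end")
  expect_error(signal_track("chr1", 0L, 10L, -2), ">= 0")
  expect_error(signal_track(c("chr1", "chr1"), c(0L, 5L), c(10L, 15L),
                            c(1, 1)), "overlap")
  expect_error(genome_intervals("chr1", 20L, 10L), "start < end")
})
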