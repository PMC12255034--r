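# Hand fixture: six PQSs with known peak/accessibility/methylation layout.
make_joint_fixture <- function() {
  pqs <- data.frame(
    chrom = "chr1",
    start = c(100L, 300L, 500L, 700L, 900L, 1100L),
    end = c(130L, 330L, 530L, 730L, 930L, 1130L),
    strand = "+",
    sequence = "", tract_starts = "", loop_lengths = "",
    n_cpg = c(1L, 1L, 1L, 1L, 0L, 1L),
    cpg_positions = c("110", "310", "510", "710", "", "1110"),
    stringsAsFactors = FALSE)
  g4_peaks <- genome_intervals("chr1", c(90L, 290L, 490L, 690L, 890L),
                               c(140L, 340L, 540L, 740L, 940L))
  atac_peaks <- genome_intervals("chr1", c(80L, 280L), c(150L, 350L))
  g4_track <- signal_track("chr1", pqs$start, pqs$end, c(8, 6, 4, 2, 5, 1))
  atac_track <- signal_track("chr1", pqs$start, pqs$end,
                             c(9, 7, 1, 0.5, 1, 1), drop_zero = FALSE)
  calls <- cpg_calls("chr1", c(110L, 310L, 510L, 710L, 1110L), "+",
                     c(8L, 1L, 9L, 2L, 5L), 10L)
  list(pqs = pqs, g4_peaks = g4_peaks, atac_peaks = atac_peaks,
       g4_track = g4_track, atac_track = atac_track, calls = calls)
}

test_that("joint table flags match a hand-annotated fixture", {
  f <- make_joint_fixture()
  tbl <- build_pqs_joint_table(f$pqs, f$g4_peaks, f$g4_track, f$atac_peaks,
                               f$atac_track, f$calls)
  # PQS5 has no CpG, PQS6 no G4 peak: both filtered out
  expect_equal(nrow(tbl), 4L)
  expect_equal(tbl$start, c(100L, 300L, 500L, 700L))
  expect_equal(tbl$open, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(tbl$meth_state, c("high", "low", "high", "low"))
  expect_equal(tbl$meth_level, c(80, 10, 90, 20))
  expect_equal(tbl$g4_signal, c(8, 6, 4, 2))

  unfiltered <- build_pqs_joint_table(f$pqs, f$g4_peaks, f$g4_track,
                                      f$atac_peaks, f$atac_track, f$calls,
                                      filter = FALSE)
  expect_equal(nrow(unfiltered), 6L)
  expect_equal(unfiltered$meth_state[5], "undefined")
})

test_that("Pearson coupling matches the textbook formula", {
  f <- make_joint_fixture()
  tbl <- build_pqs_joint_table(f$pqs, f$g4_peaks, f$g4_track, f$atac_peaks,
                               f$atac_track, f$calls)
  # exact collinearity
  lin <- data.frame(g4_signal = c(1, 2, 3, 4), atac_signal = c(2, 4, 6, 8))
  expect_equal(pearson_g4_atac(lin), 1)
  lin$atac_signal <- -lin$g4_signal + 10
  expect_equal(pearson_g4_atac(lin), -1)

  set.seed(91)
  x <- runif(20); y <- runif(20)
  rnd <- data.frame(g4_signal = x, atac_signal = y)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_g4_atac(rnd), num / den)

  # invariance under positive affine transforms
  rnd2 <- data.frame(g4_signal = 3 * x + 7, atac_signal = 0.5 * y + 1)
  expect_equal(pearson_g4_atac(rnd2), pearson_g4_atac(rnd))

  expect_error(pearson_g4_atac(data.frame(g4_signal = c(1, 1, 1),
                                          atac_signal = c(1, 2, 3))),
               "variance")
  expect_error(pearson_g4_atac(lin[1:2, ]), "at least 3")
})

test_that("strata means, additivity and t-tests behave", {
  f <- make_joint_fixture()
  tbl <- build_pqs_joint_table(f$pqs, f$g4_peaks, f$g4_track, f$atac_peaks,
                               f$atac_track, f$calls)
  ss <- stratified_summary(tbl)
  s <- ss$strata
  get <- function(nm, col) s[[col]][s$stratum == nm]
  expect_equal(get("all", "n"), 4L)
  expect_equal(get("open", "mean"), 7)       # (8 + 6) / 2
  expect_equal(get("closed", "mean"), 3)     # (4 + 2) / 2
  expect_equal(get("hypo", "mean"), 4)       # (6 + 2) / 2
  expect_equal(get("hyper", "mean"), 6)      # (8 + 4) / 2
  expect_equal(get("open_hypo", "mean"), 6)
  expect_equal(get("closed_hyper", "mean"), 4)

  # identical signal everywhere: all means equal, tests non-significant
  flat <- tbl; flat$g4_signal <- 5
  fs <- stratified_summary(flat)
  expect_true(all(fs$strata$mean == 5))
  expect_true(all(is.na(fs$tests$p_value) | fs$tests$p_value > 0.9))

  # stratum additivity on a random table
  set.seed(92)
  n <- 200L
  rnd <- data.frame(
    g4_signal = runif(n), open = runif(n) < 0.4,
    meth_state = sample(c("high", "low", "undefined"), n, TRUE))
  rs <- stratified_summary(rnd)$strata
  cnt <- function(nm) rs$n[rs$stratum == nm]
  n_open_undef <- sum(rnd$open & rnd$meth_state == "undefined")
  expect_equal(cnt("open_hypo") + cnt("open_hyper") + n_open_undef,
               cnt("open"))
  expect_equal(cnt("open") + cnt("closed"), cnt("all"))

  # single-stratum table: the missing comparisons are unavailable
  solo <- data.frame(g4_signal = runif(5), open = TRUE,
                     meth_state = "low")
  so <- stratified_summary(solo)
  expect_equal(so$strata$n[so$strata$stratum == "closed"], 0L)
  expect_true(all(is.na(so$tests$p_value)))
})

test_that("MAnorm-style selection rescales by median M", {
  peaks <- genome_intervals("chr1", seq(0L, 900L, 100L),
                            seq(50L, 950L, 100L))
  a <- rep(100, 10); b <- rep(100, 10)
  expect_equal(nrow(nondifferential_atac_peaks(peaks, a, b, 1)), 10L)

  # one 4x peak amid balanced peaks is excluded at cutoff 1
  a2 <- a; a2[4] <- 4 * b[4]
  kept <- nondifferential_atac_peaks(peaks, a2, b, 1)
  expect_equal(nrow(kept), 9L)
  expect_false(peaks$start[4] %in% kept$start)

  # a global 2x depth difference is absorbed by the median shift
  expect_equal(nrow(nondifferential_atac_peaks(peaks, 2 * b, b, 1)), 10L)

  # direct-computation check of the rescaled M values
  set.seed(93)
  ca <- rpois(10, 200); cb <- rpois(10, 150)
  m <- log2((ca + 1) / (cb + 1)); m <- m - median(m)
  got <- nondifferential_atac_peaks(peaks, ca, cb, 0.3)
  expect_equal(got$M_rescaled, m[abs(m) <= 0.3])

  empty <- peaks[0, ]
  expect_equal(nrow(nondifferential_atac_peaks(empty, numeric(),
                                               numeric(), 1)), 0L)
})

test_that("per-chromosome log2 ratios sum mass and handle absence", {
  wt <- signal_track(c("chr1", "chr2"), c(0L, 0L), c(100L, 50L), c(2, 4))
  expect_true(all(chrom_log2_ratio(wt, wt) == 0))

  ko <- wt; ko$value <- 2 * ko$value
  r <- chrom_log2_ratio(ko, wt, pseudo = 1e-9)
  expect_equal(unname(r), c(1, 1), tolerance = 1e-6)

  set.seed(94)
  ko2 <- random_track(5); wt2 <- random_track(5)
  mass <- function(t) sum((t$end - t$start) * t$value)
  expect_equal(unname(chrom_log2_ratio(ko2, wt2, pseudo = 0.5)),
               log2((mass(ko2) + 0.5) / (mass(wt2) + 0.5)))

  # chromosome present in only one track still reported; absent omitted
  solo <- signal_track("chr3", 0L, 10L, 1)
  r2 <- chrom_log2_ratio(solo, wt)
  expect_setequal(names(r2), c("chr1", "chr2", "chr3"))
})

test_that("DE filter applies strict inequalities", {
  de <- data.frame(
    gene_id = paste0("g", 1:6),
    log2fc = c(1.0, 2.0, -2.0, -1.0, 0.5, 3.0),
    p_value = c(0.01, 0.01, 0.01, 0.01, 0.001, 0.05))
  deg <- de_filter(de)
  # g1: log2fc exactly 1 -> excluded; g6: p exactly 0.05 -> excluded
  expect_equal(deg$up, "g2")
  expect_equal(deg$down, "g3")

  expect_error(de_filter(transform(de, log2fc = Inf)), "finite")
  expect_error(de_filter(transform(de, p_value = 2)), "p_value")
})

test_that("promoter G4 linkage computes per-gene deltas", {
  anchors <- transcript_anchors(paste0("g", 1:3), paste0("t", 1:3),
                                "chr1", c(2000L, 5000L, 8000L), "+")
  wt_tr <- signal_track("chr1", 0L, 10000L, 2)
  ko_tr <- signal_track("chr1", 0L, 10000L, 3)
  m_wt <- anchored_matrix(wt_tr, anchors)
  m_ko <- anchored_matrix(ko_tr, anchors)

  eq <- promoter_g4_link(c("g1", "g2"), m_wt, m_wt)
  expect_true(all(eq$per_gene$delta == 0))

  up <- promoter_g4_link(c("g1", "g2", "gX"), m_wt, m_ko)
  expect_equal(up$n_input, 3L)
  expect_equal(up$n_resolved, 2L)       # gX has no anchored TSS
  expect_equal(up$per_gene$delta, c(1, 1))
  expect_equal(up$mean_delta, 1)

  expect_error(promoter_g4_link("nope", m_wt, m_ko), "resolvable")
})

test_that("promoter fraction and Venn-style counts", {
  anchors <- transcript_anchors(c("g1", "g2"), c("t1", "t2"), "chr1",
                                c(5000L, 9000L), "+")
  peaks <- genome_intervals("chr1", c(4500L, 20000L, 8500L),
                            c(4600L, 20100L, 8600L))
  expect_equal(promoter_fraction(peaks, anchors), 2 / 3)

  b <- genome_intervals("chr1", c(4550L, 30000L), c(4560L, 30100L))
  vc <- peak_overlap_counts(peaks, b)
  expect_equal(vc$common_a, 1L)
  expect_equal(vc$a_only, 2L)
  expect_equal(vc$b_only, 1L)
})
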