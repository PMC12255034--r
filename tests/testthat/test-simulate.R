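small_cfg <- function(...) {
  defaults <- list(n_chrom = 1L, n_genes = 20L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

test_that("generation is a pure function of config and seed", {
  cfg <- small_cfg()
  a <- generate_genome(cfg, 5)
  b <- generate_genome(cfg, 5)
  expect_identical(a$genome, b$genome)
  expect_identical(a$genes, b$genes)
  expect_identical(a$pqs, b$pqs)
  expect_identical(a$cpg, b$cpg)
  c <- generate_genome(cfg, 6)
  expect_false(identical(a$genome, c$genome))

  # downstream stages deterministic too
  m1 <- simulate_methylome(a, "WT", 5)
  m2 <- simulate_methylome(b, "WT", 5)
  expect_identical(m1, m2)
  g1 <- simulate_g4(a, m1$true_level, "WT", 5)
  g2 <- simulate_g4(b, m2$true_level, "WT", 5)
  expect_identical(g1$track, g2$track)
})

test_that("the scanner recovers every planted PQS at its coordinates", {
  cfg <- small_cfg(n_genes = 10L)
  sim <- generate_genome(cfg, 9)
  found <- scan_genome_pqs(sim$genome, annotate_cpgs = TRUE)
  expect_gte(nrow(found), nrow(sim$pqs))
  key_found <- paste(found$chrom, found$start, found$end)
  key_plant <- paste(sim$pqs$chrom, sim$pqs$start, sim$pqs$end)
  expect_true(all(key_plant %in% key_found))
  # every planted PQS carries at least one CpG
  planted <- found[key_found %in% key_plant, ]
  expect_true(all(planted$n_cpg >= 1L))

  # with no planting, only chance PQSs remain (sparse)
  sim0 <- generate_genome(small_cfg(n_pqs_per_promoter = 0L), 9)
  chance <- scan_genome_pqs(sim0$genome, annotate_cpgs = FALSE)
  expect_lt(nrow(chance), 20L * 2L)
})

test_that("methylome counts follow the binomial around the true level", {
  cfg <- small_cfg()
  sim <- generate_genome(cfg, 13)
  # force a known true level at every dyad, then check the WGBS estimator
  sim$cpg <- sim$cpg[rep(seq_len(nrow(sim$cpg)),
                         length.out = 5000L), , drop = FALSE]
  sim$cpg$base_level <- 0.8
  meth <- simulate_methylome(sim, "WT", 13)
  covered <- meth$calls[meth$calls$n_total > 0L, ]
  lev <- site_methylation_level(covered$n_meth, covered$n_total)
  expect_equal(mean(lev), 80, tolerance = 0.01)

  # KO scales every true level; scale 1 leaves them identical
  cfg1 <- small_cfg(ko_meth_scale = 1)
  sim1 <- generate_genome(cfg1, 13)
  expect_identical(simulate_methylome(sim1, "WT", 13)$true_level,
                   simulate_methylome(sim1, "KO", 13)$true_level)
  cfg2 <- small_cfg(ko_meth_scale = 0.5)
  sim2 <- generate_genome(cfg2, 13)
  expect_equal(simulate_methylome(sim2, "KO", 13)$true_level,
               simulate_methylome(sim2, "WT", 13)$true_level * 0.5)

  # near-zero coverage: almost every site uncovered, and windows with a
  # modest site requirement become undefined
  cfg3 <- small_cfg(coverage_mean = 0.01)
  sim3 <- generate_genome(cfg3, 13)
  m3 <- simulate_methylome(sim3, "WT", 13)
  expect_gt(mean(m3$calls$n_total == 0L), 0.95)
  lev3 <- windows_methylation_level(
    m3$calls, genome_intervals(sim3$genes$chrom,
                               pmax(0L, sim3$genes$tss - 1000L),
                               sim3$genes$tss + 1000L), min_sites = 20L)
  expect_gt(mean(is.na(lev3)), 0.5)
})

test_that("formation probabilities follow the logistic closed form", {
  cfg <- small_cfg(beta0 = 10, beta_m = 0, beta_a = 0)
  sim <- generate_genome(cfg, 17)
  meth <- simulate_methylome(sim, "WT", 17)
  g4 <- simulate_g4(sim, meth$true_level, "WT", 17)
  expect_true(all(g4$truth$formed == 1L))
  expect_true(all(g4$truth$p_form == plogis(10)))
  expect_gte(min(g4$truth$occupancy), 0.97)

  cfg$beta0 <- -10
  sim$config <- cfg
  g4n <- simulate_g4(sim, meth$true_level, "WT", 17)
  expect_true(all(g4n$truth$formed == 0L))

  # beta0 = -2, beta_m = 3, a fixed: p = plogis(-2 + 3 * (1 - m))
  cfg2 <- small_cfg(beta0 = -2, beta_m = 3, beta_a = 0)
  sim2 <- generate_genome(cfg2, 17)
  ex_m0 <- rep(0, length(sim2$cpg$base_level))
  ex_m1 <- rep(1, length(sim2$cpg$base_level))
  g_m0 <- simulate_g4(sim2, ex_m0, "WT", 17)
  g_m1 <- simulate_g4(sim2, ex_m1, "WT", 17)
  expect_equal(unique(g_m0$truth$p_form), plogis(1))
  expect_equal(unique(g_m1$truth$p_form), plogis(-2))
})

test_that("methylation inhibits formation and the coupling widens the
           hypo/hyper gap", {
  rates <- function(bm, s) {
    cfg <- sim_config(n_chrom = 1L, n_genes = 400L, beta_m = bm)
    sim <- generate_genome(cfg, s)
    meth <- simulate_methylome(sim, "WT", s)
    g4 <- simulate_g4(sim, meth$true_level, "WT", s)
    cls <- sim$genes$meth_class[match(g4$truth$gene_id,
                                      sim$genes$gene_id)]
    c(hyper = mean(g4$truth$formed[cls == "hyper"]),
      hypo = mean(g4$truth$formed[cls == "hypo"]))
  }
  for (s in 1:2) {
    weak <- rates(1, s)
    strong <- rates(3, s)
    # formation decreases with methylation at any positive coupling
    expect_gt(weak["hypo"], weak["hyper"])
    expect_gt(strong["hypo"], strong["hyper"])
    # a stronger coupling widens the inhibition gap
    expect_gt(strong["hypo"] - strong["hyper"],
              weak["hypo"] - weak["hyper"])
  }
})

test_that("expression couples to promoter G4 occupancy with NB noise", {
  cfg <- small_cfg(n_genes = 200L, expr_effect = 3)
  sim <- generate_genome(cfg, 23)
  # crafted occupancies: half the genes jump from 0 to 1 between conditions
  jump <- rep(c(0, 1), length.out = 200L)
  fake_g4 <- function(occ) list(truth = data.frame(
    pqs_id = sim$pqs$pqs_id, gene_id = sim$pqs$gene_id,
    occupancy = occ[match(sim$pqs$gene_id, sim$genes$gene_id)],
    p_form = occ[match(sim$pqs$gene_id, sim$genes$gene_id)]))
  expr <- simulate_expression(sim, fake_g4(rep(0, 200L)),
                              fake_g4(jump), 23)
  # expected fold change is 1 + effect for jumping genes, 1 otherwise
  expect_equal(expr$truth$expected_log2fc,
               ifelse(jump == 1, log2(4), 0))
  deg <- de_filter(expr$de)
  true_up <- sim$genes$gene_id[jump == 1 &
                                 expr$truth$expected_log2fc >= 2]
  expect_gt(mean(true_up %in% deg$up), 0.8)
  expect_lt(length(deg$down), length(deg$up) / 4)

  # zero effect: expected log2 fold changes vanish
  cfg0 <- small_cfg(n_genes = 200L, expr_effect = 0)
  sim0 <- generate_genome(cfg0, 23)
  e0 <- simulate_expression(sim0, fake_g4(rep(0, 200L)),
                            fake_g4(jump), 23)
  expect_true(all(e0$truth$expected_log2fc == 0))
})

test_that("bisulfite conversion turns exactly the unmethylated Cs to T", {
  expect_equal(bisulfite_convert("ACGA"), "ATGA")
  expect_equal(bisulfite_convert("ACGA", methylated_positions = 1L), "ACGA")
  expect_error(bisulfite_convert("ACGA", methylated_positions = 0L),
               "not a cytosine")
  expect_error(bisulfite_convert("ACGA", methylated_positions = 9L),
               "outside")

  set.seed(27)
  for (i in 1:10) {
    s <- random_dna_str(80)
    chars <- strsplit(s, "")[[1]]
    cs <- which(chars == "C") - 1L
    keep <- sample(cs, min(3L, length(cs)))
    conv <- strsplit(bisulfite_convert(s, keep), "")[[1]]
    for (j in seq_along(chars)) {
      expected <- if (chars[j] == "C" && !((j - 1L) %in% keep)) "T"
        else chars[j]
      expect_equal(conv[j], expected)
    }
  }
})

test_that("calibration reports an unreachable target with its bracket", {
  cfg <- sim_config(n_chrom = 1L, n_genes = 60L)
  expect_error(
    calibrate_coupling(0.999, cfg, seeds = 1L, bounds = c(0, 1),
                       max_iter = 2L),
    "unreachable")
})

test_that("ATAC simulation opens the configured promoters", {
  cfg <- small_cfg(open_fraction = 0)
  sim <- generate_genome(cfg, 29)
  atac <- simulate_atac(sim, "WT", 29)
  expect_equal(nrow(atac$peaks), 0L)

  cfg2 <- small_cfg(open_fraction = 1, atac_background_rate = 0)
  sim2 <- generate_genome(cfg2, 29)
  atac2 <- simulate_atac(sim2, "WT", 29)
  expect_equal(nrow(atac2$peaks), 20L)
  # plateau height ~ accessibility * scale (per-bin Poisson mean)
  prom1 <- atac2$peaks[1, ]
  h <- mean_signal(atac2$track, prom1$chrom, prom1$start, prom1$end)
  expect_equal(h, sim2$genes$accessibility[1] * cfg2$atac_scale,
               tolerance = 0.15)
})
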