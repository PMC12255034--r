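# Coupled synthetic multi-omics generator with known ground truth. The
# causal model: promoter CpG methylation inhibits G4 formation,
# accessibility weakly promotes it, and promoter G4 occupancy elevates
# transcription. Per PQS the formation probability is logistic,
#   P(form) = plogis(beta0 + beta_m * (1 - m) + beta_a * a)
# with m the mean true methylation of the PQS's CpGs (0..1) and a the
# promoter accessibility (0..1). Bulk G4 CUT&Tag signal is modeled as
# occupancy (cell fraction formed, Binomial(n_cells, p)/n_cells) times a
# per-locus log-normal amplitude, on top of Poisson background; the IgG
# control is background only. Every output is a pure function of
# (config, seed).

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: balanced
#' hyper/hypomethylated promoters (Beta-distributed CpG levels around 85%
#' and 10%), balanced open/closed chromatin, WGBS-like Poisson(30) coverage
#' with Binomial methylated counts, logistic formation couplings
#' `beta0 = -2`, `beta_m = 3`, `beta_a = 1`, and a DNMT1-knockout condition
#' that multiplies every true methylation level by `ko_meth_scale = 0.5`.
#'
#' @param n_chrom number of synthetic chromosomes.
#' @param n_genes total genes (evenly split across chromosomes; one
#'   transcript per gene, strands alternating).
#' @param gene_spacing bp between consecutive TSSs (>= 4000; promoters are
#'   TSS +/- `flank` and must not crowd).
#' @param n_pqs_per_promoter canonical PQS motifs planted per promoter.
#' @param pqs_offsets motif start offsets relative to the TSS (recycled).
#' @param pqs_jitter uniform jitter (+/- bp) on each planted offset.
#' @param promoter_hyper_fraction fraction of promoters hypermethylated.
#' @param open_fraction fraction of promoters with open chromatin.
#' @param flank promoter half-width in bp.
#' @param hyper_level_mean,hypo_level_mean,background_level_mean mean true
#'   methylation (0..1) for hyper/hypo promoters and non-promoter CpGs.
#' @param level_concentration Beta concentration of per-CpG true levels.
#' @param coverage_mean mean WGBS coverage per cytosine strand (Poisson).
#' @param beta0,beta_m,beta_a logistic formation couplings (intercept,
#'   methylation inhibition, accessibility).
#' @param n_cells cells per locus for the occupancy draw.
#' @param g4_amp_meanlog,g4_amp_sdlog log-normal G4 bump amplitude.
#' @param g4_bump_halfwidth bump half-width around the PQS center (bp).
#' @param g4_background_rate,atac_background_rate Poisson background rate
#'   per track bin.
#' @param atac_scale open-chromatin ATAC plateau scale (rate = a * scale).
#' @param atac_open_shape,atac_closed_shape Beta shapes for accessibility
#'   a of open and closed promoters.
#' @param track_bin signal track bin width (bp).
#' @param g4_peak_threshold,g4_peak_min_len,g4_peak_merge_gap plumbing
#'   peak-caller settings for the G4 track.
#' @param ko_meth_scale KO multiplies every true methylation level by this.
#' @param expr_mu_meanlog,expr_mu_sdlog log-normal baseline expression.
#' @param expr_effect expression multiplier slope on promoter G4 occupancy
#'   (`mean = mu * (1 + effect * occupancy)`).
#' @param expr_dispersion negative-binomial dispersion (size = 1/disp).
#' @param n_reps replicates per condition.
#' @param conversion_failure_rate bisulfite conversion failure probability
#'   (0 = complete conversion).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 4L, n_genes = 400L, gene_spacing = 4000L,
                       n_pqs_per_promoter = 3L,
                       pqs_offsets = c(-120L, 0L, 120L), pqs_jitter = 5L,
                       promoter_hyper_fraction = 0.5, open_fraction = 0.5,
                       flank = 1000L,
                       hyper_level_mean = 0.85, hypo_level_mean = 0.10,
                       background_level_mean = 0.75,
                       level_concentration = 10,
                       coverage_mean = 30,
                       beta0 = -2, beta_m = 3, beta_a = 1,
                       n_cells = 200L,
                       g4_amp_meanlog = log(8), g4_amp_sdlog = 0.3,
                       g4_bump_halfwidth = 100L,
                       g4_background_rate = 0.2,
                       atac_scale = 6, atac_background_rate = 0.2,
                       atac_open_shape = c(8, 2),
                       atac_closed_shape = c(2, 8),
                       track_bin = 10L,
                       g4_peak_threshold = 2, g4_peak_min_len = 20L,
                       g4_peak_merge_gap = 30L,
                       ko_meth_scale = 0.5,
                       expr_mu_meanlog = log(200), expr_mu_sdlog = 1,
                       expr_effect = 3, expr_dispersion = 0.1,
                       n_reps = 3L,
                       conversion_failure_rate = 0,
                       library_size = 1e6) {
  cfg <- as.list(environment())
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  if (cfg$gene_spacing < 4000L)
    stop("overcrowded config: gene_spacing must be >= 4000")
  if (cfg$promoter_hyper_fraction < 0 || cfg$promoter_hyper_fraction > 1 ||
      cfg$open_fraction < 0 || cfg$open_fraction > 1)
    stop("fractions must lie in [0, 1]")
  if (cfg$coverage_mean <= 0) stop("coverage_mean must be > 0")
  if (cfg$ko_meth_scale <= 0 || cfg$ko_meth_scale > 1)
    stop("ko_meth_scale must be in (0, 1]")
  if (max(abs(cfg$pqs_offsets)) + cfg$pqs_jitter + 60L > cfg$flank)
    stop("overcrowded config: planted PQS offsets exceed the promoter")
  if (cfg$n_pqs_per_promoter > length(cfg$pqs_offsets))
    stop("provide one pqs_offsets entry per planted PQS")
  if (cfg$n_pqs_per_promoter > 1L &&
      min(diff(sort(cfg$pqs_offsets[seq_len(cfg$n_pqs_per_promoter)]))) <
        2L * cfg$pqs_jitter + 60L)
    stop("overcrowded config: planted PQS offsets too close")
  class(cfg) <- "sim_config"
  cfg
}

# run `expr` under a temporary RNG state seeded deterministically
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483629)
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

# one planted canonical motif; loops avoid G except the forced CpG so the
# planted interval is exactly what the scanner recovers
random_pqs_motif <- function() {
  tracts <- sample(3:4, 4L, replace = TRUE)
  loops <- sample(2:7, 3L, replace = TRUE)
  cg_loop <- sample.int(3L, 1L)
  loop_seq <- vapply(seq_len(3L), function(j) {
    body <- paste(sample(c("A", "C", "T"), loops[j], replace = TRUE),
                  collapse = "")
    if (j == cg_loop) body <- paste0("CG", substring(body, 3L))
    body
  }, "")
  paste0(strrep("G", tracts[1L]), loop_seq[1L],
         strrep("G", tracts[2L]), loop_seq[2L],
         strrep("G", tracts[3L]), loop_seq[3L],
         strrep("G", tracts[4L]))
}

#' Generate a synthetic genome with planted promoter PQSs
#'
#' Random background sequence with canonical PQS motifs planted in every
#' promoter (each containing at least one CpG in a loop), TSSs evenly
#' spaced with alternating strands, and per-gene latent states: methylation
#' class (hyper/hypo), open-chromatin flag, accessibility `a`, baseline
#' expression, and per-PQS amplitude. CpG sites are located and assigned
#' condition-independent base methylation levels here so that WT and KO
#' share them. Deterministic given `(config, seed)`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A list of class `sim_genome`: `genome` (named character vector),
#'   `anchors`, `genes` (latent truth), `pqs` (planted truth), `cpg`
#'   (per-dyad base levels), `config`, `seed`.
#' @export
generate_genome <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(seed, 1L), {
    gpc <- distribute(config$n_genes, config$n_chrom)
    chrom_names <- sprintf("chr%d", seq_len(config$n_chrom))
    genes <- list(); seqs <- character(0L)
    gid0 <- 0L
    for (ci in seq_len(config$n_chrom)) {
      ng <- gpc[ci]
      clen <- ng * config$gene_spacing
      tss <- as.integer(round((seq_len(ng) - 0.5) * config$gene_spacing))
      gene_id <- sprintf("g%05d", gid0 + seq_len(ng))
      strand <- rep_len(c("+", "-"), ng)
      offs <- config$pqs_offsets[seq_len(config$n_pqs_per_promoter)]
      plant <- list()
      for (g in seq_len(ng)) {
        if (!length(offs)) next
        jit <- sample(-config$pqs_jitter:config$pqs_jitter,
                      length(offs), replace = TRUE)
        motifs <- vapply(seq_along(offs), function(j) random_pqs_motif(), "")
        # offsets locate motif CENTERS so the planted density profile is
        # strand-symmetric (orientation flips map the offset set to itself)
        starts <- tss[g] + offs + jit - nchar(motifs) %/% 2L
        plant[[g]] <- data.frame(gene_id = gene_id[g], start = starts,
                                 motif = motifs, stringsAsFactors = FALSE)
      }
      plant <- if (length(plant)) do.call(rbind, plant) else
        data.frame(gene_id = character(), start = integer(),
                   motif = character(), stringsAsFactors = FALSE)
      plant <- plant[order(plant$start), , drop = FALSE]
      # compose: background | guard motif guard | background | ...; the
      # 13-bp G-free guards stop background G-runs from bridging into a
      # planted motif within one loop length (loop_max_len = 12)
      guard_len <- 13L
      guard <- function() paste(sample(c("A", "C", "T"), guard_len,
                                       replace = TRUE), collapse = "")
      pieces <- character(2L * nrow(plant) + 1L)
      cursor <- 0L
      for (i in seq_len(nrow(plant))) {
        pieces[2L * i - 1L] <- random_dna(plant$start[i] - guard_len - cursor)
        pieces[2L * i] <- paste0(guard(), plant$motif[i], guard())
        cursor <- plant$start[i] + nchar(plant$motif[i]) + guard_len
      }
      pieces[2L * nrow(plant) + 1L] <- random_dna(clen - cursor)
      seqs[chrom_names[ci]] <- paste(pieces, collapse = "")
      genes[[ci]] <- data.frame(
        gene_id = gene_id, transcript_id = paste0(gene_id, ".1"),
        chrom = chrom_names[ci], tss = tss, strand = strand,
        stringsAsFactors = FALSE)
      plant$chrom <- rep(chrom_names[ci], nrow(plant))
      plant$end <- plant$start + nchar(plant$motif)
      genes[[ci]]$n_pqs <- if (nrow(plant))
        as.integer(table(plant$gene_id)[genes[[ci]]$gene_id]) else 0L
      attr(genes[[ci]], "plant") <- plant
      gid0 <- gid0 + ng
    }
    plant_all <- do.call(rbind, lapply(genes, attr, "plant"))
    genes <- do.call(rbind, genes)
    rownames(genes) <- rownames(plant_all) <- NULL

    n <- nrow(genes)
    genes$meth_class <- ifelse(
      runif(n) < config$promoter_hyper_fraction, "hyper", "hypo")
    genes$open <- runif(n) < config$open_fraction
    genes$accessibility <- ifelse(
      genes$open,
      rbeta(n, config$atac_open_shape[1L], config$atac_open_shape[2L]),
      rbeta(n, config$atac_closed_shape[1L], config$atac_closed_shape[2L]))
    genes$expr_mu <- rlnorm(n, config$expr_mu_meanlog, config$expr_mu_sdlog)

    pqs <- data.frame(
      pqs_id = sprintf("pqs%06d", seq_len(nrow(plant_all))),
      gene_id = plant_all$gene_id, chrom = plant_all$chrom,
      start = plant_all$start, end = plant_all$end,
      amp = rlnorm(nrow(plant_all), config$g4_amp_meanlog,
                   config$g4_amp_sdlog),
      stringsAsFactors = FALSE)

    # CpG dyads and their condition-independent base methylation levels
    cpg <- locate_cpgs(seqs)
    prom <- genome_intervals(genes$chrom,
                             pmax(0L, genes$tss - config$flank),
                             genes$tss + config$flank)
    hit <- first_overlap(cpg$chrom, cpg$pos, prom)
    mean_lev <- rep(config$background_level_mean, nrow(cpg))
    in_prom <- !is.na(hit)
    cls <- genes$meth_class[hit[in_prom]]
    mean_lev[in_prom] <- ifelse(cls == "hyper", config$hyper_level_mean,
                                config$hypo_level_mean)
    conc <- config$level_concentration
    cpg$base_level <- rbeta(nrow(cpg), mean_lev * conc,
                            (1 - mean_lev) * conc)
    cpg$gene_idx <- hit

    anchors <- transcript_anchors(genes$gene_id, genes$transcript_id,
                                  genes$chrom, genes$tss, genes$strand)
    structure(list(genome = seqs, anchors = anchors, genes = genes,
                   pqs = pqs, cpg = cpg, config = config, seed = seed),
              class = "sim_genome")
  })
}

distribute <- function(total, k) {
  base <- total %/% k
  extra <- total %% k
  base + (seq_len(k) <= extra)
}

locate_cpgs <- function(seqs) {
  out <- lapply(names(seqs), function(chr) {
    m <- gregexpr("CG", seqs[[chr]], fixed = TRUE)[[1L]]
    if (m[1L] == -1L) return(NULL)
    data.frame(chrom = chr, pos = as.integer(m) - 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# index of the first region containing each position (NA if none);
# regions must be disjoint per chromosome
first_overlap <- function(chrom, pos, regions) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  s <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1L,
                                               regions$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, s, select = "first",
                                ignore.strand = TRUE))
  as.integer(hits)
}

#' Simulate WGBS methylation calls for one condition
#'
#' Each CpG dyad's true level is the base level times `ko_meth_scale` for
#' the KO condition (WT unchanged). Both strand cytosines of the dyad are
#' called independently: coverage ~ Poisson(`coverage_mean`), methylated
#' count ~ Binomial(coverage, level). Zero-coverage calls are retained
#' (windowed statistics treat them as uncovered).
#'
#' @param sim a [generate_genome()] result.
#' @param condition `"WT"` or `"KO"`.
#' @param seed integer seed.
#' @return A list: `calls` ([cpg_calls()] rows for both strands),
#'   `true_level` (per-dyad condition-scaled level, 0..1).
#' @export
simulate_methylome <- function(sim, condition = c("WT", "KO"), seed) {
  condition <- match.arg(condition)
  config <- sim$config
  scale <- if (condition == "KO") config$ko_meth_scale else 1
  lev <- pmin(1, sim$cpg$base_level * scale)
  with_seed(derive_seed(seed, if (condition == "WT") 21L else 22L), {
    n <- length(lev)
    cov_p <- rpois(n, config$coverage_mean)
    cov_m <- rpois(n, config$coverage_mean)
    calls <- data.frame(
      chrom = c(sim$cpg$chrom, sim$cpg$chrom),
      pos = c(sim$cpg$pos, sim$cpg$pos + 1L),
      strand = rep(c("+", "-"), each = n),
      n_meth = c(rbinom(n, cov_p, lev), rbinom(n, cov_m, lev)),
      n_total = c(cov_p, cov_m), stringsAsFactors = FALSE)
    o <- order(calls$chrom, calls$pos)
    calls <- calls[o, , drop = FALSE]
    rownames(calls) <- NULL
    list(calls = calls, true_level = lev)
  })
}

# per-PQS mean true methylation (0..1) under a condition's levels;
# PQSs without a CpG (none are planted) fall back to the genome mean
pqs_true_meth <- function(sim, true_level) {
  out <- rep(mean(true_level), nrow(sim$pqs))
  q <- GenomicRanges::GRanges(sim$pqs$chrom,
                              IRanges::IRanges(sim$pqs$start + 1L,
                                               sim$pqs$end))
  s <- GenomicRanges::GRanges(sim$cpg$chrom,
                              IRanges::IRanges(sim$cpg$pos + 1L,
                                               sim$cpg$pos + 1L))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE))
  if (length(hits)) {
    mu <- tapply(true_level[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits), mean)
    out[as.integer(names(mu))] <- as.numeric(mu)
  }
  out
}

#' Simulate an ATAC-seq track and peak set
#'
#' Open promoters receive a Poisson plateau with rate
#' `accessibility * atac_scale` per bin on top of genome-wide Poisson
#' background; peaks are the promoter windows whose noiseless plateau
#' exceeds the background (i.e. the open promoters).
#'
#' @param sim a [generate_genome()] result.
#' @param condition `"WT"` or `"KO"` (accessibility is shared; only noise
#'   differs).
#' @param seed integer seed.
#' @return A list: `track` ([signal_track()]), `peaks` (intervals),
#'   `total_reads` (nominal library size, for BPM).
#' @export
simulate_atac <- function(sim, condition = c("WT", "KO"), seed) {
  condition <- match.arg(condition)
  config <- sim$config
  with_seed(derive_seed(seed, if (condition == "WT") 31L else 32L), {
    tr <- simulate_binned_track(
      sim, base_rate = config$atac_background_rate,
      regions = promoter_windows(sim)[sim$genes$open, , drop = FALSE],
      region_rate = (sim$genes$accessibility * config$atac_scale)[sim$genes$open])
    open <- promoter_windows(sim)[sim$genes$open, , drop = FALSE]
    peaks <- genome_intervals(open$chrom, open$start, open$end,
                              name = sim$genes$gene_id[sim$genes$open])
    # equal nominal sequencing depth across conditions: BPM uses the
    # configured library size, not the track's own signal mass
    list(track = tr, peaks = peaks, total_reads = config$library_size)
  })
}

promoter_windows <- function(sim) {
  genome_intervals(sim$genes$chrom,
                   pmax(0L, sim$genes$tss - sim$config$flank),
                   sim$genes$tss + sim$config$flank)
}

# Poisson-binned track: background rate everywhere, plus per-region added
# rates (regions given as interval df + per-region rate, may overlap)
simulate_binned_track <- function(sim, base_rate, regions, region_rate) {
  bin <- sim$config$track_bin
  pieces <- lapply(names(sim$genome), function(chr) {
    clen <- nchar(sim$genome[[chr]])
    nb <- clen %/% bin
    rate <- rep(base_rate, nb)
    sel <- which(regions$chrom == chr)
    for (i in sel) {
      b0 <- regions$start[i] %/% bin + 1L
      b1 <- min(nb, (regions$end[i] - 1L) %/% bin + 1L)
      if (b1 >= b0) rate[b0:b1] <- rate[b0:b1] + region_rate[i]
    }
    v <- rpois(nb, rate)
    keep <- v > 0L
    if (!any(keep)) return(NULL)
    st <- (which(keep) - 1L) * bin
    data.frame(chrom = chr, start = st, end = st + bin, value = v[keep],
               stringsAsFactors = FALSE)
  })
  as_signal_track(merge_equal_runs(do.call(rbind, pieces)))
}

#' Simulate the G4 CUT&Tag track, peaks and IgG control
#'
#' Per planted PQS the logistic formation probability is evaluated from
#' the condition's true methylation and the promoter accessibility;
#' occupancy (fraction of cells with a formed G4) scales the locus
#' amplitude into a coverage bump over PQS center +/- `g4_bump_halfwidth`.
#' Bins draw Poisson counts at background + bump rate; IgG is background
#' only. Peaks come from the threshold caller.
#'
#' @param sim a [generate_genome()] result.
#' @param true_level per-dyad true methylation for the condition (from
#'   [simulate_methylome()]).
#' @param condition `"WT"` or `"KO"`.
#' @param seed integer seed.
#' @return A list: `track`, `igg` ([signal_track()]s), `peaks`, `truth`
#'   (per-PQS `m`, `a`, `p_form`, `occupancy`, `formed`), `total_reads`,
#'   `total_reads_igg`.
#' @export
simulate_g4 <- function(sim, true_level, condition = c("WT", "KO"), seed) {
  condition <- match.arg(condition)
  config <- sim$config
  m <- pqs_true_meth(sim, true_level)
  a <- sim$genes$accessibility[match(sim$pqs$gene_id, sim$genes$gene_id)]
  p <- plogis(config$beta0 + config$beta_m * (1 - m) + config$beta_a * a)
  with_seed(derive_seed(seed, if (condition == "WT") 41L else 42L), {
    occ <- rbinom(length(p), config$n_cells, p) / config$n_cells
    formed <- rbinom(length(p), 1L, p)
    center <- (sim$pqs$start + sim$pqs$end) %/% 2L
    hw <- config$g4_bump_halfwidth
    bumps <- genome_intervals(sim$pqs$chrom, pmax(0L, center - hw),
                              center + hw)
    tr <- simulate_binned_track(sim, base_rate = config$g4_background_rate,
                                regions = bumps,
                                region_rate = occ * sim$pqs$amp)
    igg <- simulate_binned_track(
      sim, base_rate = config$g4_background_rate,
      regions = bumps[0L, , drop = FALSE], region_rate = numeric())
    peaks <- call_peaks_threshold(tr, config$g4_peak_threshold,
                                  min_len = config$g4_peak_min_len,
                                  merge_gap = config$g4_peak_merge_gap)
    truth <- data.frame(pqs_id = sim$pqs$pqs_id, gene_id = sim$pqs$gene_id,
                        m = m, a = a, p_form = p, occupancy = occ,
                        formed = formed, stringsAsFactors = FALSE)
    list(track = tr, igg = igg, peaks = peaks, truth = truth,
         total_reads = config$library_size,
         total_reads_igg = config$library_size)
  })
}

#' Simulate replicate expression counts and a naive DE table
#'
#' Per gene the negative-binomial mean is
#' `expr_mu * (1 + expr_effect * occupancy)` with the condition's mean
#' promoter G4 occupancy. The DE table is deliberately naive (not a DESeq
#' reimplementation): per-gene log2 fold change of shifted mean counts and
#' an equal-variance Student's t on log2(count + 1).
#'
#' @param sim a [generate_genome()] result.
#' @param g4_wt,g4_ko [simulate_g4()] results for the two conditions.
#' @param seed integer seed.
#' @return A list: `counts` (genes x replicates matrix, WT then KO),
#'   `de` (`gene_id`, `log2fc`, `p_value`), `truth` (per-gene occupancies
#'   and expected log2 fold change).
#' @export
simulate_expression <- function(sim, g4_wt, g4_ko, seed) {
  config <- sim$config
  occ_gene <- function(g4) {
    v <- tapply(g4$truth$occupancy, g4$truth$gene_id, mean)
    out <- as.numeric(v[sim$genes$gene_id])
    out[is.na(out)] <- 0
    out
  }
  p_gene <- function(g4) {
    v <- tapply(g4$truth$p_form, g4$truth$gene_id, mean)
    out <- as.numeric(v[sim$genes$gene_id])
    out[is.na(out)] <- 0
    out
  }
  occ_wt <- occ_gene(g4_wt); occ_ko <- occ_gene(g4_ko)
  mu_wt <- sim$genes$expr_mu * (1 + config$expr_effect * occ_wt)
  mu_ko <- sim$genes$expr_mu * (1 + config$expr_effect * occ_ko)
  n <- nrow(sim$genes); r <- config$n_reps
  with_seed(derive_seed(seed, 51L), {
    size <- 1 / config$expr_dispersion
    cnt_wt <- matrix(rnbinom(n * r, mu = rep(mu_wt, r), size = size), n, r)
    cnt_ko <- matrix(rnbinom(n * r, mu = rep(mu_ko, r), size = size), n, r)
    counts <- cbind(cnt_wt, cnt_ko)
    colnames(counts) <- c(paste0("WT_", seq_len(r)), paste0("KO_", seq_len(r)))
    rownames(counts) <- sim$genes$gene_id
    lfc <- log2((rowMeans(cnt_ko) + 1) / (rowMeans(cnt_wt) + 1))
    lw <- log2(cnt_wt + 1); lk <- log2(cnt_ko + 1)
    pv <- vapply(seq_len(n), function(i) {
      tryCatch(t.test(lk[i, ], lw[i, ], var.equal = TRUE)$p.value,
               error = function(e) 1)
    }, 0)
    de <- data.frame(gene_id = sim$genes$gene_id, log2fc = lfc,
                     p_value = pv, stringsAsFactors = FALSE)
    expected <- log2((1 + config$expr_effect * p_gene(g4_ko)) /
                       (1 + config$expr_effect * p_gene(g4_wt)))
    truth <- data.frame(gene_id = sim$genes$gene_id, occ_wt = occ_wt,
                        occ_ko = occ_ko, expected_log2fc = expected,
                        stringsAsFactors = FALSE)
    list(counts = counts, de = de, truth = truth)
  })
}

#' In-silico bisulfite conversion
#'
#' Unmethylated cytosines read as thymine after conversion and PCR;
#' methylated cytosines stay cytosine. With a nonzero
#' `conversion_failure_rate`, each unmethylated C independently escapes
#' conversion.
#'
#' @param sequence a DNA string.
#' @param methylated_positions 0-based positions of methylated cytosines
#'   (each must be a C in `sequence`).
#' @param conversion_failure_rate probability an unmethylated C stays C.
#' @return The converted sequence string.
#' @export
bisulfite_convert <- function(sequence, methylated_positions = integer(),
                              conversion_failure_rate = 0) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  mp <- as.integer(methylated_positions)
  if (length(mp)) {
    if (any(mp < 0L | mp >= length(chars)))
      stop("methylated position outside the sequence")
    if (any(chars[mp + 1L] != "C"))
      stop("methylated position is not a cytosine")
  }
  convert <- chars == "C"
  convert[mp + 1L] <- FALSE
  if (conversion_failure_rate > 0) {
    fail <- runif(length(chars)) < conversion_failure_rate
    convert <- convert & !fail
  }
  chars[convert] <- "T"
  paste(chars, collapse = "")
}

#' Simulate one condition end to end
#'
#' @param sim a [generate_genome()] result.
#' @param condition `"WT"` or `"KO"`.
#' @param seed integer seed.
#' @return A list: `meth`, `atac`, `g4` (stage outputs), `condition`.
#' @export
simulate_condition <- function(sim, condition = c("WT", "KO"), seed) {
  condition <- match.arg(condition)
  meth <- simulate_methylome(sim, condition, seed)
  atac <- simulate_atac(sim, condition, seed)
  g4 <- simulate_g4(sim, meth$true_level, condition, seed)
  list(meth = meth, atac = atac, g4 = g4, condition = condition)
}

#' Simulate a coupled WT/KO pair over one shared genome
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A list: `sim` (genome + truth), `wt`, `ko` (per-condition
#'   stages), `expr` (counts, DE table and expression truth).
#' @export
simulate_pair <- function(config, seed) {
  sim <- generate_genome(config, seed)
  wt <- simulate_condition(sim, "WT", seed)
  ko <- simulate_condition(sim, "KO", seed)
  expr <- simulate_expression(sim, wt$g4, ko$g4, seed)
  list(sim = sim, wt = wt, ko = ko, expr = expr)
}

#' Calibrate the accessibility coupling to a target G4-ATAC correlation
#'
#' Monotone bisection on `beta_a`: at each candidate the G4 layer is
#' re-simulated for each seed (genome, methylome and ATAC do not depend on
#' `beta_a` and are reused), the filtered PQS joint table is built through
#' the standard pipeline, and `pearson_g4_atac` is averaged across seeds.
#' Stops when the averaged correlation is within `tol` of the target.
#'
#' @param target_r target Pearson correlation (0 < target < 1).
#' @param config a [sim_config()] describing the calibration cohorts.
#' @param seeds integer seeds averaged per candidate (>= 5 recommended).
#' @param bounds search interval for `beta_a`.
#' @param tol convergence tolerance on the correlation (default 0.02).
#' @param max_iter bisection iteration cap.
#' @return A list: `beta_a`, `achieved_r`, `n_eval`, `history`
#'   (`data.frame` of candidate and mean correlation).
#' @export
calibrate_coupling <- function(target_r, config, seeds = 1:5,
                               bounds = c(0, 4), tol = 0.02,
                               max_iter = 12L) {
  if (target_r <= 0 || target_r >= 1) stop("target_r must be in (0, 1)")
  base <- lapply(seeds, function(s) {
    sim <- generate_genome(config, s)
    meth <- simulate_methylome(sim, "WT", s)
    atac <- simulate_atac(sim, "WT", s)
    pqs <- scan_genome_pqs(sim$genome)
    list(sim = sim, meth = meth, atac = atac, pqs = pqs, seed = s)
  })
  eval_beta <- function(b) {
    mean(vapply(base, function(x) {
      cfg <- x$sim$config
      cfg$beta_a <- b
      x$sim$config <- cfg
      g4 <- simulate_g4(x$sim, x$meth$true_level, "WT", x$seed)
      tbl <- build_pqs_joint_table(x$pqs, g4$peaks, g4$track,
                                   x$atac$peaks, x$atac$track,
                                   x$meth$calls)
      pearson_g4_atac(tbl)
    }, 0))
  }
  history <- data.frame(beta_a = numeric(), r = numeric())
  note <- function(b, r) history[nrow(history) + 1L, ] <<- c(b, r)
  lo <- bounds[1L]; hi <- bounds[2L]
  r_lo <- eval_beta(lo); note(lo, r_lo)
  if (abs(r_lo - target_r) <= tol)
    return(list(beta_a = lo, achieved_r = r_lo, n_eval = 1L,
                history = history))
  r_hi <- eval_beta(hi); note(hi, r_hi)
  if (abs(r_hi - target_r) <= tol)
    return(list(beta_a = hi, achieved_r = r_hi, n_eval = 2L,
                history = history))
  if (target_r < min(r_lo, r_hi) - tol || target_r > max(r_lo, r_hi) + tol)
    stop(sprintf(paste0("target correlation %.3f unreachable within ",
                        "beta_a bounds [%.2f, %.2f]: bracketing values ",
                        "%.3f and %.3f"),
                 target_r, lo, hi, r_lo, r_hi))
  best <- if (abs(r_lo - target_r) < abs(r_hi - target_r))
    list(beta_a = lo, r = r_lo) else list(beta_a = hi, r = r_hi)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r_mid <- eval_beta(mid); note(mid, r_mid)
    if (abs(r_mid - target_r) < abs(best$r - target_r))
      best <- list(beta_a = mid, r = r_mid)
    if (abs(r_mid - target_r) <= tol) break
    # correlation increases with beta_a
    if (r_mid < target_r) lo <- mid else hi <- mid
  }
  if (abs(best$r - target_r) > tol)
    warning(sprintf("calibration stopped at |r - target| = %.3f > tol",
                    abs(best$r - target_r)))
  list(beta_a = best$beta_a, achieved_r = best$r,
       n_eval = nrow(history), history = history)
}
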