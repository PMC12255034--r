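# End-to-end orchestration over a simulated WT/KO pair: simulate, scan,
# select methylation strata, build metaprofiles and ratios, integrate the
# layers, and emit a machine-readable report. Each stage writes its
# intermediate tables so any stage can be re-run from file.

#' Run the full pipeline on a simulated WT/KO pair
#'
#' Executes simulate -> PQS scan -> hyper/hypo selection -> anchored
#' matrices, profiles and density ratios -> joint-table integration
#' (Pearson, strata, per-chromosome KO/WT log2 ratios, MAnorm-style
#' non-differential ATAC peaks) -> DE filter and promoter-G4 linkage.
#' All stage outputs are written under `out_dir` as plain-text formats
#' (FASTA, BED, bedGraph, TSV) together with `report.json` and `run.log`.
#'
#' @param config a [sim_config()]; analysis settings (flank 1000, bin 10,
#'   methylation threshold 50, p < 0.05, |log2FC| > 1) can be overridden
#'   via `analysis`.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed governing every stage.
#' @param analysis named list of analysis overrides: `flank`, `bin`,
#'   `top_n`, `meth_threshold`, `p_max`, `lfc_min`, `pseudocount`,
#'   `m_cutoff`, `chrom_ratio_pseudo`.
#' @param write_outputs write stage files (default TRUE; FALSE keeps the
#'   run in memory, e.g. for calibration loops).
#' @return The report, invisibly a list with: `pqs_count`, `n_hyper`,
#'   `n_hypo`, profile-ratio ranges for PQS density and G4 signal,
#'   `pearson_r`, `strata`, `tests`, `chrom_log2_ratio`, `n_up`, `n_down`,
#'   `promoter_link` summary, `n_nondiff_atac`, and `config_hash`.
#' @export
run_all <- function(config, out_dir, seed, analysis = list(),
                    write_outputs = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  opts <- utils::modifyList(list(
    flank = 1000L, bin = 10L, top_n = 10000L, meth_threshold = 50,
    p_max = 0.05, lfc_min = 1, pseudocount = 1e-3, m_cutoff = 1,
    chrom_ratio_pseudo = 1), analysis)
  if (write_outputs && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  logf <- if (write_outputs) file.path(out_dir, "run.log") else NULL
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg)
    if (!is.null(logf)) cat(msg, "\n", file = logf, append = TRUE)
  }

  log_line("stage simulate: seed ", seed)
  pair <- simulate_pair(config, seed)
  sim <- pair$sim

  log_line("stage scan: canonical PQS scan over ",
           length(sim$genome), " chromosome(s)")
  pqs <- scan_genome_pqs(sim$genome)

  log_line("stage methylome: hyper/hypo transcript selection")
  sel <- suppressWarnings(select_hyper_hypo(
    sim$anchors, pair$wt$meth$calls, flank = opts$flank,
    top_n = opts$top_n))

  log_line("stage meta-signal: anchored matrices and ratios")
  g4_wt_bpm <- bpm_normalize(pair$wt$g4$track,
                             max(1, pair$wt$g4$total_reads))
  g4_ko_bpm <- bpm_normalize(pair$ko$g4$track,
                             max(1, pair$ko$g4$total_reads))
  igg_wt_bpm <- bpm_normalize(pair$wt$g4$igg,
                              max(1, pair$wt$g4$total_reads_igg))
  igg_ko_bpm <- bpm_normalize(pair$ko$g4$igg,
                              max(1, pair$ko$g4$total_reads_igg))
  g4_wt_bs <- subtract_background(g4_wt_bpm, igg_wt_bpm)
  g4_ko_bs <- subtract_background(g4_ko_bpm, igg_ko_bpm)

  anchors_of <- function(df) sim$anchors[
    sim$anchors$transcript_id %in% df$transcript_id, , drop = FALSE]
  hyper_anchors <- anchors_of(sel$hyper)
  hypo_anchors <- anchors_of(sel$hypo)
  mat_g4_hyper <- anchored_matrix(g4_wt_bpm, hyper_anchors,
                                  flank = opts$flank, bin = opts$bin)
  mat_g4_hypo <- anchored_matrix(g4_wt_bpm, hypo_anchors,
                                 flank = opts$flank, bin = opts$bin)
  mat_pqs_hyper <- pqs_density_matrix(pqs, hyper_anchors,
                                      flank = opts$flank, bin = opts$bin)
  mat_pqs_hypo <- pqs_density_matrix(pqs, hypo_anchors,
                                     flank = opts$flank, bin = opts$bin)
  ratio_g4 <- profile_ratio(mean_profile(mat_g4_hypo)$mean,
                            mean_profile(mat_g4_hyper)$mean,
                            pseudocount = opts$pseudocount,
                            flank = opts$flank, bin = opts$bin)
  ratio_pqs <- profile_ratio(mean_profile(mat_pqs_hypo)$mean,
                             mean_profile(mat_pqs_hyper)$mean,
                             pseudocount = opts$pseudocount,
                             flank = opts$flank, bin = opts$bin)

  log_line("stage integrate: joint table and strata")
  joint <- build_pqs_joint_table(pqs, pair$wt$g4$peaks, pair$wt$g4$track,
                                 pair$wt$atac$peaks, pair$wt$atac$track,
                                 pair$wt$meth$calls,
                                 meth_threshold = opts$meth_threshold)
  r <- tryCatch(pearson_g4_atac(joint), error = function(e) NA_real_)
  strata <- stratified_summary(joint)
  ratios <- chrom_log2_ratio(g4_ko_bs, g4_wt_bs,
                             pseudo = opts$chrom_ratio_pseudo)
  common <- pair$wt$atac$peaks[
    overlaps_any(pair$wt$atac$peaks, pair$ko$atac$peaks), , drop = FALSE]
  nondiff <- nondifferential_atac_peaks(
    common,
    mean_signal_batch(pair$wt$atac$track, common) *
      (common$end - common$start),
    mean_signal_batch(pair$ko$atac$track, common) *
      (common$end - common$start),
    m_cutoff = opts$m_cutoff)

  log_line("stage expression: DE filter and promoter linkage")
  deg <- de_filter(pair$expr$de, p_max = opts$p_max,
                   lfc_min = opts$lfc_min)
  mat_wt_all <- anchored_matrix(g4_wt_bpm, sim$anchors,
                                flank = opts$flank, bin = opts$bin)
  mat_ko_all <- anchored_matrix(g4_ko_bpm, sim$anchors,
                                flank = opts$flank, bin = opts$bin)
  link <- if (length(deg$up))
    promoter_g4_link(deg$up, mat_wt_all, mat_ko_all) else NULL

  report <- list(
    seed = seed,
    config_hash = config_hash(config),
    pqs_count = nrow(pqs),
    n_hyper = nrow(sel$hyper), n_hypo = nrow(sel$hypo),
    pqs_ratio = ratio_pqs[c("min_ratio", "max_ratio", "min_ratio_prox",
                            "max_ratio_prox", "mean_ratio_prox")],
    g4_ratio = ratio_g4[c("min_ratio", "max_ratio",
                          "min_ratio_prox", "max_ratio_prox")],
    pearson_r = r,
    strata = strata$strata, tests = strata$tests,
    chrom_log2_ratio = as.list(ratios),
    n_nondiff_atac = nrow(nondiff),
    n_up = length(deg$up), n_down = length(deg$down),
    promoter_link = if (is.null(link)) NULL else
      list(n_input = link$n_input, n_resolved = link$n_resolved,
           mean_delta = link$mean_delta, p_value = link$p_value))

  if (write_outputs) {
    log_line("writing stage outputs")
    seqs <- Biostrings::DNAStringSet(sim$genome)
    Biostrings::writeXStringSet(seqs, file.path(out_dir, "genome.fa"))
    write.table(sim$anchors, file.path(out_dir, "anchors.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_pqs_bed(pqs, file.path(out_dir, "pqs.bed"),
                  file.path(out_dir, "pqs.tsv"))
    write_cpg_calls(pair$wt$meth$calls, file.path(out_dir, "calls_wt.tsv"))
    write_cpg_calls(pair$ko$meth$calls, file.path(out_dir, "calls_ko.tsv"))
    write_bedgraph(pair$wt$g4$track, file.path(out_dir, "g4_wt.bedgraph"))
    write_bedgraph(pair$ko$g4$track, file.path(out_dir, "g4_ko.bedgraph"))
    write_bedgraph(pair$wt$g4$igg, file.path(out_dir, "igg_wt.bedgraph"))
    write_bedgraph(pair$wt$atac$track,
                   file.path(out_dir, "atac_wt.bedgraph"))
    write_bed(pair$wt$g4$peaks, file.path(out_dir, "g4_peaks_wt.bed"))
    write_bed(pair$wt$atac$peaks, file.path(out_dir, "atac_peaks_wt.bed"))
    write.table(joint, file.path(out_dir, "pqs_joint_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(strata$strata, file.path(out_dir, "strata.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(pair$expr$de, file.path(out_dir, "de_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_anchored_matrix(mat_g4_hypo,
                          file.path(out_dir, "matrix_g4_hypo.tsv.gz"))
    write_anchored_matrix(mat_g4_hyper,
                          file.path(out_dir, "matrix_g4_hyper.tsv.gz"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_line("done")
  }
  invisible(report)
}

# order-stable digest of the configuration (no external digest package:
# serialize deterministically and hash with a small rolling sum)
config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 15), collapse = ","), ""), collapse = ";")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
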