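# Joint annotation of PQSs across the G4, ATAC and methylation layers, and
# the downstream statistics: Pearson G4-ATAC coupling, the 2x2
# accessibility-by-methylation stratification, MAnorm-style selection of
# non-differential ATAC peaks, per-chromosome knockout/wildtype log2
# ratios, and the differential-expression filter with promoter-G4 linkage.

#' Build the per-PQS joint annotation table
#'
#' One row per PQS with mean G4 and ATAC signal over the PQS interval,
#' G4-peak and ATAC-peak (open chromatin) overlap flags, and the CpG
#' methylation state. The canonical filter — PQSs with a G4 peak and at
#' least one CpG — is applied when `filter = TRUE`; rows are ordered by
#' `(chrom, start, strand)`.
#'
#' @param pqs CpG-annotated PQS `data.frame` (see [annotate_cpg()]).
#' @param g4_peaks,atac_peaks interval `data.frame`s.
#' @param g4_track,atac_track [signal_track()]s.
#' @param calls a [cpg_calls()] table.
#' @param filter keep only PQSs with a G4 peak and `n_cpg >= 1`
#'   (default TRUE).
#' @param meth_threshold percent threshold for the high/low state
#'   (default 50, strict).
#' @param meth_mode `"mean"` or `"any"` (see [pqs_methylation_state()]).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `n_cpg`, `has_g4_peak`, `g4_signal`, `atac_signal`, `open`,
#'   `meth_level`, `meth_state`.
#' @export
build_pqs_joint_table <- function(pqs, g4_peaks, g4_track, atac_peaks,
                                  atac_track, calls, filter = TRUE,
                                  meth_threshold = 50,
                                  meth_mode = c("mean", "any")) {
  meth_mode <- match.arg(meth_mode)
  tbl <- pqs[order(pqs$chrom, pqs$start, pqs$strand),
             c("chrom", "start", "end", "strand", "n_cpg", "cpg_positions"),
             drop = FALSE]
  rownames(tbl) <- NULL
  iv <- genome_intervals(tbl$chrom, tbl$start, tbl$end)
  tbl$has_g4_peak <- overlaps_any(iv, g4_peaks)
  tbl$g4_signal <- mean_signal_batch(g4_track, iv)
  tbl$atac_signal <- mean_signal_batch(atac_track, iv)
  tbl$open <- overlaps_any(iv, atac_peaks)
  ms <- pqs_meth_levels(tbl, calls, meth_threshold, meth_mode)
  tbl$meth_level <- ms$level
  tbl$meth_state <- ms$state
  tbl$cpg_positions <- NULL
  if (filter) {
    tbl <- tbl[tbl$has_g4_peak & tbl$n_cpg >= 1L, , drop = FALSE]
    rownames(tbl) <- NULL
  }
  tbl
}

# mean covered-site level and state per PQS; a CpG dyad contributes the
# calls covering either strand position (plus C at p, minus C at p + 1)
pqs_meth_levels <- function(tbl, calls, threshold, mode) {
  n <- nrow(tbl)
  level <- rep(NA_real_, n)
  state <- rep("undefined", n)
  cov <- calls[calls$n_total > 0L, , drop = FALSE]
  has_cpg <- which(!is.na(tbl$n_cpg) & tbl$n_cpg > 0L)
  if (nrow(cov) && length(has_cpg)) {
    key <- paste0(cov$chrom, ":", cov$pos)
    lev <- site_methylation_level(cov$n_meth, cov$n_total)
    cpg <- strsplit(tbl$cpg_positions[has_cpg], ",", fixed = TRUE)
    row_i <- rep(has_cpg, lengths(cpg))
    pos <- as.integer(unlist(cpg))
    # a CpG dyad contributes the calls on either strand position
    q_row <- c(row_i, row_i)
    q_key <- paste0(tbl$chrom[c(row_i, row_i)], ":", c(pos, pos + 1L))
    hit <- match(q_key, key)
    ok <- !is.na(hit)
    if (any(ok)) {
      site_lev <- lev[hit[ok]]
      by_row <- split(site_lev, q_row[ok])
      idx <- as.integer(names(by_row))
      st <- lapply(by_row, pqs_methylation_state,
                   threshold_pct = threshold, mode = mode)
      level[idx] <- vapply(st, `[[`, 0, "mean_level")
      state[idx] <- vapply(st, `[[`, "", "state")
    }
  }
  list(level = level, state = state)
}

#' Pearson correlation between per-PQS G4 and ATAC signal
#'
#' @param table a joint table from [build_pqs_joint_table()].
#' @param log_transform apply `log2(1 + x)` to both signals first
#'   (default FALSE; raw signal).
#' @return The sample Pearson correlation coefficient.
#' @export
pearson_g4_atac <- function(table, log_transform = FALSE) {
  x <- table$g4_signal
  y <- table$atac_signal
  if (log_transform) {
    x <- log2(1 + x); y <- log2(1 + y)
  }
  if (length(x) < 3L) stop("need at least 3 PQSs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined")
  cor(x, y, method = "pearson")
}

#' Stratified G4-signal summary over accessibility and methylation
#'
#' The nine strata of the accessibility-by-methylation analysis: all PQSs,
#' open/closed chromatin (ATAC-peak overlap), hypo/hypermethylated (CpG
#' methylation at most / above 50 percent), and the four crosses. Rows
#' without a defined methylation state are excluded from methylation
#' strata. Pairwise Student's t tests compare open vs closed, hypo vs
#' hyper, and hypo vs hyper within open and within closed.
#'
#' @param table a joint table from [build_pqs_joint_table()].
#' @param var.equal classical equal-variance Student's t (default TRUE);
#'   FALSE gives Welch.
#' @param alternative passed to [stats::t.test()] (default two-sided).
#' @return A list: `strata` (per-stratum `n`, `mean`, `sem`) and `tests`
#'   (comparison, p-value; `NA` where a stratum is empty or too small).
#' @export
stratified_summary <- function(table, var.equal = TRUE,
                               alternative = "two.sided") {
  g <- table$g4_signal
  sets <- list(
    all = rep(TRUE, nrow(table)),
    open = table$open,
    closed = !table$open,
    hypo = table$meth_state == "low",
    hyper = table$meth_state == "high",
    open_hypo = table$open & table$meth_state == "low",
    open_hyper = table$open & table$meth_state == "high",
    closed_hypo = !table$open & table$meth_state == "low",
    closed_hyper = !table$open & table$meth_state == "high")
  strata <- data.frame(
    stratum = names(sets),
    n = vapply(sets, sum, 0L),
    mean = vapply(sets, function(k) if (any(k)) mean(g[k]) else NA_real_, 0),
    sem = vapply(sets, function(k) if (sum(k) > 1L)
      sd(g[k]) / sqrt(sum(k)) else NA_real_, 0),
    row.names = NULL)
  pair_p <- function(a, b) {
    if (sum(sets[[a]]) < 2L || sum(sets[[b]]) < 2L) return(NA_real_)
    tryCatch(t.test(g[sets[[a]]], g[sets[[b]]], var.equal = var.equal,
                    alternative = alternative)$p.value,
             error = function(e) NA_real_)  # e.g. zero variance
  }
  tests <- data.frame(
    comparison = c("open_vs_closed", "hypo_vs_hyper",
                   "open:hypo_vs_hyper", "closed:hypo_vs_hyper"),
    p_value = c(pair_p("open", "closed"), pair_p("hypo", "hyper"),
                pair_p("open_hypo", "open_hyper"),
                pair_p("closed_hypo", "closed_hyper")),
    row.names = NULL)
  list(strata = strata, tests = tests)
}

#' MAnorm-style selection of non-differential ATAC peaks
#'
#' For peaks common to two conditions, `M = log2((a + 1) / (b + 1))` is
#' rescaled by subtracting the median M (absorbing global depth
#' differences); peaks with `|M_rescaled| <= m_cutoff` are returned as
#' non-differential. A simplification of MAnorm's robust-regression model
#' to its median-shift essence.
#'
#' @param common_peaks interval `data.frame` of peaks present in both
#'   conditions.
#' @param counts_a,counts_b per-peak read counts in each condition.
#' @param m_cutoff retain peaks with `|M_rescaled|` at most this value
#'   (default 1).
#' @return The retained peaks, with `M_rescaled` attached.
#' @export
nondifferential_atac_peaks <- function(common_peaks, counts_a, counts_b,
                                       m_cutoff = 1) {
  if (!nrow(common_peaks)) {
    common_peaks$M_rescaled <- numeric()
    return(common_peaks)
  }
  if (length(counts_a) != nrow(common_peaks) ||
      length(counts_b) != nrow(common_peaks))
    stop("counts must align with common_peaks rows")
  m <- log2((counts_a + 1) / (counts_b + 1))
  m <- m - median(m)
  out <- common_peaks[abs(m) <= m_cutoff, , drop = FALSE]
  out$M_rescaled <- m[abs(m) <= m_cutoff]
  rownames(out) <- NULL
  out
}

#' Per-chromosome log2 signal ratio between two tracks
#'
#' For each chromosome present in either track,
#' `log2((sum_ko + pseudo) / (sum_wt + pseudo))` where the sums are total
#' signal mass (`value * length`). Intended for background-subtracted,
#' BPM-normalized tracks.
#'
#' @param track_ko,track_wt [signal_track()]s.
#' @param pseudo pseudocount on the mass scale (default 1).
#' @return Named numeric vector of per-chromosome log2 ratios.
#' @export
chrom_log2_ratio <- function(track_ko, track_wt, pseudo = 1) {
  mass <- function(tr) {
    if (!nrow(tr)) return(stats::setNames(numeric(), character()))
    vapply(split((tr$end - tr$start) * tr$value, tr$chrom), sum, 0)
  }
  mk <- mass(track_ko)
  mw <- mass(track_wt)
  chroms <- sort(union(names(mk), names(mw)))
  k <- ifelse(chroms %in% names(mk), mk[chroms], 0)
  w <- ifelse(chroms %in% names(mw), mw[chroms], 0)
  stats::setNames(log2((k + pseudo) / (w + pseudo)), chroms)
}

#' Differential-expression filter
#'
#' Strict inequalities: upregulated genes have `p < p_max` and
#' `log2fc > lfc_min`; downregulated `p < p_max` and `log2fc < -lfc_min`.
#' A gene at exactly `|log2fc| = lfc_min` is not differential.
#'
#' @param table `data.frame` with `gene_id`, `log2fc`, `p_value`.
#' @param p_max p-value cutoff (default 0.05).
#' @param lfc_min absolute log2 fold-change cutoff (default 1).
#' @return A list with character vectors `up` and `down`.
#' @export
de_filter <- function(table, p_max = 0.05, lfc_min = 1) {
  if (any(!is.finite(table$log2fc)))
    stop("log2fc must be finite")
  if (any(table$p_value < 0 | table$p_value > 1))
    stop("p_value must be in [0, 1]")
  sig <- table$p_value < p_max
  list(up = table$gene_id[sig & table$log2fc > lfc_min],
       down = table$gene_id[sig & table$log2fc < -lfc_min])
}

#' Promoter G4 change for a gene set between conditions
#'
#' For genes resolvable to transcript anchors, the promoter
#' (TSS +/- flank) mean G4 signal per condition is the row-mean of the
#' anchored matrix; the per-gene difference (KO - WT) is summarized with a
#' paired Student's t test. Genes with several transcripts use the first
#' anchor; genes with no anchor are dropped and counted.
#'
#' @param genes character vector of gene ids (e.g. upregulated DEGs).
#' @param matrix_wt,matrix_ko [anchored_matrix()]s over the same anchors.
#' @return A list: `per_gene` (gene, WT and KO promoter means, `delta`),
#'   `n_input`, `n_resolved`, `mean_delta`, `p_value` (paired t).
#' @export
promoter_g4_link <- function(genes, matrix_wt, matrix_ko) {
  if (!identical(matrix_wt$anchors$transcript_id,
                 matrix_ko$anchors$transcript_id))
    stop("anchor sets differ between conditions")
  anc <- matrix_wt$anchors
  idx <- match(genes, anc$gene_id)
  resolved <- !is.na(idx)
  if (!any(resolved)) stop("no gene resolvable to an anchored TSS")
  ri <- idx[resolved]
  wt <- rowMeans(matrix_wt$values)[ri]
  ko <- rowMeans(matrix_ko$values)[ri]
  per_gene <- data.frame(gene_id = genes[resolved], wt = wt, ko = ko,
                         delta = ko - wt, row.names = NULL)
  p <- if (nrow(per_gene) > 1L && sd(per_gene$delta) > 0)
    t.test(per_gene$ko, per_gene$wt, paired = TRUE)$p.value else NA_real_
  list(per_gene = per_gene, n_input = length(genes),
       n_resolved = sum(resolved), mean_delta = mean(per_gene$delta),
       p_value = p)
}

#' Fraction of peaks overlapping promoter windows
#'
#' Share of peaks with at least one base inside any TSS +/- flank window.
#'
#' @param peaks interval `data.frame`.
#' @param anchors a [transcript_anchors()] table.
#' @param flank promoter half-width in bp (default 1000).
#' @return A proportion in [0, 1].
#' @export
promoter_fraction <- function(peaks, anchors, flank = 1000L) {
  if (!nrow(peaks)) return(NA_real_)
  prom <- genome_intervals(anchors$chrom,
                           pmax(0L, anchors$tss - as.integer(flank)),
                           anchors$tss + as.integer(flank))
  mean(overlaps_any(peaks, prom))
}

#' Peak-set overlap counts (Venn-style)
#'
#' @param peaks_a,peaks_b interval `data.frame`s.
#' @return A list: `common_a` (A peaks overlapping B), `common_b`,
#'   `a_only`, `b_only`.
#' @export
peak_overlap_counts <- function(peaks_a, peaks_b) {
  fa <- overlaps_any(peaks_a, peaks_b)
  fb <- overlaps_any(peaks_b, peaks_a)
  list(common_a = sum(fa), common_b = sum(fb),
       a_only = sum(!fa), b_only = sum(!fb))
}
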