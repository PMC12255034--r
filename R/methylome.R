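# Per-site and windowed 5mC methylation levels from bisulfite calls, plus
# the rank-based hyper/hypomethylated transcript selection with per-gene
# deduplication. Calls have the methratio-style shape: one row per cytosine
# and strand with methylated and total read counts.

#' Construct a CpG call table
#'
#' @param chrom,pos chromosome and 0-based cytosine position.
#' @param strand `"+"` or `"-"`.
#' @param n_meth,n_total methylated and total valid read counts,
#'   `0 <= n_meth <= n_total`.
#' @return A `data.frame` with columns `chrom`, `pos`, `strand`, `n_meth`,
#'   `n_total`.
#' @export
cpg_calls <- function(chrom = character(), pos = integer(), strand = "+",
                      n_meth = integer(), n_total = integer()) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = as.character(strand),
                   n_meth = as.integer(n_meth),
                   n_total = as.integer(n_total), stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$pos < 0L)) stop("positions must be >= 0")
    if (any(df$n_meth < 0L | df$n_meth > df$n_total))
      stop("need 0 <= n_meth <= n_total")
    if (any(!df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  }
  df
}

#' Read methylation calls from TSV
#'
#' Expects columns `chrom`, `pos`, `strand`, `n_meth`, `n_total` (the
#' methratio.py column subset); positions are 0-based.
#'
#' @param path file path (plain or gzip).
#' @return A [cpg_calls()] table.
#' @export
read_cpg_calls <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  cpg_calls(df$chrom, df$pos, df$strand, df$n_meth, df$n_total)
}

#' Write methylation calls as TSV
#' @param calls a [cpg_calls()] table.
#' @param path output path.
#' @export
write_cpg_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-site methylation level (percent)
#'
#' `100 * n_meth / n_total`. Sites with zero coverage have no defined level
#' and must be excluded before calling (they are not 0%).
#'
#' @param n_meth,n_total methylated / total valid read counts (vectorized).
#' @return Percent methylation per site.
#' @export
site_methylation_level <- function(n_meth, n_total) {
  if (any(n_total <= 0L))
    stop("site methylation level is undefined for n_total = 0; ",
         "exclude uncovered sites first")
  if (any(n_meth < 0L | n_meth > n_total))
    stop("need 0 <= n_meth <= n_total")
  100 * n_meth / n_total
}

#' Windowed methylation level (percent)
#'
#' Unweighted mean of per-site levels of covered cytosines inside a region;
#' `NA` when fewer than `min_sites` covered sites fall in the window.
#'
#' @param calls a [cpg_calls()] table.
#' @param chrom,start,end window (0-based half-open).
#' @param min_sites minimum covered sites for a defined level (default 1).
#' @return Percent, or `NA` if undefined.
#' @export
window_methylation_level <- function(calls, chrom, start, end,
                                     min_sites = 1L) {
  windows_methylation_level(
    calls, genome_intervals(chrom, start, end), min_sites = min_sites)
}

#' Windowed methylation levels for many regions at once
#'
#' @param calls a [cpg_calls()] table.
#' @param regions interval `data.frame`.
#' @param min_sites minimum covered sites per window.
#' @return Numeric vector of percent levels (`NA` where undefined).
#' @export
windows_methylation_level <- function(calls, regions, min_sites = 1L) {
  n <- nrow(regions)
  out <- rep(NA_real_, n)
  if (!n) return(out)
  cov <- calls[calls$n_total > 0L, , drop = FALSE]
  if (!nrow(cov)) return(out)
  lev <- site_methylation_level(cov$n_meth, cov$n_total)
  q <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1L, regions$end))
  s <- GenomicRanges::GRanges(cov$chrom,
                              IRanges::IRanges(cov$pos + 1L, cov$pos + 1L))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE))
  if (!length(hits)) return(out)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  cnt <- tapply(lev[si], qi, length)
  mu <- tapply(lev[si], qi, mean)
  idx <- as.integer(names(mu))
  keep <- cnt >= min_sites
  out[idx[keep]] <- as.numeric(mu[keep])
  out
}

#' Construct a transcript anchor table
#'
#' @param gene_id,transcript_id identifiers (`transcript_id` unique).
#' @param chrom chromosome names.
#' @param tss 0-based transcription start site positions.
#' @param strand `"+"` or `"-"`.
#' @return A `data.frame` with one row per transcript.
#' @export
transcript_anchors <- function(gene_id, transcript_id, chrom, tss, strand) {
  df <- data.frame(gene_id = as.character(gene_id),
                   transcript_id = as.character(transcript_id),
                   chrom = as.character(chrom), tss = as.integer(tss),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (anyDuplicated(df$transcript_id))
      stop("transcript_id values must be unique")
    if (any(df$tss < 0L)) stop("tss must be >= 0")
    if (any(!df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  }
  df
}

#' Select hyper- and hypomethylated transcripts around TSSs
#'
#' Ranks transcripts by mean methylation over `[tss - flank, tss + flank)`,
#' takes the `top_n` highest (hyper) and `top_n` lowest (hypo), then within
#' each list keeps, per gene, only the most extreme-ranked transcript.
#' Ties are broken by lexicographic `transcript_id`.
#'
#' @param anchors a [transcript_anchors()] table.
#' @param calls a [cpg_calls()] table.
#' @param flank half-window around the TSS in bp (default 1000).
#' @param top_n transcripts per tail before deduplication (default 10000).
#' @param min_sites minimum covered CpGs for a defined window level.
#' @return A list with `hyper` and `hypo` anchor tables (each with a
#'   `level` column), and `levels`, the per-transcript window levels.
#' @export
select_hyper_hypo <- function(anchors, calls, flank = 1000L,
                              top_n = 10000L, min_sites = 1L) {
  win <- genome_intervals(anchors$chrom,
                          pmax(0L, anchors$tss - as.integer(flank)),
                          anchors$tss + as.integer(flank))
  lev <- windows_methylation_level(calls, win, min_sites = min_sites)
  rankable <- which(!is.na(lev))
  if (!length(rankable))
    stop("no transcript has a defined methylation level")
  if (length(rankable) < 2L * top_n) {
    warning("only ", length(rankable), " rankable transcripts for 2 x ",
            top_n, " requested; taking all (", length(rankable) %/% 2L,
            " per tail)")
    top_n <- length(rankable) %/% 2L
  }
  a <- anchors[rankable, , drop = FALSE]
  a$level <- lev[rankable]
  hyper_rank <- a[order(-a$level, a$transcript_id), , drop = FALSE]
  hypo_rank <- a[order(a$level, a$transcript_id), , drop = FALSE]
  dedup <- function(ranked) {
    sel <- ranked[seq_len(top_n), , drop = FALSE]
    sel[!duplicated(sel$gene_id), , drop = FALSE]
  }
  hyper <- dedup(hyper_rank)
  hypo <- dedup(hypo_rank)
  rownames(hyper) <- rownames(hypo) <- NULL
  list(hyper = hyper, hypo = hypo,
       levels = stats::setNames(lev, anchors$transcript_id))
}

#' Classify a PQS's methylation state from its CpG site levels
#'
#' A PQS is high-methylation when its CpG methylation exceeds 50 percent
#' (strictly). Under `mode = "mean"` the mean site level over the PQS's
#' covered CpGs is compared to the threshold; `mode = "any"` classifies
#' high when any single covered site exceeds it.
#'
#' @param site_levels percent levels of the PQS's covered CpG sites
#'   (may be empty).
#' @param threshold_pct classification threshold (default 50).
#' @param mode `"mean"` (default) or `"any"`.
#' @return A list with `state` (`"high"`, `"low"` or `"undefined"`) and
#'   `mean_level` (`NA` when undefined).
#' @export
pqs_methylation_state <- function(site_levels, threshold_pct = 50,
                                  mode = c("mean", "any")) {
  mode <- match.arg(mode)
  site_levels <- site_levels[!is.na(site_levels)]
  if (!length(site_levels))
    return(list(state = "undefined", mean_level = NA_real_))
  mu <- mean(site_levels)
  high <- if (mode == "mean") mu > threshold_pct else
    any(site_levels > threshold_pct)
  list(state = if (high) "high" else "low", mean_level = mu)
}
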