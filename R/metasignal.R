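# TSS-anchored binned signal matrices and derived statistics: mean
# profiles with SEM, heatmap row ordering, and the hypo/hyper density-ratio
# statistic. Windows are TSS +/- flank split into fixed-width bins;
# minus-strand rows are orientation-flipped so column 1 is always the far
# upstream bin.

#' Build a TSS-anchored binned signal matrix
#'
#' Each row is one anchor's window `[tss - flank, tss + flank)` split into
#' `2 * flank / bin` bins; each cell is the base-weighted mean signal over
#' that bin. Anchors whose window would run off the chromosome start are
#' dropped with a warning (no zero-padding).
#'
#' @param track a [signal_track()].
#' @param anchors a [transcript_anchors()] table.
#' @param flank half-window in bp (default 1000).
#' @param bin bin width in bp (default 10; must divide `2 * flank`).
#' @return A list of class `anchored_matrix`: `anchors`, `flank`, `bin`,
#'   and `values` (anchors x bins numeric matrix).
#' @export
anchored_matrix <- function(track, anchors, flank = 1000L, bin = 10L) {
  flank <- as.integer(flank); bin <- as.integer(bin)
  if ((2L * flank) %% bin != 0L) stop("bin must divide 2 * flank")
  keep <- anchors$tss - flank >= 0L
  if (any(!keep)) {
    warning(sum(!keep), " anchor(s) dropped: window clipped at contig edge")
    anchors <- anchors[keep, , drop = FALSE]
  }
  nb <- 2L * flank %/% bin
  n <- nrow(anchors)
  if (!n) {
    return(structure(list(anchors = anchors, flank = flank, bin = bin,
                          values = matrix(numeric(), 0L, nb)),
                     class = "anchored_matrix"))
  }
  starts <- rep(anchors$tss - flank, each = nb) +
    rep.int(seq_len(nb) - 1L, n) * bin
  regions <- genome_intervals(rep(anchors$chrom, each = nb),
                              starts, starts + bin)
  vals <- mean_signal_batch(track, regions)
  mat <- matrix(vals, nrow = n, ncol = nb, byrow = TRUE)
  flip <- anchors$strand == "-"
  if (any(flip)) mat[flip, ] <- mat[flip, rev(seq_len(nb)), drop = FALSE]
  rownames(mat) <- anchors$transcript_id
  structure(list(anchors = anchors, flank = flank, bin = bin, values = mat),
            class = "anchored_matrix")
}

#' Build a TSS-anchored PQS density matrix
#'
#' Cell value = number of PQS bases overlapping the bin divided by the bin
#' width; plus- and minus-strand PQSs are pooled (densities add).
#'
#' @param pqs PQS `data.frame` (intervals used; strands pooled).
#' @inheritParams anchored_matrix
#' @return An `anchored_matrix` of per-bin PQS base density.
#' @export
pqs_density_matrix <- function(pqs, anchors, flank = 1000L, bin = 10L) {
  # base-coverage track counting overlapping PQSs per base, strands pooled
  cov <- pqs_base_coverage(pqs)
  anchored_matrix(cov, anchors, flank = flank, bin = bin)
}

# piecewise-constant track of per-base PQS counts (strands pooled)
pqs_base_coverage <- function(pqs) {
  if (!nrow(pqs)) return(signal_track())
  pieces <- lapply(unique(pqs$chrom), function(chr) {
    p <- pqs[pqs$chrom == chr, , drop = FALSE]
    cov <- IRanges::coverage(IRanges::IRanges(p$start + 1L, p$end))
    ends <- cumsum(S4Vectors::runLength(cov))
    starts <- ends - S4Vectors::runLength(cov)   # back to 0-based
    val <- S4Vectors::runValue(cov)
    keep <- val > 0
    data.frame(chrom = chr, start = starts[keep], end = ends[keep],
               value = val[keep], stringsAsFactors = FALSE)
  })
  as_signal_track(do.call(rbind, pieces))
}

#' Column-wise mean profile with SEM
#'
#' @param am an [anchored_matrix()].
#' @return A `data.frame` with one row per bin: `bin_start` (bp relative to
#'   the anchor), `mean`, `sem` (`sd / sqrt(n)`).
#' @export
mean_profile <- function(am) {
  v <- am$values
  if (!nrow(v)) stop("cannot profile an empty matrix")
  mu <- colMeans(v)
  s <- if (nrow(v) > 1L) apply(v, 2L, sd) / sqrt(nrow(v)) else
    rep(NA_real_, ncol(v))
  data.frame(bin_start = seq(-am$flank, am$flank - am$bin, by = am$bin),
             mean = mu, sem = s, row.names = NULL)
}

#' Reorder matrix rows by decreasing row-mean of a key matrix
#'
#' The usual heatmap convention: rows sorted by decreasing mean of a key
#' signal (e.g. WGBS); ties keep their original order (stable sort).
#'
#' @param am matrix to reorder.
#' @param key_am matrix providing the ordering key; must have identical
#'   anchors in identical order.
#' @return The reordered `anchored_matrix`.
#' @export
order_rows_by <- function(am, key_am) {
  if (!identical(am$anchors$transcript_id, key_am$anchors$transcript_id))
    stop("anchor sets differ between matrix and key")
  o <- order(-rowMeans(key_am$values))
  am$anchors <- am$anchors[o, , drop = FALSE]
  am$values <- am$values[o, , drop = FALSE]
  am
}

#' Per-bin hypo/hyper profile ratio
#'
#' Element-wise `(hypo + pseudocount) / (hyper + pseudocount)` over two
#' mean profiles on the same bin grid, with ratio ranges reported both over
#' all bins and over the TSS-proximal bins (within `prox_bp` of the
#' anchor).
#'
#' @param profile_hypo,profile_hyper numeric per-bin mean profiles.
#' @param pseudocount added to both numerator and denominator
#'   (default 1e-3 on profile units).
#' @param flank,bin the grid geometry (for locating TSS-proximal bins).
#' @param prox_bp half-width of the TSS-proximal window (default 200).
#' @return A list: `ratio` (per bin), `min_ratio`, `max_ratio` (all bins),
#'   `min_ratio_prox`, `max_ratio_prox` (TSS-proximal bins), `mean_ratio`
#'   and `mean_ratio_prox` (ratio of window-aggregated profile means, the
#'   steadier statistic for sparse densities), and `prox_bins`.
#' @export
profile_ratio <- function(profile_hypo, profile_hyper, pseudocount = 1e-3,
                          flank = 1000L, bin = 10L, prox_bp = 200L) {
  if (length(profile_hypo) != length(profile_hyper))
    stop("profiles must share one bin grid")
  r <- (profile_hypo + pseudocount) / (profile_hyper + pseudocount)
  bin_start <- seq(-flank, flank - bin, by = bin)
  prox <- which(bin_start >= -prox_bp & bin_start + bin <= prox_bp)
  agg <- function(i) (mean(profile_hypo[i]) + pseudocount) /
    (mean(profile_hyper[i]) + pseudocount)
  list(ratio = r, min_ratio = min(r), max_ratio = max(r),
       min_ratio_prox = if (length(prox)) min(r[prox]) else NA_real_,
       max_ratio_prox = if (length(prox)) max(r[prox]) else NA_real_,
       mean_ratio = agg(seq_along(r)),
       mean_ratio_prox = if (length(prox)) agg(prox) else NA_real_,
       prox_bins = prox)
}

#' Write an anchored matrix as (optionally gzipped) TSV
#'
#' One header line records the geometry; rows are anchors.
#'
#' @param am an [anchored_matrix()].
#' @param path output path (`.gz` for gzip).
#' @export
write_anchored_matrix <- function(am, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# anchors=%d flank=%d bin=%d", nrow(am$values),
                     am$flank, am$bin), con)
  df <- data.frame(transcript_id = am$anchors$transcript_id, am$values,
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
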