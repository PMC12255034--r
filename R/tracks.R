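#' @importFrom stats median rbeta rbinom rlnorm rnbinom rpois runif sd t.test cor plogis
#' @importFrom utils read.table write.table
NULL

# Coordinates are 0-based half-open ([start, end)) everywhere, matching BED
# and bedGraph. Readers that accept 1-based input must convert at the
# boundary and say so.

#' Construct a genomic interval table
#'
#' The basic record underlying peaks, PQSs, promoter windows and anchors:
#' one row per interval with 0-based half-open coordinates.
#'
#' @param chrom character vector of chromosome names (non-empty).
#' @param start,end integer vectors, `0 <= start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` (recycled).
#' @param name,score optional per-interval annotation.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
genome_intervals <- function(chrom, start, end, strand = ".", name = ".",
                             score = 0) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(chrom) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be integers")
  if (any(start < 0L) || any(start >= end))
    stop("intervals require 0 <= start < end")
  if (any(!nzchar(chrom)))
    stop("chrom names must be non-empty")
  if (any(!strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  data.frame(chrom = chrom, start = start, end = end,
             name = as.character(name), score = as.numeric(score),
             strand = as.character(strand), stringsAsFactors = FALSE)
}

#' Construct a signal track
#'
#' A sparse run-length coverage track: per chromosome, sorted, disjoint runs
#' of constant non-negative signal. Uncovered bases read as 0 (the bedGraph
#' sparse convention).
#'
#' @param chrom,start,end run coordinates (0-based half-open).
#' @param value finite, non-negative signal per run.
#' @param drop_zero drop zero-valued runs (default TRUE; they are implicit).
#' @return A `data.frame` of class `signal_track` with columns `chrom`,
#'   `start`, `end`, `value`, sorted by `(chrom, start)`.
#' @export
signal_track <- function(chrom = character(), start = integer(),
                         end = integer(), value = numeric(),
                         drop_zero = TRUE) {
  tr <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (nrow(tr)) {
    if (any(tr$start < 0L) || any(tr$start >= tr$end))
      stop("signal runs require 0 <= start < end")
    if (any(!is.finite(tr$value)) || any(tr$value < 0))
      stop("signal values must be finite and >= 0")
    tr <- tr[order(tr$chrom, tr$start), , drop = FALSE]
    prev_end <- c(-1L, tr$end[-nrow(tr)])
    same <- c(FALSE, tr$chrom[-1L] == tr$chrom[-nrow(tr)])
    if (any(same & tr$start < prev_end))
      stop("signal runs overlap within a chromosome")
    if (drop_zero) tr <- tr[tr$value > 0, , drop = FALSE]
    rownames(tr) <- NULL
  }
  class(tr) <- c("signal_track", "data.frame")
  tr
}

as_signal_track <- function(df, drop_zero = TRUE) {
  signal_track(df$chrom, df$start, df$end, df$value, drop_zero = drop_zero)
}

#' Read a BED file of intervals/peaks
#'
#' Accepts BED3+ (tab-separated); `track`/`browser`/`#` header lines are
#' skipped. Reads plain or gzip files.
#'
#' @param path file path.
#' @return Interval `data.frame` as from [genome_intervals()].
#' @export
read_bed <- function(path) {
  lines <- read_text_lines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) return(genome_intervals(character(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L))
    stop("BED parse error at line ", lineno[which(ncol < 3L)[1L]],
         ": fewer than 3 columns")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start < 0L | start >= end
  if (any(bad))
    stop("BED parse error at line ", lineno[which(bad)[1L]],
         ": invalid interval coordinates")
  name <- ifelse(ncol >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), ".")
  score <- ifelse(ncol >= 5L,
                  suppressWarnings(as.numeric(vapply(fields, function(f) f[min(5L, length(f))], ""))),
                  0)
  score[is.na(score)] <- 0
  strand <- ifelse(ncol >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""), ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  genome_intervals(chrom, start, end, strand = strand, name = name,
                   score = score)
}

#' Write intervals as BED6
#' @param x interval `data.frame`.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  df <- data.frame(x$chrom, x$start, x$end,
                   if (is.null(x$name)) "." else x$name,
                   if (is.null(x$score)) 0 else x$score,
                   if (is.null(x$strand)) "." else x$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a 4-column bedGraph signal track
#'
#' Runs may arrive unsorted; overlapping runs and negative values are
#' rejected. Reads plain or gzip files.
#'
#' @param path file path.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path) {
  lines <- read_text_lines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) return(signal_track())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L))
    stop("bedGraph parse error at line ", lineno[which(lengths(fields) < 4L)[1L]],
         ": fewer than 4 columns")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
  bad <- is.na(start) | is.na(end) | is.na(value) | start < 0L | start >= end
  if (any(bad))
    stop("bedGraph parse error at line ", lineno[which(bad)[1L]])
  if (any(value < 0))
    stop("bedGraph parse error at line ", lineno[which(value < 0)[1L]],
         ": negative value")
  signal_track(chrom, start, end, value, drop_zero = FALSE)
}

#' Write a signal track as bedGraph
#' @param track a [signal_track()].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  write.table(data.frame(track$chrom, track$start, track$end, track$value),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rt")  # transparently reads plain text too
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Bins-per-million (BPM) normalization
#'
#' Rescales coverage so values are on a per-million-mapped-reads scale:
#' every run value is multiplied by `1e6 / total_mapped_reads`.
#'
#' @param track a [signal_track()].
#' @param total_mapped_reads positive library size.
#' @return Rescaled [signal_track()].
#' @export
bpm_normalize <- function(track, total_mapped_reads) {
  if (!is.numeric(total_mapped_reads) || length(total_mapped_reads) != 1L ||
      is.na(total_mapped_reads) || total_mapped_reads <= 0)
    stop("total_mapped_reads must be a single positive number")
  track$value <- track$value * 1e6 / total_mapped_reads
  track
}

#' Subtract a background track (IgG) from a signal track
#'
#' Per-base floored difference `max(0, signal - background)`; regions absent
#' from the background count as 0.
#'
#' @param signal,background [signal_track()]s on the same scale.
#' @return A [signal_track()].
#' @export
subtract_background <- function(signal, background) {
  if (!nrow(background)) return(signal)
  if (!nrow(signal)) return(signal)
  pieces <- lapply(unique(signal$chrom), function(chr) {
    s <- signal[signal$chrom == chr, , drop = FALSE]
    b <- background[background$chrom == chr, , drop = FALSE]
    if (!nrow(b)) return(s[, c("chrom", "start", "end", "value")])
    bounds <- sort(unique(c(s$start, s$end, b$start, b$end)))
    lo <- bounds[-length(bounds)]
    hi <- bounds[-1L]
    vs <- runs_value_at(s, lo)
    vb <- runs_value_at(b, lo)
    v <- pmax(0, vs - vb)
    data.frame(chrom = chr, start = lo, end = hi, value = v,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- merge_equal_runs(out[out$value > 0, , drop = FALSE])
  as_signal_track(out)
}

# value of sorted disjoint runs at positions (left edges of query pieces)
runs_value_at <- function(runs, pos) {
  if (!nrow(runs)) return(numeric(length(pos)))
  idx <- findInterval(pos, runs$start)
  v <- numeric(length(pos))
  ok <- idx >= 1L
  ok[ok] <- pos[ok] < runs$end[idx[ok]]
  v[ok] <- runs$value[idx[ok]]
  v
}

merge_equal_runs <- function(df) {
  if (nrow(df) < 2L) return(df)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  n <- nrow(df)
  joinable <- c(FALSE, df$chrom[-1L] == df$chrom[-n] &
                  df$start[-1L] == df$end[-n] &
                  df$value[-1L] == df$value[-n])
  grp <- cumsum(!joinable)
  data.frame(chrom = df$chrom[!joinable],
             start = df$start[!joinable],
             end = as.integer(tapply(df$end, grp, max)),
             value = df$value[!joinable], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Base-weighted mean signal over a region
#'
#' Uncovered bases contribute 0, so the mean is the covered signal mass
#' divided by the region width.
#'
#' @param track a [signal_track()].
#' @param chrom,start,end region (0-based half-open).
#' @return A single number.
#' @export
mean_signal <- function(track, chrom, start, end) {
  mean_signal_batch(track, genome_intervals(chrom, start, end))
}

#' Mean signal over many regions at once
#'
#' @param track a [signal_track()].
#' @param regions interval `data.frame`.
#' @return Numeric vector, one base-weighted mean per region row.
#' @export
mean_signal_batch <- function(track, regions) {
  n <- nrow(regions)
  if (n == 0L) return(numeric())
  out <- numeric(n)
  if (!nrow(track)) return(out)
  q <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1L, regions$end))
  s <- GenomicRanges::GRanges(track$chrom,
                              IRanges::IRanges(track$start + 1L, track$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE))
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    w <- pmin(regions$end[qi], track$end[si]) -
      pmax(regions$start[qi], track$start[si])
    mass <- tapply(w * track$value[si], qi, sum)
    out[as.integer(names(mass))] <- as.numeric(mass)
  }
  out / (regions$end - regions$start)
}

#' Flag query intervals that share at least one base with a subject set
#'
#' Strand is ignored; half-open adjacency does not count as overlap.
#'
#' @param query,subject interval `data.frame`s.
#' @return Logical vector, one flag per query row.
#' @export
overlaps_any <- function(query, subject) {
  if (!nrow(query)) return(logical())
  if (!nrow(subject)) return(rep(FALSE, nrow(query)))
  q <- GenomicRanges::GRanges(query$chrom,
                              IRanges::IRanges(query$start + 1L, query$end))
  s <- GenomicRanges::GRanges(subject$chrom,
                              IRanges::IRanges(subject$start + 1L, subject$end))
  suppressWarnings(
    GenomicRanges::countOverlaps(q, s, ignore.strand = TRUE)) > 0L
}

#' Threshold-based peak caller (plumbing)
#'
#' A deliberately simple caller for synthetic tracks: maximal stretches with
#' signal at or above `threshold`, merged across gaps of at most `merge_gap`
#' bases, then filtered to a minimum length. Not a statistical peak caller.
#'
#' @param track a [signal_track()].
#' @param threshold positive signal cutoff.
#' @param min_len minimum peak width in bp.
#' @param merge_gap maximum gap (bp) bridged when merging adjacent stretches.
#' @return Interval `data.frame` of peaks with `score` = mean signal.
#' @export
call_peaks_threshold <- function(track, threshold, min_len = 1L,
                                 merge_gap = 0L) {
  if (threshold <= 0) stop("threshold must be > 0")
  empty <- genome_intervals(character(), integer(), integer())
  if (!nrow(track)) return(empty)
  above <- track[track$value >= threshold, , drop = FALSE]
  if (!nrow(above)) return(empty)
  pieces <- lapply(unique(above$chrom), function(chr) {
    a <- above[above$chrom == chr, , drop = FALSE]
    n <- nrow(a)
    new_peak <- c(TRUE, a$start[-1L] - a$end[-n] > merge_gap)
    grp <- cumsum(new_peak)
    data.frame(chrom = chr,
               start = tapply(a$start, grp, min),
               end = tapply(a$end, grp, max),
               stringsAsFactors = FALSE)
  })
  pk <- do.call(rbind, pieces)
  pk <- pk[pk$end - pk$start >= min_len, , drop = FALSE]
  if (!nrow(pk)) return(empty)
  out <- genome_intervals(pk$chrom, pk$start, pk$end,
                          name = sprintf("peak_%d", seq_len(nrow(pk))))
  out$score <- mean_signal_batch(track, out)
  out
}
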