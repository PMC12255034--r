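# Canonical PQS detection: G{3+} (N{1-12} G{3+}) x3, the pqsfinder
# parameterization run_min_len = 3, loop_min_len = 1, loop_max_len = 12,
# max_defects = 0, which reduces detection to the canonical motif. Scoring
# is not reproduced; among overlapping candidates the leftmost-starting,
# then longest, match is kept, with G-tracts taken greedily maximal.

#' Canonical PQS scan parameters
#'
#' @param run_min_len minimum G-tract length (default 3).
#' @param loop_min_len,loop_max_len loop length bounds (defaults 1 and 12).
#' @param n_runs number of G-tracts (default 4; three loops).
#' @return A list of class `pqs_params`.
#' @export
pqs_params <- function(run_min_len = 3L, loop_min_len = 1L,
                       loop_max_len = 12L, n_runs = 4L) {
  run_min_len <- as.integer(run_min_len)
  loop_min_len <- as.integer(loop_min_len)
  loop_max_len <- as.integer(loop_max_len)
  n_runs <- as.integer(n_runs)
  if (run_min_len < 2L) stop("run_min_len must be >= 2")
  if (loop_min_len < 1L || loop_min_len > loop_max_len)
    stop("need 0 < loop_min_len <= loop_max_len")
  if (n_runs < 2L) stop("n_runs must be >= 2")
  structure(list(run_min_len = run_min_len, loop_min_len = loop_min_len,
                 loop_max_len = loop_max_len, n_runs = n_runs),
            class = "pqs_params")
}

#' Scan a sequence for canonical PQSs on both strands
#'
#' Finds maximal, non-overlapping canonical PQSs per strand (strands are
#' scanned independently; plus/minus PQSs may overlap). Minus-strand PQSs
#' are C-run motifs on the plus strand, located by scanning the reverse
#' complement. Selection is greedy: leftmost-starting candidate first, and
#' at each start the longest admissible match.
#'
#' @param sequence a single string over A/C/G/T/N (case-insensitive).
#' @param chrom chromosome name attached to the records.
#' @param params a [pqs_params()] object.
#' @return A `data.frame`, one row per PQS: `chrom`, `start`, `end`,
#'   `strand`, `sequence` (plus-strand letters), `tract_starts` and
#'   `loop_lengths` (comma-separated, offsets on the PQS strand's own
#'   5'->3' sequence), `n_cpg`, `cpg_positions` (plus-strand genomic
#'   positions of CpG cytosines; filled by [annotate_cpg()]).
#' @export
scan_canonical_pqs <- function(sequence, chrom = "chr1",
                               params = pqs_params()) {
  seq_up <- toupper(sequence)
  if (grepl("[^ACGTN]", seq_up))
    stop("sequence contains characters outside A/C/G/T/N")
  L <- nchar(seq_up)
  plus <- find_pqs_one_strand(seq_up, params)
  rc <- revcomp(seq_up)
  minus_rc <- find_pqs_one_strand(rc, params)
  rows <- list()
  if (nrow(plus)) {
    rows[[1L]] <- data.frame(
      chrom = chrom, start = plus$start, end = plus$end, strand = "+",
      sequence = substring(seq_up, plus$start + 1L, plus$end),
      tract_starts = plus$tract_starts, loop_lengths = plus$loop_lengths,
      stringsAsFactors = FALSE)
  }
  if (nrow(minus_rc)) {
    # map reverse-complement coordinates back to the plus strand
    st <- L - minus_rc$end
    en <- L - minus_rc$start
    rows[[2L]] <- data.frame(
      chrom = chrom, start = st, end = en, strand = "-",
      sequence = substring(seq_up, st + 1L, en),
      tract_starts = minus_rc$tract_starts,
      loop_lengths = minus_rc$loop_lengths, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), sequence = character(),
               tract_starts = character(), loop_lengths = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$n_cpg <- rep(NA_integer_, nrow(out))
  out$cpg_positions <- rep(NA_character_, nrow(out))
  out
}

# One-strand scan. Returns start/end (0-based half-open, scanned-strand
# coordinates) plus the tract/loop decomposition achieving the longest
# match (longest tract first, then shortest loop).
find_pqs_one_strand <- function(s, params) {
  empty <- data.frame(start = integer(), end = integer(),
                      tract_starts = character(), loop_lengths = character(),
                      stringsAsFactors = FALSE)
  rmin <- params$run_min_len
  lmin <- params$loop_min_len
  lmax <- params$loop_max_len
  k <- params$n_runs
  m <- gregexpr(sprintf("G{%d,}", rmin), s, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty)
  run_start <- as.integer(m) - 1L               # 0-based
  run_len <- attr(m, "match.length")
  run_end <- run_start + run_len
  nr <- length(run_start)

  # cluster runs whose gaps could be bridged by loops; a cluster must be
  # able to host k tracts (long runs can be split into tract-loop-tract)
  gap <- c(Inf, run_start[-1L] - run_end[-nr])
  cluster <- cumsum(gap > lmax)
  capacity <- (run_len + lmin) %/% (rmin + lmin)
  hits <- list()
  for (idx in unname(split(seq_len(nr), cluster))) {
    if (sum(capacity[idx]) < k) next
    hits[[length(hits) + 1L]] <-
      scan_cluster(run_start[idx], run_end[idx], rmin, lmin, lmax, k)
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  if (!nrow(out)) return(empty)
  out
}

# Greedy maximal matching within one cluster of G-runs.
scan_cluster <- function(rs, re, rmin, lmin, lmax, k) {
  memo <- new.env(parent = emptyenv())
  # G positions in this cluster: run lookup
  run_len_at <- function(p) {
    i <- findInterval(p, rs)
    if (i < 1L || p >= re[i]) return(0L)
    re[i] - p
  }
  # longest end of a chain of `need` tracts whose first tract starts at p
  longest <- function(p, need) {
    key <- paste0(p, "_", need)
    if (!is.null(v <- memo[[key]])) return(v)
    rl <- run_len_at(p)
    best <- -1L
    if (rl >= rmin) {
      if (need == 1L) {
        best <- p + rl                      # greedy-maximal final tract
      } else {
        for (t in rmin:rl) {
          for (l in lmin:lmax) {
            q <- p + t + l
            if (run_len_at(q) >= rmin) {
              e <- longest(q, need - 1L)
              if (e > best) best <- e
            }
          }
        }
      }
    }
    memo[[key]] <- best
    best
  }
  # recover one decomposition for the selected match: longest tract, then
  # shortest loop, consistent with reaching `target_end`
  decompose <- function(p, need, target_end) {
    rl <- run_len_at(p)
    if (need == 1L) return(list(tracts = target_end - p, loops = integer()))
    for (t in rev(rmin:rl)) {
      for (l in lmin:lmax) {
        q <- p + t + l
        if (run_len_at(q) >= rmin && longest(q, need - 1L) == target_end) {
          rest <- decompose(q, need - 1L, target_end)
          return(list(tracts = c(t, rest$tracts), loops = c(l, rest$loops)))
        }
      }
    }
    stop("internal error: decomposition not found")
  }
  starts <- integer(); ends <- integer(); tl <- character(); ll <- character()
  cur <- -1L
  for (p in rs) {
    if (p < cur) next
    e <- longest(p, k)
    if (e > 0L) {
      d <- decompose(p, k, e)
      starts <- c(starts, p); ends <- c(ends, e)
      tract_pos <- p + cumsum(c(0L, d$tracts[-k] + d$loops)) - p
      tl <- c(tl, paste(tract_pos, collapse = ","))
      ll <- c(ll, paste(d$loops, collapse = ","))
      cur <- e
    }
  }
  data.frame(start = starts, end = ends, tract_starts = tl,
             loop_lengths = ll, stringsAsFactors = FALSE)
}

#' Reverse complement of a DNA string
#' @param s a single DNA string (A/C/G/T/N).
#' @return The reverse complement string.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Scan a whole genome (set of chromosome sequences) for canonical PQSs
#'
#' @param genome named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param params a [pqs_params()] object.
#' @param annotate_cpgs also fill CpG annotation columns (default TRUE).
#' @return Combined PQS `data.frame` (see [scan_canonical_pqs()]).
#' @export
scan_genome_pqs <- function(genome, params = pqs_params(),
                            annotate_cpgs = TRUE) {
  if (inherits(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  res <- lapply(names(genome), function(chr) {
    scan_canonical_pqs(genome[[chr]], chrom = chr, params = params)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (annotate_cpgs && nrow(out)) out <- annotate_cpg(out, genome)
  out
}

#' Annotate PQSs with the CpG dinucleotides they contain
#'
#' CpG is strand-symmetric; each dinucleotide is counted once, by the
#' plus-strand genomic position of its C.
#'
#' @param pqs PQS `data.frame` from [scan_canonical_pqs()].
#' @param genome named character vector of chromosome sequences covering
#'   the PQS intervals.
#' @return The PQS table with `n_cpg` and `cpg_positions` filled.
#' @export
annotate_cpg <- function(pqs, genome) {
  if (!nrow(pqs)) return(pqs)
  genome <- lapply(genome, toupper)
  for (i in seq_len(nrow(pqs))) {
    seqi <- substring(genome[[pqs$chrom[i]]],
                      pqs$start[i] + 1L, pqs$end[i])
    m <- gregexpr("CG", seqi, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) {
      pqs$n_cpg[i] <- 0L
      pqs$cpg_positions[i] <- ""
    } else {
      pos <- pqs$start[i] + as.integer(m) - 1L
      pqs$n_cpg[i] <- length(pos)
      pqs$cpg_positions[i] <- paste(pos, collapse = ",")
    }
  }
  pqs
}

#' Write PQS records as BED6 (+ companion TSV)
#'
#' The BED name column encodes the tract/loop structure
#' (`t<starts>;l<loop lengths>`); the full table, including CpG columns,
#' goes to `tsv_path` when given.
#'
#' @param pqs PQS `data.frame`.
#' @param path BED6 output path.
#' @param tsv_path optional TSV output with all columns.
#' @export
write_pqs_bed <- function(pqs, path, tsv_path = NULL) {
  nm <- if (nrow(pqs))
    sprintf("t%s;l%s", pqs$tract_starts, pqs$loop_lengths) else character()
  iv <- genome_intervals(pqs$chrom, pqs$start, pqs$end, strand = pqs$strand,
                         name = nm, score = 0)
  write_bed(iv, path)
  if (!is.null(tsv_path))
    write.table(pqs, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
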