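# Independent oracles used across test files. Each is deliberately written
# with a different mechanism than the implementation it checks (regex
# backtracking vs run-chain search, per-base loops vs interval arithmetic).

# Brute-force canonical PQS oracle: at every possible start, test all
# substring lengths against the full anchored pattern with PCRE
# backtracking, take the longest match, then select greedily
# (leftmost-starting first, non-overlapping).
oracle_scan_pqs <- function(s, run_min = 3L, loop_max = 12L) {
  s <- toupper(s)
  n <- nchar(s)
  pat <- sprintf("^G{%d,}([ACGTN]{1,%d}G{%d,}){3}$",
                 run_min, loop_max, run_min)
  min_len <- 4L * run_min + 3L
  chars <- strsplit(s, "")[[1]]
  starts <- which(chars == "G")
  starts <- starts[vapply(starts, function(i) {
    i + run_min - 1L <= n && all(chars[i:(i + run_min - 1L)] == "G")
  }, TRUE)]
  cands <- list()
  for (i in starts) {
    if (i + min_len - 1L > n) next
    best_end <- -1L
    for (e in seq(n, i + min_len - 1L)) {
      if (grepl(pat, substr(s, i, e), perl = TRUE)) {
        best_end <- e
        break  # scanning lengths from longest down: first hit is longest
      }
    }
    if (best_end > 0L)
      cands[[length(cands) + 1L]] <- c(start = i - 1L, end = best_end)
  }
  if (!length(cands))
    return(data.frame(start = integer(), end = integer()))
  df <- as.data.frame(do.call(rbind, cands))
  df <- df[order(df$start, -df$end), , drop = FALSE]
  out <- list(); cur <- -1L
  for (r in seq_len(nrow(df))) {
    if (df$start[r] >= cur) {
      out[[length(out) + 1L]] <- df[r, ]
      cur <- df$end[r]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# per-base brute-force mean of a signal track over a region
oracle_mean_signal <- function(track, chrom, start, end) {
  total <- 0
  for (b in seq_len(end - start)) {
    v <- 0
    for (i in seq_len(nrow(track))) {
      if (track$chrom[i] == chrom && track$start[i] <= start + b - 1L &&
          start + b - 1L < track$end[i]) v <- track$value[i]
    }
    total <- total + v
  }
  total / (end - start)
}

# all-pairs interval overlap oracle
oracle_overlaps <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          subject$end > query$start[i])
  }, TRUE)
}

# random signal track with sorted disjoint runs on one chromosome
random_track <- function(n_runs, chrom = "chr1", max_pos = 500L,
                         max_val = 10) {
  bounds <- sort(sample.int(max_pos, 2L * n_runs))
  starts <- bounds[seq(1L, 2L * n_runs, by = 2L)]
  ends <- bounds[seq(2L, 2L * n_runs, by = 2L)]
  keep <- ends > starts
  signal_track(rep(chrom, sum(keep)), starts[keep], ends[keep],
               round(runif(sum(keep), 0, max_val), 3), drop_zero = FALSE)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
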