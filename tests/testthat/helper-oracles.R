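# Independent brute-force oracles used to cross-check the interval,
# occupancy, density and hypergeometric implementations. All work
# per-base or by exhaustive enumeration and share no code with R/.

# union length of 0-based half-open intervals by per-base membership
brute_covered_length <- function(df, max_coord = 1e4) {
  total <- 0
  for (cc in unique(df$chrom)) {
    hit <- logical(max_coord)
    d <- df[df$chrom == cc, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      hit[(d$start[i] + 1):d$end[i]] <- TRUE
    }
    total <- total + sum(hit)
  }
  total
}

# bp of [ws, we) covered by the union of peaks, per-base
brute_window_overlap <- function(chrom, ws, we, peaks) {
  if (we <= ws) return(0)
  hit <- logical(we - ws)
  d <- peaks[peaks$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(d))) {
    a <- max(d$start[i], ws); b <- min(d$end[i], we)
    if (b > a) hit[(a - ws + 1):(b - ws)] <- TRUE
  }
  sum(hit)
}

# per-base depth lookup, then bin means
brute_bin_means <- function(track_df, chrom, center, flank, bin_size) {
  pos <- (center - flank):(center + flank - 1)  # 0-based bases
  depth <- numeric(length(pos))
  d <- track_df[track_df$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(d))) {
    sel <- pos >= d$start[i] & pos < d$end[i]
    depth[sel] <- d$depth[i]
  }
  colMeans(matrix(depth, nrow = bin_size))
}

# P(X >= x) by exhaustive enumeration of all C(N, n) draws; items 1..K
# are the annotated ones
enum_upper_tail <- function(x, n, K, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= x)
}

random_intervals <- function(n, chroms = "chrT", max_coord = 1e4,
                             max_len = 500) {
  start <- sample.int(max_coord - max_len, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + len, stringsAsFactors = FALSE)
}
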