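# Independent oracles and small fixture builders used across the suite.

# Exhaustive-enumeration oracle for the upper-tail hypergeometric
# probability: enumerate all C(N, n) query subsets of 1..N, take the first K
# elements as the term, and count subsets with at least k term members.
enum_hypergeom_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)
  mean(overlaps >= k)
}

# Per-element 3-bit membership classification oracle for the Venn partition.
brute_venn_counts <- function(a, b, c_) {
  u <- unique(c(a, b, c_))
  pat <- paste0(as.integer(u %in% a), as.integer(u %in% b), as.integer(u %in% c_))
  keys <- c("100", "010", "001", "110", "101", "011", "111")
  vapply(keys, function(k) sum(pat == k), 0L)
}

# Step-up BH oracle: direct evaluation of min_{j >= i} p_(j) * m / j.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[ord][i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# Random canonical edge list over the given symbols.
random_edges <- function(symbols, p = 0.2, score_range = c(0L, 1000L)) {
  n <- length(symbols)
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  data.frame(node_a = symbols[pairs[keep, 1L]],
             node_b = symbols[pairs[keep, 2L]],
             combined_score = sample(seq(score_range[1L], score_range[2L]),
                                     sum(keep), replace = TRUE),
             stringsAsFactors = FALSE)
}

# Minimal affinity record data frame.
affinity_records <- function(symbol, activity_nM,
                             measure = "Ki", mode = "inhibitor") {
  n <- length(symbol)
  data.frame(target_symbol = symbol, activity_value_nM = activity_nM,
             activity_measure = rep_len(measure, n),
             interaction_mode = rep_len(mode, n),
             source_ref = rep_len(NA_character_, n), stringsAsFactors = FALSE)
}

# Write lines to a temp file, returning its path.
tmpfile_lines <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
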