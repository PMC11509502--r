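# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# two-sided signed-rank p by enumerating all 2^n sign patterns on the
# (fixed) ranks of |d|; zero differences must be removed by the caller
oracle_wilcoxon_enum <- function(d) {
  stopifnot(all(d != 0), length(d) <= 12)
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    pos <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    sum(r[pos])
  }, 0)
  p_ge <- mean(ws >= w_obs)
  p_le <- mean(ws <= w_obs)
  min(1, 2 * min(p_ge, p_le))
}

# hypergeometric upper tail by enumerating all choose(N, K) placements of
# the K marked items and counting >= b marked among the first n ranks
oracle_hg_tail_enum <- function(N, K, n, b) {
  if (b == 0) return(1)
  placements <- utils::combn(N, K)
  mean(apply(placements, 2, function(pos) sum(pos <= n) >= b))
}

# mHG score of a 0/1 arrangement using base phyper only (no package code)
oracle_mhg_score <- function(labels) {
  N <- length(labels)
  K <- sum(labels)
  if (K == 0 || N == 1) return(1)
  ns <- seq_len(N - 1)
  b <- cumsum(labels)[ns]
  min(stats::phyper(b - 1, K, N - K, ns, lower.tail = FALSE))
}

# exact mHG p-value by exhausting all arrangements of K ones in N slots
oracle_mhg_pvalue_enum <- function(score, N, K) {
  if (K == 0) return(1)
  placements <- utils::combn(N, K)
  scores <- apply(placements, 2, function(pos) {
    labels <- integer(N)
    labels[pos] <- 1L
    oracle_mhg_score(labels)
  })
  mean(scores <= score * (1 + 1e-12))
}

# tiny paired dataset builders -------------------------------------------

make_intensity <- function(values, ids = sprintf("P%02d", seq_len(nrow(values))),
                           samples = sprintf("S%02d", seq_len(ncol(values)))) {
  intensity_matrix(ids, samples, values)
}

make_design <- function(n, cond_a = "A", cond_b = "B") {
  subj <- sprintf("subj%02d", seq_len(n))
  paired_design(subj, cond_a, cond_b,
                paste0(subj, "_a"), paste0(subj, "_b"))
}

# intensity matrix laid out to match make_design(n): columns subjXX_a then
# subjXX_b
make_paired_intensity <- function(values_a, values_b, d) {
  stopifnot(ncol(values_a) == length(d$subjects))
  vals <- cbind(values_a, values_b)
  make_intensity(vals, samples = c(d$pairs$sample_a, d$pairs$sample_b))
}
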