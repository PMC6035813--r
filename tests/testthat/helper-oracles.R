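# Independent brute-force oracles, written from first principles so
# they share no code path with the package's implementations.

# O(n*m) double loop: indices of every overlapping (query, subject) pair.
bf_overlap_pairs <- function(q, s) {
  out <- NULL
  for (i in seq_len(nrow(q))) for (j in seq_len(nrow(s))) {
    if (q$chrom[i] == s$chrom[j] && q$start[i] < s$end[j] &&
        s$start[j] < q$end[i])
      out <- rbind(out, c(i, j))
  }
  if (is.null(out)) data.frame(query = integer(), subject = integer())
  else data.frame(query = out[, 1], subject = out[, 2])
}

# O(n*m) double loop: loci contained in intervals.
bf_loci_in <- function(lo, iv) {
  out <- NULL
  for (i in seq_len(nrow(lo))) for (j in seq_len(nrow(iv))) {
    if (lo$chrom[i] == iv$chrom[j] && iv$start[j] <= lo$pos[i] &&
        lo$pos[i] < iv$end[j])
      out <- rbind(out, c(i, j))
  }
  if (is.null(out)) data.frame(locus = integer(), interval = integer())
  else data.frame(locus = out[, 1], interval = out[, 2])
}

# BH step-up by its definition: the adjusted value of p_i is the
# smallest p_j * m / rank_j over all j whose p is at least p_i.
# Assumes untied p (draw from runif in tests).
bf_bh <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    q <- Inf
    for (j in seq_len(m)) {
      if (p[j] >= p[i]) q <- min(q, p[j] * m / sum(p <= p[j]))
    }
    min(q, 1)
  }, 0)
}

# Upper-tail hypergeometric P(X >= k) by full enumeration of all
# n-subsets of a universe of size N whose first K elements are successes.
bf_hyper_tail <- function(N, K, n, k) {
  combs <- utils::combn(N, n)
  mean(colSums(combs <= K) >= k)
}

# Log-rank chi-square by direct O/E/V tabulation over event times.
bf_logrank_chisq <- function(time, event, in_a) {
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & in_a)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in_a)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Random interval / locus fixtures on a small genome.
rand_intervals <- function(n, chroms = c("chr1", "chr2"), span = 1e5) {
  start <- sample.int(span, n, replace = TRUE) - 1
  genomic_intervals(sample(chroms, n, replace = TRUE), start,
                    start + sample.int(500, n, replace = TRUE))
}

rand_loci <- function(n, chroms = c("chr1", "chr2"), span = 1e5) {
  loci(sample(chroms, n, replace = TRUE),
       sample.int(span, n, replace = TRUE) - 1)
}

# Small paired beta matrix built by hand.
toy_beta_matrix <- function(beta) {
  np <- ncol(beta) / 2
  colnames(beta) <- c(paste0("T", seq_len(np)), paste0("N", seq_len(np)))
  if (is.null(rownames(beta))) rownames(beta) <- paste0("cg", seq_len(nrow(beta)))
  beta_matrix(beta, data.frame(
    sample_id = colnames(beta),
    group = rep(c("tumor", "paratumor"), each = np),
    pair_id = rep(paste0("P", seq_len(np)), 2)))
}
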