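# Independent oracles: deliberately naive implementations used only to
# compute expected values. They never share code with the package paths
# they check.

# Hudson per-site components evaluated literally from the Bhatia et al.
# formulas, scalar arithmetic only.
oracle_hudson_site <- function(ref1, alt1, ref2, alt2) {
  n1 <- ref1 + alt1; n2 <- ref2 + alt2
  p1 <- alt1 / n1; p2 <- alt2 / n2
  N <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  D <- p1 * (1 - p2) + p2 * (1 - p1)
  c(N = N, D = D)
}

# Brute-force nucleotide diversity: expand allele counts into explicit
# haplotypes and average Hamming distances over all pairs.
oracle_pi <- function(count_matrix, length_bp) {
  # count_matrix: sites x alleles
  total <- 0
  for (s in seq_len(nrow(count_matrix))) {
    haps <- rep(seq_len(ncol(count_matrix)), count_matrix[s, ])
    n <- length(haps)
    if (n < 2) next
    diffs <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) diffs <- diffs + (haps[i] != haps[j])
    }
    total <- total + diffs / choose(n, 2)
  }
  total / length_bp
}

# Exhaustive hypergeometric upper tail: enumerate all C(N, n) draws.
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- combn(N, n)
  annotated <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% annotated))
  mean(hits >= k)
}

# Exact two-sided Mann-Whitney p by enumerating all labelings.
oracle_mwu_enum <- function(a, b) {
  vals <- c(a, b)
  n_a <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  labelings <- combn(length(vals), n_a)
  mu <- n_a * length(b) / 2
  us <- apply(labelings, 2, function(idx) u_of(vals[idx], vals[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
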