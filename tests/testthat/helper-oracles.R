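# Independent brute-force oracles shared by unit and acceptance tests.

# enumerate every global alignment recursively with affine scoring
# (first gapped position costs gap_open, each further one gap_extend)
bruteAlignScore <- function(a, b, sub, go, ge) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B))
      best <- max(best, sub[A[i], B[j]] + rec(i + 1, j + 1, "M"))
    if (i <= length(A))
      best <- max(best, -(if (prev == "X") ge else go) + rec(i + 1, j, "X"))
    if (j <= length(B))
      best <- max(best, -(if (prev == "Y") ge else go) + rec(i, j + 1, "Y"))
    best
  }
  rec(1, 1, "S")
}

# adjacency double-sum definition of generalized modularity:
# Q = (1/2m) sum_ij [A_ij - g k_i k_j / (2m)] delta(c_i, c_j)
bruteModularity <- function(g, membership, gamma) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  k <- rowSums(A)
  m <- sum(A) / 2
  q <- 0
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(A)))
      if (membership[i] == membership[j])
        q <- q + A[i, j] - gamma * k[i] * k[j] / (2 * m)
  unname(q / (2 * m))
}

# smallest observed score whose >=-threshold call set meets the FDR target
bruteCalThreshold <- function(scores, labels, target) {
  for (t in sort(unique(scores))) {
    called <- scores >= t
    fp <- sum(called & labels == "negative")
    tp <- sum(called & labels == "positive")
    fdr <- if (fp + tp == 0) 0 else fp / (fp + tp)
    if (fdr <= target) return(t)
  }
  Inf
}
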