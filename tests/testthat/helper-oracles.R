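# independent oracles shared across test files

# exact combinatorial summation of the hypergeometric upper tail
hyper_tail_oracle <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# quadratic-time Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (r in seq_len(m)) {
    j <- r:m
    q[o[r]] <- min(1, min(p[o[j]] * m / j))
  }
  q
}
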