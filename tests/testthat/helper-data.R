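# Shared fixtures: random small datasets (tied and untied) and an
# independent hypergeometric route to the binary-data p-value.

# Random two-sample dataset; values drawn from a small integer lattice so
# ties are frequent, or from a continuous distribution for untied cases.
random_dataset <- function(n1, n2, tied = TRUE) {
  if (tied) {
    vals <- sample(seq(0, 3, by = 0.5), n1 + n2, replace = TRUE)
  } else {
    vals <- stats::rnorm(n1 + n2)
  }
  list(x = vals[seq_len(n1)], y = vals[n1 + seq_len(n2)])
}

# Two-sided p-value for binary data straight from the hypergeometric
# distribution of a = number of ones in group 1, under the same
# distance-from-mean tail convention as the package's exact test. This is
# an independent closed-form route: no ranking, no shift algorithm.
binary_p2_hyper <- function(a, n1, b, n2) {
  m <- a + b                      # pooled ones
  N <- n1 + n2
  support <- max(0, n1 - (N - m)):min(n1, m)
  prob <- stats::dhyper(support, m, N - m, n1)
  mean_a <- n1 * m / N
  sum(prob[abs(support - mean_a) >= abs(a - mean_a) - 1e-12])
}
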