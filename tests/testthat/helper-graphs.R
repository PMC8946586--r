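round_half_up_oracle <- function(x) trunc(x + 0.5)

# Random binary symmetric zero-diagonal adjacency
rand_adj <- function(n, p = 0.4) {
  a <- matrix(0, n, n)
  idx <- which(upper.tri(a))
  a[idx] <- stats::rbinom(length(idx), 1, p)
  a + t(a)
}

rand_stack <- function(n, m, p = 0.4) {
  layer_stack(replicate(m, rand_adj(n, p), simplify = FALSE))
}

# Random symmetric zero-diagonal matrix with all-distinct off-diagonal values
rand_conn <- function(n) {
  r <- matrix(0, n, n)
  vals <- sample(stats::runif(n * (n - 1) / 2, -1, 1))
  r[upper.tri(r)] <- vals
  r + t(r)
}

# Stack in which node 1 has prescribed per-layer degrees
stack_with_degrees <- function(degrees) {
  n <- max(degrees) + 1
  layers <- lapply(degrees, function(k) {
    a <- matrix(0, n, n)
    if (k > 0) {
      a[1, 1 + seq_len(k)] <- 1
      a[1 + seq_len(k), 1] <- 1
    }
    a
  })
  layer_stack(layers)
}
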