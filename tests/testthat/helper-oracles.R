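# Independent oracles used across tests.  These deliberately re-derive
# quantities with naive code paths (exhaustive scans, explicit loops)
# so they never share logic with the implementation they check.

# all-pairs Euclidean scan: distance from i to its j-th nearest other point
brute_nn <- function(x, q) {
  n <- nrow(x)
  out <- matrix(0, n, q)
  nbr <- matrix(0L, n, q)
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (j in seq_len(n)) {
      if (j != i) d[j] <- sqrt(sum((x[i, ] - x[j, ])^2))
    }
    ord <- order(d)[seq_len(q)]
    out[i, ] <- d[ord]
    nbr[i, ] <- ord
  }
  list(distances = out, neighbours = nbr)
}

# enumerate all set partitions of n items (first-occurrence labelling),
# iteratively via successor computation on restricted growth strings
enumerate_partitions <- function(n) {
  out <- list(rep(1L, n))
  a <- rep(1L, n)
  repeat {
    # find rightmost position that can be incremented
    i <- n
    while (i >= 2L) {
      if (a[i] <= max(a[seq_len(i - 1L)])) break
      i <- i - 1L
    }
    if (i < 2L) break
    a[i] <- a[i] + 1L
    if (i < n) a[(i + 1L):n] <- 1L
    out[[length(out) + 1L]] <- a
  }
  out
}

# posterior-expected VI lower bound, written as explicit per-point loops
vi_bound_naive <- function(pcm, labels) {
  n <- length(labels)
  total <- 0
  for (i in seq_len(n)) {
    in_cl <- labels == labels[i]
    total <- total + log2(sum(in_cl)) + log2(sum(pcm[i, ])) -
      2 * log2(sum(pcm[i, in_cl]))
  }
  total / n
}

# Moran's I evaluated term by term from its definition
moran_naive <- function(x, w) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + w[i, j] * (x[i] - xb) * (x[j] - xb)
  }
  (n / sum(w)) * num / sum((x - xb)^2)
}

# a small two-group label chain with occasional relabelled/noisy sweeps
toy_label_chain <- function(n_obs = 8L, n_iter = 400L, flip = 0.1, seed = 99L) {
  withr::with_seed(seed, {
    base <- rep(1:2, each = n_obs / 2)
    t(vapply(seq_len(n_iter), function(t) {
      l <- base
      swap <- runif(n_obs) < flip
      l[swap] <- 3L - l[swap]
      if (runif(1) < 0.5) l <- 3L - l  # label switching
      l
    }, integer(n_obs)))
  })
}
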