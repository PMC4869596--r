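# Independent brute-force oracles and fixture builders for the test suite.
# Oracles are deliberately naive (loops / exhaustive enumeration) and share
# no code with the implementation paths they check.

# random symmetric PSI-like matrix with distinct entries, diag 0
random_psi <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2, 0.05, 0.95)
  m <- m + t(m)
  rownames(m) <- colnames(m) <- paste0("ch", seq_len(n))
  m
}

# random sparse weighted graph: K edges drawn uniformly, weights in (0, 1]
random_graph_fixture <- function(n, K, seed) {
  set.seed(seed)
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  sel <- sample(nrow(pairs), K)
  w <- matrix(0, n, n)
  w[pairs[sel, , drop = FALSE]] <- stats::runif(K, 0.1, 1)
  w <- w + t(w)
  rownames(w) <- colnames(w) <- paste0("n", seq_len(n))
  weighted_graph(w)
}

# spatially clustered synthetic association matrix (stand-in for a measured
# PSI matrix): channels on a ring, synchrony decays with ring distance plus
# weak noise -- the locally ordered organization real scalp matrices show
clustered_psi_fixture <- function(n = 28, seed = 1) {
  set.seed(seed)
  d <- outer(seq_len(n), seq_len(n), function(i, j) pmin(abs(i - j), n - abs(i - j)))
  m <- 0.35 + 0.55 * exp(-d / 2.5) + matrix(stats::rnorm(n * n, 0, 0.015), n, n)
  m <- (m + t(m)) / 2
  m <- pmin(pmax(m, 0.01), 0.99)
  diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("ch", seq_len(n))
  m
}

# --- brute-force graph-metric oracles ---------------------------------------

bf_degree <- function(g) {
  n <- nrow(g$w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) s <- s + g$w[i, j]
    out[i] <- s
  }
  out
}

# Onnela clustering by explicit triangle enumeration over ordered pairs
bf_clustering_onnela <- function(g) {
  w <- g$w / max(g$w)
  n <- nrow(w)
  Ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(g$w[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h) {
        s <- s + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
      }
    }
    Ci[i] <- s / (k * (k - 1))
  }
  mean(Ci)
}

bf_clustering_literal <- function(g) {
  w <- g$w
  n <- nrow(w)
  Ci <- numeric(n)
  for (i in seq_len(n)) {
    D <- sum(w[i, ])
    if (D * (D - 1) <= 0) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h) {
        s <- s + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
      }
    }
    Ci[i] <- s / (D * (D - 1))
  }
  mean(Ci)
}

# harmonic characteristic path length via Floyd-Warshall on 1/w lengths
bf_path_length <- function(g) {
  n <- nrow(g$w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && g$w[i, j] > 0) d[i, j] <- 1 / g$w[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  off <- d[row(d) != col(d)]
  1 / mean(1 / off)
}

# binary degree sequence of a weighted graph
bin_degrees <- function(g) unname(sort(rowSums(g$w > 0)))

# small epochset fixture built directly (no generator)
toy_epochset <- function(values, channels = NULL, srate = 1000,
                         t0 = 0, condition = NULL) {
  d <- dim(values)
  if (is.null(channels)) channels <- paste0("ch", seq_len(d[1]))
  if (is.null(condition)) condition <- rep("Go", d[3])
  times <- t0 + (seq_len(d[2]) - 1) * 1000 / srate
  epochset(values, channels, times, srate, condition)
}
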