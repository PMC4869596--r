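# Weighted graph construction from PSI matrices and small-world
# characterization: node strength, Onnela clustering, harmonic
# characteristic path length, degree-preserving rewired nulls.

#' Threshold a PSI matrix to a fixed edge count
#'
#' Retains exactly `K` edges: the K largest upper-triangle values under a
#' deterministic total order (descending value, ties broken by ascending
#' node-pair lexicographic order), keeping their original weights; all
#' other entries become 0. Exact-K keeps the network density analytic:
#' density = K / (n(n-1)/2).
#'
#' @param psi symmetric nonnegative matrix with zero diagonal (labels in
#'   dimnames)
#' @param K number of edges to retain, 1 <= K <= n(n-1)/2
#' @return object of class `weighted_graph`: `w` (weight matrix), `labels`,
#'   `K`, `threshold` (the K-th largest retained value), `density`
#' @export
threshold_graph <- function(psi, K) {
  n <- nrow(psi)
  if (!isTRUE(all.equal(psi, t(psi), tolerance = 1e-12,
                        check.attributes = FALSE))) {
    stop("PSI matrix must be symmetric")
  }
  kmax <- n * (n - 1) / 2
  if (K < 1 || K > kmax) stop("K out of range 1..", kmax)
  ut <- which(upper.tri(psi), arr.ind = TRUE)
  vals <- psi[ut]
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(K)]
  w <- matrix(0, n, n, dimnames = dimnames(psi))
  w[ut[keep, , drop = FALSE]] <- vals[keep]
  w <- w + t(w)
  structure(list(w = w, labels = rownames(psi) %||% as.character(seq_len(n)),
                 K = as.integer(K), threshold = min(vals[keep]),
                 density = K / kmax),
            class = "weighted_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a weighted graph directly from a weight matrix
#' @param w symmetric nonnegative matrix, zero diagonal
#' @return a `weighted_graph`
#' @export
weighted_graph <- function(w) {
  n <- nrow(w)
  if (any(diag(w) != 0)) stop("diagonal must be zero")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-12, check.attributes = FALSE))) {
    stop("weight matrix must be symmetric")
  }
  K <- sum(w[upper.tri(w)] > 0)
  structure(list(w = w + 0, labels = rownames(w) %||% as.character(seq_len(n)),
                 K = as.integer(K), threshold = NA_real_,
                 density = K / (n * (n - 1) / 2)),
            class = "weighted_graph")
}

#' Node degree (strength) vector
#'
#' For weighted networks the degree of node i is the sum of its edge
#' weights, `D_i = sum_j w_ij`.
#'
#' @param graph a `weighted_graph`
#' @return named numeric vector of node strengths
#' @export
node_degree <- function(graph) {
  stats::setNames(rowSums(graph$w), graph$labels)
}

#' Mean weighted clustering coefficient
#'
#' `mode = "onnela"` (default): per node,
#' `C_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (what_ij what_ih what_jh)^{1/3}`
#' with weights normalized by the network maximum (`what = w / max(w)`) and
#' `k_i` the count of nonzero neighbors; nodes with fewer than 2 neighbors
#' contribute 0. `mode = "literal"`: the same geometric-mean triangle sum
#' but divided by `D_i (D_i - 1)` with `D_i` the weighted degree — offered
#' because that denominator occasionally appears in print, though it is
#' dimensionally inconsistent with the cited definition.
#'
#' @param graph a `weighted_graph`
#' @param mode "onnela" or "literal"
#' @return scalar mean clustering coefficient
#' @export
clustering_coefficient <- function(graph, mode = c("onnela", "literal")) {
  mode <- match.arg(mode)
  w <- graph$w
  n <- nrow(w)
  if (n < 3) stop("need at least 3 nodes")
  mx <- max(w)
  if (mx == 0) return(0)
  if (mode == "onnela") {
    W3 <- (w / mx)^(1 / 3)
    tri <- diag(W3 %*% W3 %*% W3)      # ordered-pair geometric triangle sum
    k <- rowSums(w > 0)
    denom <- k * (k - 1)
  } else {
    W3 <- w^(1 / 3)                    # raw weights, as printed
    tri <- diag(W3 %*% W3 %*% W3)
    D <- rowSums(w)
    denom <- D * (D - 1)
  }
  Ci <- ifelse(denom > 0, tri / denom, 0)
  mean(Ci)
}

#' Characteristic path length (harmonic form)
#'
#' Shortest paths use edge length `1 / w_ij` (stronger synchrony = shorter
#' distance). The characteristic path length is the inverse of the mean of
#' `1 / d_ij` over ordered pairs i != j; a disconnected pair has
#' `d = Inf` and contributes 0 to the mean, so disconnection is handled
#' without special cases. `mode = "arithmetic"` gives the plain average of
#' finite `d_ij` instead.
#'
#' @param graph a `weighted_graph`
#' @param mode "harmonic" (default) or "arithmetic"
#' @return scalar path length
#' @export
char_path_length <- function(graph, mode = c("harmonic", "arithmetic")) {
  mode <- match.arg(mode)
  d <- shortest_path_matrix(graph)
  off <- d[row(d) != col(d)]
  if (mode == "harmonic") {
    1 / mean(1 / off)
  } else {
    mean(off[is.finite(off)])
  }
}

# all-pairs weighted shortest-path distances with length = 1/w (igraph
# Dijkstra); Inf for disconnected pairs
shortest_path_matrix <- function(graph) {
  w <- graph$w
  n <- nrow(w)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(ut) == 0) {
    d <- matrix(Inf, n, n); diag(d) <- 0
    return(d)
  }
  g <- igraph::graph_from_edgelist(ut, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::distances(g, weights = 1 / w[ut])
}

#' Degree-preserving random rewiring of a weighted graph
#'
#' Randomizes the binary topology with double-edge swaps that preserve each
#' node's binary degree exactly (no self-loops or multi-edges are ever
#' created), then reassigns the original multiset of edge weights to the
#' rewired edges in random order. `10 * K` swaps are attempted.
#'
#' @param graph a `weighted_graph` with K >= 2
#' @param seed integer seed
#' @param n_swaps attempted swaps (default `10 * K`)
#' @return a rewired `weighted_graph`
#' @export
rewire_random <- function(graph, seed = 1, n_swaps = NULL) {
  if (graph$K < 2) stop("need at least 2 edges to rewire")
  n <- nrow(graph$w)
  with_seed(seed, {
    ut <- which(upper.tri(graph$w) & graph$w > 0, arr.ind = TRUE)
    edges <- ut                                  # rows: (i, j), i < j
    adj <- graph$w > 0
    n_try <- if (is.null(n_swaps)) 10L * graph$K else n_swaps
    m <- nrow(edges)
    done <- 0L
    for (s in seq_len(n_try)) {
      pick <- sample.int(m, 2)
      e1 <- edges[pick[1], ]; e2 <- edges[pick[2], ]
      a <- e1[1]; b <- e1[2]; c <- e2[1]; d <- e2[2]
      if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      # propose (a,c) and (b,d)
      if (a == c || b == d || a == d || b == c) next
      if (adj[a, c] || adj[b, d]) next
      adj[a, b] <- adj[b, a] <- FALSE
      adj[c, d] <- adj[d, c] <- FALSE
      adj[a, c] <- adj[c, a] <- TRUE
      adj[b, d] <- adj[d, b] <- TRUE
      edges[pick[1], ] <- sort(c(a, c))
      edges[pick[2], ] <- sort(c(b, d))
      done <- done + 1L
    }
    if (done == 0L) warning("no valid swap found; returning input topology")
    wts <- graph$w[ut]
    wts <- wts[sample.int(m)]
    w_new <- matrix(0, n, n, dimnames = dimnames(graph$w))
    w_new[edges] <- wts
    w_new <- w_new + t(w_new)
    out <- weighted_graph(w_new)
    out$labels <- graph$labels
    out
  })
}

#' Small-world indices against rewired nulls
#'
#' Computes C (Onnela mean clustering) and L (harmonic characteristic path
#' length) of the graph, the means C_rand and L_rand over `n_random`
#' degree-preserving rewired null networks, and the normalized indices
#' gamma = C / C_rand, lambda = L / L_rand, sigma = gamma / lambda. For a
#' small-world network sigma > 1 (gamma > 1, lambda ~ 1).
#'
#' @param graph a `weighted_graph`
#' @param n_random number of null networks (default 20)
#' @param seed master seed; null i uses `seed + i`
#' @param clustering_mode passed to [clustering_coefficient()]
#' @param path_mode passed to [char_path_length()]
#' @return list of class `network_summary`: degree, C, L, C_rand, L_rand,
#'   gamma, lambda, sigma, K, density, n_random, seed
#' @export
small_world_indices <- function(graph, n_random = 20, seed = 1,
                                clustering_mode = "onnela",
                                path_mode = "harmonic") {
  stopifnot(n_random >= 1)
  C <- clustering_coefficient(graph, clustering_mode)
  L <- char_path_length(graph, path_mode)
  Cr <- Lr <- numeric(n_random)
  for (i in seq_len(n_random)) {
    g0 <- rewire_random(graph, seed = (seed + i) %% .Machine$integer.max)
    Cr[i] <- clustering_coefficient(g0, clustering_mode)
    Lr[i] <- char_path_length(g0, path_mode)
  }
  C_rand <- mean(Cr); L_rand <- mean(Lr)
  if (C_rand == 0) stop("degenerate null: C_rand = 0")
  gamma <- C / C_rand
  lambda <- L / L_rand
  structure(list(degree = node_degree(graph), C = C, L = L,
                 C_rand = C_rand, L_rand = L_rand,
                 gamma = gamma, lambda = lambda, sigma = gamma / lambda,
                 K = graph$K, density = graph$density,
                 n_random = n_random, seed = seed),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(
    "network summary: K=%d density=%.4f C=%.4f L=%.4f gamma=%.3f lambda=%.3f sigma=%.3f\n",
    x$K, x$density, x$C, x$L, x$gamma, x$lambda, x$sigma))
  invisible(x)
}

#' Small-world indices across a density sweep
#'
#' Thresholds one PSI matrix at each edge count in `K_values` (default
#' 60..180 step 20, spanning densities ~0.16-0.48 for 28 nodes) and
#' summarizes each level.
#'
#' @param psi symmetric PSI matrix
#' @param K_values integer vector of edge counts
#' @param n_random nulls per level
#' @param seed master seed
#' @return list of `network_summary`, one per K
#' @export
density_sweep <- function(psi, K_values = seq(60, 180, by = 20),
                          n_random = 20, seed = 1) {
  lapply(seq_along(K_values), function(i) {
    g <- threshold_graph(psi, K_values[i])
    small_world_indices(g, n_random = n_random,
                        seed = (seed + 1000L * i) %% .Machine$integer.max)
  })
}

#' Summary table for a density sweep
#' @param sweep list returned by [density_sweep()]
#' @param ... constant annotation columns to prepend (e.g. subject, band)
#' @return data.table with one row per density level
#' @export
sweep_table <- function(sweep, ...) {
  ann <- list(...)
  data.table::rbindlist(lapply(sweep, function(s) {
    c(ann, list(K = s$K, density = s$density, C = s$C, L = s$L,
                C_rand = s$C_rand, L_rand = s$L_rand,
                gamma = s$gamma, lambda = s$lambda, sigma = s$sigma,
                seed = s$seed))
  }))
}
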