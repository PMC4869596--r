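test_that("threshold_graph keeps exactly the K largest PSIs", {
  m <- random_psi(28, seed = 1)
  g <- threshold_graph(m, 378)
  expect_equal(g$density, 1)
  expect_equal(g$w, m, ignore_attr = TRUE)
  g120 <- threshold_graph(m, 120)
  expect_equal(g120$density, 120 / 378)
  expect_identical(sum(g120$w[upper.tri(g120$w)] > 0), 120L)
  # brute-force sort oracle on a 4-node matrix
  m4 <- random_psi(4, seed = 2)
  g3 <- threshold_graph(m4, 3)
  vals <- sort(m4[upper.tri(m4)], decreasing = TRUE)
  expect_equal(sort(g3$w[upper.tri(g3$w) & g3$w > 0], decreasing = TRUE),
               vals[1:3])
  expect_equal(g3$threshold, vals[3])
  expect_error(threshold_graph(m4, 7), "out of range")
  expect_error(threshold_graph(m4, 0), "out of range")
})

test_that("metrics at K depend only on the top-K edge set", {
  m <- random_psi(28, seed = 3)
  g <- threshold_graph(m, 120)
  # perturb entries strictly below the K-th largest: same K=120 graph
  m2 <- m
  below <- m < g$threshold & upper.tri(m)
  m2[below] <- m[below] * 0.5
  m2[lower.tri(m2)] <- t(m2)[lower.tri(m2)]
  g2 <- threshold_graph(m2, 120)
  expect_identical(g$w, g2$w)
})

test_that("node degree matches the handshake identity and brute force", {
  g <- random_graph_fixture(5, 7, seed = 4)
  expect_equal(unname(node_degree(g)), bf_degree(g), tolerance = 1e-12)
  expect_equal(sum(node_degree(g)), 2 * sum(g$w[upper.tri(g$w)]))
  # complete equal-weight graph
  w <- matrix(0.5, 4, 4); diag(w) <- 0
  expect_equal(unname(node_degree(weighted_graph(w))), rep(1.5, 4))
})

test_that("clustering handles canonical cases in both modes", {
  tri <- matrix(0, 3, 3)
  tri[upper.tri(tri)] <- 1
  tri <- tri + t(tri)
  expect_equal(clustering_coefficient(weighted_graph(tri)), 1)
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  expect_equal(clustering_coefficient(weighted_graph(star)), 0)
  # weighted triangle (0.8, 0.5, 0.2) against explicit enumeration
  wt <- matrix(0, 3, 3)
  wt[1, 2] <- 0.8; wt[1, 3] <- 0.5; wt[2, 3] <- 0.2
  wt <- wt + t(wt)
  g <- weighted_graph(wt)
  expect_equal(clustering_coefficient(g, "onnela"), bf_clustering_onnela(g),
               tolerance = 1e-12)
  expect_equal(clustering_coefficient(g, "literal"), bf_clustering_literal(g),
               tolerance = 1e-12)
})

test_that("path length matches canonical cases", {
  two <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  expect_equal(char_path_length(weighted_graph(two)), 1 / 0.4)
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(char_path_length(weighted_graph(tri)), 1)
  # disconnected node contributes 0 to the harmonic mean, no error
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1
  L <- char_path_length(weighted_graph(w))
  expect_true(is.finite(L))
  expect_equal(L, 1 / (2 / 6))    # only pair (1,2) in both directions finite
})

test_that("degree, clustering and path length match brute force on n <= 8", {
  for (s in 1:25) {
    n <- sample(4:8, 1)
    K <- sample(seq(3, n * (n - 1) / 2), 1)
    g <- random_graph_fixture(n, K, seed = 1000 + s)
    expect_equal(unname(node_degree(g)), bf_degree(g), tolerance = 1e-10)
    expect_equal(clustering_coefficient(g, "onnela"),
                 bf_clustering_onnela(g), tolerance = 1e-10)
    expect_equal(char_path_length(g), bf_path_length(g), tolerance = 1e-10)
  }
})

test_that("rewiring preserves binary degrees and the weight multiset", {
  g <- threshold_graph(random_psi(20, seed = 6), 60)
  for (s in 1:10) {
    r <- rewire_random(g, seed = s)
    expect_identical(bin_degrees(r), bin_degrees(g))
    expect_equal(sort(r$w[upper.tri(r$w) & r$w > 0]),
                 sort(g$w[upper.tri(g$w) & g$w > 0]), tolerance = 1e-12)
    expect_true(all(diag(r$w) == 0))
  }
})

test_that("rewiring destroys lattice clustering", {
  n <- 28
  w <- matrix(0, n, n)
  for (i in 1:n) for (s in 1:2) {
    j <- ((i - 1 + s) %% n) + 1
    w[i, j] <- w[j, i] <- 1
  }
  g <- weighted_graph(w)
  C0 <- clustering_coefficient(g)
  drops <- vapply(1:20, function(s)
    clustering_coefficient(rewire_random(g, seed = s)) < 0.5 * C0, logical(1))
  expect_gte(mean(drops), 0.95)
})

test_that("small-world indices are internally consistent", {
  g <- threshold_graph(clustered_psi_fixture(28, seed = 2), 120)
  sw <- small_world_indices(g, n_random = 20, seed = 5)
  expect_equal(sw$sigma, sw$gamma / sw$lambda, tolerance = 1e-12)
  expect_equal(sw$gamma, sw$C / sw$C_rand, tolerance = 1e-12)
  expect_equal(sw$lambda, sw$L / sw$L_rand, tolerance = 1e-12)
  expect_equal(sw$density, 120 / 378)
  expect_gt(sw$sigma, 1)          # locally ordered association matrix
  # a rewired null normalized against further rewirings is ~1
  null_in <- rewire_random(g, seed = 77)
  swn <- small_world_indices(null_in, n_random = 20, seed = 6)
  expect_gt(swn$gamma, 0.8); expect_lt(swn$gamma, 1.2)
  expect_gt(swn$lambda, 0.8); expect_lt(swn$lambda, 1.2)
  expect_gt(swn$sigma, 0.8); expect_lt(swn$sigma, 1.2)
})

test_that("density sweep covers the canonical 7 levels", {
  m <- clustered_psi_fixture(28, seed = 3)
  sw <- density_sweep(m, n_random = 2, seed = 1)
  expect_length(sw, 7)
  dens <- vapply(sw, `[[`, numeric(1), "density")
  expect_equal(round(dens[1], 2), 0.16)
  expect_equal(round(dens[7], 2), 0.48)
  tab <- sweep_table(sw, band = "theta")
  expect_identical(nrow(tab), 7L)
  expect_identical(tab$K, seq(60L, 180L, by = 20L))
})
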