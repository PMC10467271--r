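complete_graph <- function(n) {
  A <- matrix(TRUE, n, n); diag(A) <- FALSE; A
}
star_graph <- function(n) {
  A <- matrix(FALSE, n, n)
  A[1, 2:n] <- A[2:n, 1] <- TRUE
  A
}
path_graph <- function(n) {
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- TRUE
  A
}

test_that("closed-form values hold on canonical graphs", {
  K14 <- complete_graph(14)
  expect_equal(clustering_coefficient(K14)$global, 1)
  expect_equal(characteristic_path_length(K14), 1)
  eff <- network_efficiencies(K14)
  expect_equal(eff$Eg, 1)
  expect_equal(eff$Ne, rep(1, 14))
  expect_equal(eff$Eloc, 1)
  expect_equal(betweenness_centrality(complete_graph(4)), rep(0, 4))
  expect_identical(degree_centrality(complete_graph(4)), rep(3L, 4))

  S5 <- star_graph(5)
  expect_identical(degree_centrality(S5), c(4L, 1L, 1L, 1L, 1L))
  expect_equal(clustering_coefficient(S5)$global, 0)
  expect_equal(betweenness_centrality(S5), c(choose(4, 2), 0, 0, 0, 0))
  expect_equal(assortativity_coefficient(S5), -1)

  K3 <- complete_graph(3)
  expect_equal(clustering_coefficient(K3)$nodal, rep(1, 3))

  P4 <- path_graph(4)
  D <- shortest_path_lengths(P4)
  expect_equal(D[1, 4], 3)
  expect_equal(characteristic_path_length(P4), (1 + 2 + 3 + 1 + 2 + 1) / 6)

  P3 <- path_graph(3)
  expect_equal(network_efficiencies(P3)$Eg, 5 / 6)

  # Lp >= 1 whenever an edge exists
  expect_gte(characteristic_path_length(star_graph(8)), 1)
})

test_that("degenerate metric cases are reported as missing", {
  K4 <- complete_graph(4)
  expect_true(is.na(assortativity_coefficient(K4)))   # regular graph
  expect_true(is.na(hierarchy_coefficient(K4)))       # no degree variance
  empty <- matrix(FALSE, 5, 5)
  expect_true(is.na(characteristic_path_length(empty)))
  expect_identical(network_efficiencies(empty)$Eg, 0)
})

test_that("hierarchy recovers a constructed power law exactly", {
  # two K3s sharing structure with a K5: NCp = 1 at every eligible node of
  # a disjoint union of cliques, so build NCp ~ k^-1 differently: verify on
  # a graph against the OLS oracle instead, plus the exact-slope case of
  # same-degree eligibility
  A <- complete_graph(5)
  B <- complete_graph(3)
  G <- matrix(FALSE, 8, 8)
  G[1:5, 1:5] <- A; G[6:8, 6:8] <- B
  # all NCp = 1 over degrees 4 and 2: slope of log(1) on log(k) is 0
  expect_equal(hierarchy_coefficient(G), 0)

  set.seed(1)
  for (k in 1:50) {
    R <- rand_adjacency(sample(8:14, 1), runif(1, 0.3, 0.7))
    expect_equal(hierarchy_coefficient(R), oracle_hierarchy(R),
                 tolerance = 1e-10)
  }
})

test_that("every metric equals its brute-force oracle on 200 random graphs", {
  set.seed(42)
  for (k in 1:200) {
    n <- sample(8:14, 1)
    A <- rand_adjacency(n, runif(1, 0.15, 0.8))
    expect_identical(degree_centrality(A), as.integer(rowSums(A)))
    expect_equal(clustering_coefficient(A)$nodal, oracle_clustering_nodal(A),
                 tolerance = 1e-10)
    D <- shortest_path_lengths(A)
    expect_equal(D, oracle_distances(A))
    off <- D[row(D) != col(D)]
    lp_oracle <- if (any(is.finite(off))) mean(off[is.finite(off)]) else NA
    expect_equal(characteristic_path_length(A), lp_oracle, tolerance = 1e-10)
    eff <- network_efficiencies(A)
    orc <- oracle_efficiencies(A)
    expect_equal(eff$Eg, orc$Eg, tolerance = 1e-10)
    expect_equal(eff$Ne, orc$Ne, tolerance = 1e-10)
    expect_equal(eff$NLe, orc$NLe, tolerance = 1e-10)
    expect_equal(betweenness_centrality(A), oracle_betweenness(A),
                 tolerance = 1e-10)
    expect_equal(assortativity_coefficient(A), oracle_assortativity(A),
                 tolerance = 1e-10)
  }
})

test_that("graph metrics agree with igraph as an independent implementation", {
  skip_if_not_installed("igraph")
  set.seed(8)
  for (k in 1:25) {
    A <- rand_adjacency(12, 0.35)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(betweenness_centrality(A), igraph::betweenness(g),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(clustering_coefficient(A)$nodal,
                 ifelse(is.nan(igraph::transitivity(g, type = "local")), 0,
                        igraph::transitivity(g, type = "local")),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(assortativity_coefficient(A),
                 suppressWarnings(igraph::assortativity_degree(g)),
                 tolerance = 1e-10)
    Dg <- igraph::distances(g)
    expect_equal(shortest_path_lengths(A), Dg, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("handshake identity and structural invariances hold", {
  set.seed(9)
  for (k in 1:25) {
    A <- rand_adjacency(14, runif(1, 0.2, 0.6))
    expect_identical(sum(degree_centrality(A)),
                     as.integer(2 * sum(A) / 2))
    # isomorphism invariance
    perm <- sample(14)
    Ap <- A[perm, perm]
    expect_equal(clustering_coefficient(Ap)$global,
                 clustering_coefficient(A)$global, tolerance = 1e-12)
    expect_equal(sort(betweenness_centrality(Ap)),
                 sort(betweenness_centrality(A)), tolerance = 1e-10)
    expect_equal(characteristic_path_length(Ap),
                 characteristic_path_length(A), tolerance = 1e-12)
    # monotonicity: adding one edge never increases Lp nor decreases Eg
    miss <- which(upper.tri(A) & !A, arr.ind = TRUE)
    if (nrow(miss)) {
      e <- miss[sample.int(nrow(miss), 1), ]
      A2 <- A; A2[e[1], e[2]] <- A2[e[2], e[1]] <- TRUE
      d1 <- shortest_path_lengths(A); d2 <- shortest_path_lengths(A2)
      expect_true(all(d2 <= d1))
      expect_gte(network_efficiencies(A2)$Eg, network_efficiencies(A)$Eg)
    }
  }
})

test_that("rewired references preserve the degree sequence and edge count", {
  set.seed(10)
  A <- rand_adjacency(14, 0.3)
  refs <- random_references(A, n_rand = 20, seed = 1)
  for (r in refs) {
    expect_identical(rowSums(r), rowSums(A))
    expect_identical(sum(r), sum(A))
    expect_identical(r, t(r))
    expect_true(all(!diag(r)))
  }
  # reproducible under the seed
  refs2 <- random_references(A, n_rand = 20, seed = 1)
  expect_identical(refs, refs2)
  # a ring lattice loses clustering under rewiring
  ring <- ring_lattice(14, 4)
  rr <- random_references(ring, n_rand = 100, seed = 2)
  cp_rand <- mean(sapply(rr, function(x) clustering_coefficient(x)$global))
  expect_lt(cp_rand, clustering_coefficient(ring)$global)
})

test_that("small-world indices behave as expected", {
  A <- ring_lattice(14, 4)
  # self-normalization gives exactly 1
  sw <- small_world_indices(A, list(A))
  expect_equal(sw$Gamma, 1)
  expect_equal(sw$Lambda, 1)
  expect_equal(sw$Sigma, 1)

  # Watts-Strogatz-like ring: Sigma > 1
  set.seed(11)
  ws <- ring_lattice(14, 4, p = 0.1)
  refs <- random_references(ws, n_rand = 100, seed = 3)
  expect_gt(small_world_indices(ws, refs)$Sigma, 1)

  # Erdos-Renyi graphs are their own null: Sigma ~ 1
  sig <- replicate(20, {
    er <- rand_adjacency(14, 0.3)
    refs <- suppressWarnings(random_references(er, n_rand = 50))
    small_world_indices(er, refs)$Sigma
  })
  expect_equal(mean(sig, na.rm = TRUE), 1, tolerance = 0.2)
})

test_that("metric AUC is the trapezoidal integral over the sweep", {
  s <- seq(0.15, 0.50, by = 0.05)
  expect_equal(metric_auc(rep(3, 8), s), 0.35 * 3)
  ramp <- seq(0, 1, length.out = 8)
  expect_equal(metric_auc(ramp, s), 0.175)
  # fine-grid quadrature oracle of the sampled polynomial curve
  v <- 2 * s^2 - s + 0.5
  fine <- seq(0.15, 0.50, length.out = 10001)
  vf <- approx(s, v, xout = fine)$y
  oracle <- sum(diff(fine) * (head(vf, -1) + tail(vf, -1)) / 2)
  expect_equal(metric_auc(v, s), oracle, tolerance = 1e-9)
  # missing propagation
  v[3] <- NA
  expect_true(is.na(metric_auc(v, s)))
})

test_that("a metric sweep delivers 9 global + 5 x 14 nodal AUC values", {
  set.seed(12)
  x <- matrix(rnorm(14 * 1200), 14)
  x[2, ] <- x[1, ] * 0.6 + rnorm(1200, 0, 0.8)
  cm <- pearson_fisher(x)
  ms <- metric_sweep(cm, n_rand = 5, seed = 1)
  expect_length(ms$auc$global, 9)
  expect_identical(dim(ms$auc$nodal), c(5L, 14L))
  expect_identical(dim(ms$per_threshold$global), c(9L, 8L))
  # Sigma = Gamma / Lambda wherever both are finite
  g <- ms$per_threshold$global
  ok <- is.finite(g["Gamma", ]) & is.finite(g["Lambda", ])
  expect_equal(g["Sigma", ok], g["Gamma", ok] / g["Lambda", ok],
               tolerance = 1e-12)
  # bounded metrics stay in [0, 1]
  for (m in c("Cp", "Eloc", "Eg")) {
    expect_true(all(g[m, ] >= 0 & g[m, ] <= 1))
  }
  expect_true(all(ms$per_threshold$nodal[c("NCp", "Ne", "NLe"), , ] >= 0 &
                    ms$per_threshold$nodal[c("NCp", "Ne", "NLe"), , ] <= 1))
})
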