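# Unit tests for the graph-metric layer against closed forms and the
# brute-force oracles in helper-oracles.R.

test_that("clustering, transitivity, efficiency and Lp match oracles on random graphs", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(4:7, 1)
    a <- oracle_random_graph(n, stats::runif(1, 0.3, 0.9))
    expect_equal(clustering_coefficient(a), oracle_clustering(a), tolerance = 1e-12)
    expect_equal(transitivity_coefficient(a), oracle_transitivity(a), tolerance = 1e-12)
    expect_equal(local_efficiency(a), oracle_eloc(a), tolerance = 1e-12)
    expect_equal(global_efficiency(a), oracle_eglob(a), tolerance = 1e-12)
    if (oracle_connected(a)) {
      expect_equal(characteristic_path_length(a), oracle_lp(a), tolerance = 1e-12)
    } else {
      expect_error(characteristic_path_length(a), "disconnected")
    }
  }
})

test_that("assortativity matches the edge-end Pearson oracle, including NaN cases", {
  set.seed(102)
  for (rep in 1:30) {
    n <- sample(4:7, 1)
    a <- oracle_random_graph(n, stats::runif(1, 0.4, 0.9))
    if (sum(a) == 0) next
    ours <- degree_assortativity(a)
    ref <- oracle_assortativity(a)
    if (is.nan(ref)) expect_true(is.nan(ours)) else expect_equal(ours, ref, tolerance = 1e-12)
  }
  # regular graphs have zero degree variance -> NaN
  expect_true(is.nan(degree_assortativity(graph_ring_lattice(10, 4))))
  expect_true(is.nan(degree_assortativity(graph_complete(5))))
})

test_that("betweenness matches the path-enumeration oracle", {
  set.seed(103)
  for (rep in 1:30) {
    n <- sample(4:7, 1)
    a <- oracle_random_graph(n, stats::runif(1, 0.3, 0.9))
    bn <- betweenness_nodal(a)
    expect_equal(bn$bc_raw, oracle_betweenness(a), tolerance = 1e-12)
    if (!bn$degenerate) {
      expect_equal(bn$bc_norm, bn$bc_raw / mean(bn$bc_raw), tolerance = 1e-12)
    }
  }
})

test_that("modularity equals the exhaustive-partition maximum on small graphs", {
  set.seed(104)
  for (rep in 1:15) {
    n <- sample(4:7, 1)
    a <- oracle_random_graph(n, stats::runif(1, 0.4, 0.9))
    if (sum(a) == 0) next
    expect_equal(modularity_q(a), oracle_modularity(a), tolerance = 1e-12)
  }
})

test_that("modularity handles canonical community structure", {
  # two disjoint triangles: optimal partition is the two triangles, Q = 1/2
  a <- matrix(0, 6, 6)
  a[1:3, 1:3] <- 1; a[4:6, 4:6] <- 1; diag(a) <- 0
  expect_equal(modularity_q(a), 0.5, tolerance = 1e-12)
  expect_equal(modularity_q(graph_complete(4)), 0, tolerance = 1e-12)
  expect_error(modularity_q(matrix(0, 3, 3)), "edgeless")
})

test_that("degree-preserving nulls keep the per-node degree sequence", {
  for (g in list(graph_ring_lattice(20, 4), oracle_random_graph(15, 0.4))) {
    for (s in 1:5) {
      dn <- scnet:::.cpp_null_degrees(scnet:::as_adjacency(g), 10, s)
      expect_identical(dn, as.integer(rowSums(g)))
    }
  }
})

test_that("null ensemble means are deterministic and reduce lattice clustering", {
  a <- graph_ring_lattice(20, 4)
  nl <- random_null_ensemble(a, n_null = 10, seed = 77)
  expect_identical(nl, random_null_ensemble(a, n_null = 10, seed = 77))
  expect_lt(nl[["cprand"]], clustering_coefficient(a))
  expect_error(random_null_ensemble(a, n_null = 0), "at least 1")
})

test_that("small-world normalization recovers the ring-lattice signature", {
  a <- graph_ring_lattice(20, 4)
  gm <- global_metrics(a, n_null = 20, seed = 3)
  # lattice: high clustering relative to degree-matched randomizations
  expect_gt(gm$gamma, 1)
  expect_gt(gm$sigma, 1)
  expect_equal(gm$gamma / gm$lambda, gm$sigma, tolerance = 1e-12)
  expect_equal(small_world(gm$cp, gm$lp, gm$cprand, gm$lprand)$sigma,
               gm$sigma, tolerance = 1e-12)
})

test_that("metric functions validate their input", {
  asym <- matrix(0, 3, 3); asym[1, 2] <- 1
  expect_error(clustering_coefficient(asym), "symmetric")
  bad <- graph_complete(4); bad[1, 2] <- bad[2, 1] <- 2
  expect_error(clustering_coefficient(bad), "binary")
  badd <- graph_complete(4); diag(badd) <- 1
  expect_error(global_efficiency(badd), "diagonal")
  expect_error(characteristic_path_length(matrix(0, 2, 3)), "square")
})
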