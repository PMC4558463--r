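test_that("global efficiency matches hand-worked cases", {
  W2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(global_efficiency(W2), 1)
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  # 3-node path, w = 0.5 on both edges: distances 2, 2, 4
  W3 <- matrix(0, 3, 3); W3[1, 2] <- W3[2, 3] <- 0.5; W3 <- W3 + t(W3)
  expect_equal(global_efficiency(W3), (1 / 2 + 1 / 2 + 1 / 4) / 3)
  expect_error(global_efficiency(matrix(0, 1, 1)), "2 nodes")
})

test_that("clustering matches the geometric-mean triangle form", {
  tri <- matrix(0, 3, 3)
  tri[upper.tri(tri)] <- c(1, 1, 1); tri <- tri + t(tri)
  expect_equal(mean_clustering(tri), 1)
  # star graph has no triangles
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  expect_equal(mean_clustering(star), 0)
  # triangle with rescaled weights 1, 1, 0.125: each node (1*1*0.125)^(1/3)
  tri2 <- matrix(0, 3, 3)
  tri2[1, 2] <- 0.8; tri2[1, 3] <- 0.8; tri2[2, 3] <- 0.1
  tri2 <- tri2 + t(tri2)
  expect_equal(mean_clustering(tri2), 0.5)
  expect_warning(v <- mean_clustering(matrix(0, 2, 2)), "3 nodes")
  expect_equal(v, 0)
})

test_that("betweenness matches enumeration on small graphs", {
  # complete equal-weight graph: no pair routes through a third node
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(mean_betweenness(K4), 0)
  # 3-node path: the middle node carries the single indirect pair
  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 3] <- 0.5; P3 <- P3 + t(P3)
  expect_equal(mean_betweenness(P3), 1 / 3)
  E1 <- matrix(0, 3, 3); E1[1, 2] <- E1[2, 1] <- 1
  expect_equal(mean_betweenness(E1), 0)
})

test_that("path metrics agree with brute-force oracles on random graphs", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    W <- random_weight_matrix(n, p = 0.5)
    expect_equal(global_efficiency(W), oracle_efficiency(W),
                 tolerance = 1e-10)
    expect_equal(char_path_length(W), oracle_charpath(W), tolerance = 1e-10)
    expect_equal(mean_betweenness(W), mean(oracle_betweenness(W)),
                 tolerance = 1e-8)
    expect_equal(mean_clustering(W), oracle_clustering(W), tolerance = 1e-10)
  }
})

test_that("metrics are invariant under node relabelling", {
  set.seed(5)
  W <- random_weight_matrix(9, p = 0.45)
  p <- sample.int(9)
  Wp <- W[p, p]
  expect_equal(global_efficiency(Wp), global_efficiency(W))
  expect_equal(mean_clustering(Wp), mean_clustering(W))
  expect_equal(mean_betweenness(Wp), mean_betweenness(W))
})

test_that("efficiency does not decrease when an edge is added", {
  set.seed(9)
  for (i in 1:10) {
    W <- random_weight_matrix(7, p = 0.35)
    vac <- which(upper.tri(W) & W == 0)
    if (!length(vac)) next
    W2 <- W
    W2[vac[1]] <- 0.5
    W2 <- pmax(W2, t(W2))
    expect_gte(global_efficiency(W2), global_efficiency(W) - 1e-12)
  }
})

test_that("smallworldness behaves across regimes", {
  expect_true(is.na(smallworldness(matrix(0, 5, 5))))
  # ring lattice N = 20, k = 4, equal weights: clustered but short-ranged
  n <- 20
  R <- matrix(0, n, n)
  for (i in 1:n) for (d in 1:2) {
    j <- ((i + d - 1) %% n) + 1
    R[i, j] <- R[j, i] <- 1
  }
  expect_gt(smallworldness(R, n_null = 20, seed = 1), 1)
  # a network drawn from the null ensemble scores ~1 on average
  set.seed(42)
  w <- runif(40, 0.1, 1)
  vals <- replicate(30, {
    M <- matrix(0, 12, 12)
    slots <- sample(which(upper.tri(M)), 40)
    M[slots] <- sample(w)
    M <- M + t(M)
    smallworldness(M, n_null = 15, seed = sample.int(1e6, 1))
  })
  expect_equal(mean(vals, na.rm = TRUE), 1, tolerance = 0.15)
})

test_that("count metrics and sweeps are consistent", {
  conn <- make_conn(c(1, 2, 3), 3)
  cm <- count_metrics(conn)
  expect_equal(unname(cm), c(3, 6))
  thr <- apply_threshold(conn, 1)
  expect_equal(unname(count_metrics(thr)), c(2, 5))

  set.seed(21)
  big <- connectome(random_weight_matrix(20, p = 0.25, integer_counts = TRUE))
  sweep <- metric_sweep(big, 0:6,
                        metrics = c("global_efficiency", "n_edges"),
                        seed = 3)
  ne <- sweep$value[sweep$metric == "n_edges"]
  expect_true(all(diff(ne) <= 0))
  # tau = 0 row equals the unthresholded metric
  expect_equal(sweep$value[sweep$metric == "global_efficiency"][1],
               global_efficiency(big$W))
  # each entry equals an independent per-tau call
  for (tau in c(2, 5)) {
    expect_equal(
      sweep$value[sweep$metric == "global_efficiency"][tau + 1],
      global_efficiency(apply_threshold(big, tau)$W))
  }
  expect_error(metric_sweep(big, 0:2, metrics = "bogus"), "unknown metric")
})

test_that("cohort metric matrices line up with per-subject sweeps", {
  spec <- synthetic_spec(n_nodes = 20)
  truth <- generate_ground_truth(spec, seed = 2)
  cohort <- generate_cohort(truth, 4, spec, seed = 3)
  vals <- cohort_metric_matrix(cohort, 0:4, "mean_clustering")
  expect_equal(dim(vals), c(4, 5))
  expect_equal(vals[2, 3],
               mean_clustering(apply_threshold(cohort[[2]], 2)$W))
})
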