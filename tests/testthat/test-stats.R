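test_that("Mann-Whitney U matches brute force and wilcox.test", {
  expect_equal(mann_whitney_u(c(4, 5, 6), c(1, 2, 3)), 9)
  x <- c(2, 2, 2); expect_equal(mann_whitney_u(x, x), 4.5)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
  set.seed(13)
  for (i in 1:20) {
    x <- sample(1:8, 5, replace = TRUE)  # ties exercised via integers
    y <- sample(1:8, 7, replace = TRUE)
    u <- mann_whitney_u(x, y)
    expect_equal(u + mann_whitney_u(y, x), 5 * 7)
    expect_gte(u, 0); expect_lte(u, 35)
    # brute-force count of pairwise wins with half-credit ties
    brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(u, brute)
    expect_equal(u, unname(suppressWarnings(
      wilcox.test(x, y)$statistic)))
  }
})

test_that("pooled t statistic matches t.test", {
  expect_equal(t_statistic(c(1, 2, 3), c(4, 5, 6)), -3.674, tolerance = 1e-3)
  expect_equal(t_statistic(c(1, 2, 3), c(4, 5, 6)),
               -t_statistic(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(t_statistic(c(1, 2), c(1.5, 1.5001)) > 0, FALSE)
  expect_error(t_statistic(1, c(1, 2)), "at least 2")
  expect_error(t_statistic(c(1, 1), c(1, 1)), "pooled variance")
  set.seed(17)
  x <- rnorm(9); y <- rnorm(12, 0.5)
  expect_equal(t_statistic(x, y),
               unname(t.test(x, y, var.equal = TRUE)$statistic))
})

test_that("instability has its closed forms and invariances", {
  expect_error(instability(5), "at least 2")
  expect_equal(instability(rep(3, 8))$sigma_dot, 0)
  expect_equal(instability(c(0, 2))$sigma_dot, sqrt(2))
  for (s in c(-2.5, 0.3, 4)) for (n in c(3, 7, 12)) {
    lin <- 1 + s * (0:(n - 1))
    expect_equal(instability(lin)$sigma_dot, abs(s) / sqrt(2),
                 tolerance = 1e-12)
  }
  set.seed(19)
  S <- rnorm(15)
  base <- instability(S)$sigma_dot
  expect_equal(instability(S + 100)$sigma_dot, base)        # translation
  expect_equal(instability(-3 * S)$sigma_dot, 3 * base)     # homogeneity
})

test_that("stat curves drop masked subjects and skip thin columns", {
  vals <- matrix(rnorm(40), 8, 5)
  vals[1:4, 2] <- NA          # group a reduced to 0 usable subjects
  vals[1, 4] <- NA            # one subject dropped
  lab <- factor(rep(c("a", "b"), each = 4))
  sc <- stat_curve(vals, lab, taus = 0:4)
  expect_true(is.na(sc$S[2]) && sc$skipped[2])
  expect_equal(sc$n1_eff[4], 3)
  expect_equal(sc$S[4],
               mann_whitney_u(vals[2:4, 4], vals[5:8, 4]))
  # doubling the data changes no rank, hence no U and no instability
  sc2 <- stat_curve(vals * 2, lab, taus = 0:4)
  expect_equal(sc2$S, sc$S)
})

test_that("permutation ensembles match direct recomputation", {
  set.seed(23)
  vals <- matrix(rnorm(60), 12, 5)
  vals[3, 2] <- NA
  lab <- factor(rep(c("g1", "g2"), each = 6))
  ens <- permute_null(vals, lab, statistic = "U", n_rand = 25, seed = 7)
  expect_equal(dim(ens$S_perm), c(25, 5))
  # rebuild each row with the same RNG stream and plain mann_whitney_u
  P <- with(list(), {
    set.seed(7)
    t(replicate(25, {
      g1 <- sample.int(12, 6)
      seq_len(12) %in% g1
    }))
  })
  for (r in c(1, 9, 25)) for (j in c(1, 2, 5)) {
    ok <- !is.na(vals[, j])
    x <- vals[P[r, ] & ok, j]; y <- vals[!P[r, ] & ok, j]
    expect_equal(ens$S_perm[r, j], mann_whitney_u(x, y))
  }
  # t-statistic pathway against t_statistic directly
  enst <- permute_null(vals, lab, statistic = "t", n_rand = 10, seed = 3)
  set.seed(3)
  Pt <- t(replicate(10, seq_len(12) %in% sample.int(12, 6)))
  for (r in c(2, 10)) for (j in c(1, 4)) {
    ok <- !is.na(vals[, j])
    expect_equal(enst$S_perm[r, j],
                 t_statistic(vals[Pt[r, ] & ok, j], vals[!Pt[r, ] & ok, j]),
                 tolerance = 1e-12)
  }
  # reproducibility and constant-metric degeneracy
  ens2 <- permute_null(vals, lab, statistic = "U", n_rand = 25, seed = 7)
  expect_identical(ens$S_perm, ens2$S_perm)
  flat <- matrix(5, 10, 3)
  ensf <- permute_null(flat, factor(rep(c("a", "b"), 5)), n_rand = 4,
                       seed = 1)
  expect_true(all(ensf$S_perm == 25 / 2))
})

test_that("under a true null the observed U rank is uniform", {
  set.seed(29)
  n_rep <- 200
  ranks <- vapply(seq_len(n_rep), function(i) {
    vals <- matrix(rnorm(16), 16, 1)
    lab <- factor(rep(c("a", "b"), each = 8))
    u <- stat_curve(vals, lab, taus = 0)$S[1]
    ens <- permute_null(vals, lab, n_rand = 99, seed = i)
    mean(ens$S_perm[, 1] <= u)
  }, numeric(1))
  # empirical p-values roughly uniform: mean near 1/2, spread near 1/12
  expect_equal(mean(ranks), 0.5, tolerance = 0.06)
  # U is discrete, so the empirical p-values sit on a lattice; allow a
  # generous band around the uniform variance
  expect_equal(var(ranks), 1 / 12, tolerance = 0.15)
})

test_that("instability experiment ranks noisy metrics above controls", {
  spec <- synthetic_spec(n_nodes = 20, dispersion = 0)
  truth <- generate_ground_truth(spec, seed = 3)
  flat_spec <- synthetic_spec(n_nodes = 20, dispersion = 0,
                              fp_ne_rate = 0, fp_ee_rate = 0)
  flat <- generate_cohort(truth, 6, flat_spec, seed = 4)
  # identical subjects -> constant U curves -> zero instability
  res0 <- instability_experiment(flat, 0:5, metrics = "n_streamlines",
                                 n_splits = 10, seed = 5)
  expect_equal(res0$sigma_dot, 0)

  spec2 <- synthetic_spec(n_nodes = 20)
  cohort <- generate_cohort(truth, 12, spec2, seed = 6)
  res <- instability_experiment(
    cohort, 0:8, metrics = c("smallworldness", "n_streamlines"),
    n_splits = 25, seed = 7)
  sw <- res$sigma_dot[res$metric == "smallworldness"]
  ns <- res$sigma_dot[res$metric == "n_streamlines"]
  expect_gt(sw, ns)
  expect_error(instability_experiment(cohort[1:3], 0:3), "at least 4")
})
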