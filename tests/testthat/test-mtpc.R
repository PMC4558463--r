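# A hand-built ensemble: wrap a statistic matrix in the structure
# permute_null returns, with fixed effective group sizes.
fake_ensemble <- function(S, n1 = 4, n2 = 4, statistic = "t") {
  structure(
    list(S_perm = S,
         n1_eff = matrix(n1, nrow(S), ncol(S)),
         n2_eff = matrix(n2, nrow(S), ncol(S)),
         statistic = statistic, n1 = n1, n2 = n2,
         n_rand = nrow(S), seed = NULL),
    class = "null_ensemble")
}

fake_curve <- function(S, n1 = 4, n2 = 4, statistic = "t") {
  structure(
    list(tau = seq_along(S) - 1, S = S, statistic = statistic,
         n1 = n1, n2 = n2,
         n1_eff = rep(n1, length(S)), n2_eff = rep(n2, length(S)),
         skipped = is.na(S)),
    class = "stat_curve")
}

test_that("max-statistic null summarises each permutation's extremum", {
  ens1 <- fake_ensemble(matrix(c(3, -1, 2), 3, 1))
  expect_equal(max_null_distribution(ens1, "upper"), c(3, -1, 2))
  ens <- fake_ensemble(rbind(c(5, 3, 4), c(2, 6, 1)))
  expect_equal(max_null_distribution(ens, "upper"), c(5, 6))
  # lower direction: elementwise minimum, on the extremity scale
  expect_equal(-max_null_distribution(ens, "lower"), c(3, 1))
  expect_equal(max_null_distribution(ens, "two_sided"), c(5, 6))
  # U statistic centres at n1*n2/2 before the absolute value
  ensu <- fake_ensemble(rbind(c(1, 8), c(7, 9)), statistic = "U")
  expect_equal(max_null_distribution(ensu, "two_sided"), c(7, 1))
})

test_that("the max-statistic null dominates single-threshold nulls", {
  set.seed(37)
  S <- matrix(rnorm(200 * 6), 200, 6)
  mx <- max_null_distribution(fake_ensemble(S), "upper")
  # stochastic dominance: upper quantiles of the max exceed any column's
  for (j in 1:6)
    expect_gte(quantile(mx, 0.95), quantile(S[, j], 0.95))
})

test_that("critical values use the interpolated upper quantile", {
  expect_equal(critical_value(1:100, alpha = 0.05), 95.05)
  # alpha -> 1 rejects everything: critical value at the sample minimum
  expect_equal(critical_value(1:100, alpha = 1 - 1e-12), 1,
               tolerance = 1e-6)
  expect_warning(cv <- critical_value(rep(2, 10), 0.05), "degenerate")
  expect_equal(cv, 2)
  expect_error(critical_value(numeric(0), 0.05), "empty")
})

test_that("cluster finding measures exceedance area by trapezoid", {
  crv <- fake_curve(c(0, 0, 0, 0, 0))
  expect_equal(nrow(find_clusters(crv, 1, "upper")), 0)
  # constant margin m over 5 consecutive taus -> one cluster, area 4m
  m <- 1.5
  crv2 <- fake_curve(c(0, rep(2 + m, 5), 0))
  cl <- find_clusters(crv2, 2, "upper")
  expect_equal(nrow(cl), 1)
  expect_equal(cl$auc, 4 * m)
  expect_equal(cl$tau_start, 1); expect_equal(cl$tau_end, 5)
  # two separated runs are measured independently
  crv3 <- fake_curve(c(5, 0, 0, 4, 6, 0))
  cl3 <- find_clusters(crv3, 3, "upper")
  expect_equal(nrow(cl3), 2)
  expect_equal(cl3$auc, c(0, (1 + 3) / 2))
  expect_equal(cl3$peak_S, c(5, 6))
  # single-point clusters have zero area unless widened
  cl3w <- find_clusters(crv3, 3, "upper", widen_single_points = TRUE)
  expect_equal(cl3w$auc[1], 2)
})

test_that("critical AUC averages super-critical permutations", {
  S0 <- matrix(0, 5, 4)
  expect_equal(critical_auc(fake_ensemble(S0), 1, "upper"), 0)
  # every permutation exceeds by m over exactly 3 taus -> area 2m
  m <- 0.8
  S <- matrix(0, 6, 5); S[, 2:4] <- 1 + m
  expect_equal(critical_auc(fake_ensemble(S), 1, "upper"), 2 * m)
  # permutation order is irrelevant
  S2 <- S; S2[1, 2:4] <- 1 + 3 * m
  expect_equal(critical_auc(fake_ensemble(S2), 1, "upper"),
               critical_auc(fake_ensemble(S2[sample(6), ]), 1, "upper"))
  # zero-inclusive averaging counts sub-critical permutations as 0
  S3 <- S; S3[1:3, ] <- 0
  expect_equal(critical_auc(fake_ensemble(S3), 1, "upper"), 2 * m)
  expect_equal(critical_auc(fake_ensemble(S3), 1, "upper",
                            zero_inclusive = TRUE), m)
})

test_that("mtpc composes its steps and is deterministic", {
  set.seed(41)
  vals <- matrix(rnorm(20 * 8), 20, 8)
  lab <- factor(rep(c("a", "b"), each = 10))
  cfg <- mtpc_config(alpha = 0.05, n_rand = 99, taus = 0:7, seed = 11)
  r1 <- mtpc(vals, lab, cfg)
  r2 <- mtpc(vals, lab, cfg)
  expect_identical(r1$s_crit, r2$s_crit)
  expect_identical(r1$clusters, r2$clusters)
  expect_identical(r1$reject, r2$reject)
  # a strong broad group effect is detected
  vals2 <- vals; vals2[1:10, ] <- vals2[1:10, ] + 3
  r3 <- mtpc(vals2, lab, cfg)
  expect_true(r3$reject)
  expect_gt(r3$a_mtpc, r3$a_crit)
  # the rejection rule is exactly: a cluster exists and A_MTPC > A_crit
  r0 <- mtpc(matrix(rnorm(20 * 8), 20, 8), lab, cfg)
  expect_identical(r0$reject,
                   nrow(r0$clusters) > 0 && r0$a_mtpc > r0$a_crit)
  expect_error(mtpc(vals, lab, mtpc_config(taus = 0:3, n_rand = 10)),
               "taus")
})

test_that("node-level mtpc pools the null over nodes and thresholds", {
  set.seed(43)
  arr <- array(rnorm(16 * 6 * 3), dim = c(16, 6, 3))
  arr[1:8, 3:5, 2] <- arr[1:8, 3:5, 2] + 4   # effect in node 2 only
  lab <- factor(rep(c("a", "b"), each = 8))
  cfg <- mtpc_config(n_rand = 99, taus = 0:5, seed = 13,
                     node_level = TRUE)
  r <- mtpc(arr, lab, cfg)
  expect_true(r$reject)
  expect_true(all(r$clusters$node == 2))
  # node-level pooling raises the bar relative to a single-node run
  r_single <- mtpc(arr[, , 2], lab,
                   mtpc_config(n_rand = 99, taus = 0:5, seed = 13))
  expect_gte(r$s_crit, r_single$s_crit)
})

test_that("the AUC method reduces to a test on per-subject areas", {
  # constant curves: AUC = c * n_intervals, group test on the constants
  vals <- matrix(rep(c(1:6, 11:16), times = 4), nrow = 12)
  lab <- factor(rep(c("lo", "hi"), each = 6), levels = c("lo", "hi"))
  cfg <- mtpc_config(n_rand = 200, taus = 0:3, seed = 17)
  res <- auc_method(vals, lab, cfg)
  expect_equal(res$auc, c(1:6, 11:16) * 3)
  expect_equal(res$statistic, mann_whitney_u(1:6 * 3, 11:16 * 3))
  expect_true(res$reject)
})

test_that("minimum detectable effect interpolates the first crossing", {
  xi <- c(0, 0.05, 0.1, 0.15, 0.2)
  expect_equal(min_detectable_effect(xi, c(1, 2, 3, 5, 7), crit = 4), 0.125)
  expect_true(is.na(min_detectable_effect(xi, rep(1, 5), crit = 4)))
  expect_equal(min_detectable_effect(xi, c(1, 2, 4, 5, 6), crit = 4), 0.1)
  expect_equal(min_detectable_effect(xi, c(5, 6, 7, 8, 9), crit = 4), 0)
  expect_error(min_detectable_effect(xi, 1:3, crit = rep(1, 5)), "grid")
})
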