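#' Mann-Whitney U statistic of the first sample
#'
#' Rank-sum form with midrank tie handling: `U = R1 - n1(n1+1)/2` where
#' `R1` is the rank sum of `x` in the pooled sample. Satisfies the
#' complement identity `U(x, y) + U(y, x) = n1 * n2`.
#'
#' @param x,y numeric samples for the two groups (non-empty).
#' @return The U statistic of `x`, in `[0, n1 * n2]`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Pooled-variance independent-samples t statistic
#'
#' @param x,y numeric samples, each of size >= 2.
#' @return The t statistic for `mean(x) - mean(y)`; errors on zero pooled
#'   variance.
#' @export
t_statistic <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 observations")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance")
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Group statistic per threshold column, dropping NA subjects per column.
# Returns the statistic plus per-column effective group sizes; a column is
# NA when either group falls below `min_group` usable subjects.
column_stats <- function(values, g1, g2, statistic = c("U", "t"),
                         min_group = 2L) {
  statistic <- match.arg(statistic)
  n_tau <- ncol(values)
  S <- n1e <- n2e <- rep(NA_real_, n_tau)
  for (j in seq_len(n_tau)) {
    v <- values[, j]
    ok <- !is.na(v)
    i1 <- g1[ok[g1]]; i2 <- g2[ok[g2]]
    if (length(i1) < min_group || length(i2) < min_group) next
    S[j] <- if (statistic == "U") mann_whitney_u(v[i1], v[i2])
            else tryCatch(t_statistic(v[i1], v[i2]),
                          error = function(e) NA_real_)
    n1e[j] <- length(i1); n2e[j] <- length(i2)
  }
  list(S = S, n1_eff = n1e, n2_eff = n2e)
}

#' Group test-statistic curve across thresholds
#'
#' Computes the Mann-Whitney U (or pooled t) statistic comparing the two
#' groups of a subjects x thresholds metric matrix, independently at each
#' threshold. Subjects with an undefined metric at a threshold are dropped
#' at that threshold only; a threshold where either group falls below 2
#' usable subjects is skipped (`NA`, recorded in `skipped`).
#'
#' @param values numeric matrix, subjects in rows, thresholds in columns
#'   (as from [cohort_metric_matrix()]).
#' @param labels group assignment of each subject: factor or vector with
#'   exactly two levels; the first level is "group 1" (the statistic's
#'   reference group).
#' @param taus optional threshold grid for labelling (defaults to
#'   `0:(ncol(values) - 1)`).
#' @param statistic `"U"` or `"t"`.
#' @return A `stat_curve` object: list with `tau`, `S`, `statistic`, `n1`,
#'   `n2`, per-threshold effective sizes and the skipped-column mask.
#' @export
stat_curve <- function(values, labels, taus = NULL,
                       statistic = c("U", "t")) {
  statistic <- match.arg(statistic)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("`labels` must have exactly two levels")
  if (length(labels) != nrow(values))
    stop("one label per row of `values` required")
  if (is.null(taus)) taus <- seq_len(ncol(values)) - 1
  g1 <- which(labels == levels(labels)[1])
  g2 <- which(labels == levels(labels)[2])
  cs <- column_stats(values, g1, g2, statistic)
  structure(
    list(tau = taus, S = cs$S, statistic = statistic,
         n1 = length(g1), n2 = length(g2),
         n1_eff = cs$n1_eff, n2_eff = cs$n2_eff,
         skipped = is.na(cs$S)),
    class = "stat_curve")
}

#' @export
print.stat_curve <- function(x, ...) {
  cat(sprintf("<stat_curve> %s statistic, groups %d/%d, %d thresholds (%d skipped)\n",
              x$statistic, x$n1, x$n2, length(x$tau), sum(x$skipped)))
  invisible(x)
}

#' Adjacent-threshold instability of a statistic curve
#'
#' An analogue of the standard deviation restricted to adjacent threshold
#' pairs: `sigma_dot = sqrt( sum( (S_tau - S_{tau+1})^2 / 2 ) / (n - 1) )`
#' over the `n` thresholds of the curve. It is zero iff the curve is
#' constant, translation-invariant, and absolutely homogeneous
#' (`sigma_dot(a S + b) = |a| sigma_dot(S)`); a straight line of slope `s`
#' gives `|s| / sqrt(2)`. Large values flag statistics whose inference
#' flips erratically between neighbouring thresholds.
#'
#' @param curve a [stat_curve], or a plain numeric vector of statistics on
#'   a unit-spaced threshold grid. `NA` entries (skipped thresholds) are
#'   dropped, splitting is not attempted: deviations are taken between
#'   consecutive non-missing entries.
#' @return List with `sigma_dot` and `n` (thresholds used).
#' @export
instability <- function(curve) {
  S <- if (inherits(curve, "stat_curve")) curve$S else as.numeric(curve)
  S <- S[!is.na(S)]
  n <- length(S)
  if (n < 2) stop("instability needs at least 2 thresholds")
  d <- diff(S)
  list(sigma_dot = sqrt(sum(d^2 / 2) / (n - 1)), n = n)
}

# n_rand x n_subjects indicator matrix of group-1 membership under random
# label permutations (uniform, with replacement across rows).
permutation_indicators <- function(n, n1, n_rand) {
  P <- matrix(0, n_rand, n)
  for (r in seq_len(n_rand)) P[r, sample.int(n, n1)] <- 1
  P
}

#' Permutation null ensemble of threshold-wise statistics
#'
#' Draws `n_rand` random group-label permutations and recomputes the test
#' statistic at every threshold under each permutation, with the same
#' label assignment used at every threshold within a permutation (so the
#' strong dependence of the statistic between neighbouring thresholds is
#' preserved in the null). Permutations are sampled uniformly with
#' replacement; the identity permutation is not forcibly included.
#'
#' Missing metric values are handled as in [stat_curve()]: the subject is
#' dropped at that threshold, and the threshold is `NA` when either
#' permuted group has fewer than 2 usable subjects.
#'
#' @inheritParams stat_curve
#' @param n_rand number of permutations (>= 1).
#' @param seed optional integer seed; recorded on the result.
#' @return A `null_ensemble` object: list with `S_perm` (`n_rand` x
#'   `n_tau` statistic matrix), matching `n1_eff`/`n2_eff` matrices,
#'   `statistic`, group sizes, and `seed`.
#' @export
permute_null <- function(values, labels, statistic = c("U", "t"),
                         n_rand = 1000, seed = NULL) {
  statistic <- match.arg(statistic)
  if (n_rand < 1) stop("`n_rand` must be >= 1")
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("`labels` must have exactly two levels")
  n <- nrow(values)
  n1 <- sum(labels == levels(labels)[1])
  n_tau <- ncol(values)
  P <- with_seed(seed, permutation_indicators(n, n1, n_rand))
  ok <- !is.na(values)
  V0 <- values; V0[!ok] <- 0
  S <- matrix(NA_real_, n_rand, n_tau)
  N1e <- P %*% ok                      # usable group-1 size per (perm, tau)
  N2e <- colSums(ok)[col(N1e)] ; dim(N2e) <- dim(N1e); N2e <- N2e - N1e
  if (statistic == "U") {
    # ranks within each column (midranks, NA excluded), then U via the
    # rank-sum identity, fully vectorised over permutations.
    R <- matrix(0, n, n_tau)
    for (j in seq_len(n_tau)) R[ok[, j], j] <- rank(values[ok[, j], j])
    R1 <- P %*% R
    S <- R1 - N1e * (N1e + 1) / 2
  } else {
    for (j in seq_len(n_tau)) {
      v <- values[, j]; okj <- ok[, j]
      nj <- sum(okj)
      if (nj < 4) next
      Pj <- P[, okj, drop = FALSE]
      vj <- v[okj]
      n1j <- rowSums(Pj); n2j <- nj - n1j
      s1 <- as.vector(Pj %*% vj); s2 <- sum(vj) - s1
      q1 <- as.vector(Pj %*% vj^2); q2 <- sum(vj^2) - q1
      var1 <- (q1 - s1^2 / n1j) / (n1j - 1)
      var2 <- (q2 - s2^2 / n2j) / (n2j - 1)
      sp2 <- ((n1j - 1) * var1 + (n2j - 1) * var2) / (nj - 2)
      tj <- (s1 / n1j - s2 / n2j) / sqrt(sp2 * (1 / n1j + 1 / n2j))
      tj[n1j < 2 | n2j < 2 | sp2 <= 0] <- NA_real_
      S[, j] <- tj
    }
  }
  S[N1e < 2 | N2e < 2] <- NA_real_
  structure(
    list(S_perm = S, n1_eff = N1e, n2_eff = N2e, statistic = statistic,
         n1 = n1, n2 = n - n1, n_rand = n_rand, seed = seed),
    class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %d permutations x %d thresholds (%s statistic)\n",
              nrow(x$S_perm), ncol(x$S_perm), x$statistic))
  invisible(x)
}

#' Instability of U-statistic curves under random group splits
#'
#' Replicates the random-groups instability experiment: subjects are
#' repeatedly split at random into two equal groups, the Mann-Whitney U
#' curve across thresholds is computed for each metric, and its
#' adjacent-threshold instability `sigma_dot` recorded. Non-network
#' control metrics (`n_edges`, `n_streamlines`) provide the reference
#' level of instability.
#'
#' @param cohort list of [connectome] objects (>= 4 subjects).
#' @param taus integer threshold grid.
#' @param metrics metric names to test (see [metric_names()]).
#' @param n_splits number of random group splits.
#' @param n_null,seed smallworldness null-ensemble size and master seed.
#' @param values optional pre-computed named list of subject x threshold
#'   matrices (one per metric), to avoid recomputation.
#' @return data.frame with columns `metric`, `sigma_dot` (mean across
#'   splits), `se` and `n_splits`.
#' @export
instability_experiment <- function(cohort, taus, metrics = metric_names(),
                                   n_splits = 250, n_null = 20, seed = NULL,
                                   values = NULL) {
  if (length(cohort) < 4) stop("need at least 4 subjects")
  n <- length(cohort)
  seeds <- child_seeds(seed, length(metrics) + 1L)
  if (is.null(values)) {
    values <- lapply(seq_along(metrics), function(m)
      cohort_metric_matrix(cohort, taus, metrics[m], n_null = n_null,
                           seed = seeds[[m]]))
    names(values) <- metrics
  }
  splits <- with_seed(seeds[[length(seeds)]],
    lapply(seq_len(n_splits), function(i) sample.int(n, floor(n / 2))))
  rows <- lapply(metrics, function(m) {
    sig <- vapply(splits, function(g1) {
      lab <- factor(ifelse(seq_len(n) %in% g1, "a", "b"))
      sc <- stat_curve(values[[m]], lab, taus = taus, statistic = "U")
      if (sum(!is.na(sc$S)) < 2) return(NA_real_)
      instability(sc)$sigma_dot
    }, numeric(1))
    sig <- sig[!is.na(sig)]
    data.frame(metric = m, sigma_dot = mean(sig),
               se = sd(sig) / sqrt(length(sig)), n_splits = length(sig))
  })
  do.call(rbind, rows)
}
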