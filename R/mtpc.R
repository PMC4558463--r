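#' MTPC configuration
#'
#' Bundles the tunable parameters of the multi-threshold permutation
#' correction: the confidence level, the permutation count, the threshold
#' grid, the effect direction and the statistic kind.
#'
#' @param alpha confidence level in (0, 1); the critical statistic is the
#'   upper `alpha` tail of the max-statistic null (5\% is the usual
#'   example value).
#' @param n_rand number of group-label permutations (500-1000 is a
#'   reasonable initial choice; at least 100 recommended).
#' @param taus integer threshold grid (unit spacing, starting at 0).
#' @param direction `"two_sided"` (default), `"upper"` or `"lower"`. For
#'   the U statistic, two-sided extremity is the centred absolute
#'   deviation `|U - n1 n2 / 2|`; for t it is `|t|`.
#' @param statistic `"U"` or `"t"`.
#' @param node_level set `TRUE` when `values` is a subjects x thresholds x
#'   nodes array of node-level metrics; the max-statistic null then pools
#'   over nodes as well as thresholds.
#' @param a_crit_zero_inclusive if `TRUE`, the critical cluster area
#'   averages over all permutations (counting permutations without any
#'   super-critical cluster as 0) instead of only permutations that have
#'   one.
#' @param widen_single_points if `TRUE`, a single-threshold cluster is
#'   widened by half-unit flanks so its trapezoidal area is nonzero;
#'   default off (a single-point cluster has zero area and so can only
#'   reject when the critical area is itself 0).
#' @param seed integer seed controlling the permutation draw.
#' @return An `mtpc_config` list.
#' @export
mtpc_config <- function(alpha = 0.05, n_rand = 1000, taus = 0:30,
                        direction = c("two_sided", "upper", "lower"),
                        statistic = c("U", "t"), node_level = FALSE,
                        a_crit_zero_inclusive = FALSE,
                        widen_single_points = FALSE, seed = NULL) {
  direction <- match.arg(direction)
  statistic <- match.arg(statistic)
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)")
  if (n_rand < 1) stop("`n_rand` must be >= 1")
  structure(list(alpha = alpha, n_rand = n_rand, taus = taus,
                 direction = direction, statistic = statistic,
                 node_level = node_level,
                 a_crit_zero_inclusive = a_crit_zero_inclusive,
                 widen_single_points = widen_single_points, seed = seed),
            class = "mtpc_config")
}

# Map raw statistics to the "extremity" scale on which larger = more
# extreme in the effect direction. `center` is the null centre of the
# statistic (n1*n2/2 for U, 0 for t), recycled to length(S).
effect_extremity <- function(S, direction, center = 0) {
  switch(direction,
         upper = S,
         lower = -S,
         two_sided = abs(S - center))
}

stat_center <- function(statistic, n1_eff, n2_eff) {
  if (statistic == "U") n1_eff * n2_eff / 2 else 0 * n1_eff
}

#' Max-statistic null distribution across thresholds
#'
#' Reduces a permutation ensemble to one summarised null statistic per
#' permutation: the most extreme statistic (in the effect direction)
#' across all thresholds, and across nodes as well when the ensemble is
#' node-level. This summarised distribution stochastically dominates any
#' single-threshold null column, which is what buys family-wise error
#' control over the threshold grid.
#'
#' @param ensemble a `null_ensemble` from [permute_null()], or a list of
#'   them (one per node) for node-level correction.
#' @param direction effect direction as in [mtpc_config()].
#' @return Numeric vector of length `n_rand` on the extremity scale;
#'   errors if every value of a permutation is masked.
#' @export
max_null_distribution <- function(ensemble,
                                  direction = c("two_sided", "upper", "lower")) {
  direction <- match.arg(direction)
  ens_list <- if (inherits(ensemble, "null_ensemble")) list(ensemble)
              else ensemble
  ext <- lapply(ens_list, function(e) {
    ctr <- stat_center(e$statistic, e$n1_eff, e$n2_eff)
    effect_extremity(e$S_perm, direction, ctr)
  })
  E <- do.call(cbind, ext)
  mx <- apply(E, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  if (all(is.na(mx))) stop("all permutation statistics are masked")
  mx
}

#' Critical statistic from a max-statistic null
#'
#' The upper `alpha` tail quantile of the summarised null distribution on
#' the extremity scale, using the linear-interpolation quantile (type 7),
#' so the critical value is bit-reproducible given the ensemble.
#'
#' @param max_null numeric vector from [max_null_distribution()].
#' @param alpha confidence level in (0, 1].
#' @return `S_crit` on the extremity scale; a degenerate (constant) null
#'   returns that constant with a warning.
#' @export
critical_value <- function(max_null, alpha = 0.05) {
  max_null <- max_null[!is.na(max_null)]
  if (!length(max_null)) stop("empty null distribution")
  if (length(unique(max_null)) == 1L) {
    warning("degenerate null distribution; S_crit equals the common value")
    return(max_null[1])
  }
  unname(quantile(max_null, probs = 1 - alpha, type = 7))
}

# Trapezoidal area of positive exceedance `e - crit` over a run of
# consecutive thresholds (unit spacing).
cluster_auc <- function(exceed, widen_single = FALSE) {
  if (length(exceed) == 1L)
    return(if (widen_single) exceed else 0)
  sum((exceed[-1] + exceed[-length(exceed)]) / 2)
}

#' Super-critical clusters of a statistic curve
#'
#' Finds maximal runs of consecutive thresholds where the observed
#' statistic is more extreme than the critical value in the effect
#' direction, and measures each run by the trapezoidal area of its
#' exceedance `|S - S_crit|` over the run (unit threshold spacing).
#'
#' @param curve a [stat_curve].
#' @param s_crit critical statistic on the extremity scale (from
#'   [critical_value()]).
#' @param direction effect direction.
#' @param widen_single_points see [mtpc_config()].
#' @return data.frame with one row per cluster: `tau_start`, `tau_end`,
#'   `auc`, `peak_S` (raw statistic at the most extreme point), and
#'   `peak_tau`. Zero rows when nothing is super-critical.
#' @export
find_clusters <- function(curve, s_crit,
                          direction = c("two_sided", "upper", "lower"),
                          widen_single_points = FALSE) {
  direction <- match.arg(direction)
  stopifnot(inherits(curve, "stat_curve"))
  ctr <- stat_center(curve$statistic, curve$n1_eff, curve$n2_eff)
  e <- effect_extremity(curve$S, direction, ctr)
  sup <- !is.na(e) & e > s_crit
  out <- data.frame(tau_start = numeric(0), tau_end = numeric(0),
                    auc = numeric(0), peak_S = numeric(0),
                    peak_tau = numeric(0))
  if (!any(sup)) return(out)
  r <- rle(sup)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (b in which(r$values)) {
    idx <- starts[b]:ends[b]
    exceed <- e[idx] - s_crit
    pk <- idx[which.max(e[idx])]
    out <- rbind(out, data.frame(
      tau_start = curve$tau[starts[b]], tau_end = curve$tau[ends[b]],
      auc = cluster_auc(exceed, widen_single_points),
      peak_S = curve$S[pk], peak_tau = curve$tau[pk]))
  }
  out
}

# Largest super-critical cluster area of one permutation row (0 if none).
row_max_cluster_auc <- function(e_row, s_crit, widen_single = FALSE) {
  sup <- !is.na(e_row) & e_row > s_crit
  if (!any(sup)) return(0)
  r <- rle(sup)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- 0
  for (b in which(r$values)) {
    exceed <- e_row[starts[b]:ends[b]] - s_crit
    best <- max(best, cluster_auc(exceed, widen_single))
  }
  best
}

#' Critical cluster area from the permutation ensemble
#'
#' The expected size of super-critical clusters arising from noise alone:
#' for each permutation, the largest super-critical cluster area is found
#' (0 when the permutation never exceeds `s_crit`); the critical area is
#' the mean over permutations that have at least one super-critical
#' cluster (or over all permutations when `zero_inclusive`).
#'
#' @param ensemble a `null_ensemble`, or list of them for node-level
#'   correction (the per-permutation maximum is then taken over nodes).
#' @param s_crit critical statistic on the extremity scale.
#' @param direction effect direction.
#' @param zero_inclusive average over all permutations instead of only
#'   super-critical ones.
#' @param widen_single_points see [mtpc_config()].
#' @return `A_crit` (0 when no permutation is ever super-critical).
#' @export
critical_auc <- function(ensemble, s_crit,
                         direction = c("two_sided", "upper", "lower"),
                         zero_inclusive = FALSE,
                         widen_single_points = FALSE) {
  direction <- match.arg(direction)
  ens_list <- if (inherits(ensemble, "null_ensemble")) list(ensemble)
              else ensemble
  per_node <- lapply(ens_list, function(e) {
    ctr <- stat_center(e$statistic, e$n1_eff, e$n2_eff)
    E <- effect_extremity(e$S_perm, direction, ctr)
    apply(E, 1, row_max_cluster_auc, s_crit = s_crit,
          widen_single = widen_single_points)
  })
  aucs <- do.call(pmax, per_node)
  if (zero_inclusive) return(mean(aucs))
  pos <- aucs[aucs > 0]
  if (!length(pos)) return(0)
  mean(pos)
}

#' Multi-threshold permutation correction
#'
#' The full MTPC procedure on a subjects x thresholds metric table:
#' (1) the observed statistic curve across thresholds; (2-3) a
#' permutation ensemble with the same label permutation applied at every
#' threshold; (4) the max-statistic null over thresholds (and nodes, for
#' node-level input); (5) the critical statistic `S_crit` from its upper
#' `alpha` tail; (6) super-critical clusters of the observed curve and
#' their areas; (7) the critical area `A_crit` from the permutations'
#' own super-critical clusters; (8) rejection iff a super-critical
#' cluster exists and its area exceeds `A_crit`.
#'
#' @param values numeric subjects x thresholds matrix (from
#'   [cohort_metric_matrix()]), or a subjects x thresholds x nodes array
#'   with `node_level = TRUE` in the config.
#' @param labels two-level group assignment, one per subject.
#' @param config an [mtpc_config()].
#' @return An `mtpc_result`: list with `s_crit`, `clusters`, `s_mtpc`
#'   (peak raw statistic inside the winning cluster), `tau_mtpc`,
#'   `a_mtpc` (largest cluster area), `a_crit`, `reject`, plus the
#'   observed curve(s), max-statistic null and provenance (config).
#' @export
mtpc <- function(values, labels, config = mtpc_config()) {
  stopifnot(inherits(config, "mtpc_config"))
  node_level <- config$node_level && length(dim(values)) == 3L
  slices <- if (node_level)
    lapply(seq_len(dim(values)[3]), function(k) values[, , k])
  else list(as.matrix(values))
  taus <- config$taus
  if (length(taus) != ncol(slices[[1]]))
    stop("length of config$taus must match ncol(values)")
  seeds <- child_seeds(config$seed, length(slices))
  curves <- lapply(slices, stat_curve, labels = labels, taus = taus,
                   statistic = config$statistic)
  # one shared permutation draw across nodes keeps the node-level max
  # statistic honest: the same relabelling is applied everywhere
  perm_seed <- if (is.null(config$seed)) NULL else seeds[[1]]
  ensembles <- lapply(slices, function(v)
    permute_null(v, labels, statistic = config$statistic,
                 n_rand = config$n_rand, seed = perm_seed))
  mx <- max_null_distribution(ensembles, config$direction)
  s_crit <- critical_value(mx, config$alpha)
  cl_list <- lapply(curves, find_clusters, s_crit = s_crit,
                    direction = config$direction,
                    widen_single_points = config$widen_single_points)
  clusters <- do.call(rbind, lapply(seq_along(cl_list), function(k) {
    cl <- cl_list[[k]]
    if (nrow(cl)) cl$node <- k
    cl
  }))
  a_crit <- critical_auc(ensembles, s_crit, config$direction,
                         zero_inclusive = config$a_crit_zero_inclusive,
                         widen_single_points = config$widen_single_points)
  if (!is.null(clusters) && nrow(clusters)) {
    best <- which.max(clusters$auc)
    a_mtpc <- clusters$auc[best]
    s_mtpc <- clusters$peak_S[best]
    tau_mtpc <- clusters$peak_tau[best]
  } else {
    clusters <- data.frame(tau_start = numeric(0), tau_end = numeric(0),
                           auc = numeric(0), peak_S = numeric(0),
                           peak_tau = numeric(0), node = integer(0))
    a_mtpc <- 0; s_mtpc <- NA_real_; tau_mtpc <- NA_real_
  }
  reject <- nrow(clusters) > 0 && a_mtpc > a_crit
  structure(
    list(s_crit = s_crit, clusters = clusters, s_mtpc = s_mtpc,
         tau_mtpc = tau_mtpc, a_mtpc = a_mtpc, a_crit = a_crit,
         reject = reject, max_null = mx,
         curve = if (node_level) curves else curves[[1]],
         config = config),
    class = "mtpc_result")
}

#' @export
print.mtpc_result <- function(x, ...) {
  cat("<mtpc_result>\n")
  cat(sprintf("  S_crit (extremity scale): %.4g\n", x$s_crit))
  cat(sprintf("  clusters: %d\n", nrow(x$clusters)))
  if (nrow(x$clusters))
    cat(sprintf("  S_MTPC = %.4g at tau = %g; A_MTPC = %.4g vs A_crit = %.4g\n",
                x$s_mtpc, x$tau_mtpc, x$a_mtpc, x$a_crit))
  cat(sprintf("  reject H0: %s\n", if (x$reject) "YES" else "no"))
  invisible(x)
}

# Per-subject trapezoidal area under the metric-vs-threshold curve,
# integrating over non-missing thresholds at their actual spacing.
subject_auc <- function(v, taus) {
  ok <- !is.na(v)
  if (sum(ok) < 2) return(NA_real_)
  x <- taus[ok]; y <- v[ok]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' AUC-method group test (comparator to MTPC)
#'
#' The established alternative multi-threshold summary: each subject's
#' metric-vs-threshold curve is reduced to its trapezoidal area before a
#' single group test. The same permutation machinery used by [mtpc()]
#' calibrates the statistic. Because the curve is collapsed before
#' testing, effects confined to a narrow threshold window are diluted by
#' the rest of the curve - the failure mode MTPC was designed to avoid.
#'
#' @inheritParams mtpc
#' @return List with `statistic` (raw group statistic on the AUCs),
#'   `extremity`, `crit` (extremity-scale critical value), `reject`,
#'   `auc` (per-subject areas) and `config`.
#' @export
auc_method <- function(values, labels, config = mtpc_config()) {
  stopifnot(inherits(config, "mtpc_config"))
  values <- as.matrix(values)
  taus <- config$taus
  if (length(taus) != ncol(values))
    stop("length of config$taus must match ncol(values)")
  aucs <- apply(values, 1, subject_auc, taus = taus)
  A <- matrix(aucs, ncol = 1)
  curve <- stat_curve(A, labels, taus = 0, statistic = config$statistic)
  perm_seed <- if (is.null(config$seed)) NULL
               else child_seeds(config$seed, 1L)[[1]]
  ens <- permute_null(A, labels, statistic = config$statistic,
                      n_rand = config$n_rand, seed = perm_seed)
  mx <- max_null_distribution(ens, config$direction)
  crit <- critical_value(mx, config$alpha)
  ctr <- stat_center(config$statistic, curve$n1_eff, curve$n2_eff)
  e_obs <- effect_extremity(curve$S, config$direction, ctr)
  list(statistic = curve$S[1], extremity = e_obs[1], crit = crit,
       reject = isTRUE(e_obs[1] > crit), auc = aucs, config = config)
}

#' Minimum detectable effect size by critical-value crossing
#'
#' Given a statistic and its critical value evaluated on a grid of effect
#' sizes (e.g. atrophy scale), returns the effect size at which the
#' statistic first crosses its critical value, linearly interpolated
#' between the bracketing grid points. Both sequences are interpreted on
#' the extremity scale (larger = more extreme), so a crossing is from
#' below-critical to above-critical.
#'
#' @param effect numeric grid of effect sizes (increasing).
#' @param stat statistic per effect size (extremity scale).
#' @param crit critical value per effect size (same grid; may be a
#'   single value, recycled).
#' @return The interpolated crossing point, or `NA` when the statistic
#'   never exceeds its critical value on the grid. A crossing exactly at
#'   a grid point returns that grid value; a statistic already critical
#'   at the smallest effect returns the first grid value.
#' @export
min_detectable_effect <- function(effect, stat, crit) {
  if (length(crit) == 1L) crit <- rep(crit, length(effect))
  if (length(effect) != length(stat) || length(effect) != length(crit))
    stop("`effect`, `stat` and `crit` must share one grid")
  d <- stat - crit
  above <- d >= 0
  if (!any(above, na.rm = TRUE)) return(NA_real_)
  k <- which(above)[1]
  if (k == 1L || is.na(d[k - 1L]) || d[k] == 0) return(effect[k])
  # linear interpolation between the bracketing grid points
  x0 <- effect[k - 1L]; x1 <- effect[k]
  y0 <- d[k - 1L]; y1 <- d[k]
  x0 + (0 - y0) * (x1 - x0) / (y1 - y0)
}
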