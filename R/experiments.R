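#' Configuration for a canned simulation experiment
#'
#' A single object driving [run_experiment()]: which experiment to run,
#' the generative spec, the perturbation / threshold / atrophy grids, the
#' randomisation counts and the master seed. Defaults are desk-scale
#' (40-node networks, modest randomisation counts); full-scale presets (116-node, higher randomisation counts)
#' are obtained by raising `R`, `n_rand` and `spec$n_nodes`.
#'
#' @param experiment one of `"exp1a"` (false-positive injection),
#'   `"exp1b"` (edge displacement), `"exp1c"` (thresholding of corrupted
#'   networks), `"exp2a"` (instability under random splits), `"exp2b"`
#'   (atrophy detection across thresholds), `"exp2c"` (MTPC vs the AUC
#'   method across atrophy levels).
#' @param spec a [synthetic_spec()]; by default the perturbation
#'   experiments (exp1a-1c) use the pruned-model preset
#'   [model_network_spec()] and the cohort experiments (exp2a-2c) the
#'   whole-brain-regime [synthetic_spec()], mirroring the two kinds of
#'   dataset the experiments are designed around.
#' @param k_values false-positive / displacement counts to test.
#' @param xi_values atrophy scales to test.
#' @param taus integer threshold grid.
#' @param R number of perturbation randomisations (exp1a-1c).
#' @param n_splits number of random group splits (exp2a).
#' @param n_rand number of label permutations (exp2b-2c).
#' @param n_subjects cohort size (exp2a-2c).
#' @param metrics metric names to evaluate.
#' @param alpha confidence level for MTPC / AUC tests.
#' @param n_null smallworldness null-ensemble size.
#' @param seed master seed; every emitted table records it.
#' @param outdir output directory for CSVs (`NULL` = return only).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(experiment = c("exp1a", "exp1b", "exp1c",
                                             "exp2a", "exp2b", "exp2c"),
                              spec = NULL,
                              k_values = c(0, 1, 2, 5, 10, 20),
                              xi_values = seq(0, 0.3, by = 0.05),
                              taus = 0:10, R = 50, n_splits = 100,
                              n_rand = 200, n_subjects = 40,
                              metrics = c("global_efficiency",
                                          "mean_clustering",
                                          "mean_betweenness",
                                          "smallworldness"),
                              alpha = 0.05, n_null = 20, seed = 1,
                              outdir = NULL) {
  experiment <- match.arg(experiment)
  if (is.null(spec))
    spec <- if (experiment %in% c("exp1a", "exp1b", "exp1c"))
      model_network_spec() else synthetic_spec()
  structure(list(experiment = experiment, spec = spec, k_values = k_values,
                 xi_values = xi_values, taus = taus, R = R,
                 n_splits = n_splits, n_rand = n_rand,
                 n_subjects = n_subjects, metrics = metrics, alpha = alpha,
                 n_null = n_null, seed = seed, outdir = outdir),
            class = "experiment_config")
}

stamp <- function(df, cfg) {
  df$experiment <- cfg$experiment
  df$seed <- cfg$seed
  df$version <- as.character(utils::packageVersion("mtpconn"))
  df
}

emit <- function(df, cfg, name) {
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(df, file.path(cfg$outdir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  df
}

# Metrics of one connectome as a named vector (deterministic given seed).
metric_vector <- function(conn, metrics, n_null, seed) {
  vapply(metrics, function(m)
    tryCatch(as.numeric(eval_metric(conn, m, n_null = n_null, seed = seed)),
             error = function(e) NA_real_), numeric(1))
}

# Shared machinery of exp1a / exp1b: corrupt `truth` R times at each k,
# summarise proportional change and z per metric.
perturbation_experiment <- function(cfg, corrupt) {
  seeds <- child_seeds(cfg$seed, 3L)
  truth <- generate_ground_truth(cfg$spec, seed = seeds[[1]])
  sup <- generate_fp_superset(truth, cfg$spec, seed = seeds[[2]])
  cand <- split_candidates(sup, truth)
  truth_m <- metric_vector(truth, cfg$metrics, cfg$n_null, seeds[[3]])
  kinds <- corrupt(NULL, NULL, NULL, kinds_only = TRUE)
  rows <- list()
  for (kind in kinds) {
    for (k in cfg$k_values) {
      rseeds <- child_seeds(cfg$seed + k + 1000L * match(kind, kinds), cfg$R)
      vals <- vapply(seq_len(cfg$R), function(r) {
        pert <- corrupt(truth, k, cand, kind = kind, seed = rseeds[[r]])
        metric_vector(pert, cfg$metrics, cfg$n_null, rseeds[[r]])
      }, numeric(length(cfg$metrics)))
      vals <- matrix(vals, nrow = length(cfg$metrics))
      for (m in seq_along(cfg$metrics)) {
        if (!is.finite(truth_m[m]) || truth_m[m] == 0) next
        ps <- perturbation_summary(vals[m, ], truth_m[m])
        rows[[length(rows) + 1L]] <- data.frame(
          kind = kind, k = k, metric = cfg$metrics[m],
          mean_prop_change = ps$mean, se = ps$se, z = ps$z)
      }
    }
  }
  do.call(rbind, rows)
}

run_exp1a <- function(cfg) {
  corrupt <- function(truth, k, cand, kind = NULL, seed = NULL,
                      kinds_only = FALSE) {
    if (kinds_only) return(c("FP_NE", "FP_EE"))
    if (k == 0) return(truth)
    if (kind == "FP_NE") add_fp_ne(truth, min(k, nrow(cand$ne)), cand$ne,
                                   seed = seed)
    else add_fp_ee(truth, k, cand$ee, seed = seed)
  }
  emit(stamp(perturbation_experiment(cfg, corrupt), cfg), cfg, "exp1a_fp")
}

run_exp1b <- function(cfg) {
  corrupt <- function(truth, k, cand, kind = NULL, seed = NULL,
                      kinds_only = FALSE) {
    if (kinds_only) return("DISPLACE")
    if (k == 0) return(truth)
    displace_edges(truth, k, seed = seed)
  }
  emit(stamp(perturbation_experiment(cfg, corrupt), cfg), cfg,
       "exp1b_displacement")
}

run_exp1c <- function(cfg) {
  seeds <- child_seeds(cfg$seed, 3L)
  truth <- generate_ground_truth(cfg$spec, seed = seeds[[1]])
  sup <- generate_fp_superset(truth, cfg$spec, seed = seeds[[2]])
  cand <- split_candidates(sup, truth)
  # thresholded-truth reference metrics per tau
  truth_by_tau <- lapply(cfg$taus, function(tau)
    metric_vector(apply_threshold(truth, tau), cfg$metrics, cfg$n_null,
                  seeds[[3]]))
  truth_unthr <- truth_by_tau[[1]]
  rows <- list()
  for (k in cfg$k_values) {
    rseeds <- child_seeds(cfg$seed + 7919L * k, cfg$R)
    # only FP-EE: FP-NEs have count 1 and vanish at any positive threshold
    pert <- lapply(seq_len(cfg$R), function(r)
      if (k == 0) truth else add_fp_ee(truth, k, cand$ee, seed = rseeds[[r]]))
    for (ti in seq_along(cfg$taus)) {
      tau <- cfg$taus[ti]
      vals <- vapply(seq_len(cfg$R), function(r)
        metric_vector(apply_threshold(pert[[r]], tau), cfg$metrics,
                      cfg$n_null, rseeds[[r]]), numeric(length(cfg$metrics)))
      vals <- matrix(vals, nrow = length(cfg$metrics))
      for (m in seq_along(cfg$metrics)) {
        ref_intra <- truth_by_tau[[ti]][m]
        ref_inter <- truth_unthr[m]
        if (!is.finite(ref_intra) || ref_intra == 0 ||
            !is.finite(ref_inter) || ref_inter == 0) next
        pi_ <- perturbation_summary(vals[m, ], ref_intra)
        pe_ <- perturbation_summary(vals[m, ], ref_inter)
        rows[[length(rows) + 1L]] <- data.frame(
          k = k, tau = tau, metric = cfg$metrics[m],
          intra_prop_change = pi_$mean, intra_z = pi_$z,
          inter_prop_change = pe_$mean, inter_z = pe_$z)
      }
    }
  }
  emit(stamp(do.call(rbind, rows), cfg), cfg, "exp1c_thresholding")
}

run_exp2a <- function(cfg) {
  seeds <- child_seeds(cfg$seed, 3L)
  truth <- generate_ground_truth(cfg$spec, seed = seeds[[1]])
  cohort <- generate_cohort(truth, cfg$n_subjects, cfg$spec,
                            seed = seeds[[2]])
  metrics <- unique(c(cfg$metrics, "n_edges", "n_streamlines"))
  res <- instability_experiment(cohort, cfg$taus, metrics = metrics,
                                n_splits = cfg$n_splits,
                                n_null = cfg$n_null, seed = seeds[[3]])
  emit(stamp(res, cfg), cfg, "exp2a_instability")
}

run_exp2b <- function(cfg) {
  seeds <- child_seeds(cfg$seed, 4L)
  truth <- generate_ground_truth(cfg$spec, seed = seeds[[1]])
  cohort <- generate_cohort(truth, cfg$n_subjects, cfg$spec,
                            seed = seeds[[2]])
  metrics <- unique(c(cfg$metrics, "n_edges", "n_streamlines"))
  rows <- list()
  for (xi in cfg$xi_values) {
    ac <- make_atrophied_cohort(cohort, xi, seed = seeds[[3]])
    for (m in metrics) {
      vals <- cohort_metric_matrix(ac$cohort, cfg$taus, m,
                                   n_null = cfg$n_null, seed = seeds[[4]])
      sc <- stat_curve(vals, ac$labels, taus = cfg$taus, statistic = "U")
      ens <- permute_null(vals, ac$labels, statistic = "U",
                          n_rand = cfg$n_rand, seed = seeds[[4]])
      lo <- apply(ens$S_perm, 2, quantile, probs = cfg$alpha / 2,
                  na.rm = TRUE, type = 7)
      hi <- apply(ens$S_perm, 2, quantile, probs = 1 - cfg$alpha / 2,
                  na.rm = TRUE, type = 7)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, xi = xi, tau = cfg$taus, U = sc$S,
        null_lo = lo, null_hi = hi)
    }
  }
  emit(stamp(do.call(rbind, rows), cfg), cfg, "exp2b_atrophy")
}

run_exp2c <- function(cfg) {
  seeds <- child_seeds(cfg$seed, 4L)
  truth <- generate_ground_truth(cfg$spec, seed = seeds[[1]])
  cohort <- generate_cohort(truth, cfg$n_subjects, cfg$spec,
                            seed = seeds[[2]])
  rows <- list()
  for (m in cfg$metrics) {
    stat_grid <- crit_grid <- auc_grid <- auc_crit_grid <- numeric(0)
    for (xi in cfg$xi_values) {
      ac <- make_atrophied_cohort(cohort, xi, seed = seeds[[3]])
      vals <- cohort_metric_matrix(ac$cohort, cfg$taus, m,
                                   n_null = cfg$n_null, seed = seeds[[4]])
      config <- mtpc_config(alpha = cfg$alpha, n_rand = cfg$n_rand,
                            taus = cfg$taus, statistic = "U",
                            seed = seeds[[4]])
      mres <- mtpc(vals, ac$labels, config)
      ares <- auc_method(vals, ac$labels, config)
      rows[[length(rows) + 1L]] <- data.frame(
        method = c("MTPC", "AUC"), metric = m, xi = xi,
        statistic = c(mres$a_mtpc, ares$extremity),
        critical = c(mres$a_crit, ares$crit),
        reject = c(mres$reject, ares$reject))
      stat_grid <- c(stat_grid, mres$a_mtpc)
      crit_grid <- c(crit_grid, mres$a_crit)
      auc_grid <- c(auc_grid, ares$extremity)
      auc_crit_grid <- c(auc_crit_grid, ares$crit)
    }
    xi_star_mtpc <- min_detectable_effect(cfg$xi_values, stat_grid, crit_grid)
    xi_star_auc <- min_detectable_effect(cfg$xi_values, auc_grid,
                                         auc_crit_grid)
    rows[[length(rows) + 1L]] <- data.frame(
      method = c("MTPC", "AUC"), metric = m, xi = NA_real_,
      statistic = NA_real_, critical = NA_real_, reject = NA)
    rows[[length(rows)]]$xi_star <- c(xi_star_mtpc, xi_star_auc)
  }
  res <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$xi_star)) r$xi_star <- NA_real_
    r
  }))
  emit(stamp(res, cfg), cfg, "exp2c_mtpc_vs_auc")
}

#' Run a canned simulation experiment
#'
#' Executes the experiment selected in the config on synthetic
#' connectomes and returns (and optionally writes, as CSV under
#' `config$outdir`) a tidy result table. Every row carries the experiment
#' id, master seed and package version. Reruns with an identical config
#' produce identical tables.
#'
#' @param config an [experiment_config()].
#' @return The result data.frame, invisibly when written to disk.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  res <- switch(config$experiment,
                exp1a = run_exp1a(config),
                exp1b = run_exp1b(config),
                exp1c = run_exp1c(config),
                exp2a = run_exp2a(config),
                exp2b = run_exp2b(config),
                exp2c = run_exp2c(config))
  if (is.null(config$outdir)) res else invisible(res)
}
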