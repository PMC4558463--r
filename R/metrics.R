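#' Weighted global network metrics
#'
#' Global metrics of weighted undirected networks following Brain
#' Connectivity Toolbox conventions: shortest paths run over edge lengths
#' `1/w` (strong connections are short), clustering is the Onnela
#' geometric-mean-of-triangle-weights form on weights rescaled by the
#' global maximum, and betweenness shares credit proportionally among tied
#' shortest paths.
#'
#' @param W symmetric nonnegative weight matrix, or a [connectome] (its
#'   proportion-weight matrix is used).
#' @return A single numeric value; see the individual functions.
#' @name network-metrics
NULL

as_weight_matrix <- function(W) {
  if (inherits(W, "connectome")) W <- W$W
  if (!is.matrix(W) || !is.numeric(W)) stop("`W` must be a numeric matrix")
  if (nrow(W) != ncol(W)) stop("`W` must be square")
  W
}

# Shortest-path distance matrix on lengths 1/w (Inf where unreachable).
weight_distances <- function(W) {
  L <- W
  nz <- W > 0
  L[nz] <- 1 / W[nz]
  L[!nz] <- 0
  .fw_distances(L)
}

#' @describeIn network-metrics mean inverse shortest-path distance over
#'   ordered node pairs (Latora-Marchiori global efficiency); disconnected
#'   pairs contribute 0, so the value lies in `[0, 1]` whenever no weight
#'   exceeds 1. A measure of network integration.
#' @export
global_efficiency <- function(W) {
  W <- as_weight_matrix(W)
  n <- nrow(W)
  if (n < 2) stop("global efficiency needs at least 2 nodes")
  D <- weight_distances(W)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' @describeIn network-metrics characteristic path length: the mean
#'   shortest-path distance over connected (finite-distance) ordered node
#'   pairs; `NA` when no pair is connected.
#' @export
char_path_length <- function(W) {
  W <- as_weight_matrix(W)
  D <- weight_distances(W)
  diag(D) <- NA
  fin <- is.finite(D)
  if (!any(fin, na.rm = TRUE)) return(NA_real_)
  mean(D[which(fin)])
}

#' @describeIn network-metrics mean weighted clustering coefficient
#'   (Onnela form): per node, the geometric mean of triangle weights
#'   (rescaled by the maximum weight) summed over triangles through the
#'   node, divided by `k(k-1)` for node degree `k`; nodes with degree < 2
#'   contribute 0. A measure of segregation.
#' @export
mean_clustering <- function(W) {
  W <- as_weight_matrix(W)
  n <- nrow(W)
  if (n < 3) {
    warning("clustering is undefined for fewer than 3 nodes; returning 0")
    return(0)
  }
  mx <- max(W)
  if (mx == 0) return(0)
  Ws <- (W / mx)^(1 / 3)
  cyc3 <- diag(Ws %*% Ws %*% Ws)
  k <- colSums(W > 0)
  denom <- k * (k - 1)
  ci <- ifelse(denom > 0, cyc3 / denom, 0)
  mean(ci)
}

#' @describeIn network-metrics mean betweenness centrality on `1/w` edge
#'   lengths, unnormalised, with each unordered pair's shortest paths
#'   counted once and ties sharing credit proportionally.
#' @export
mean_betweenness <- function(W) {
  W <- as_weight_matrix(W)
  n <- nrow(W)
  if (n < 3) return(0)
  if (all(W == 0)) return(0)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  b <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
                           normalized = FALSE)
  mean(b)
}

# One draw from the small-world null model: same node count and edge
# count, edges placed uniformly at random among node pairs, the observed
# weight multiset permuted onto the new edges.
random_same_density <- function(W) {
  n <- nrow(W)
  ut <- upper.tri(W)
  w <- W[ut & W > 0]
  m <- length(w)
  R <- matrix(0, n, n)
  slots <- which(ut)
  pick <- sample(slots, m)
  R[pick] <- sample(w)
  R + t(R)
}

#' Smallworldness against a same-density random null ensemble
#'
#' Computes `(C / C_rand) / (L / L_rand)` where `C` is the mean weighted
#' clustering coefficient, `L` the characteristic path length over
#' connected pairs, and `C_rand`, `L_rand` are ensemble means over
#' `n_null` random networks with the same node count, edge count and
#' weight multiset (edges re-placed uniformly at random). Values above 1
#' indicate small-world organisation: more clustered than random while
#' remaining about as integrated.
#'
#' @param W symmetric nonnegative weight matrix or [connectome].
#' @param n_null size of the random null ensemble.
#' @param seed optional integer seed for the null ensemble.
#' @return Numeric smallworldness, or `NA` when undefined (empty graph, or
#'   any normaliser zero or undefined).
#' @export
smallworldness <- function(W, n_null = 20, seed = NULL) {
  W <- as_weight_matrix(W)
  if (all(W == 0) || nrow(W) < 3) return(NA_real_)
  C <- mean_clustering(W)
  L <- char_path_length(W)
  if (is.na(L) || is.na(C)) return(NA_real_)
  nulls <- with_seed(seed, lapply(seq_len(n_null), function(i) {
    R <- random_same_density(W)
    c(mean_clustering(R), char_path_length(R))
  }))
  nulls <- do.call(rbind, nulls)
  C_rand <- mean(nulls[, 1], na.rm = TRUE)
  L_rand <- mean(nulls[, 2], na.rm = TRUE)
  if (!is.finite(C_rand) || !is.finite(L_rand) ||
      C_rand == 0 || L_rand == 0 || L == 0)
    return(NA_real_)
  (C / C_rand) / (L / L_rand)
}

#' Edge and streamline totals of a connectome
#'
#' The two non-network control metrics: the number of (unordered) edges
#' with at least one streamline, and the total streamline count.
#'
#' @param conn a [connectome].
#' @return Named numeric vector `c(n_edges = ..., n_streamlines = ...)`.
#' @export
count_metrics <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  ut <- upper.tri(conn$C)
  c(n_edges = sum(conn$C[ut] > 0), n_streamlines = sum(conn$C[ut]))
}

#' Names of the metrics understood by the sweep functions
#' @return Character vector of metric names.
#' @export
metric_names <- function() {
  c("global_efficiency", "mean_clustering", "mean_betweenness",
    "smallworldness", "n_edges", "n_streamlines")
}

# Evaluate one named metric on a (possibly thresholded) connectome.
eval_metric <- function(conn, metric, n_null = 20, seed = NULL) {
  switch(metric,
    global_efficiency = global_efficiency(conn$W),
    mean_clustering   = mean_clustering(conn$W),
    mean_betweenness  = mean_betweenness(conn$W),
    smallworldness    = smallworldness(conn$W, n_null = n_null, seed = seed),
    n_edges           = unname(count_metrics(conn)["n_edges"]),
    n_streamlines     = unname(count_metrics(conn)["n_streamlines"]),
    stop("unknown metric: ", metric))
}

#' Sweep network metrics across streamline-count thresholds
#'
#' Applies [apply_threshold()] at every `tau` and evaluates each requested
#' metric on the surviving, re-normalised network. Metrics that are
#' undefined at a given threshold (e.g. smallworldness once the graph is
#' empty) are returned as `NA` with `missing = TRUE` rather than erroring.
#'
#' @param conn a [connectome].
#' @param taus integer threshold grid (typically `0:n_tau`, unit spacing).
#' @param metrics character vector of metric names (see [metric_names()]).
#' @param n_null,seed passed to [smallworldness()]; the seed makes the
#'   sweep deterministic.
#' @return A data.frame with columns `tau`, `metric`, `value`, `missing`.
#' @export
metric_sweep <- function(conn, taus, metrics = metric_names(),
                         n_null = 20, seed = NULL) {
  stopifnot(inherits(conn, "connectome"))
  bad <- setdiff(metrics, metric_names())
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
  seeds <- child_seeds(seed, length(taus))
  rows <- lapply(seq_along(taus), function(i) {
    thr <- apply_threshold(conn, taus[i])
    vals <- vapply(metrics, function(m) {
      v <- tryCatch(eval_metric(thr, m, n_null = n_null, seed = seeds[[i]]),
                    error = function(e) NA_real_)
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    data.frame(tau = taus[i], metric = metrics, value = unname(vals),
               missing = is.na(vals), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Subject-by-threshold metric matrix for a cohort
#'
#' Evaluates one metric for every subject at every threshold; this
#' subjects x thresholds matrix is the common input of the group-statistic
#' and MTPC machinery.
#'
#' @param cohort list of [connectome] objects.
#' @param taus integer threshold grid.
#' @param metric a single metric name (see [metric_names()]).
#' @param n_null,seed passed to [smallworldness()].
#' @return Numeric matrix, `length(cohort)` rows and `length(taus)`
#'   columns; `NA` marks undefined values.
#' @export
cohort_metric_matrix <- function(cohort, taus, metric, n_null = 20,
                                 seed = NULL) {
  stopifnot(length(metric) == 1L)
  seeds <- child_seeds(seed, length(cohort))
  out <- t(vapply(seq_along(cohort), function(s) {
    ms <- metric_sweep(cohort[[s]], taus, metrics = metric,
                       n_null = n_null, seed = seeds[[s]])
    ms$value
  }, numeric(length(taus))))
  dimnames(out) <- list(names(cohort), paste0("tau", taus))
  out
}
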