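# Independent brute-force oracles for the path-based metrics. These use
# min-plus matrix powering and direct enumeration, deliberately different
# algorithms from the package's Floyd-Warshall / igraph routes.

# All-pairs shortest paths by repeated min-plus squaring of the length
# matrix (lengths 1/w, no edge = Inf).
oracle_distances <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (it in seq_len(ceiling(log2(max(n, 2))))) {
    Dn <- D
    for (i in seq_len(n)) for (j in seq_len(n))
      Dn[i, j] <- min(D[i, ] + D[, j])
    D <- Dn
  }
  D
}

oracle_efficiency <- function(W) {
  n <- nrow(W)
  D <- oracle_distances(W)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_charpath <- function(W) {
  D <- oracle_distances(W)
  diag(D) <- NA
  fin <- is.finite(D)
  if (!any(fin, na.rm = TRUE)) return(NA_real_)
  mean(D[which(fin)])
}

# Number of shortest paths between every pair, by dynamic programming on
# the distance matrix: sigma[s,t] sums sigma[s,u] over predecessors u of
# t (neighbours with d[s,u] + l(u,t) == d[s,t]), filling targets in
# order of increasing distance from s.
oracle_path_counts <- function(W, D, tol = 1e-9) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      pred <- which(W[, t] > 0 & abs(D[s, ] + L[, t] - D[s, t]) < tol)
      sigma[s, t] <- sum(sigma[s, pred])
    }
  }
  sigma
}

# Betweenness by the pair-dependency formula: for each node v and pair
# (s,t), the fraction of shortest s-t paths through v, each unordered
# pair counted once.
oracle_betweenness <- function(W, tol = 1e-9) {
  n <- nrow(W)
  D <- oracle_distances(W)
  sigma <- oracle_path_counts(W, D, tol)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || sigma[s, t] == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (abs(D[s, v] + D[v, t] - D[s, t]) < tol)
        b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  b
}

# Onnela clustering by direct triangle enumeration on max-rescaled
# weights.
oracle_clustering <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (mx == 0) return(0)
  Ws <- W / mx
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    acc <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      j <- nb[a]; l <- nb[b]
      if (W[j, l] > 0)
        acc <- acc + (Ws[i, j] * Ws[i, l] * Ws[j, l])^(1 / 3)
    }
    ci[i] <- 2 * acc / (k * (k - 1))
  }
  mean(ci)
}

# Random connected-ish weighted graph for oracle trials.
random_weight_matrix <- function(n, p = 0.5, integer_counts = FALSE) {
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- ut[runif(length(ut)) < p]
  W[on] <- if (integer_counts) sample.int(9, length(on), replace = TRUE)
           else runif(length(on), 0.05, 1)
  W + t(W)
}

# Small connectome from explicit upper-triangle counts.
make_conn <- function(counts_ut, n, hemisphere = NULL) {
  C <- matrix(0, n, n)
  C[upper.tri(C)] <- counts_ut
  C <- C + t(C)
  connectome(C, hemisphere = hemisphere)
}
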