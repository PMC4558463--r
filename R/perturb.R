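#' Candidate false-positive edge sets from a streamline superset
#'
#' Partitions the edges of a raw "superset" connectome (streamlines prior
#' to any pruning or segmentation) against a ground-truth network into two
#' candidate pools: \strong{NE} candidates (superset edges absent from the
#' truth, whose injection creates a new edge) and \strong{EE} candidates
#' (truth edges the superset overcounts; only the surplus streamlines beyond
#' the truth count enter the pool). Within each pool, a candidate edge's
#' sampling probability is its streamline count divided by the pool total,
#' mirroring the rate at which a tractography pipeline would emit that
#' false positive.
#'
#' @param superset [connectome] of all raw streamlines (must contain the
#'   truth elementwise).
#' @param truth ground-truth [connectome] on the same node set.
#' @return List with elements `ne` and `ee`, each an `fp_candidates`
#'   object: a data.frame of columns `i`, `j` (upper-triangle node
#'   indices), `count` and `prob`, with attribute `kind`.
#' @export
split_candidates <- function(superset, truth) {
  stopifnot(inherits(superset, "connectome"), inherits(truth, "connectome"))
  if (!identical(superset$labels, truth$labels))
    stop("superset and truth must share the same node set")
  ut <- which(upper.tri(truth$C), arr.ind = TRUE)
  cs <- superset$C[upper.tri(superset$C)]
  ct <- truth$C[upper.tri(truth$C)]
  make_set <- function(keep, count, kind) {
    df <- data.frame(i = ut[keep, 1], j = ut[keep, 2], count = count[keep])
    df$prob <- if (nrow(df)) df$count / sum(df$count) else numeric(0)
    structure(df, kind = kind, class = c("fp_candidates", "data.frame"))
  }
  ne_keep <- ct == 0 & cs > 0
  surplus <- pmax(cs - ct, 0)
  ee_keep <- ct > 0 & surplus > 0
  list(ne = make_set(ne_keep, cs, "NE"),
       ee = make_set(ee_keep, surplus, "EE"))
}

#' Inject false positives that create new edges (FP-NE)
#'
#' Samples `k` distinct candidate edges without replacement, with
#' probability proportional to their superset streamline counts, and adds
#' each as a new edge carrying a single streamline (one false positive is
#' one streamline, and each FP-NE creates a unique edge). Weights are
#' re-normalised to the new streamline total, so the edge count rises by
#' exactly `k` and the streamline count by exactly `k`.
#'
#' @param conn [connectome] to corrupt.
#' @param k number of false positives (each one a new edge).
#' @param cand NE candidate set from [split_candidates()].
#' @param seed optional integer seed.
#' @return The corrupted [connectome].
#' @export
add_fp_ne <- function(conn, k, cand, seed = NULL) {
  stopifnot(inherits(conn, "connectome"))
  if (!identical(attr(cand, "kind"), "NE")) stop("`cand` must be the NE set")
  if (k == 0) return(conn)
  if (k > nrow(cand))
    stop("k = ", k, " exceeds the NE candidate pool (", nrow(cand), ")")
  pick <- with_seed(seed,
    sample.int(nrow(cand), k, replace = FALSE, prob = cand$prob))
  C <- conn$C
  for (r in pick) {
    C[cand$i[r], cand$j[r]] <- C[cand$i[r], cand$j[r]] + 1L
    C[cand$j[r], cand$i[r]] <- C[cand$j[r], cand$i[r]] + 1L
  }
  rebuild_connectome(conn, C)
}

#' Inject false positives onto existing edges (FP-EE)
#'
#' Adds `k` streamlines one at a time, with replacement, to candidate
#' existing edges sampled with probability proportional to their surplus
#' counts. The edge set is unchanged; the streamline total rises by `k`;
#' weights are re-normalised.
#'
#' @inheritParams add_fp_ne
#' @param cand EE candidate set from [split_candidates()].
#' @return The corrupted [connectome].
#' @export
add_fp_ee <- function(conn, k, cand, seed = NULL) {
  stopifnot(inherits(conn, "connectome"))
  if (!identical(attr(cand, "kind"), "EE")) stop("`cand` must be the EE set")
  if (conn$empty) stop("cannot add FP-EE to an empty network")
  if (k == 0) return(conn)
  if (nrow(cand) == 0) stop("empty EE candidate pool")
  pick <- with_seed(seed,
    sample.int(nrow(cand), k, replace = TRUE, prob = cand$prob))
  C <- conn$C
  for (r in pick) {
    C[cand$i[r], cand$j[r]] <- C[cand$i[r], cand$j[r]] + 1L
    C[cand$j[r], cand$i[r]] <- C[cand$j[r], cand$i[r]] + 1L
  }
  rebuild_connectome(conn, C)
}

# Default edge adjacency for displacement: two node pairs are adjacent
# when they share a node (a stand-in for volumetric bundle overlap).
default_displacement_targets <- function(n, i, j) {
  others <- setdiff(seq_len(n), c(i, j))
  rbind(cbind(pmin(i, others), pmax(i, others)),
        cbind(pmin(j, others), pmax(j, others)))
}

#' Displace edges to adjacent vacant node pairs
#'
#' Moves `k` distinct edges, each with its full streamline count, to a
#' uniformly chosen vacant node pair adjacent to the original edge.
#' Adjacency defaults to sharing a node; supply `adjacency` to encode
#' e.g. volumetric bundle-overlap tables. Neither the number of edges nor
#' the number of streamlines changes.
#'
#' @inheritParams add_fp_ne
#' @param k number of edges to displace.
#' @param adjacency optional function `(i, j) -> two-column matrix` of
#'   candidate target pairs for the edge `(i, j)`.
#' @param max_retries bound on resampling when a drawn edge has no vacant
#'   admissible target.
#' @return The displaced [connectome].
#' @export
displace_edges <- function(conn, k, adjacency = NULL, seed = NULL,
                           max_retries = 100L) {
  stopifnot(inherits(conn, "connectome"))
  if (k == 0) return(conn)
  n <- nrow(conn$C)
  C <- conn$C
  with_seed(seed, {
    moved <- 0L
    tried <- 0L
    done <- integer(0)
    while (moved < k) {
      if (tried > max_retries + k)
        stop("could not find vacant adjacent targets after bounded retries")
      tried <- tried + 1L
      eidx <- which(upper.tri(C) & C > 0)
      eidx <- setdiff(eidx, done)
      if (!length(eidx)) stop("no remaining edges eligible for displacement")
      e <- if (length(eidx) == 1L) eidx else sample(eidx, 1L)
      j <- ((e - 1L) %/% n) + 1L
      i <- e - (j - 1L) * n
      targets <- if (is.null(adjacency)) default_displacement_targets(n, i, j)
                 else adjacency(i, j)
      if (is.null(targets) || nrow(targets) == 0) next
      vac <- targets[C[cbind(targets[, 1], targets[, 2])] == 0 &
                     targets[, 1] != targets[, 2], , drop = FALSE]
      if (nrow(vac) == 0) next
      t_row <- vac[if (nrow(vac) == 1L) 1L else sample.int(nrow(vac), 1L), ]
      w <- C[i, j]
      C[i, j] <- C[j, i] <- 0L
      C[t_row[1], t_row[2]] <- C[t_row[2], t_row[1]] <- w
      done <- c(done, as.integer((t_row[2] - 1L) * n + t_row[1]))
      moved <- moved + 1L
    }
  })
  rebuild_connectome(conn, C)
}

#' Simulate interhemispheric atrophy
#'
#' For every masked edge, a removal proportion `p = |z|` with
#' `z ~ Normal(0, xi^2)` (clipped at 1) is drawn, and the surviving count
#' is resampled as `Binomial(C, 1 - p)`, keeping counts integral. Unmasked
#' edges are untouched; weights are re-normalised to the surviving total.
#' The mask defaults to interhemispheric node pairs (differing hemisphere
#' tags), the connections implicated in callosal atrophy.
#'
#' @inheritParams add_fp_ne
#' @param xi nonnegative scale (standard deviation) of the half-normal
#'   removal-proportion distribution; `xi = 0` is the identity.
#' @param mask logical matrix selecting edges eligible for atrophy;
#'   defaults to the interhemispheric mask of `conn`.
#' @return The atrophied [connectome].
#' @export
apply_atrophy <- function(conn, xi, mask = NULL, seed = NULL) {
  stopifnot(inherits(conn, "connectome"))
  if (xi < 0) stop("`xi` must be nonnegative")
  if (xi == 0) return(conn)
  if (is.null(mask)) mask <- interhemispheric_mask(conn)
  C <- conn$C
  idx <- which(upper.tri(C) & mask & C > 0)
  if (length(idx)) {
    with_seed(seed, {
      p <- pmin(abs(rnorm(length(idx), 0, xi)), 1)
      keep <- rbinom(length(idx), C[idx], 1 - p)
      C[idx] <- keep
    })
    C <- C * upper.tri(C)
    C <- C + t(C)
  }
  rebuild_connectome(conn, C)
}

#' Summarise a perturbation experiment against the ground truth
#'
#' Given one metric value per randomisation of a perturbation and the
#' metric of the unperturbed truth, computes the proportional change per
#' randomisation and the standard z-score: the mean proportional change
#' normalised by its standard error across randomisations. A zero-variance
#' sample with nonzero mean yields an infinite z (flagged, not an error).
#'
#' @param values numeric vector: the metric under each randomisation.
#' @param truth_value the metric of the unperturbed network (nonzero).
#' @return List with `prop` (per-randomisation proportional changes),
#'   `mean`, `se` and `z`.
#' @export
perturbation_summary <- function(values, truth_value) {
  if (length(values) < 2) stop("need at least 2 randomisations")
  if (!is.finite(truth_value) || truth_value == 0)
    stop("truth metric must be finite and nonzero")
  prop <- (values - truth_value) / truth_value
  m <- mean(prop)
  se <- sd(prop) / sqrt(length(prop))
  z <- if (se == 0) {
    if (m == 0) 0 else sign(m) * Inf
  } else m / se
  list(prop = prop, mean = m, se = se, z = z)
}
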