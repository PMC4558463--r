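#' Specification for synthetic model connectomes
#'
#' Parameters of the generative model for ground-truth connectomes with
#' the structure of a manually segmented tractography network: clustered
#' fibre bundles confined to the left hemisphere, short-range U-fibres
#' between adjacent regions, interhemispheric edges restricted to
#' left-right homologues, and an exact mirror of the left hemisphere onto
#' the right.
#'
#' @param n_nodes even number of nodes; the first half are left-hemisphere
#'   (`L`), the second half right (`R`), with `mirror(i) = i + n/2`.
#'   Default 40 (desk scale); use 116 for an AAL-like dimensionality.
#' @param coverage fraction of each hemisphere's regions in the
#'   well-supported core (bundles, U-fibre lattice, callosal homologue
#'   edges); the remaining regions carry no segmented fibres, as atlas
#'   regions far from the major retained pathways have.
#' @param periph_scale mean streamline count of weak chain edges
#'   attaching the non-core regions; the default 0 leaves them isolated
#'   (a manually pruned model network retains nothing there), while a
#'   positive value hangs them off the core in sparse two-hop stubs.
#' @param n_bundles number of long-range association bundles per
#'   hemisphere; each connects a set of distant covered regions
#'   all-to-all.
#' @param bundle_size integer range (min, max) of regions per bundle.
#' @param intra_scale mean streamline count of intra-bundle links.
#' @param u_scale mean streamline count of U-fibres (edges between
#'   index-adjacent regions).
#' @param inter_scale mean streamline count of homologue interhemispheric
#'   (callosal) edges. The corpus callosum is by far the largest
#'   white-matter structure, and in whole-brain tractography its homologue
#'   edges are typically the heaviest in the network, hence the default of
#'   three times the association-bundle scale; [model_network_spec()]
#'   uses a callosal scale equal to the association scale, as a manually
#'   segmented single-subject model yields.
#' @param count_size negative-binomial size parameter of the per-edge
#'   count draws: small values (the default 1.5) give the heavy-tailed
#'   count distributions of whole-brain tractography, where every
#'   threshold removes real edge mass; larger values give the tight
#'   counts of consistently reconstructed, manually segmented bundles.
#' @param dispersion negative-binomial dispersion of inter-subject count
#'   noise: subject counts have variance `mu + dispersion * mu^2`
#'   (0 = subjects identical to the truth).
#' @param fp_superset_scale mean surplus streamline count per superset
#'   false-positive edge (0 = superset identical to the truth).
#' @param fp_ne_rate,fp_ee_rate mean number of FP-NE / FP-EE streamlines
#'   admixed per subject when generating cohorts.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_nodes = 40, coverage = 0.7, n_bundles = 4,
                           bundle_size = c(3, 5), intra_scale = 30,
                           u_scale = 8, inter_scale = 90, periph_scale = 0,
                           count_size = 1.5, dispersion = 0.05,
                           fp_superset_scale = 4,
                           fp_ne_rate = 5, fp_ee_rate = 5) {
  if (n_nodes %% 2 != 0) stop("`n_nodes` must be even (two hemispheres)")
  if (n_nodes < 6) stop("`n_nodes` too small")
  if (coverage <= 0 || coverage > 1) stop("`coverage` must be in (0, 1]")
  if (any(c(intra_scale, u_scale, inter_scale) <= 0))
    stop("count scales must be positive")
  if (bundle_size[2] > ceiling(coverage * n_nodes / 2))
    stop("bundle larger than the covered hemisphere is infeasible")
  structure(list(n_nodes = n_nodes, coverage = coverage,
                 n_bundles = n_bundles, periph_scale = periph_scale,
                 bundle_size = bundle_size, intra_scale = intra_scale,
                 u_scale = u_scale, inter_scale = inter_scale,
                 count_size = count_size, dispersion = dispersion,
                 fp_superset_scale = fp_superset_scale,
                 fp_ne_rate = fp_ne_rate, fp_ee_rate = fp_ee_rate),
            class = "synthetic_spec")
}

#' Preset for the pruned single-subject model network
#'
#' The false-positive injection and thresholding experiments operate on a
#' manually segmented, pruned model network from a single subject:
#' callosal homologue edges carry counts comparable to the association
#' bundles (rather than dominating the network as in whole-brain data)
#' and U-fibres are sparse, so the streamline-count threshold sweep
#' removes real edge mass at every level. [synthetic_spec()] with its
#' defaults is the whole-brain cohort regime; this preset only changes
#' those scales.
#'
#' @param ... overrides passed on to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
model_network_spec <- function(...) {
  args <- list(...)
  defaults <- list(inter_scale = 30, u_scale = 5)
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  do.call(synthetic_spec, args)
}

# Positive streamline count with mean `scale` (always >= 1). At the
# default size the distribution is heavy-tailed, as whole-brain per-edge
# streamline tallies are (many low-count edges, a few very large ones,
# so thresholds bite at every level); large `size` gives the tight
# counts of consistently reconstructed segmented bundles.
pos_count <- function(n, scale, size = 1.5)
  1L + rnbinom(n, mu = max(scale - 1, 0), size = size)

#' Generate a hemispherically mirrored ground-truth connectome
#'
#' Builds the left hemisphere of a segmented model network from three
#' fibre classes and mirrors it exactly onto the right:
#' \itemize{
#'   \item short-range U-fibres linking each covered region to its two
#'     nearest index-neighbours on either side, the locally clustered
#'     lattice of the cortical sheet;
#'   \item `n_bundles` long-range association bundles, each connecting a
#'     set of distant covered regions all-to-all (association pathways
#'     such as the arcuate or fronto-occipital fasciculi join region sets
#'     far apart on the sheet, providing shortcut redundancy);
#'   \item homologue-only interhemispheric (callosal) edges for core
#'     regions.
#' }
#' Only a `coverage` fraction of each hemisphere's regions belongs to
#' this well-supported core; the remaining regions carry no segmented
#' fibres and stay isolated (or, with `periph_scale > 0`, hang off the
#' core as sparse two-hop stubs), as atlas regions far from the major
#' segmented pathways do. All counts are positive integers, heavy-tailed
#' at the default `count_size`.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; the matrix is a deterministic function of
#'   `(spec, seed)`.
#' @return A [connectome] with hemisphere tags `L`/`R`.
#' @export
generate_ground_truth <- function(spec = synthetic_spec(), seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_nodes
  h <- n / 2
  cov <- max(spec$bundle_size[1], round(spec$coverage * h))
  C <- matrix(0, n, n)
  with_seed(seed, {
    # U-fibre lattice over the covered regions
    if (cov >= 2) for (i in seq_len(cov - 1L))
      C[i, i + 1L] <- C[i, i + 1L] + pos_count(1, spec$u_scale, spec$count_size)
    if (cov >= 3) for (i in seq_len(cov - 2L))
      C[i, i + 2L] <- C[i, i + 2L] + pos_count(1, spec$u_scale, spec$count_size)
    # association bundles: all-to-all among a distant member set
    for (b in seq_len(spec$n_bundles)) {
      size <- sample(spec$bundle_size[1]:spec$bundle_size[2], 1)
      mem <- sort(sample.int(cov, size))
      for (a in seq_len(size - 1L)) for (bb in (a + 1L):size) {
        i <- mem[a]; j <- mem[bb]
        C[i, j] <- C[i, j] + pos_count(1, spec$intra_scale, spec$count_size)
      }
    }
    # optional weakly attached periphery: sparse-count edges hanging off
    # the core in two-node stubs (at most two weak hops deep); with the
    # default periph_scale = 0 the non-core regions stay isolated
    if (spec$periph_scale > 0 && cov < h) for (p in (cov + 1L):h) {
      d <- p - cov
      anchor <- if (d %% 2L == 1L) ((d %/% 2L) %% cov) + 1L else p - 1L
      C[min(anchor, p), max(anchor, p)] <-
        C[min(anchor, p), max(anchor, p)] + pos_count(1, spec$periph_scale)
    }
    # mirror left-hemisphere fibres onto the right
    C[(h + 1):n, (h + 1):n] <- C[1:h, 1:h]
    # homologue-only interhemispheric edges for core regions
    for (i in seq_len(cov))
      C[i, i + h] <- pos_count(1, spec$inter_scale, spec$count_size)
  })
  C <- C * upper.tri(C)
  C <- C + t(C)
  connectome(C,
             labels = c(paste0("L", seq_len(h)), paste0("R", seq_len(h))),
             hemisphere = rep(c("L", "R"), each = h))
}

#' Generate a false-positive streamline superset around a truth network
#'
#' Emulates the raw tractography output before pruning: the truth plus a
#' heavy-tailed scatter of surplus streamlines, some on vacant node pairs
#' (future FP-NE candidates) and some on existing edges (future FP-EE
#' candidates). New-pair scatter counts are geometric with mean
#' `fp_superset_scale`, so a few candidate edges dominate the sampling
#' probability, as in empirical FP supersets. Overcounting of existing
#' edges concentrates on weakly supported connections, where streamline
#' assignment is least certain: edges at or below the median count
#' receive negative-binomial surplus with mean `fp_superset_scale`,
#' stronger edges a quarter of that. The superset contains the truth
#' elementwise; `fp_superset_scale = 0` returns the truth.
#'
#' @param truth ground-truth [connectome].
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @return The superset [connectome].
#' @export
generate_fp_superset <- function(truth, spec = synthetic_spec(),
                                 seed = NULL) {
  stopifnot(inherits(truth, "connectome"))
  if (spec$fp_superset_scale == 0) return(truth)
  C <- truth$C
  ut <- upper.tri(C)
  with_seed(seed, {
    vac <- which(ut & C == 0)
    n_new <- max(1L, round(0.15 * length(vac)))
    touched_new <- sample(vac, n_new)
    C[touched_new] <- rgeom(n_new, 1 / (1 + spec$fp_superset_scale)) + 1L
    ex <- which(ut & truth$C > 0)
    Ce <- truth$C[ex]
    mu_ee <- ifelse(Ce <= stats::median(Ce), spec$fp_superset_scale,
                    spec$fp_superset_scale / 4)
    C[ex] <- C[ex] + rnbinom(length(ex), mu = mu_ee, size = 1)
  })
  C <- C * ut
  C <- C + t(C)
  rebuild_connectome(truth, C)
}

#' Generate a multi-subject cohort around a ground truth
#'
#' Each subject's counts are drawn as negative-binomial perturbations of
#' the truth counts (overdispersed, as streamline tallies are), then a
#' small subject-specific admixture of FP-NE and FP-EE streamlines is
#' injected from the superset candidate pools. With `dispersion = 0` and
#' zero FP rates every subject equals the truth exactly.
#'
#' @param truth ground-truth [connectome].
#' @param n_subjects cohort size (>= 4).
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; the cohort is reproducible from
#'   `(spec, seed)`.
#' @param superset optional pre-generated FP superset (generated from
#'   `spec` when `NULL` and an FP admixture is requested).
#' @return Named list of [connectome] objects (`s001`, `s002`, ...).
#' @export
generate_cohort <- function(truth, n_subjects, spec = synthetic_spec(),
                            seed = NULL, superset = NULL) {
  stopifnot(inherits(truth, "connectome"))
  if (n_subjects < 4) stop("`n_subjects` must be >= 4")
  want_fp <- spec$fp_ne_rate > 0 || spec$fp_ee_rate > 0
  seeds <- child_seeds(seed, n_subjects + 2L)
  if (want_fp && is.null(superset))
    superset <- generate_fp_superset(truth, spec, seed = seeds[[n_subjects + 1L]])
  cand <- if (want_fp) split_candidates(superset, truth) else NULL
  ut <- upper.tri(truth$C)
  idx <- which(ut & truth$C > 0)
  mu <- truth$C[idx]
  cohort <- lapply(seq_len(n_subjects), function(s) {
    with_seed(seeds[[s]], {
      C <- truth$C
      if (spec$dispersion > 0)
        C[idx] <- rnbinom(length(idx), mu = mu, size = 1 / spec$dispersion)
      C <- C * ut
      C <- C + t(C)
      subj <- rebuild_connectome(truth, C)
      if (want_fp) {
        k_ne <- min(rpois(1, spec$fp_ne_rate), nrow(cand$ne))
        k_ee <- rpois(1, spec$fp_ee_rate)
        if (k_ne > 0) subj <- add_fp_ne(subj, k_ne, cand$ne)
        if (k_ee > 0 && nrow(cand$ee) > 0 && !subj$empty)
          subj <- add_fp_ee(subj, k_ee, cand$ee)
      }
      subj
    })
  })
  names(cohort) <- sprintf("s%03d", seq_len(n_subjects))
  cohort
}

#' Split a cohort in half and atrophy one side
#'
#' Randomly assigns half the subjects to a healthy group and half to an
#' atrophied group, then applies half-normal interhemispheric atrophy of
#' scale `xi` to the atrophied half (see [apply_atrophy()]). With
#' `xi = 0` the two groups are statistically exchangeable.
#'
#' @param cohort named list of [connectome] objects, of even length.
#' @param xi atrophy scale (half-normal standard deviation of the
#'   removal proportion).
#' @param seed integer seed controlling both the split and the atrophy
#'   draws.
#' @return List with `labels` (factor, levels `healthy` / `atrophied`,
#'   one per subject in cohort order) and `cohort` (the modified list).
#' @export
make_atrophied_cohort <- function(cohort, xi, seed = NULL) {
  n <- length(cohort)
  if (n %% 2 != 0) stop("cohort size must be even")
  seeds <- child_seeds(seed, n + 1L)
  atro <- with_seed(seeds[[n + 1L]], sample.int(n, n / 2))
  labels <- factor(ifelse(seq_len(n) %in% atro, "atrophied", "healthy"),
                   levels = c("healthy", "atrophied"))
  if (xi > 0)
    cohort[atro] <- lapply(seq_along(atro), function(k)
      apply_atrophy(cohort[[atro[k]]], xi, seed = seeds[[k]]))
  list(labels = labels, cohort = cohort)
}
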