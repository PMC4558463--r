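#' Weighted streamline-count connectome
#'
#' Construct and validate a weighted connectome: a symmetric matrix of
#' nonnegative integer streamline counts `C` between labelled nodes, together
#' with the derived proportion-weight matrix `W` in which each surviving
#' edge is weighted by its share of the total streamline count (upper
#' triangle of `W` sums to 1 whenever the network carries at least one
#' streamline).
#'
#' Asymmetric input is symmetrised as `max(C, t(C))` with a warning; real
#' streamline tallies are symmetric by construction, so asymmetry signals an
#' upstream bookkeeping problem rather than directionality.
#'
#' @param counts square numeric matrix of nonnegative integer streamline
#'   counts; the diagonal is forced to zero.
#' @param labels character vector of node labels, one per row. Defaults to
#'   `"n1"`, `"n2"`, ...
#' @param hemisphere per-node hemisphere tag, each one of `"L"`, `"R"` or
#'   `"M"` (midline). Defaults to `"M"` for every node.
#' @return An object of class `connectome`: a list with elements `labels`,
#'   `hemisphere`, `C` (integer counts), `W` (proportion weights) and
#'   `empty` (TRUE when the network carries no streamlines).
#' @examples
#' C <- matrix(0, 3, 3)
#' C[1, 2] <- C[2, 1] <- 4
#' C[2, 3] <- C[3, 2] <- 6
#' conn <- connectome(C)
#' conn$W[1, 2] # 0.4
#' @export
connectome <- function(counts, labels = NULL, hemisphere = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix")
  if (nrow(counts) != ncol(counts))
    stop("non-square count matrix: ", nrow(counts), " x ", ncol(counts))
  n <- nrow(counts)
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("negative streamline counts are not allowed")
  if (max(abs(counts - round(counts))) > 1e-8)
    stop("streamline counts must be integers")
  counts <- round(counts)
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 0))) {
    warning("asymmetric count matrix; symmetrising as max(C, t(C))")
    counts <- pmax(counts, t(counts))
  }
  diag(counts) <- 0
  if (is.null(labels)) labels <- paste0("n", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("label count (", length(labels), ") does not match matrix size (", n, ")")
  if (is.null(hemisphere)) hemisphere <- rep("M", n)
  hemisphere <- as.character(hemisphere)
  if (length(hemisphere) != n || !all(hemisphere %in% c("L", "R", "M")))
    stop("`hemisphere` must be one of \"L\", \"R\", \"M\" per node")
  W <- normalize_weights(counts)
  structure(
    list(labels = labels, hemisphere = hemisphere, C = counts, W = W,
         empty = attr(W, "empty")),
    class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  em <- count_metrics(x)
  cat(sprintf("<connectome> %d nodes (%d L / %d R / %d M), %d edges, %d streamlines%s\n",
              length(x$labels), sum(x$hemisphere == "L"),
              sum(x$hemisphere == "R"), sum(x$hemisphere == "M"),
              em[["n_edges"]], em[["n_streamlines"]],
              if (x$empty) " [empty]" else ""))
  invisible(x)
}

#' Normalise streamline counts to proportion weights
#'
#' Divides every entry of a symmetric count matrix by the total number of
#' streamlines (the upper-triangle sum), so that edge weights express each
#' connection's share of the network and are invariant to global changes in
#' streamline yield. An all-zero matrix is returned as-is with attribute
#' `empty = TRUE` rather than raising an error.
#'
#' @param C symmetric nonnegative count matrix.
#' @return Weight matrix `W` with `sum(W[upper.tri(W)]) == 1` for non-empty
#'   input; attribute `empty` flags the degenerate all-zero case.
#' @export
normalize_weights <- function(C) {
  total <- sum(C[upper.tri(C)])
  if (total == 0) {
    W <- C * 0
    attr(W, "empty") <- TRUE
    return(W)
  }
  W <- C / total
  attr(W, "empty") <- FALSE
  W
}

# Rebuild a connectome around a replacement count matrix, recomputing W.
# Internal fast path: skips revalidation (callers guarantee symmetry).
rebuild_connectome <- function(conn, counts) {
  counts <- round(counts)
  diag(counts) <- 0
  W <- normalize_weights(counts)
  conn$C <- counts
  conn$W <- W
  conn$empty <- attr(W, "empty")
  conn
}

#' Threshold a connectome by streamline count
#'
#' Removes every edge carrying `tau` or fewer streamlines (inclusive
#' removal), then recomputes the proportion weights from the surviving
#' counts so that the weights of the thresholded network again sum to 1.
#' `tau = 0` therefore only removes count-zero pairs (a no-op on the edge
#' set), and the surviving edge set is non-increasing in `tau`.
#'
#' @param conn a [connectome].
#' @param tau nonnegative integer streamline-count threshold.
#' @return The thresholded `connectome`.
#' @export
apply_threshold <- function(conn, tau) {
  stopifnot(inherits(conn, "connectome"))
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("`tau` must be a single nonnegative number")
  C <- conn$C
  C[C <= tau] <- 0L
  rebuild_connectome(conn, C)
}

#' Read a connectome matrix and its node metadata from text files
#'
#' The matrix file is a square delimited numeric table (comma or tab,
#' autodetected) with no header; the labels file is a TSV with header
#' columns `label` and `hemisphere`, one row per matrix row, in matrix
#' order (node order in the labels file is authoritative).
#'
#' @param path path to the delimited square count matrix.
#' @param labels_path path to the node-metadata TSV; `NULL` for default
#'   labels and midline hemisphere tags.
#' @return A validated [connectome].
#' @export
read_connectome <- function(path, labels_path = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  if (sep == "\t" && !grepl("\t", first, fixed = TRUE)) sep <- ""
  M <- as.matrix(read.table(path, sep = sep, header = FALSE))
  dimnames(M) <- NULL
  if (!is.numeric(M)) stop("matrix file is not numeric: ", path)
  labels <- NULL
  hemi <- NULL
  if (!is.null(labels_path)) {
    meta <- read.table(labels_path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
    if (!all(c("label", "hemisphere") %in% names(meta)))
      stop("labels file must have columns `label` and `hemisphere`")
    labels <- meta$label
    hemi <- meta$hemisphere
  }
  connectome(M, labels = labels, hemisphere = hemi)
}

#' Write a connectome to delimited text files
#'
#' Inverse of [read_connectome()]: the count matrix as headerless
#' tab-separated text and (optionally) the node metadata TSV.
#'
#' @param conn a [connectome].
#' @param path output path for the count matrix.
#' @param labels_path optional output path for the node-metadata TSV.
#' @return `conn`, invisibly.
#' @export
write_connectome <- function(conn, path, labels_path = NULL) {
  stopifnot(inherits(conn, "connectome"))
  write.table(conn$C, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  if (!is.null(labels_path))
    write.table(data.frame(label = conn$labels, hemisphere = conn$hemisphere),
                labels_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(conn)
}

#' Read a cohort of connectomes from a manifest
#'
#' The manifest is a TSV with header columns `subject_id`, `matrix_path`
#' and `group`; matrix paths are resolved relative to the manifest's
#' directory unless absolute.
#'
#' @param manifest_path path to the cohort manifest TSV.
#' @param labels_path optional shared node-metadata TSV applied to every
#'   subject.
#' @return A list with elements `subjects` (named list of [connectome]
#'   objects) and `group` (factor of group assignments, named by subject).
#' @export
read_cohort <- function(manifest_path, labels_path = NULL) {
  man <- read.table(manifest_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  if (!all(c("subject_id", "matrix_path", "group") %in% names(man)))
    stop("manifest must have columns subject_id, matrix_path, group")
  base <- dirname(manifest_path)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$matrix_path), man$matrix_path,
                  file.path(base, man$matrix_path))
  subjects <- lapply(paths, read_connectome, labels_path = labels_path)
  names(subjects) <- man$subject_id
  list(subjects = subjects,
       group = factor(man$group))
}

# TRUE for upper-triangle entries whose endpoints are in different
# hemispheres; the default atrophy mask.
interhemispheric_mask <- function(conn) {
  h <- conn$hemisphere
  outer(h, h, FUN = "!=") & outer(h != "M", h != "M", FUN = "&")
}
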