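#' Number of condition pairs
#'
#' Number of unordered stimulus pairs among `n` conditions, i.e. the length
#' of a vectorized RDM: `n(n-1)/2`. A 96-image experiment yields 4560
#' pairwise dissimilarities.
#'
#' @param n Number of conditions (>= 2).
#' @return Integer pair count.
#' @export
num_pairs <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("`n` must be a single number >= 2")
  as.integer(n * (n - 1) / 2)
}

#' Pair index table for the package-wide RDM vector order
#'
#' All vectorized RDMs in this package use one fixed pair order: the
#' row-major lower triangle of the square matrix, i.e. pairs (i, j) with
#' i < j ordered by j, then i (1-based here). This equals the column-major
#' upper triangle, so `m[upper.tri(m)]` extracts an RDM vector in order.
#'
#' @param n Number of conditions.
#' @return Integer matrix with columns `i`, `j` (i < j), one row per pair.
#' @export
pair_indices <- function(n) {
  n <- as.integer(n)
  j <- rep.int(seq_len(n), pmax(seq_len(n) - 1L, 0L))
  i <- sequence(pmax(seq_len(n) - 1L, 0L))
  cbind(i = i, j = j)
}

#' Construct an RDM object
#'
#' A representational dissimilarity matrix stored in vector form (see
#' [pair_indices()] for the pair order) together with its stimulus
#' identifiers and a provenance label.
#'
#' @param dissim Numeric vector of length `n(n-1)/2`, all finite.
#' @param stimulus_ids Character vector of `n` unique stimulus identifiers.
#' @param meta Provenance label (free-form character scalar).
#' @return An object of class `"rdm"`.
#' @export
rdm <- function(dissim, stimulus_ids, meta = "") {
  stimulus_ids <- as.character(stimulus_ids)
  n <- length(stimulus_ids)
  if (n < 2L) stop("an RDM needs >= 2 stimuli")
  if (anyDuplicated(stimulus_ids)) stop("stimulus_ids must be unique")
  dissim <- as.numeric(dissim)
  if (length(dissim) != num_pairs(n))
    stop(sprintf("dissim has length %d; expected n(n-1)/2 = %d",
                 length(dissim), num_pairs(n)))
  if (!all(is.finite(dissim))) stop("all dissimilarities must be finite")
  structure(list(stimulus_ids = stimulus_ids, dissim = dissim,
                 meta = as.character(meta)[1L]),
            class = "rdm")
}

is_rdm <- function(x) inherits(x, "rdm")

n_stimuli <- function(x) length(x$stimulus_ids)

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM over %d stimuli (%d pairs)%s\n", n_stimuli(x),
              length(x$dissim),
              if (nzchar(x$meta)) paste0(" [", x$meta, "]") else ""))
  cat(sprintf("  dissimilarity range: [%.4g, %.4g]\n",
              min(x$dissim), max(x$dissim)))
  invisible(x)
}

#' Activity-pattern set
#'
#' Per-stimulus multichannel response patterns (e.g. multivoxel t-maps), the
#' raw material for a correlation-distance RDM.
#'
#' @param patterns Numeric matrix, stimuli x channels; rownames used as
#'   stimulus ids if `stimulus_ids` missing.
#' @param stimulus_ids Optional stimulus identifiers.
#' @param subject_id,session_id Provenance labels.
#' @return An object of class `"pattern_set"`.
#' @export
pattern_set <- function(patterns, stimulus_ids = rownames(patterns),
                        subject_id = "s1", session_id = "1") {
  patterns <- as.matrix(patterns)
  if (is.null(stimulus_ids)) stimulus_ids <- paste0("stim", seq_len(nrow(patterns)))
  stimulus_ids <- as.character(stimulus_ids)
  if (nrow(patterns) < 2L) stop("need >= 2 stimuli")
  if (ncol(patterns) < 2L) stop("need >= 2 channels")
  if (length(stimulus_ids) != nrow(patterns))
    stop("stimulus_ids must match pattern rows")
  rownames(patterns) <- stimulus_ids
  structure(list(stimulus_ids = stimulus_ids, patterns = patterns,
                 subject_id = subject_id, session_id = session_id),
            class = "pattern_set")
}

#' Correlation-distance RDM from activity patterns
#'
#' Dissimilarity between two stimuli is 1 minus the Pearson correlation of
#' their response patterns across channels: 0 for perfectly correlated,
#' 1 for uncorrelated, 2 for perfectly anticorrelated patterns.
#'
#' @param x A [pattern_set()].
#' @return An [rdm()] with entries in \[0, 2\].
#' @export
rdm_from_patterns <- function(x) {
  stopifnot(inherits(x, "pattern_set"))
  v <- apply(x$patterns, 1L, stats::var)
  if (any(v == 0))
    stop("zero-variance pattern(s) for stimuli: ",
         paste(x$stimulus_ids[v == 0], collapse = ", "),
         " (correlation distance undefined)")
  cc <- stats::cor(t(x$patterns))
  d <- 1 - cc
  # numerical guard: clamp tiny excursions outside [0, 2] and snap
  # floating-point residue at the exact-correlation anchors
  d <- pmin(pmax(d, 0), 2)
  d[d < 1e-12] <- 0
  d[d > 2 - 1e-12] <- 2
  rdm(d[upper.tri(d)], x$stimulus_ids,
      meta = sprintf("corr-dist %s/%s", x$subject_id, x$session_id))
}

#' Square-matrix form of an RDM
#'
#' @param x An [rdm()].
#' @return Symmetric matrix with zero diagonal, dimnames = stimulus ids.
#' @export
to_square <- function(x) {
  stopifnot(is_rdm(x))
  n <- n_stimuli(x)
  m <- matrix(0, n, n, dimnames = list(x$stimulus_ids, x$stimulus_ids))
  m[upper.tri(m)] <- x$dissim
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' RDM from a square dissimilarity matrix
#'
#' @param m Symmetric numeric matrix with zero diagonal.
#' @param stimulus_ids Stimulus ids; defaults to rownames.
#' @param meta Provenance label.
#' @param tol Tolerance for symmetry/zero-diagonal checks.
#' @return An [rdm()].
#' @export
from_square <- function(m, stimulus_ids = rownames(m), meta = "", tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (max(abs(m - t(m))) > tol) stop("matrix is not symmetric within tolerance")
  if (max(abs(diag(m))) > tol) stop("matrix diagonal is not zero within tolerance")
  if (is.null(stimulus_ids)) stimulus_ids <- paste0("stim", seq_len(nrow(m)))
  m <- (m + t(m)) / 2
  rdm(m[upper.tri(m)], stimulus_ids, meta = meta)
}

#' Stack of RDMs over a common stimulus set
#'
#' @param rdms List of [rdm()] objects sharing stimulus ids (same order).
#' @param labels One label per RDM; defaults to member `meta` fields.
#' @return An object of class `"rdm_stack"`.
#' @export
rdm_stack <- function(rdms, labels = NULL) {
  if (is_rdm(rdms)) rdms <- list(rdms)
  if (length(rdms) == 0L) stop("empty RDM stack")
  stopifnot(all(vapply(rdms, is_rdm, logical(1))))
  ids <- rdms[[1L]]$stimulus_ids
  same <- vapply(rdms, function(r) identical(r$stimulus_ids, ids), logical(1))
  if (!all(same)) stop("all RDMs in a stack must share stimulus ids and order")
  if (is.null(labels))
    labels <- vapply(rdms, function(r) r$meta, character(1))
  if (length(labels) != length(rdms)) stop("one label per RDM required")
  structure(list(rdms = rdms, labels = as.character(labels),
                 stimulus_ids = ids),
            class = "rdm_stack")
}

#' @export
length.rdm_stack <- function(x) length(x$rdms)

#' @export
print.rdm_stack <- function(x, ...) {
  cat(sprintf("RDM stack: %d RDMs over %d stimuli\n", length(x$rdms),
              length(x$stimulus_ids)))
  invisible(x)
}

#' Dissimilarity vectors of a stack as a matrix
#'
#' @param x An [rdm_stack()].
#' @return Matrix, pairs x RDMs, columns named by stack labels.
#' @export
stack_matrix <- function(x) {
  stopifnot(inherits(x, "rdm_stack"))
  out <- vapply(x$rdms, function(r) r$dissim,
                numeric(length(x$rdms[[1L]]$dissim)))
  out <- matrix(out, ncol = length(x$rdms),
                dimnames = list(NULL, x$labels))
  out
}

#' Average a stack of RDMs
#'
#' Entrywise arithmetic mean of the member dissimilarity vectors; the way
#' per-session RDMs are combined across sessions and subjects. The mean is
#' flat (each member weighted equally).
#'
#' @param x An [rdm_stack()] (or list of RDMs).
#' @param meta Provenance label for the result.
#' @return An [rdm()].
#' @export
average_rdms <- function(x, meta = "average") {
  if (!inherits(x, "rdm_stack")) x <- rdm_stack(x)
  rdm(rowMeans(stack_matrix(x)), x$stimulus_ids, meta = meta)
}

#' Rank-percentile transform of an RDM
#'
#' Replaces dissimilarities by their ranks (average ranks for ties), mapped
#' linearly onto \[0, 1\]. A constant RDM maps to all 0.5 (degenerate input,
#' reported via a warning). Used before residual computation and, scaled to
#' \[0, 100\], for percentile heat-map displays.
#'
#' @param x An [rdm()].
#' @return An [rdm()] with entries in \[0, 1\].
#' @export
rank_percentile_transform <- function(x) {
  stopifnot(is_rdm(x))
  v <- x$dissim
  m <- length(v)
  if (max(v) == min(v)) {
    warning("constant RDM: rank-percentile transform set to 0.5 everywhere")
    out <- rep(0.5, m)
  } else {
    out <- (rank(v, ties.method = "average") - 1) / (m - 1)
  }
  rdm(out, x$stimulus_ids, meta = paste0(x$meta, " (rank-percentile)"))
}

#' Signed residuals between a data RDM and a model prediction
#'
#' Both RDMs are rank-percentile transformed into \[0, 1\] and the prediction
#' is subtracted from the data, so residuals lie in \[-1, 1\] (or
#' \[-100, 100\] when expressed in percentiles).
#'
#' @param data,prediction [rdm()] objects over the same stimuli.
#' @return Numeric residual vector in RDM pair order.
#' @export
residual_rdm <- function(data, prediction) {
  stopifnot(is_rdm(data), is_rdm(prediction))
  if (!identical(data$stimulus_ids, prediction$stimulus_ids))
    stop("data and prediction must share the same stimulus set and order")
  rank_percentile_transform(data)$dissim -
    rank_percentile_transform(prediction)$dissim
}
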