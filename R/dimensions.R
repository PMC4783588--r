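#' Description-vote tensor
#'
#' Binary marks from a labeling experiment: which subject marked which
#' description for which image. The generation phase records who produced a
#' description; the validation phase records who judged a description as
#' correctly applying to an image.
#'
#' @param votes 3-way 0/1 array, description x stimulus x subject, with
#'   dimnames.
#' @param phase `"generation"` or `"validation"`.
#' @return An object of class `"description_votes"`.
#' @export
description_votes <- function(votes, phase = c("generation", "validation")) {
  phase <- match.arg(phase)
  votes <- as.array(votes)
  if (length(dim(votes)) != 3L)
    stop("votes must be a 3-way array (description x stimulus x subject)")
  if (!all(votes %in% c(0L, 1L))) stop("votes must be binary")
  if (is.null(dimnames(votes)))
    dimnames(votes) <- list(paste0("d", seq_len(dim(votes)[1L])),
                            paste0("stim", seq_len(dim(votes)[2L])),
                            paste0("subj", seq_len(dim(votes)[3L])))
  structure(list(votes = votes, phase = phase,
                 descriptions = dimnames(votes)[[1L]],
                 stimulus_ids = dimnames(votes)[[2L]],
                 subjects = dimnames(votes)[[3L]]),
            class = "description_votes")
}

#' Filter generated descriptions by subject support
#'
#' Keeps a description if it was produced by at least `min_subjects`
#' distinct subjects (default 3, mirroring a 3-out-of-15 generation
#' threshold). By default a subject counts once per description regardless
#' of how many images they produced it for; with `per_image = TRUE` the
#' threshold must instead be reached on at least one single image.
#'
#' @param votes A generation-phase [description_votes()].
#' @param min_subjects Minimum distinct-subject count (default 3).
#' @param per_image Count support per image rather than across images.
#' @return Character vector of retained description labels.
#' @export
filter_generated_descriptions <- function(votes, min_subjects = 3,
                                          per_image = FALSE) {
  stopifnot(inherits(votes, "description_votes"))
  if (votes$phase != "generation")
    stop("filter_generated_descriptions expects generation-phase votes")
  if (sum(votes$votes) == 0) stop("empty vote tensor")
  if (per_image) {
    per_img_subj <- apply(votes$votes, c(1L, 2L), sum)   # desc x stim
    support <- apply(per_img_subj, 1L, max)
  } else {
    produced <- apply(votes$votes, c(1L, 3L), max)       # desc x subj
    support <- rowSums(produced)
  }
  votes$descriptions[support >= min_subjects]
}

#' Dimension matrix (stimuli scored on category/feature dimensions)
#'
#' @param values Numeric matrix, dimension x stimulus, entries in \[0, 1\].
#'   Unmerged dimensions are exactly binary.
#' @param dimension_labels One label per dimension; merged labels are
#'   "/"-joined.
#' @param stimulus_ids One id per stimulus column.
#' @param merge_groups List of character vectors: the source labels merged
#'   into each dimension.
#' @return An object of class `"dim_matrix"`.
#' @export
dimension_matrix <- function(values, dimension_labels = rownames(values),
                             stimulus_ids = colnames(values),
                             merge_groups = NULL) {
  values <- as.matrix(values)
  if (is.null(dimension_labels))
    dimension_labels <- paste0("dim", seq_len(nrow(values)))
  if (is.null(stimulus_ids))
    stimulus_ids <- paste0("stim", seq_len(ncol(values)))
  if (any(values < 0 | values > 1)) stop("dimension values must lie in [0, 1]")
  if (length(dimension_labels) != nrow(values))
    stop("one label per dimension required")
  if (length(stimulus_ids) != ncol(values))
    stop("one id per stimulus required")
  if (is.null(merge_groups))
    merge_groups <- as.list(dimension_labels)
  rownames(values) <- dimension_labels
  colnames(values) <- stimulus_ids
  structure(list(dimension_labels = as.character(dimension_labels),
                 stimulus_ids = as.character(stimulus_ids),
                 values = values, merge_groups = merge_groups),
            class = "dim_matrix")
}

#' @export
print.dim_matrix <- function(x, ...) {
  n_merged <- sum(lengths(x$merge_groups) > 1L)
  cat(sprintf("Dimension matrix: %d dimensions x %d stimuli (%d merged)\n",
              nrow(x$values), ncol(x$values), n_merged))
  invisible(x)
}

#' Validate descriptions into a binary dimension matrix
#'
#' An (image, description) entry becomes 1 when at least `min_votes`
#' validation subjects marked it as correct (default 6, mirroring a
#' 6-out-of-8 threshold). Descriptions whose resulting binary vector is all
#' zeros are removed, as are any labels on the `exclude` list (manual
#' cleanup of inconsistent or redundant descriptions is a human judgment,
#' supplied as data rather than automated).
#'
#' @param votes A validation-phase [description_votes()].
#' @param min_votes Minimum subject count per (description, image) pair.
#' @param exclude Character vector of description labels to drop.
#' @return A binary [dimension_matrix()].
#' @export
validate_descriptions <- function(votes, min_votes = 6, exclude = NULL) {
  stopifnot(inherits(votes, "description_votes"))
  if (votes$phase != "validation")
    stop("validate_descriptions expects validation-phase votes")
  n_subj <- length(votes$subjects)
  if (min_votes > n_subj)
    stop(sprintf("min_votes (%d) exceeds subject count (%d)", min_votes, n_subj))
  counts <- apply(votes$votes, c(1L, 2L), sum)
  vals <- (counts >= min_votes) * 1
  keep <- rowSums(vals) > 0 & !(rownames(vals) %in% exclude)
  if (!any(keep)) stop("no description survived validation thresholding")
  dimension_matrix(vals[keep, , drop = FALSE],
                   dimension_labels = votes$descriptions[keep],
                   stimulus_ids = votes$stimulus_ids)
}

# Pairwise Pearson correlations between dimension rows; zero-variance rows
# get NA correlations (excluded from merging).
dimension_correlations <- function(values) {
  sds <- apply(values, 1L, stats::sd)
  cc <- suppressWarnings(stats::cor(t(values)))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc) <- NA_real_
  cc
}

#' Iteratively merge highly correlated dimensions
#'
#' Alternates between computing all pairwise Pearson correlations over
#' stimuli and averaging the single most correlated pair (entrywise mean,
#' labels "/"-joined, merge provenance unioned) while any correlation
#' exceeds `threshold` (default 0.9). Ties are broken by lexicographic
#' label order; zero-variance dimensions have undefined correlations and
#' are never merged. Merging stabilizes downstream regression weights.
#'
#' @param dims A [dimension_matrix()].
#' @param threshold Correlation threshold in (0, 1\].
#' @return A [dimension_matrix()] with all pairwise correlations <= threshold.
#' @export
merge_correlated_dimensions <- function(dims, threshold = 0.9) {
  stopifnot(inherits(dims, "dim_matrix"))
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  values <- dims$values
  labels <- dims$dimension_labels
  groups <- dims$merge_groups
  if (any(apply(values, 1L, stats::sd) == 0))
    message("zero-variance dimension(s) present; excluded from merging")
  repeat {
    if (nrow(values) < 2L) break
    cc <- dimension_correlations(values)
    if (all(is.na(cc)) || max(cc, na.rm = TRUE) <= threshold) break
    top <- max(cc, na.rm = TRUE)
    cand <- which(cc >= top - 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- paste(pmin(labels[cand[, 1L]], labels[cand[, 2L]]),
                 pmax(labels[cand[, 1L]], labels[cand[, 2L]]), sep = "\r")
    pick <- cand[order(key)[1L], ]
    a <- pick[[1L]]; b <- pick[[2L]]
    merged_vals <- (values[a, ] + values[b, ]) / 2
    merged_label <- paste(labels[a], labels[b], sep = "/")
    merged_group <- union(groups[[a]], groups[[b]])
    keep <- setdiff(seq_len(nrow(values)), c(a, b))
    values <- rbind(values[keep, , drop = FALSE], merged_vals)
    labels <- c(labels[keep], merged_label)
    groups <- c(groups[keep], list(merged_group))
  }
  dimension_matrix(values, dimension_labels = labels,
                   stimulus_ids = dims$stimulus_ids, merge_groups = groups)
}

#' Single-dimension model RDMs
#'
#' For each dimension the model RDM entry for a pair of stimuli is the
#' squared difference between their values on that dimension. Binary
#' dimensions yield 0/1 entries (0 = present or absent in both images, 1 =
#' present in exactly one); merged dimensions may yield entries in (0, 1).
#'
#' @param dims A [dimension_matrix()].
#' @return An [rdm_stack()] with one RDM per dimension, labels carried over.
#' @export
single_dimension_rdms <- function(dims) {
  stopifnot(inherits(dims, "dim_matrix"))
  pi <- pair_indices(length(dims$stimulus_ids))
  rdms <- lapply(seq_len(nrow(dims$values)), function(k) {
    f <- dims$values[k, ]
    rdm((f[pi[, "i"]] - f[pi[, "j"]])^2, dims$stimulus_ids,
        meta = dims$dimension_labels[k])
  })
  rdm_stack(rdms, labels = dims$dimension_labels)
}

#' Labels-per-image summary
#'
#' Mean and standard deviation, over images, of the number of dimensions
#' with nonzero value. The SD is the population SD (divide by n), a
#' descriptive statistic over the full image set.
#'
#' @param dims A [dimension_matrix()].
#' @return Named numeric vector `c(mean = ..., sd = ...)`.
#' @export
labels_per_image_stats <- function(dims) {
  stopifnot(inherits(dims, "dim_matrix"))
  counts <- colSums(dims$values > 0)
  mu <- mean(counts)
  c(mean = mu, sd = sqrt(mean((counts - mu)^2)))
}
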