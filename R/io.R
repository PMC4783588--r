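#' Write an RDM to a delimited file
#'
#' Two layouts are supported: `"square"` writes the full symmetric matrix
#' with stimulus ids as header row and first column; `"long"` writes one
#' row per pair (`stim_i`, `stim_j`, `dissim`) in the package pair order
#' (row-major lower triangle; see [pair_indices()]).
#'
#' @param x An [rdm()].
#' @param path Output file path.
#' @param format `"square"` or `"long"`.
#' @param sep Field separator (`,` for CSV, `"\t"` for TSV).
#' @export
write_rdm <- function(x, path, format = c("square", "long"), sep = ",") {
  stopifnot(is_rdm(x))
  format <- match.arg(format)
  if (format == "square") {
    m <- to_square(x)
    df <- data.frame(stimulus = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    pi <- pair_indices(n_stimuli(x))
    df <- data.frame(stim_i = x$stimulus_ids[pi[, "i"]],
                     stim_j = x$stimulus_ids[pi[, "j"]],
                     dissim = x$dissim)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read an RDM from a delimited file
#'
#' Auto-detects the layout written by [write_rdm()]: a long-form table with
#' columns `stim_i`, `stim_j`, `dissim`, or a square matrix with stimulus
#' ids in the header and first column.
#'
#' @param path Input file path.
#' @param sep Field separator.
#' @param meta Provenance label for the resulting RDM.
#' @return An [rdm()].
#' @export
read_rdm <- function(path, sep = ",", meta = basename(path)) {
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (all(c("stim_i", "stim_j", "dissim") %in% names(df))) {
    ids <- unique(c(df$stim_i, df$stim_j))
    n <- length(ids)
    m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    diag(m) <- 0
    m[cbind(match(df$stim_i, ids), match(df$stim_j, ids))] <- df$dissim
    m[cbind(match(df$stim_j, ids), match(df$stim_i, ids))] <- df$dissim
    if (anyNA(m)) stop("long-form RDM file is missing pairs: ", path)
    return(from_square(m, ids, meta = meta))
  }
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (!identical(colnames(m), ids))
    stop("square RDM file: header ids do not match row ids: ", path)
  rownames(m) <- ids
  from_square(m, ids, meta = meta)
}

#' Write / read activity-pattern sets
#'
#' CSV with stimulus ids as the first column and channels as the remaining
#' columns.
#'
#' @param x A [pattern_set()].
#' @param path File path.
#' @export
write_patterns <- function(x, path) {
  stopifnot(inherits(x, "pattern_set"))
  df <- data.frame(stimulus = x$stimulus_ids, x$patterns, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_patterns
#' @param subject_id,session_id Provenance labels for the read set.
#' @export
read_patterns <- function(path, subject_id = "s1", session_id = "1") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  pattern_set(m, stimulus_ids = as.character(df[[1L]]),
              subject_id = subject_id, session_id = session_id)
}

#' Write / read a dimension matrix
#'
#' CSV with one row per dimension: a `label` column ("/"-joined for merged
#' dimensions) followed by one column per stimulus, values in \[0, 1\].
#'
#' @param x A [dimension_matrix()].
#' @param path File path.
#' @export
write_dimension_matrix <- function(x, path) {
  stopifnot(inherits(x, "dim_matrix"))
  df <- data.frame(label = x$dimension_labels, x$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dimension_matrix
#' @export
read_dimension_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  labs <- as.character(df[[1L]])
  dimension_matrix(vals, dimension_labels = labs,
                   stimulus_ids = colnames(vals),
                   merge_groups = strsplit(labs, "/", fixed = TRUE))
}

#' Write / read description-vote tensors
#'
#' Long-form CSV with columns `description`, `stimulus`, `subject`, `mark`
#' (0/1). Rows with mark 0 may be omitted on disk.
#'
#' @param x A [description_votes()].
#' @param path File path.
#' @export
write_votes <- function(x, path) {
  stopifnot(inherits(x, "description_votes"))
  idx <- which(x$votes == 1L, arr.ind = TRUE)
  df <- data.frame(description = dimnames(x$votes)[[1L]][idx[, 1L]],
                   stimulus = dimnames(x$votes)[[2L]][idx[, 2L]],
                   subject = dimnames(x$votes)[[3L]][idx[, 3L]],
                   mark = 1L)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_votes
#' @param phase `"generation"` or `"validation"`.
#' @param descriptions,stimulus_ids,subjects Optional full level sets (so
#'   that levels with no marks survive the round trip).
#' @export
read_votes <- function(path, phase, descriptions = NULL, stimulus_ids = NULL,
                       subjects = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(descriptions)) descriptions <- sort(unique(df$description))
  if (is.null(stimulus_ids)) stimulus_ids <- sort(unique(df$stimulus))
  if (is.null(subjects)) subjects <- sort(unique(df$subject))
  votes <- array(0L, dim = c(length(descriptions), length(stimulus_ids),
                             length(subjects)),
                 dimnames = list(descriptions, stimulus_ids, subjects))
  keep <- df$mark != 0
  votes[cbind(match(df$description[keep], descriptions),
              match(df$stimulus[keep], stimulus_ids),
              match(df$subject[keep], subjects))] <- 1L
  description_votes(votes, phase = phase)
}

#' Write / read multi-arrangement trial records
#'
#' Long-form CSV with columns `subject`, `trial`, `item_i`, `item_j`,
#' `distance` (on-screen distance, arbitrary per-trial scale).
#'
#' @param x A [subject_judgments()].
#' @param path File path.
#' @export
write_trials <- function(x, path) {
  stopifnot(inherits(x, "subject_judgments"))
  rows <- lapply(seq_along(x$trials), function(t) {
    tr <- x$trials[[t]]
    data.frame(subject = x$subject_id, trial = t,
               item_i = tr$pairs$item_i, item_j = tr$pairs$item_j,
               distance = tr$pairs$distance)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @return `read_trials` returns a list of [subject_judgments()], one per
#'   subject in the file.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$subject), function(sub) {
    trials <- lapply(split(sub, sub$trial), function(tr) {
      arrangement_trial(data.frame(item_i = as.character(tr$item_i),
                                   item_j = as.character(tr$item_j),
                                   distance = tr$distance,
                                   stringsAsFactors = FALSE))
    })
    subject_judgments(sub$subject[1L], unname(trials))
  })
  unname(out)
}
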