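#' A single multi-arrangement trial
#'
#' One arena arrangement: a subset of items and the on-screen distances
#' between them. Only the relations between distances within a trial are
#' meaningful; the absolute scale is arbitrary per trial.
#'
#' @param pairs Data frame with columns `item_i`, `item_j`, `distance`
#'   (>= 0), one row per item pair shown on the trial.
#' @return An object of class `"arrangement_trial"`.
#' @export
arrangement_trial <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(all(c("item_i", "item_j", "distance") %in% names(pairs)))
  items <- sort(unique(c(pairs$item_i, pairs$item_j)))
  if (length(items) < 3L) stop("a trial needs >= 3 items")
  if (any(pairs$distance < 0)) stop("distances must be >= 0")
  if (nrow(pairs) != num_pairs(length(items)))
    stop("distance count must equal choose(|items|, 2)")
  structure(list(item_ids = items, pairs = pairs),
            class = "arrangement_trial")
}

#' All trials of one subject
#'
#' @param subject_id Subject label.
#' @param trials List of [arrangement_trial()] objects.
#' @return An object of class `"subject_judgments"`.
#' @export
subject_judgments <- function(subject_id, trials) {
  stopifnot(length(trials) >= 1L,
            all(vapply(trials, inherits, logical(1), "arrangement_trial")))
  structure(list(subject_id = as.character(subject_id), trials = trials),
            class = "subject_judgments")
}

all_items <- function(judgments) {
  sort(unique(unlist(lapply(judgments$trials, `[[`, "item_ids"))))
}

pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "\r")

#' Per-pair evidence summary for multi-arrangement trials
#'
#' For each stimulus pair, the number of trials containing it and (after
#' aggregation-style scaling with unit trial scales) the total evidence
#' weight: the sum of squared on-screen distances across trials.
#'
#' @param judgments A [subject_judgments()].
#' @return Data frame with columns `item_i`, `item_j`, `n_trials`, `weight`.
#' @export
coverage_report <- function(judgments) {
  stopifnot(inherits(judgments, "subject_judgments"))
  items <- all_items(judgments)
  pi <- pair_indices(length(items))
  keys <- pair_key(items[pi[, "i"]], items[pi[, "j"]])
  n_tr <- stats::setNames(numeric(length(keys)), keys)
  wt <- n_tr
  for (tr in judgments$trials) {
    k <- pair_key(tr$pairs$item_i, tr$pairs$item_j)
    n_tr[k] <- n_tr[k] + 1
    wt[k] <- wt[k] + tr$pairs$distance^2
  }
  data.frame(item_i = items[pi[, "i"]], item_j = items[pi[, "j"]],
             n_trials = as.integer(n_tr), weight = as.numeric(wt))
}

#' Aggregate multi-arrangement trials into a subject RDM
#'
#' Iterative evidence-weighted averaging: alternately rescale each trial's
#' distances (least-squares alignment to the current evidence-weighted
#' average over the trial's pairs) and recompute the evidence-weighted
#' average, until the average stabilizes. The evidence weight of a pair
#' within a trial is its squared scaled on-screen distance (items placed
#' close together provide weak dissimilarity evidence); `weighting =
#' "uniform"` weights all observations equally instead. The output RDM is
#' normalized to unit root-mean-square because only relative distances are
#' meaningful.
#'
#' @param judgments A [subject_judgments()] whose trials jointly cover all
#'   stimulus pairs.
#' @param tol Convergence tolerance on the relative change of the average
#'   RDM (default 1e-6).
#' @param max_iter Iteration cap (default 1000); non-convergence warns.
#' @param weighting `"distance_sq"` (default) or `"uniform"`.
#' @return An [rdm()] with RMS 1.
#' @export
aggregate_trials <- function(judgments, tol = 1e-6, max_iter = 1000,
                             weighting = c("distance_sq", "uniform")) {
  stopifnot(inherits(judgments, "subject_judgments"))
  weighting <- match.arg(weighting)
  items <- all_items(judgments)
  n <- length(items)
  pi <- pair_indices(n)
  keys <- pair_key(items[pi[, "i"]], items[pi[, "j"]])
  pair_pos <- stats::setNames(seq_along(keys), keys)

  trial_pos <- lapply(judgments$trials, function(tr) {
    if (nrow(tr$pairs) < 2L) stop("each trial must contain >= 2 pairs")
    unname(pair_pos[pair_key(tr$pairs$item_i, tr$pairs$item_j)])
  })
  trial_d <- lapply(judgments$trials, function(tr) tr$pairs$distance)

  covered <- sort(unique(unlist(trial_pos)))
  if (length(covered) < length(keys)) {
    missing <- setdiff(seq_along(keys), covered)
    stop("incomplete pair coverage; missing pairs: ",
         paste(items[pi[missing, "i"]], items[pi[missing, "j"]],
               sep = "-", collapse = ", "))
  }

  scales <- rep(1, length(trial_d))
  avg <- NULL
  converged <- FALSE
  objective <- numeric(0)   # weighted disagreement, tracked per iteration
  for (iter in seq_len(max_iter)) {
    num <- numeric(length(keys))
    den <- numeric(length(keys))
    cnt_num <- numeric(length(keys))
    cnt_den <- numeric(length(keys))
    for (t in seq_along(trial_d)) {
      sd_t <- scales[t] * trial_d[[t]]
      w <- if (weighting == "distance_sq") sd_t^2 else rep(1, length(sd_t))
      p <- trial_pos[[t]]
      num[p] <- num[p] + w * sd_t
      den[p] <- den[p] + w
      cnt_num[p] <- cnt_num[p] + sd_t
      cnt_den[p] <- cnt_den[p] + 1
    }
    new_avg <- ifelse(den > 0, num / pmax(den, .Machine$double.eps),
                      cnt_num / cnt_den)  # all-zero-evidence pairs: plain mean
    rms <- sqrt(mean(new_avg^2))
    if (rms == 0) stop("degenerate trials: all distances are zero")
    new_avg <- new_avg / rms
    if (!is.null(avg) &&
        sqrt(mean((new_avg - avg)^2)) / sqrt(mean(avg^2)) < tol) {
      avg <- new_avg
      converged <- TRUE
      break
    }
    avg <- new_avg
    # least-squares rescale of each trial onto the current average
    for (t in seq_along(trial_d)) {
      d <- trial_d[[t]]
      denom <- sum(d^2)
      scales[t] <- if (denom > 0) sum(d * avg[trial_pos[[t]]]) / denom else 1
    }
    disagreement <- 0
    for (t in seq_along(trial_d)) {
      sd_t <- scales[t] * trial_d[[t]]
      w <- if (weighting == "distance_sq") sd_t^2 else rep(1, length(sd_t))
      disagreement <- disagreement + sum(w * (sd_t - avg[trial_pos[[t]]])^2)
    }
    objective <- c(objective, disagreement)
  }
  if (!converged)
    warning(sprintf("aggregation did not converge in %d iterations", max_iter))
  out <- rdm(avg, items, meta = sprintf("judgments %s", judgments$subject_id))
  attr(out, "objective_trace") <- objective
  attr(out, "iterations") <- length(objective)
  out
}
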