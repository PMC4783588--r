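#' Non-negative least squares on precomputed normal equations
#'
#' Active-set NNLS (Lawson--Hanson, in the fast-NNLS formulation of Bro &
#' de Jong that works from the normal equations `A'A`, `A'b`). Operating on
#' the normal equations lets cross-validation update the problem per fold
#' by subtracting the contribution of held-out rows instead of refactoring
#' the full design.
#'
#' The solution satisfies the Karush--Kuhn--Tucker conditions: the gradient
#' of the residual sum of squares is (numerically) zero for predictors with
#' positive weight and non-negative for predictors at the zero bound.
#'
#' @param AtA Symmetric K x K matrix `crossprod(A)`.
#' @param Atb Length-K vector `crossprod(A, b)`.
#' @param tol Dual-feasibility tolerance; default scales with the problem.
#' @param init_passive Optional logical vector: initial guess of the
#'   support (passive set), e.g. the support of a neighboring fold's
#'   solution. A good guess cuts the active-set iterations sharply; the
#'   result is the same fixed point regardless.
#' @return List with `x` (weights, >= 0), `gradient` (`AtA x - Atb`), and
#'   `passive` (logical support).
#' @export
nnls_normal <- function(AtA, Atb, tol = NULL, init_passive = NULL) {
  K <- length(Atb)
  stopifnot(nrow(AtA) == K, ncol(AtA) == K)
  if (is.null(tol)) tol <- 1e-10 * max(1, max(abs(Atb)))
  x <- numeric(K)
  passive <- if (is.null(init_passive)) logical(K) else as.logical(init_passive)
  feasibility_loop <- function() {
    # shrink the passive set until its unconstrained solution is positive
    repeat {
      P <- which(passive)
      if (length(P) == 0L) return(invisible())
      s <- psd_solve(AtA[P, P, drop = FALSE], Atb[P])
      if (all(s > tol)) {
        x[] <<- 0
        x[P] <<- s
        return(invisible())
      }
      bad <- s <= tol
      denom <- x[P][bad] - s[bad]
      alpha <- suppressWarnings(min(x[P][bad][denom > 0] / denom[denom > 0]))
      if (!is.finite(alpha)) alpha <- 0
      x[P] <<- x[P] + alpha * (s - x[P])
      passive[P][x[P] <= tol] <<- FALSE
      x[!passive] <<- 0
    }
  }
  if (any(passive)) feasibility_loop()
  w <- Atb - drop(AtA %*% x)
  max_outer <- 30L * K + 100L
  for (outer in seq_len(max_outer)) {
    free <- !passive
    if (!any(free) || max(w[free]) <= tol) break
    j <- which(free)[which.max(w[free])]
    passive[j] <- TRUE
    feasibility_loop()
    w <- Atb - drop(AtA %*% x)
  }
  list(x = pmax(x, 0), gradient = drop(AtA %*% x) - Atb, passive = passive)
}

#' Model specification: a stack of single-dimension RDM predictors
#'
#' Bundles the single-dimension model RDMs of one model (categorical,
#' feature-based, or their concatenation) with a flag for the constant
#' confound-mean predictor that every fitted model includes to absorb the
#' overall mean dissimilarity.
#'
#' @param predictors An [rdm_stack()] of single-dimension model RDMs.
#' @param include_confound_mean Include an all-ones predictor (default TRUE).
#' @param label Model label, e.g. `"categorical"`, `"feature"`, `"combined"`.
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(predictors, include_confound_mean = TRUE,
                       label = "custom") {
  stopifnot(inherits(predictors, "rdm_stack"), length(predictors) >= 1L)
  structure(list(predictors = predictors,
                 include_confound_mean = isTRUE(include_confound_mean),
                 label = as.character(label)[1L]),
            class = "model_spec")
}

#' Concatenate model specs into a combined model
#'
#' @param ... [model_spec()] objects over the same stimuli.
#' @param label Label for the combined model.
#' @return A [model_spec()] whose predictor stack is the concatenation.
#' @export
combine_models <- function(..., label = "combined") {
  specs <- list(...)
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, inherits, logical(1), "model_spec")))
  rdms <- unlist(lapply(specs, function(s) s$predictors$rdms),
                 recursive = FALSE)
  labels <- unlist(lapply(specs, function(s) s$predictors$labels))
  model_spec(rdm_stack(rdms, labels = labels),
             include_confound_mean = any(vapply(specs, function(s)
               s$include_confound_mean, logical(1))),
             label = label)
}

design_matrix <- function(model) {
  X <- stack_matrix(model$predictors)
  if (model$include_confound_mean)
    X <- cbind(X, `.confound_mean` = 1)
  X
}

check_alignment <- function(model, data) {
  if (!identical(model$predictors$stimulus_ids, data$stimulus_ids))
    stop("model predictors and data RDM must share stimulus ids and order")
}

new_fit_result <- function(w, labels, confound, rss, predicted, model,
                           cross_validated = FALSE, n_folds = NA_integer_) {
  rdm_weights <- stats::setNames(w, labels)
  structure(list(model_label = model$label,
                 rdm_weights = rdm_weights,
                 confound_weight = confound,
                 dimension_weights = sqrt(rdm_weights),
                 training_rss = rss,
                 predicted = predicted,
                 cross_validated = cross_validated,
                 n_folds = n_folds),
            class = "rdm_fit")
}

#' @export
print.rdm_fit <- function(x, ...) {
  cat(sprintf("NNLS fit [%s]%s: %d predictors, %d with positive weight\n",
              x$model_label,
              if (x$cross_validated)
                sprintf(" (cross-validated, %d folds)", x$n_folds) else "",
              length(x$rdm_weights), sum(x$rdm_weights > 0)))
  cat(sprintf("  training RSS: %.6g\n", x$training_rss))
  invisible(x)
}

#' Fit non-negative weights for single-dimension model RDMs
#'
#' Finds the non-negatively weighted sum of the model's single-dimension
#' RDMs (plus the confound-mean predictor) that best explains the data RDM
#' in the least-squares sense, optionally restricted to a subset of pairs.
#' Because a dimension scaled by `w` scales its single-dimension RDM by
#' `w^2`, the fitted RDM weights are the squared dimension weights;
#' `dimension_weights` returns their square roots.
#'
#' Predictors that are all-zero (or constant) on the fitted pairs simply
#' resolve to zero weight (or trade off against the confound); they are
#' retained so weight vectors stay aligned across cross-validation folds.
#'
#' @param model A [model_spec()].
#' @param data An [rdm()] over the same stimuli.
#' @param pair_mask Optional logical or integer vector selecting pairs to
#'   fit on (default: all pairs).
#' @return An object of class `"rdm_fit"`; `predicted` is the model RDM
#'   evaluated on all pairs.
#' @export
nnls_fit <- function(model, data, pair_mask = NULL) {
  stopifnot(inherits(model, "model_spec"), is_rdm(data))
  check_alignment(model, data)
  X <- design_matrix(model)
  y <- data$dissim
  if (is.null(pair_mask)) pair_mask <- seq_along(y)
  Xm <- X[pair_mask, , drop = FALSE]
  ym <- y[pair_mask]
  if (length(ym) == 0L) stop("empty pair mask")
  sol <- nnls_normal(crossprod(Xm), drop(crossprod(Xm, ym)))
  w <- sol$x
  rss <- sum((ym - drop(Xm %*% w))^2)
  K <- length(model$predictors)
  confound <- if (model$include_confound_mean) w[K + 1L] else 0
  predicted <- rdm(drop(X %*% w), data$stimulus_ids,
                   meta = sprintf("fitted %s", model$label))
  new_fit_result(w[seq_len(K)], model$predictors$labels, confound, rss,
                 predicted, model)
}

#' Cross-validation scheme over stimuli
#'
#' Draws random held-out stimulus sets of size `heldout_size` (default 8,
#' as when 88 of 96 images form each training set) until every stimulus
#' pair has appeared together in at least one held-out set, so that every
#' pairwise dissimilarity eventually receives a prediction from a fold that
#' never saw it. Deterministic given `seed`.
#'
#' @param stimulus_ids Stimulus identifiers.
#' @param heldout_size Held-out set size (>= 2; singletons contain no pairs).
#' @param seed Integer seed (required; the only stochastic step of fitting).
#' @param max_folds Safety cap on fold draws.
#' @return An object of class `"crossval_scheme"` with a list of held-out
#'   id sets.
#' @export
build_crossval_scheme <- function(stimulus_ids, heldout_size = 8, seed,
                                  max_folds = 1e5) {
  stimulus_ids <- as.character(stimulus_ids)
  n <- length(stimulus_ids)
  if (heldout_size < 2) stop("heldout_size must be >= 2 (a singleton contains no pairs)")
  if (heldout_size > n) stop("heldout_size exceeds the stimulus count")
  if (missing(seed)) stop("`seed` is required")
  folds <- with_seed(seed, {
    covered <- matrix(FALSE, n, n)
    fl <- list()
    while (any(!covered[upper.tri(covered)])) {
      if (length(fl) >= max_folds) stop("pair coverage not reached within max_folds")
      held <- sort(sample.int(n, heldout_size))
      covered[held, held] <- TRUE
      fl[[length(fl) + 1L]] <- stimulus_ids[held]
    }
    fl
  })
  structure(list(folds = folds, heldout_size = as.integer(heldout_size),
                 seed = as.integer(seed), stimulus_ids = stimulus_ids),
            class = "crossval_scheme")
}

#' @export
print.crossval_scheme <- function(x, ...) {
  cat(sprintf("Cross-validation scheme: %d folds of %d held-out stimuli (seed %d)\n",
              length(x$folds), x$heldout_size, x$seed))
  invisible(x)
}

#' Cross-validated model prediction of a data RDM
#'
#' For each fold, the model weights are estimated by NNLS on the pairs of
#' training images only (pairs with both members outside the held-out set),
#' then used to predict the pairs among the held-out images. Pairs that
#' touch a held-out image with one member are neither fitted nor predicted
#' on that fold, which prevents any leakage of held-out dissimilarities
#' into the fit. Pairs predicted on multiple folds are averaged.
#'
#' @param model A [model_spec()].
#' @param data An [rdm()].
#' @param scheme A [build_crossval_scheme()] covering all pairs.
#' @return An `"rdm_fit"` whose `predicted` RDM is assembled entirely from
#'   held-out predictions; `rdm_weights` are the across-fold mean weights
#'   and `training_rss` the across-fold mean training RSS.
#' @export
crossval_predict <- function(model, data, scheme) {
  stopifnot(inherits(model, "model_spec"), is_rdm(data),
            inherits(scheme, "crossval_scheme"))
  check_alignment(model, data)
  if (!identical(scheme$stimulus_ids, data$stimulus_ids))
    stop("scheme stimulus ids do not match the data RDM")
  n <- n_stimuli(data)
  X <- design_matrix(model)
  y <- data$dissim
  AtA_full <- crossprod(X)
  Atb_full <- drop(crossprod(X, y))
  yty_full <- sum(y^2)
  pi <- pair_indices(n)

  pred_sum <- numeric(length(y))
  pred_cnt <- integer(length(y))
  K <- ncol(X)
  w_sum <- numeric(K)
  rss_sum <- 0
  # warm-start each fold from the previous support (folds share most pairs)
  support <- nnls_normal(AtA_full, Atb_full)$passive
  for (fold in scheme$folds) {
    held <- match(fold, data$stimulus_ids)
    in_held_i <- pi[, "i"] %in% held
    in_held_j <- pi[, "j"] %in% held
    touched <- in_held_i | in_held_j
    test <- in_held_i & in_held_j
    Xt <- X[touched, , drop = FALSE]
    yt <- y[touched]
    AtA <- AtA_full - crossprod(Xt)
    Atb <- Atb_full - drop(crossprod(Xt, yt))
    sol <- nnls_normal(AtA, Atb, init_passive = support)
    support <- sol$passive
    w <- sol$x
    rss_sum <- rss_sum +
      (yty_full - sum(yt^2)) - 2 * sum(w * Atb) + drop(crossprod(w, AtA %*% w))
    pred_sum[test] <- pred_sum[test] + drop(X[test, , drop = FALSE] %*% w)
    pred_cnt[test] <- pred_cnt[test] + 1L
    w_sum <- w_sum + w
  }
  if (any(pred_cnt == 0L))
    stop("cross-validation scheme left pairs without prediction")
  n_folds <- length(scheme$folds)
  w_mean <- w_sum / n_folds
  predicted <- rdm(pred_sum / pred_cnt, data$stimulus_ids,
                   meta = sprintf("cv-fitted %s", model$label))
  nK <- length(model$predictors)
  confound <- if (model$include_confound_mean) w_mean[nK + 1L] else 0
  new_fit_result(w_mean[seq_len(nK)], model$predictors$labels, confound,
                 rss_sum / n_folds, predicted, model,
                 cross_validated = TRUE, n_folds = n_folds)
}

#' Equal-weights (non-fitted) model prediction
#'
#' The prediction under the assumption that every model dimension
#' contributes equally: the plain sum of the single-dimension model RDMs,
#' with no confound predictor and no fitting.
#'
#' @param model A [model_spec()].
#' @return An [rdm()].
#' @export
equal_weights_prediction <- function(model) {
  stopifnot(inherits(model, "model_spec"))
  X <- stack_matrix(model$predictors)
  rdm(rowSums(X), model$predictors$stimulus_ids,
      meta = sprintf("equal-weights %s", model$label))
}
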