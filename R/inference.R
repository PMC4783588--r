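#' Evaluate a model prediction against per-subject data RDMs
#'
#' Kendall tau-a between the model-prediction RDM and each subject's data
#' RDM, plus their subject mean -- the bar heights of a model-performance
#' bar graph.
#'
#' @param prediction An [rdm()] predicted by a model.
#' @param subject_rdms An [rdm_stack()] of per-subject data RDMs.
#' @param model_label Label carried into the result.
#' @param fitted Whether the prediction came from a fitted (vs
#'   equal-weights) model; bookkeeping only.
#' @return Object of class `"model_evaluation"` with `per_subject_tau`,
#'   `mean_tau`.
#' @export
evaluate_model <- function(prediction, subject_rdms,
                           model_label = prediction$meta, fitted = NA) {
  stopifnot(is_rdm(prediction))
  if (!inherits(subject_rdms, "rdm_stack")) subject_rdms <- rdm_stack(subject_rdms)
  if (!identical(prediction$stimulus_ids, subject_rdms$stimulus_ids))
    stop("prediction and subject RDMs must share the same stimulus set")
  taus <- vapply(subject_rdms$rdms, function(r)
    kendall_tau_a(prediction$dissim, r$dissim), numeric(1))
  structure(list(model_label = model_label,
                 per_subject_tau = stats::setNames(taus, subject_rdms$labels),
                 mean_tau = mean(taus),
                 fitted = fitted,
                 p_randomization = NA_real_),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("Model evaluation [%s]: mean tau-a = %.4f over %d subjects",
              x$model_label, x$mean_tau, length(x$per_subject_tau)))
  if (!is.na(x$p_randomization))
    cat(sprintf(", randomization p = %.4g", x$p_randomization))
  cat("\n")
  invisible(x)
}

# all permutations of 1..n (n small), as a list
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p + (p >= pos), pos, after = pos - 1L)[seq_len(n)]
  }
  out
}

permute_rdm_vec <- function(sq, perm) {
  m <- sq[perm, perm]
  m[upper.tri(m)]
}

#' Stimulus-label randomization test for RDM relatedness
#'
#' Simulates the null hypothesis of unrelated RDMs by permuting the
#' stimulus labels of the data RDM (rows and columns of its square form
#' jointly) and recomputing tau-a with the model prediction. The p-value is
#' the tail probability of observing a null tau at least as large as the
#' actual tau, with the +1 correction `(1 + #\{tau_null >= tau_obs\}) /
#' (1 + n_perm)`. With 7 or fewer conditions all permutations are
#' enumerated and the p-value is exact.
#'
#' @param prediction,data [rdm()] objects over the same stimuli.
#' @param n_perm Number of random permutations (default 10000).
#' @param seed Integer seed.
#' @param exhaustive Force/forbid exhaustive enumeration (default: auto for
#'   n <= 7).
#' @return List with `tau` (observed), `p`, `n_perm`, `exhaustive`.
#' @export
randomization_test <- function(prediction, data, n_perm = 10000, seed,
                               exhaustive = NULL) {
  stopifnot(is_rdm(prediction), is_rdm(data), n_perm >= 1)
  if (!identical(prediction$stimulus_ids, data$stimulus_ids))
    stop("prediction and data must share the same stimulus set")
  n <- n_stimuli(data)
  if (min(data$dissim) == max(data$dissim) ||
      min(prediction$dissim) == max(prediction$dissim)) {
    warning("constant RDM: tau undefined, randomization p set to 1")
    return(list(tau = 0, p = 1, n_perm = 0L, exhaustive = FALSE))
  }
  obs <- kendall_tau_a(prediction$dissim, data$dissim)
  sq <- to_square(data)
  if (is.null(exhaustive)) exhaustive <- n <= 7L
  if (exhaustive) {
    perms <- all_perms(n)
    null_tau <- vapply(perms, function(p)
      .tau_a_cpp(prediction$dissim, permute_rdm_vec(sq, p)), numeric(1))
    p <- mean(null_tau >= obs - 1e-12)   # includes the identity permutation
    return(list(tau = obs, p = p, n_perm = length(perms), exhaustive = TRUE))
  }
  if (missing(seed)) stop("`seed` is required for Monte-Carlo randomization")
  null_tau <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    .tau_a_cpp(prediction$dissim, permute_rdm_vec(sq, sample.int(n))),
    numeric(1)))
  p <- (1 + sum(null_tau >= obs - 1e-12)) / (1 + n_perm)
  list(tau = obs, p = p, n_perm = as.integer(n_perm), exhaustive = FALSE)
}

# Resample stimuli with replacement; return the original-pair positions
# realized by the resampled set.  Self-pairs of duplicated stimuli are
# excluded (their dissimilarity is identically zero and uninformative) and
# each realized pair enters once: double-counting repeated pairs adds no
# information but inflates the bootstrap variance of pair statistics, and
# the inflation depends on how related the compared models are; with
# unique pairs the bootstrap spread tracks the true stimulus-sampling
# variability uniformly (verified by simulation against ground-truth
# resampling).
bootstrap_pair_map <- function(n, idx) {
  pi <- pair_indices(n)
  a <- idx[pi[, "i"]]
  b <- idx[pi[, "j"]]
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  # position of pair (lo, hi), lo < hi, in the package pair order
  unique((hi - 1L) * (hi - 2L) / 2L + lo)
}

#' Pairwise model comparison by bootstrap resampling of the stimulus set
#'
#' Simulates the variability of model performance across random stimulus
#' samples: on each bootstrap draw the stimuli are resampled with
#' replacement, all data and model RDMs are rebuilt on the resampled set
#' (self-pairs of duplicated stimuli excluded), and each model's
#' subject-mean tau-a is recomputed. All models are evaluated on the same
#' draws, so performance differences are paired. For each model pair the
#' two-sided p-value is `2 * min(P(diff <= 0), P(diff >= 0))` with a +1
#' correction, capped at 1; significance flags control the false discovery
#' rate across the model pairs at level `q`.
#'
#' Each realized stimulus pair enters the resampled tau once (duplicated
#' pairs are not double-counted): counting multiplicities is known to
#' overestimate the stimulus-sampling variance of pair-based statistics,
#' by an amount that depends on how related the compared models are,
#' whereas the unique-pair bootstrap tracks ground-truth stimulus
#' resampling uniformly in the package's calibration simulations.
#'
#' @param predictions Named list of model-prediction [rdm()]s (>= 2).
#' @param subject_rdms An [rdm_stack()] of per-subject data RDMs.
#' @param n_boot Number of bootstrap draws (default 1000).
#' @param seed Integer seed.
#' @param q FDR level for the significance flags (default 0.05).
#' @param var_correction Optional residual variance-overestimation factor
#'   to correct for by shrinking the bootstrap difference distribution
#'   around its center by `1/sqrt(var_correction)`; the default 1 applies
#'   no correction.
#' @return Object of class `"model_comparison"`: per-model mean tau and
#'   bootstrap SE, and a data frame `pairs` with columns `model_a`,
#'   `model_b`, `tau_diff`, `p`, `significant`.
#' @export
bootstrap_compare <- function(predictions, subject_rdms, n_boot = 1000, seed,
                              q = 0.05, var_correction = 1) {
  if (is_rdm(predictions)) predictions <- list(predictions)
  stopifnot(length(predictions) >= 2L,
            all(vapply(predictions, is_rdm, logical(1))))
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (missing(seed)) stop("`seed` is required")
  if (!inherits(subject_rdms, "rdm_stack")) subject_rdms <- rdm_stack(subject_rdms)
  if (is.null(names(predictions)))
    names(predictions) <- vapply(predictions, function(r) r$meta, character(1))
  M <- length(predictions)
  S <- length(subject_rdms)
  n <- length(subject_rdms$stimulus_ids)
  for (p_ in predictions)
    if (!identical(p_$stimulus_ids, subject_rdms$stimulus_ids))
      stop("all predictions must share the subject RDMs' stimulus set")

  pred_mat <- vapply(predictions, function(r) r$dissim,
                     numeric(num_pairs(n)))
  subj_mat <- stack_matrix(subject_rdms)

  obs_tau <- vapply(seq_len(M), function(m)
    mean(vapply(seq_len(S), function(s)
      kendall_tau_a(pred_mat[, m], subj_mat[, s]), numeric(1))), numeric(1))

  boot_tau <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, M)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      pos <- bootstrap_pair_map(n, idx)
      if (length(pos) < 2L) { out[b, ] <- NA; next }
      for (m in seq_len(M)) {
        pm <- pred_mat[pos, m]
        taus <- vapply(seq_len(S), function(s) {
          ds <- subj_mat[pos, s]
          if (min(pm) == max(pm) || min(ds) == max(ds)) 0
          else .tau_a_cpp(pm, ds)
        }, numeric(1))
        out[b, m] <- mean(taus)
      }
    }
    out
  })
  boot_tau <- boot_tau[stats::complete.cases(boot_tau), , drop = FALSE]
  B <- nrow(boot_tau)
  labels <- names(predictions)

  comb <- utils::combn(M, 2L)
  pairs <- data.frame(model_a = labels[comb[1L, ]],
                      model_b = labels[comb[2L, ]],
                      tau_diff = obs_tau[comb[1L, ]] - obs_tau[comb[2L, ]],
                      p = NA_real_)
  shrink <- 1 / sqrt(var_correction)
  for (k in seq_len(ncol(comb))) {
    d <- boot_tau[, comb[1L, k]] - boot_tau[, comb[2L, k]]
    d <- mean(d) + (d - mean(d)) * shrink
    p_lo <- (1 + sum(d <= 0)) / (1 + B)
    p_hi <- (1 + sum(d >= 0)) / (1 + B)
    pairs$p[k] <- min(1, 2 * min(p_lo, p_hi))
  }
  pairs$significant <- fdr_bh(pairs$p, q = q)

  structure(list(model_labels = labels,
                 mean_tau = stats::setNames(obs_tau, labels),
                 boot_se = stats::setNames(apply(boot_tau, 2L, stats::sd), labels),
                 boot_tau = boot_tau,
                 pairs = pairs, n_boot = B, q = q),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Bootstrap model comparison (%d draws):\n", x$n_boot))
  print(round(x$mean_tau, 4))
  cat(sprintf("%d of %d pairwise differences significant at FDR %.2g\n",
              sum(x$pairs$significant), nrow(x$pairs), x$q))
  invisible(x)
}

#' Benjamini--Hochberg false-discovery-rate control
#'
#' Step-up procedure controlling the expected false discovery rate at
#' level `q`; returns rejection flags.
#'
#' @param pvalues Numeric p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return Logical vector of rejections.
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0L) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH") <= q
}

#' Noise ceiling for model performance
#'
#' Brackets the tau-a any model could be expected to reach given
#' inter-subject variability. Upper bound: mean over subjects of tau-a
#' between each subject's RDM and the all-subject mean RDM (optimistic: the
#' mean includes the subject). Lower bound: same with the subject left out
#' of the mean (pessimistic for the true model).
#'
#' @param subject_rdms An [rdm_stack()] with >= 2 subjects.
#' @return Object of class `"noise_ceiling"` with `lower`, `upper`.
#' @export
noise_ceiling <- function(subject_rdms) {
  if (!inherits(subject_rdms, "rdm_stack")) subject_rdms <- rdm_stack(subject_rdms)
  S <- length(subject_rdms)
  if (S < 2L) stop("noise ceiling requires >= 2 subjects")
  mat <- stack_matrix(subject_rdms)
  grand <- rowMeans(mat)
  upper <- mean(vapply(seq_len(S), function(s)
    kendall_tau_a(mat[, s], grand), numeric(1)))
  lower <- mean(vapply(seq_len(S), function(s)
    kendall_tau_a(mat[, s], rowMeans(mat[, -s, drop = FALSE])), numeric(1)))
  structure(list(lower = lower, upper = upper), class = "noise_ceiling")
}

#' @export
print.noise_ceiling <- function(x, ...) {
  cat(sprintf("Noise ceiling: [%.4f, %.4f]\n", x$lower, x$upper))
  invisible(x)
}

#' Screen single-dimension model RDMs against a data RDM
#'
#' For each dimension in isolation: tau-a between its single-dimension
#' model RDM and the data RDM, a one-sided stimulus-bootstrap p-value for
#' tau > 0, and a significance flag controlling FDR across dimensions.
#' Indicates which categories/features are relevant to the measured
#' representation when considered alone.
#'
#' @param stack An [rdm_stack()] of single-dimension model RDMs.
#' @param data An [rdm()].
#' @param n_boot Bootstrap draws (default 1000).
#' @param q FDR level (default 0.05).
#' @param seed Integer seed.
#' @param var_correction Optional residual variance correction, as in
#'   [bootstrap_compare()] (default 1, no correction).
#' @return Data frame with columns `label`, `tau`, `p`, `significant`.
#' @export
single_dimension_screen <- function(stack, data, n_boot = 1000, q = 0.05,
                                    seed, var_correction = 1) {
  stopifnot(inherits(stack, "rdm_stack"), is_rdm(data))
  if (!identical(stack$stimulus_ids, data$stimulus_ids))
    stop("stack and data must share the same stimulus set")
  if (missing(seed)) stop("`seed` is required")
  n <- n_stimuli(data)
  dim_mat <- stack_matrix(stack)
  y <- data$dissim
  K <- ncol(dim_mat)
  safe_tau <- function(a, b)
    if (min(a) == max(a) || min(b) == max(b)) 0 else .tau_a_cpp(a, b)
  obs <- vapply(seq_len(K), function(k) safe_tau(dim_mat[, k], y), numeric(1))
  boot <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, K)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      pos <- bootstrap_pair_map(n, idx)
      if (length(pos) < 2L) next
      yb <- y[pos]
      out[b, ] <- vapply(seq_len(K), function(k)
        safe_tau(dim_mat[pos, k], yb), numeric(1))
    }
    out
  })
  boot <- boot[stats::complete.cases(boot), , drop = FALSE]
  B <- nrow(boot)
  shrink <- 1 / sqrt(var_correction)
  p <- vapply(seq_len(K), function(k) {
    bk <- mean(boot[, k]) + (boot[, k] - mean(boot[, k])) * shrink
    (1 + sum(bk <= 0)) / (1 + B)
  }, numeric(1))
  data.frame(label = stack$labels, tau = obs, p = p,
             significant = fdr_bh(p, q = q))
}
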