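#' Ground truth for a synthetic dataset
#'
#' Everything the generator knows and the analysis is supposed to recover:
#' the dimension matrix, the true dimension weights (a dimension scaled by
#' `w` contributes `w^2` times its single-dimension RDM to the target), the
#' channel-noise scale and the sampling sizes.
#'
#' @param dims A [dimension_matrix()] (categorical and feature dimensions
#'   concatenated).
#' @param dimension_weights Non-negative weight per dimension (w_k, on the
#'   dimension scale; the RDM-scale weights are `w_k^2`).
#' @param shared_variance_mix Fraction of generating weight mass on
#'   category dimensions that have correlated feature partners.
#' @param noise_sd Channel noise SD relative to unit signal RMS.
#' @param n_subjects,n_channels,seed Sampling sizes and seed.
#' @return Object of class `"ground_truth"`.
#' @export
ground_truth <- function(dims, dimension_weights, shared_variance_mix = NA,
                         noise_sd = 0, n_subjects = 4, n_channels = NULL,
                         seed = NA) {
  stopifnot(inherits(dims, "dim_matrix"),
            length(dimension_weights) == nrow(dims$values),
            all(dimension_weights >= 0))
  structure(list(dims = dims,
                 dimension_weights = as.numeric(dimension_weights),
                 rdm_weights = as.numeric(dimension_weights)^2,
                 shared_variance_mix = shared_variance_mix,
                 noise_sd = noise_sd, n_subjects = n_subjects,
                 n_channels = n_channels, seed = seed),
            class = "ground_truth")
}

# draw a non-constant binary vector, retrying a few times
rand_binary <- function(n, p) {
  for (i in 1:50) {
    v <- stats::rbinom(n, 1L, p)
    if (min(v) != max(v)) return(v)
  }
  v[sample.int(n, 1L)] <- 1 - v[1L]
  v
}

#' Generate hierarchically nested category and correlated feature dimensions
#'
#' Categories are indicator vectors of the nodes of a random nesting tree
#' over the stimuli (each child's present-set is a strict subset of its
#' parent's), emulating labels that range from specific to abstract.
#' Features are binary vectors that are either *related* -- constructed
#' from a randomly chosen category vector by independent entry flips tuned
#' to a target point-biserial correlation (`feature_category_corr`; 1
#' duplicates the category, 0 is independent) -- or category-unrelated
#' random binary vectors.
#'
#' @param n_stimuli Number of stimuli.
#' @param n_categories,n_features Dimension counts (e.g. 114 and 120 for a
#'   96-image set).
#' @param nesting_depth Maximum tree depth (default 8).
#' @param feature_category_corr Target correlation of related features with
#'   their source category, in \[0, 1\].
#' @param prop_related Fraction of features that are category-related.
#' @param reserve_frac Fraction of categories excluded from feature
#'   attachment (category divisions without visual-feature correlates,
#'   e.g. purely semantic splits); sampled with the same balance
#'   preference as feature sources.
#' @param max_partners_per_category Cap on the number of features attached
#'   to any one category (default unlimited); features beyond the cap
#'   become category-unrelated.
#' @param attach_support Length-2 numeric: categories with support in this
#'   (exclusive) range are candidate feature-attachment targets; defaults
#'   to the balanced band `(n/6, 5n/6)`.
#' @param seed Integer seed.
#' @return List with `categorical` and `feature` [dimension_matrix()]s; the
#'   feature matrix carries an attribute `related_to` (source category
#'   label per feature, NA for unrelated features).
#' @export
generate_dimension_matrix <- function(n_stimuli, n_categories, n_features,
                                      nesting_depth = 8,
                                      feature_category_corr = 0.88,
                                      prop_related = 0.6, reserve_frac = 0.25,
                                      max_partners_per_category = Inf,
                                      attach_support = NULL,
                                      seed) {
  stopifnot(n_stimuli >= 4, n_categories >= 1, n_features >= 1)
  if (feature_category_corr < 0 || feature_category_corr > 1) {
    warning("feature_category_corr clamped into [0, 1]")
    feature_category_corr <- min(max(feature_category_corr, 0), 1)
  }
  with_seed(seed, {
    stim <- paste0("stim", formatC(seq_len(n_stimuli), width = 3, flag = "0"))
    # nesting tree: split nodes breadth-first into 2-3 nonempty parts
    cat_rows <- list()
    level <- list(seq_len(n_stimuli))
    depth <- 0L
    while (length(cat_rows) < n_categories && depth < nesting_depth) {
      depth <- depth + 1L
      nxt <- list()
      for (node in level) {
        if (length(node) < 2L) next
        k_max <- if (length(node) >= n_stimuli / 3) 4L else 3L
        k <- if (length(node) == 2L) 2L else sample(2:min(k_max, length(node)), 1L)
        # uneven child sizes give a mix of broad and narrow categories
        p <- stats::runif(k, 0.6, 1.6)
        grp <- sample(c(seq_len(k),
                        sample.int(k, length(node) - k, replace = TRUE,
                                   prob = p)))
        for (g in seq_len(k)) {
          child <- node[grp == g]
          v <- integer(n_stimuli)
          v[child] <- 1L
          cat_rows[[length(cat_rows) + 1L]] <- v
          nxt[[length(nxt) + 1L]] <- child
        }
      }
      if (length(nxt) == 0L) break
      level <- nxt
    }
    if (length(cat_rows) < n_categories)
      warning(sprintf("nesting tree exhausted at %d category dimensions (%d requested)",
                      length(cat_rows), n_categories))
    cat_vals <- do.call(rbind, cat_rows[seq_len(min(n_categories,
                                                    length(cat_rows)))])
    rownames(cat_vals) <- paste0("cat", formatC(seq_len(nrow(cat_vals)),
                                                width = 3, flag = "0"))
    categorical <- dimension_matrix(cat_vals, stimulus_ids = stim)

    # features: flips of category vectors, or independent binaries
    n_related <- round(prop_related * n_features)
    flip_p <- (1 - feature_category_corr) / 2
    feat_vals <- matrix(0L, n_features, n_stimuli)
    related_to <- rep(NA_character_, n_features)
    # related features attach to informative (balanced) categories: a
    # meaningful point-biserial correlation needs a category that splits
    # the image set, not a near-singleton label
    supp <- rowSums(cat_vals)
    balance <- supp * (n_stimuli - supp)
    src_prob <- balance
    if (!is.null(attach_support))
      src_prob[supp <= attach_support[1L] | supp >= attach_support[2L]] <- 0
    # reserve a fraction of the major balanced divisions: those stay
    # feature-free, the rest remain the dominant attachment targets.
    # reserving a division removes its whole subtree from attachment,
    # otherwise features tied to its child categories would reconstruct it
    top <- which(supp > n_stimuli / 6 & supp < 5 * n_stimuli / 6)
    n_reserve <- if (reserve_frac > 0 && length(top) > 2L)
      min(max(2L, round(reserve_frac * length(top))), length(top) - 2L)
    else 0L
    if (n_reserve > 0) {
      roots <- top[sample.int(length(top), n_reserve)]
      for (r in roots) {
        inside <- cat_vals %*% cat_vals[r, ] == rowSums(cat_vals)  # support subset
        cand <- src_prob
        cand[inside] <- 0
        if (sum(cand > 0) >= 2L) src_prob <- cand   # keep attachment targets
      }
    }
    partner_count <- integer(nrow(cat_vals))
    for (f in seq_len(n_features)) {
      open <- src_prob > 0 & partner_count < max_partners_per_category
      if (f <= n_related && any(open)) {
        src <- sample.int(nrow(cat_vals), 1L, prob = src_prob * open)
        partner_count[src] <- partner_count[src] + 1L
        v <- cat_vals[src, ]
        if (flip_p > 0) {
          repeat {
            flips <- stats::rbinom(n_stimuli, 1L, flip_p)
            cand <- as.integer(xor(v, flips))
            if (min(cand) != max(cand)) { v <- cand; break }
          }
        }
        related_to[f] <- rownames(cat_vals)[src]
        feat_vals[f, ] <- v
      } else {
        # unrelated features span broad to single-object support, like
        # rare descriptive labels that apply to one or two images
        feat_vals[f, ] <- rand_binary(n_stimuli, stats::runif(1, 0.02, 0.5))
      }
    }
    # exact duplicates make the combined design rank-deficient; nudge them
    # (except in the corr = 1 copy limit, where duplication is the point)
    if (feature_category_corr < 1) {
      all_vals <- rbind(cat_vals, feat_vals)
      repeat {
        dup <- which(duplicated(apply(all_vals, 1L, paste, collapse = "")))
        dup <- dup[dup > nrow(cat_vals)]
        if (length(dup) == 0L) break
        for (d in dup) {
          i <- sample.int(n_stimuli, 1L)
          all_vals[d, i] <- 1L - all_vals[d, i]
        }
      }
      feat_vals <- all_vals[-seq_len(nrow(cat_vals)), , drop = FALSE]
    }
    rownames(feat_vals) <- paste0("feat", formatC(seq_len(n_features),
                                                  width = 3, flag = "0"))
    feature <- dimension_matrix(feat_vals, stimulus_ids = stim)
    attr(feature, "related_to") <- related_to
    list(categorical = categorical, feature = feature)
  })
}

#' Target RDM implied by a ground truth
#'
#' The weighted-sum forward model: `sum_k w_k^2 RDM_k` over the truth's
#' dimensions, plus an optional constant offset.
#'
#' @param truth A [ground_truth()].
#' @param offset Constant added to every pair (default 0).
#' @return An [rdm()].
#' @export
generate_target_rdm <- function(truth, offset = 0) {
  stopifnot(inherits(truth, "ground_truth"))
  stack <- single_dimension_rdms(truth$dims)
  X <- stack_matrix(stack)
  rdm(drop(X %*% truth$rdm_weights) + offset, truth$dims$stimulus_ids,
      meta = "synthetic target")
}

# orthonormal basis of R^C orthogonal to the all-ones vector, first r columns
ones_complement_basis <- function(C, r) {
  stopifnot(r <= C - 1L)
  Q <- qr.Q(qr(cbind(rep(1, C), diag(C)[, seq_len(r), drop = FALSE])))
  Q[, 1L + seq_len(r), drop = FALSE]
}

#' Generate per-subject channel patterns realizing a target RDM
#'
#' Constructs stimulus response patterns whose correlation-distance RDM
#' matches the target (linearly rescaled so its maximum equals
#' `scale_max`), then adds independent Gaussian channel noise per subject.
#' The shared signal is obtained by double-centering the implied
#' correlation matrix into a Gram matrix, projecting to the nearest
#' positive-semidefinite matrix where needed (the projection error is
#' returned as attribute `projection_error`), factorizing, and rotating the
#' factors into a channel basis orthogonal to the constant channel so that
#' Pearson correlations across channels reproduce the target exactly.
#'
#' @param target An [rdm()] (any non-negative scale).
#' @param n_subjects Number of subjects (shared signal, independent noise).
#' @param n_channels Channel count; must exceed the stimulus count.
#' @param noise_sd Noise SD relative to the unit-RMS signal.
#' @param seed Integer seed.
#' @param scale_max Correlation distance assigned to the largest target
#'   dissimilarity (default 0.8, i.e. the most dissimilar pair still
#'   correlates at r = 0.2, typical of multivoxel pattern data; moderate
#'   values also keep weighted-sum targets exactly embeddable as
#'   correlation structures).
#' @return List of [pattern_set()], one per subject, with attributes
#'   `projection_error` and `scaled_target` (the rescaled target [rdm()]).
#' @export
generate_subject_patterns <- function(target, n_subjects, n_channels,
                                      noise_sd, seed, scale_max = 0.8) {
  stopifnot(is_rdm(target), scale_max > 0, scale_max <= 2)
  n <- n_stimuli(target)
  if (n_channels < n + 1L)
    stop("n_channels must exceed the stimulus count (need n_stimuli + 1)")
  d <- target$dissim
  if (max(d) > 0) d <- d / max(d) * scale_max
  R <- 1 - to_square(rdm(d, target$stimulus_ids))
  eg <- eigen(R, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  Rp <- eg$vectors %*% (lam * t(eg$vectors))
  dg <- pmax(diag(Rp), 1e-12)
  Rp <- Rp / sqrt(outer(dg, dg))
  proj_err <- max(abs((1 - Rp[upper.tri(Rp)]) - d))
  if (proj_err > 1e-8)
    message(sprintf("target projected to nearest correlation structure (max adjustment %.3g)",
                    proj_err))
  eg2 <- eigen(Rp, symmetric = TRUE)
  keep <- eg2$values > max(eg2$values) * 1e-12
  X <- eg2$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eg2$values[keep]), sum(keep))
  basis <- ones_complement_basis(n_channels, ncol(X))
  signal <- X %*% t(basis) * sqrt(n_channels)   # unit entry RMS, zero row mean
  rownames(signal) <- target$stimulus_ids
  out <- with_seed(seed, lapply(seq_len(n_subjects), function(s) {
    noise <- matrix(stats::rnorm(n * n_channels, sd = noise_sd), n, n_channels)
    pattern_set(signal + noise, stimulus_ids = target$stimulus_ids,
                subject_id = sprintf("s%02d", s))
  }))
  attr(out, "projection_error") <- proj_err
  attr(out, "scaled_target") <- rdm(d, target$stimulus_ids,
                                    meta = "scaled target")
  out
}

#' Simulate description-generation and validation vote tensors
#'
#' Subjects mark a (description, image) pair that is truly present with
#' probability `1 - flip_rate` and a truly absent one with probability
#' `flip_rate`. With a small flip rate, the standard thresholds (3 of 15
#' generators, 6 of 8 validators) recover the planted binary dimensions.
#'
#' @param dims A [dimension_matrix()] (truth; values > 0 count as present).
#' @param n_generators,n_validators Subject counts for the two phases.
#' @param flip_rate Mark-error probability in \[0, 1\].
#' @param seed Integer seed.
#' @return List with `generation` and `validation` [description_votes()].
#' @export
generate_vote_tensor <- function(dims, n_generators = 15, n_validators = 8,
                                 flip_rate, seed) {
  stopifnot(inherits(dims, "dim_matrix"),
            flip_rate >= 0, flip_rate <= 1)
  truth <- dims$values > 0
  mk <- function(n_subj, prefix) {
    p <- ifelse(truth, 1 - flip_rate, flip_rate)
    votes <- array(0L, dim = c(nrow(truth), ncol(truth), n_subj),
                   dimnames = list(dims$dimension_labels, dims$stimulus_ids,
                                   paste0(prefix, seq_len(n_subj))))
    for (s in seq_len(n_subj))
      votes[, , s] <- (matrix(stats::runif(length(p)), nrow(p)) < p) * 1L
    votes
  }
  with_seed(seed, list(
    generation = description_votes(mk(n_generators, "gen"),
                                   phase = "generation"),
    validation = description_votes(mk(n_validators, "val"),
                                   phase = "validation")))
}

# 2-D configuration of a sub-RDM via classical scaling, zero-padded
planar_config <- function(sq) {
  cfg <- suppressWarnings(stats::cmdscale(sq, k = 2))
  if (ncol(cfg) < 2) cfg <- cbind(cfg, 0)
  cfg
}

#' Simulate multi-arrangement trials from a latent judgment RDM
#'
#' The first trial shows all items; each later trial shows the
#' `subset_size` items touching the pairs with the least accumulated
#' evidence ("zooming in" on weakly separated items). Per trial, items are
#' placed at the 2-D classical-scaling configuration of the corresponding
#' target sub-RDM, jittered with Gaussian placement noise, and recorded at
#' a random per-trial arena scale -- absolute on-screen distances carry no
#' information, as in the real task.
#'
#' @param target Latent judgment [rdm()].
#' @param n_trials Total trial count (>= 1; the first trial alone covers
#'   all pairs).
#' @param subset_size Items per subsequent trial (>= 3).
#' @param placement_noise Coordinate jitter SD relative to the
#'   configuration RMS radius.
#' @param seed Integer seed.
#' @param subject_id Subject label.
#' @return A [subject_judgments()].
#' @export
generate_arrangement_trials <- function(target, n_trials = 10, subset_size,
                                        placement_noise, seed,
                                        subject_id = "sim") {
  stopifnot(is_rdm(target), subset_size >= 3, n_trials >= 1)
  n <- n_stimuli(target)
  sq <- to_square(target)
  ids <- target$stimulus_ids
  pi <- pair_indices(n)
  evidence <- numeric(nrow(pi))
  with_seed(seed, {
    trials <- vector("list", n_trials)
    for (t in seq_len(n_trials)) {
      if (t == 1L) sel <- seq_len(n)
      else {
        ord <- order(evidence, stats::runif(length(evidence)))
        sel <- integer(0)
        for (k in ord) {
          sel <- union(sel, c(pi[k, "i"], pi[k, "j"]))
          if (length(sel) >= subset_size) break
        }
        sel <- sort(sel[seq_len(min(subset_size, length(sel)))])
      }
      cfg <- planar_config(sq[sel, sel, drop = FALSE])
      radius <- sqrt(mean(rowSums(cfg^2)))
      if (radius == 0) radius <- 1
      cfg <- cfg + matrix(stats::rnorm(length(cfg),
                                       sd = placement_noise * radius),
                          nrow(cfg))
      scale_t <- stats::runif(1, 0.5, 2)
      dmat <- as.matrix(stats::dist(cfg)) * scale_t
      sub_pi <- pair_indices(length(sel))
      trials[[t]] <- arrangement_trial(data.frame(
        item_i = ids[sel[sub_pi[, "i"]]],
        item_j = ids[sel[sub_pi[, "j"]]],
        distance = dmat[upper.tri(dmat)],
        stringsAsFactors = FALSE))
      # accumulate evidence (squared placed distance) for shown pairs
      pos <- (sel[sub_pi[, "j"]] - 1L) * (sel[sub_pi[, "j"]] - 2L) / 2L +
        sel[sub_pi[, "i"]]
      evidence[pos] <- evidence[pos] + dmat[upper.tri(dmat)]^2 / scale_t^2
    }
    subject_judgments(subject_id, trials)
  })
}

#' Calibration constants of the named synthetic scenarios
#'
#' One set of generator settings per scenario, scaled from the reference
#' study size (96 stimuli, 114 categorical + 120 feature dimensions).
#' `it_like` puts all generating weight on category dimensions that have
#' exactly coextensive feature partners (pure shared variance, as in
#' high-level visual cortex, where the two model families explain the
#' same structure); `judgment_like` adds weight on reserved category
#' divisions without feature partners (extra categorical variance, as in
#' similarity judgments) and has more, cleaner subjects; `evc_like`
#' generates data from latent dimensions unrelated to the models; `null`
#' is pure channel noise.
#'
#' @param scenario Scenario name.
#' @param n_stimuli Stimulus count.
#' @return Named list of generator settings.
#' @export
scenario_defaults <- function(scenario = c("it_like", "judgment_like",
                                           "evc_like", "null"),
                              n_stimuli = 96) {
  scenario <- match.arg(scenario)
  base <- list(
    n_categories = max(6L, round(114 * n_stimuli / 96)),
    n_features = max(6L, round(120 * n_stimuli / 96)),
    feature_category_corr = 0.88,
    prop_related = 0.6,
    reserve_frac = 0.25,
    max_partners_per_category = Inf,
    feat_mass_ratio = 1,
    tiebreak_mass = 0,
    attach_all = FALSE,
    n_channels = 3L * n_stimuli + 4L,
    weight_range = c(0.7, 1.3))
  extra <- switch(scenario,
    it_like = list(n_subjects = 4L, noise_sd = 2.5,
                   shared_variance_mix = 1.0, feature_category_corr = 1,
                   reserve_frac = 0, tiebreak_mass = 0.002,
                   prop_related = 0.88, max_partners_per_category = 1,
                   attach_all = TRUE),
    judgment_like = list(n_subjects = 16L, noise_sd = 0.8,
                         shared_variance_mix = 0.25),
    evc_like = list(n_subjects = 4L, noise_sd = 1.0,
                    shared_variance_mix = NA, n_latent = 10L),
    null = list(n_subjects = 4L, noise_sd = 1.0, shared_variance_mix = NA))
  utils::modifyList(base, extra)
}

#' Scenario configuration
#'
#' @param scenario One of `"it_like"`, `"judgment_like"`, `"evc_like"`,
#'   `"null"`.
#' @param n_stimuli Stimulus count (default 96).
#' @param heldout_size Held-out set size for downstream cross-validation.
#' @param seed Integer seed.
#' @param ... Overrides for individual [scenario_defaults()] entries
#'   (e.g. `noise_sd = 0` for a noiseless recovery check).
#' @return Object of class `"scenario_config"`.
#' @export
scenario_config <- function(scenario, n_stimuli = 96, heldout_size = 8,
                            seed, ...) {
  scenario <- match.arg(scenario, c("it_like", "judgment_like", "evc_like",
                                    "null"))
  if (missing(seed)) stop("`seed` is required")
  settings <- scenario_defaults(scenario, n_stimuli)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(settings))
  if (length(unknown))
    stop("unknown scenario settings: ", paste(unknown, collapse = ", "))
  settings[names(overrides)] <- overrides
  structure(list(scenario = scenario, n_stimuli = n_stimuli,
                 heldout_size = heldout_size, seed = as.integer(seed),
                 settings = settings),
            class = "scenario_config")
}

#' Generate a full synthetic dataset for a named scenario
#'
#' Produces every input the analysis pipeline consumes -- category and
#' feature dimension matrices, the latent target RDM, per-subject channel
#' patterns and their correlation-distance RDMs, and the subject-average
#' data RDM -- together with the generating ground truth.
#'
#' @param config A [scenario_config()].
#' @return List with elements `config`, `categorical`, `feature`
#'   ([dimension_matrix()]s), `truth` ([ground_truth()]), `target`
#'   ([rdm()]), `patterns` (list of [pattern_set()]), `subject_rdms`
#'   ([rdm_stack()]), `data_rdm` (subject-average [rdm()]).
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  s <- config$settings
  seed <- config$seed
  dims <- generate_dimension_matrix(
    config$n_stimuli, s$n_categories, s$n_features,
    feature_category_corr = s$feature_category_corr,
    prop_related = s$prop_related, reserve_frac = s$reserve_frac,
    max_partners_per_category = s$max_partners_per_category,
    attach_support = if (isTRUE(s$attach_all)) c(0, config$n_stimuli)
                     else c(config$heldout_size,
                            config$n_stimuli - config$heldout_size),
    seed = seed)
  related <- unique(stats::na.omit(attr(dims$feature, "related_to")))
  cat_labels <- dims$categorical$dimension_labels
  shared_cats <- intersect(cat_labels, related)
  specific_cats <- setdiff(cat_labels, related)

  combined <- dimension_matrix(
    rbind(dims$categorical$values, dims$feature$values),
    dimension_labels = c(dims$categorical$dimension_labels,
                         dims$feature$dimension_labels),
    stimulus_ids = dims$categorical$stimulus_ids)

  # dimensions whose value pattern stays non-constant on every training
  # set of n - heldout_size stimuli: support at least heldout_size + 1
  # away from empty and full.  Weight planted outside this set could never
  # be recovered by held-out prediction (the dimension may vanish from a
  # training fold), so the generator confines the signal to it.
  support <- rowSums(combined$values > 0)
  eligible <- combined$dimension_labels[
    support > config$heldout_size & support < config$n_stimuli - config$heldout_size]
  # weighted dimensions must also be pairwise separable on every training
  # fold: two dimensions differing on very few stimuli become collinear
  # whenever those stimuli are all held out, leaving their weight split --
  # and hence the held-out prediction -- undetermined.  Greedily keep
  # larger divisions, dropping candidates within min_diff of a kept one.
  min_diff <- ceiling(config$heldout_size / 2)
  is_cat <- combined$dimension_labels %in% dims$categorical$dimension_labels
  ord <- order(!is_cat, -support, combined$dimension_labels)
  kept <- character(0)
  kept_vals <- NULL
  for (idx in ord) {
    l <- combined$dimension_labels[idx]
    if (!(l %in% eligible)) next
    v <- combined$values[idx, ]
    if (is.null(kept_vals) ||
        min(rowSums(abs(kept_vals - matrix(v, nrow(kept_vals), length(v),
                                           byrow = TRUE)))) >= min_diff) {
      kept <- c(kept, l)
      kept_vals <- rbind(kept_vals, v)
    }
  }
  eligible <- kept
  related_feats <- dims$feature$dimension_labels[
    !is.na(attr(dims$feature, "related_to"))]
  w <- with_seed(seed + 1L, {
    w <- numeric(nrow(combined$values))
    names(w) <- combined$dimension_labels
    if (config$scenario %in% c("it_like", "judgment_like")) {
      # shared component: category divisions with correlated feature
      # partners plus the partner features themselves, mass-balanced
      # across the two halves so neither model family is favored -- each
      # model contains one half exactly and reconstructs the other from
      # its correlated counterparts
      shared_c <- intersect(shared_cats, eligible)
      shared_f <- intersect(related_feats, eligible)
      shared <- c(shared_c, shared_f)
      w[shared] <- stats::runif(length(shared),
                                s$weight_range[1L], s$weight_range[2L])
      # set the feature-side share of the shared RDM-weight mass; the
      # equality point is below 1/2 because a category is reconstructed
      # by several partner features more faithfully than a feature is by
      # its single source category
      if (length(shared_c) > 0L && length(shared_f) > 0L)
        w[shared_f] <- w[shared_f] *
          sqrt(s$feat_mass_ratio * sum(w[shared_c]^2) / sum(w[shared_f]^2))
      # a whisper of weight on category-unrelated features breaks exact
      # value ties in the target (needed for rank-based recovery checks)
      # without measurably favoring the feature-based model
      if (s$tiebreak_mass > 0 && length(shared) > 0L) {
        tb <- intersect(dims$feature$dimension_labels[
          is.na(attr(dims$feature, "related_to"))], eligible)
        if (length(tb) > 0L) {
          w[tb] <- stats::runif(length(tb), s$weight_range[1L],
                                s$weight_range[2L])
          w[tb] <- w[tb] * sqrt(s$tiebreak_mass * sum(w[shared]^2) /
                                  sum(w[tb]^2))
        }
      }
      mix <- s$shared_variance_mix
      spec_pool <- intersect(specific_cats, eligible)
      if (mix < 1 && length(spec_pool) > 0L) {
        # category-specific component, scaled so that a fraction (1 - mix)
        # of the RDM-weight mass is unexplainable by features
        k <- min(length(spec_pool), max(3L, round(length(shared) / 2)))
        spec <- sample(spec_pool, k)
        w[spec] <- stats::runif(k, s$weight_range[1L], s$weight_range[2L])
        mass_ratio <- (1 - mix) / mix * sum(w[shared]^2) / sum(w[spec]^2)
        w[spec] <- w[spec] * sqrt(mass_ratio)
      }
    }
    w
  })
  truth <- ground_truth(combined, w,
                        shared_variance_mix = s$shared_variance_mix,
                        noise_sd = s$noise_sd, n_subjects = s$n_subjects,
                        n_channels = s$n_channels, seed = seed)

  if (config$scenario == "evc_like") {
    # data driven by latent dimensions unrelated to either model
    latent <- with_seed(seed + 2L, {
      v <- t(vapply(seq_len(s$n_latent), function(i)
        rand_binary(config$n_stimuli, stats::runif(1, 0.2, 0.5)),
        integer(config$n_stimuli)))
      dimension_matrix(v, stimulus_ids = combined$stimulus_ids)
    })
    target <- generate_target_rdm(
      ground_truth(latent, rep(1, nrow(latent$values))))
  } else if (config$scenario == "null" || all(w == 0)) {
    target <- rdm(rep(1, num_pairs(config$n_stimuli)),
                  combined$stimulus_ids, meta = "flat target")
  } else {
    target <- generate_target_rdm(truth)
  }

  if (config$scenario == "null" || max(target$dissim) == min(target$dissim)) {
    # pure noise: no shared signal component
    patterns <- with_seed(seed + 3L, lapply(seq_len(s$n_subjects), function(i)
      pattern_set(matrix(stats::rnorm(config$n_stimuli * s$n_channels,
                                      sd = max(s$noise_sd, 1)),
                         config$n_stimuli, s$n_channels),
                  stimulus_ids = combined$stimulus_ids,
                  subject_id = sprintf("s%02d", i))))
    attr(patterns, "projection_error") <- 0
  } else {
    patterns <- generate_subject_patterns(target, s$n_subjects, s$n_channels,
                                          s$noise_sd, seed = seed + 3L)
  }
  subject_rdms <- rdm_stack(lapply(patterns, rdm_from_patterns),
                            labels = vapply(patterns, function(p)
                              p$subject_id, character(1)))
  list(config = config, categorical = dims$categorical,
       feature = dims$feature, truth = truth, target = target,
       patterns = patterns, subject_rdms = subject_rdms,
       data_rdm = average_rdms(subject_rdms, meta = "subject average"))
}
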