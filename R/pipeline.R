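#' Run configuration for the fitting/evaluation pipeline
#'
#' Collects every setting of a full analysis run. Defaults mirror the
#' standard protocol: held-out sets of 8 stimuli, 10,000 stimulus-label
#' randomizations, 1,000 stimulus-bootstrap draws, FDR level 0.05.
#'
#' @param seed Integer seed (required; drives every stochastic stage).
#' @param heldout_size Cross-validation held-out set size.
#' @param n_perm Randomization-test permutations (0 disables the tests).
#' @param n_boot Bootstrap draws for model comparisons.
#' @param q FDR level.
#' @param mds_restarts Restarts for the second-order MDS.
#' @param output_dir Optional report directory (NULL: no files written).
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(seed, heldout_size = 8, n_perm = 10000, n_boot = 1000,
                       q = 0.05, mds_restarts = 8, output_dir = NULL) {
  if (missing(seed)) stop("`seed` is required")
  structure(list(seed = as.integer(seed),
                 heldout_size = as.integer(heldout_size),
                 n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
                 q = q, mds_restarts = as.integer(mds_restarts),
                 output_dir = output_dir),
            class = "run_config")
}

#' Build dimension models from labeling votes
#'
#' Runs the full model-construction chain: generation-threshold filtering,
#' validation thresholding with all-zero pruning, optional manual
#' exclusions, and iterative merging of highly correlated dimensions; then
#' derives the single-dimension model RDMs. A provenance log records the
#' description count surviving each stage.
#'
#' @param generation_votes Generation-phase [description_votes()].
#' @param validation_votes Validation-phase [description_votes()].
#' @param min_subjects Generation threshold (default 3).
#' @param min_votes Validation threshold (default 6).
#' @param merge_threshold Correlation threshold for merging (default 0.9).
#' @param exclude Description labels to drop (manual cleanup list).
#' @param output_dir Optional directory for the dimension CSV and log.
#' @return List with `dims` ([dimension_matrix()]), `rdms` ([rdm_stack()]),
#'   and `log` (data frame of per-stage description counts).
#' @export
build_models_pipeline <- function(generation_votes, validation_votes,
                                  min_subjects = 3, min_votes = 6,
                                  merge_threshold = 0.9, exclude = NULL,
                                  output_dir = NULL) {
  n_start <- length(generation_votes$descriptions)
  kept <- filter_generated_descriptions(generation_votes, min_subjects)
  sub <- validation_votes$votes[kept, , , drop = FALSE]
  vv <- description_votes(sub, phase = "validation")
  dims <- validate_descriptions(vv, min_votes = min_votes, exclude = exclude)
  n_validated <- nrow(dims$values)
  merged <- merge_correlated_dimensions(dims, threshold = merge_threshold)
  log <- data.frame(
    stage = c("generated", "generation_threshold", "validated", "merged"),
    n_descriptions = c(n_start, length(kept), n_validated,
                       nrow(merged$values)))
  rdms <- single_dimension_rdms(merged)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_dimension_matrix(merged, file.path(output_dir, "dimensions.csv"))
    utils::write.csv(log, file.path(output_dir, "build_log.csv"),
                     row.names = FALSE)
  }
  list(dims = merged, rdms = rdms, log = log)
}

#' Fit, evaluate and compare representational models end to end
#'
#' For each model: cross-validated NNLS prediction and an equal-weights
#' prediction; Kendall tau-a evaluation against each subject's RDM;
#' stimulus-label randomization tests (FDR-flagged across models);
#' stimulus-bootstrap pairwise model comparisons; the noise ceiling; and a
#' second-order MDS of the data RDM and fitted predictions. The returned
#' object embeds the exact configuration so any run is reproducible.
#'
#' @param models Named list of [model_spec()]s (e.g. categorical, feature,
#'   combined).
#' @param subject_rdms An [rdm_stack()] of per-subject data RDMs.
#' @param config A [run_config()].
#' @return Object of class `"pipeline_result"`: `fits`, `predictions`
#'   (fitted and equal-weights), `evaluations`, `randomization` (data
#'   frame), `comparison` ([bootstrap_compare()] result or NULL),
#'   `ceiling`, `embedding`, `config`.
#' @export
fit_evaluate_pipeline <- function(models, subject_rdms, config) {
  stopifnot(inherits(config, "run_config"),
            all(vapply(models, inherits, logical(1), "model_spec")))
  if (!inherits(subject_rdms, "rdm_stack")) subject_rdms <- rdm_stack(subject_rdms)
  if (is.null(names(models)))
    names(models) <- vapply(models, function(m) m$label, character(1))
  data_rdm <- average_rdms(subject_rdms, meta = "data")
  for (m in models) check_alignment(m, data_rdm)

  scheme <- build_crossval_scheme(data_rdm$stimulus_ids,
                                  heldout_size = config$heldout_size,
                                  seed = config$seed)
  fits <- lapply(models, function(m) crossval_predict(m, data_rdm, scheme))
  predictions <- c(
    stats::setNames(lapply(fits, `[[`, "predicted"),
                    paste0("fitted_", names(models))),
    stats::setNames(lapply(models, equal_weights_prediction),
                    paste0("equal_", names(models))))

  evaluations <- lapply(names(predictions), function(nm)
    evaluate_model(predictions[[nm]], subject_rdms, model_label = nm,
                   fitted = startsWith(nm, "fitted_")))
  names(evaluations) <- names(predictions)

  randomization <- NULL
  if (config$n_perm > 0) {
    rows <- lapply(seq_along(predictions), function(i)
      c(list(model = names(predictions)[i]),
        randomization_test(predictions[[i]], data_rdm,
                           n_perm = config$n_perm,
                           seed = config$seed + i)[c("tau", "p")]))
    randomization <- do.call(rbind, lapply(rows, as.data.frame))
    randomization$significant <- fdr_bh(randomization$p, q = config$q)
    for (nm in names(evaluations))
      evaluations[[nm]]$p_randomization <-
        randomization$p[randomization$model == nm]
  }

  comparison <- NULL
  if (config$n_boot > 0)
    comparison <- bootstrap_compare(predictions, subject_rdms,
                                    n_boot = config$n_boot,
                                    seed = config$seed, q = config$q)
  ceiling <- if (length(subject_rdms) >= 2L) noise_ceiling(subject_rdms)

  embed_stack <- rdm_stack(
    c(list(data_rdm), lapply(fits, `[[`, "predicted")),
    labels = c("data", paste0("fitted_", names(models))))
  embedding <- if (length(embed_stack) >= 3L)
    mds_embed(second_order_rdm(embed_stack), seed = config$seed,
              n_restarts = config$mds_restarts)

  result <- structure(list(fits = fits, predictions = predictions,
                           evaluations = evaluations,
                           randomization = randomization,
                           comparison = comparison, ceiling = ceiling,
                           embedding = embedding, config = config,
                           scheme_folds = length(scheme$folds)),
                      class = "pipeline_result")
  if (!is.null(config$output_dir))
    render_report(config$output_dir, evaluations, comparisons = comparison,
                  ceiling = ceiling, data_rdm = data_rdm,
                  predictions = predictions, embedding = embedding)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d models, %d cross-validation folds (seed %d)\n",
              length(x$fits), x$scheme_folds, x$config$seed))
  for (e in x$evaluations) print(e)
  if (!is.null(x$ceiling)) print(x$ceiling)
  invisible(x)
}
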