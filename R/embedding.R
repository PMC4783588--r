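#' Second-order RDM: distances between RDMs
#'
#' RDMs live in a space with one axis per stimulus pair; relatedness
#' between RDMs is measured there as `1 - Spearman r` between their
#' dissimilarity vectors, which is invariant to monotone transforms of each
#' RDM. A constant RDM has undefined rank correlation; its distances are
#' set to 1 with a warning.
#'
#' @param stack An [rdm_stack()] with >= 2 members.
#' @return Object of class `"second_order_rdm"`: `labels` and a symmetric
#'   `distances` matrix with zero diagonal, entries in \[0, 2\].
#' @export
second_order_rdm <- function(stack) {
  stopifnot(inherits(stack, "rdm_stack"))
  if (length(stack) < 2L) stop("need >= 2 RDMs")
  mat <- stack_matrix(stack)
  const <- apply(mat, 2L, function(v) min(v) == max(v))
  cc <- suppressWarnings(stats::cor(mat, method = "spearman"))
  d <- 1 - cc
  if (any(const)) {
    warning("constant RDM(s): second-order distance set to 1")
    d[const, ] <- 1
    d[, const] <- 1
  }
  diag(d) <- 0
  d <- pmin(pmax((d + t(d)) / 2, 0), 2)
  dimnames(d) <- list(stack$labels, stack$labels)
  structure(list(labels = stack$labels, distances = d),
            class = "second_order_rdm")
}

# One SMACOF (majorization) run minimizing raw metric stress
# sum_(i<j) (delta_ij - d_ij(X))^2 from a given start configuration.
smacof_run <- function(delta, X, max_iter = 300, tol = 1e-10) {
  n <- nrow(delta)
  dist_mat <- function(X) as.matrix(stats::dist(X))
  raw_stress <- function(D) sum((delta[upper.tri(delta)] - D[upper.tri(D)])^2)
  D <- dist_mat(X)
  s_old <- raw_stress(D)
  for (iter in seq_len(max_iter)) {
    ratio <- ifelse(D > 0, delta / D, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / n                       # Guttman transform
    D <- dist_mat(X)
    s_new <- raw_stress(D)
    if (s_old - s_new < tol * max(s_old, 1e-12)) break
    s_old <- s_new
  }
  list(X = X, stress = s_new, D = D)
}

#' Metric-stress MDS embedding of a second-order RDM
#'
#' Places the RDMs in two dimensions so that plotted distances approximate
#' the second-order distances, minimizing metric stress by SMACOF
#' majorization. Several restarts (classical-scaling start plus seeded
#' random starts) are run and the lowest-stress solution kept. The
#' reported `stress` is normalized (Kruskal stress-1,
#' `sqrt(sum((delta - d)^2) / sum(delta^2))`); `distortion` gives the
#' signed per-edge discrepancy `plotted - actual` (negative: the actual
#' distance is longer than displayed).
#'
#' @param so A [second_order_rdm()] with >= 3 members.
#' @param seed Integer seed for the random restarts.
#' @param n_restarts Number of restarts (default 8).
#' @param max_iter Majorization iterations per restart.
#' @return Object of class `"rdm_embedding"`: `coordinates` (labels x 2),
#'   `stress`, `distortion` (data frame `a`, `b`, `actual`, `plotted`).
#' @export
mds_embed <- function(so, seed, n_restarts = 8, max_iter = 300) {
  stopifnot(inherits(so, "second_order_rdm"))
  delta <- so$distances
  n <- nrow(delta)
  if (n < 3L) stop("need >= 3 RDMs for a 2-D embedding")
  if (missing(seed)) stop("`seed` is required")
  best <- NULL
  starts <- with_seed(seed, {
    init <- suppressWarnings(stats::cmdscale(delta, k = 2))
    if (ncol(init) < 2) init <- cbind(init, 0)[, 1:2, drop = FALSE]
    c(list(init),
      lapply(seq_len(max(n_restarts - 1L, 0L)), function(i)
        matrix(stats::rnorm(2L * n, sd = stats::sd(delta)), n, 2L)))
  })
  for (X0 in starts) {
    run <- smacof_run(delta, X0, max_iter = max_iter)
    if (is.null(best) || run$stress < best$stress) best <- run
  }
  denom <- sum(delta[upper.tri(delta)]^2)
  stress1 <- if (denom > 0) sqrt(best$stress / denom) else 0
  coords <- best$X
  rownames(coords) <- so$labels
  colnames(coords) <- c("x", "y")
  pi <- pair_indices(n)
  distortion <- data.frame(
    a = so$labels[pi[, "i"]], b = so$labels[pi[, "j"]],
    actual = delta[upper.tri(delta)],
    plotted = best$D[upper.tri(best$D)])
  distortion$distortion <- distortion$plotted - distortion$actual
  structure(list(coordinates = coords, stress = stress1,
                 distortion = distortion, n_restarts = n_restarts),
            class = "rdm_embedding")
}

#' @export
print.rdm_embedding <- function(x, ...) {
  cat(sprintf("2-D metric-stress MDS of %d RDMs; stress-1 = %.4g\n",
              nrow(x$coordinates), x$stress))
  invisible(x)
}

#' Write a figure-ready analysis report bundle
#'
#' Writes the numeric content of the standard result figures to a
#' directory: percentile-transformed heat-map data for data, prediction
#' and residual RDMs (entries in \[0, 100\]), a bar-graph table of model
#' evaluations with bootstrap standard errors and significance flags,
#' the pairwise-comparison table, noise-ceiling bounds, and MDS
#' coordinates with per-edge distortions. All tables are plain CSV/JSON,
#' reproducible without any plotting layer.
#'
#' @param path Output directory (created if needed).
#' @param evaluations List of [evaluate_model()] results.
#' @param comparisons Optional [bootstrap_compare()] result.
#' @param ceiling Optional [noise_ceiling()] result.
#' @param data_rdm Optional data [rdm()].
#' @param predictions Optional named list of prediction [rdm()]s; residual
#'   maps are written for each against `data_rdm`.
#' @param embedding Optional [mds_embed()] result.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(path, evaluations, comparisons = NULL,
                          ceiling = NULL, data_rdm = NULL,
                          predictions = NULL, embedding = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, file) {
    fp <- file.path(path, file)
    utils::write.csv(df, fp, row.names = FALSE, quote = FALSE)
    written <<- c(written, fp)
  }
  percentile <- function(r) {
    out <- suppressWarnings(rank_percentile_transform(r))
    out$dissim <- out$dissim * 100
    out
  }

  eval_df <- do.call(rbind, lapply(evaluations, function(e)
    data.frame(model = e$model_label, mean_tau = e$mean_tau,
               fitted = e$fitted, p_randomization = e$p_randomization)))
  if (!is.null(comparisons)) {
    eval_df$boot_se <- comparisons$boot_se[match(eval_df$model,
                                                 comparisons$model_labels)]
    emit(comparisons$pairs, "model_comparisons.csv")
  }
  if (!is.null(ceiling)) {
    eval_df$ceiling_lower <- ceiling$lower
    eval_df$ceiling_upper <- ceiling$upper
  }
  emit(eval_df, "model_evaluations.csv")

  if (!is.null(data_rdm)) {
    write_rdm(percentile(data_rdm), file.path(path, "data_rdm_percentile.csv"))
    written <- c(written, file.path(path, "data_rdm_percentile.csv"))
  }
  if (!is.null(predictions)) {
    if (is.null(names(predictions)))
      names(predictions) <- vapply(predictions, function(r) r$meta, character(1))
    for (nm in names(predictions)) {
      safe <- gsub("[^A-Za-z0-9_.-]+", "_", nm)
      fp <- file.path(path, sprintf("prediction_%s_percentile.csv", safe))
      write_rdm(percentile(predictions[[nm]]), fp)
      written <- c(written, fp)
      if (!is.null(data_rdm)) {
        res <- residual_rdm(data_rdm, predictions[[nm]]) * 100
        pi <- pair_indices(n_stimuli(data_rdm))
        emit(data.frame(stim_i = data_rdm$stimulus_ids[pi[, "i"]],
                        stim_j = data_rdm$stimulus_ids[pi[, "j"]],
                        residual_percentile = res),
             sprintf("residual_%s.csv", safe))
      }
    }
  }
  if (!is.null(embedding)) {
    emit(data.frame(label = rownames(embedding$coordinates),
                    embedding$coordinates), "mds_coordinates.csv")
    emit(embedding$distortion, "mds_distortion.csv")
  }
  summary <- list(
    models = eval_df$model,
    ceiling = if (!is.null(ceiling)) c(lower = ceiling$lower,
                                       upper = ceiling$upper),
    mds_stress = if (!is.null(embedding)) embedding$stress)
  jsonlite::write_json(summary, file.path(path, "report_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  written <- c(written, file.path(path, "report_summary.json"))
  invisible(written)
}
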