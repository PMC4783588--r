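test_that("a predictor identical to the data gets weight 1, zero residual", {
  set.seed(1)
  d <- random_rdm(5)
  m <- model_spec(rdm_stack(list(d), labels = "self"),
                  include_confound_mean = FALSE)
  f <- nnls_fit(m, d)
  expect_equal(unname(f$rdm_weights), 1, tolerance = 1e-10)
  expect_equal(f$training_rss, 0, tolerance = 1e-12)
  expect_equal(f$predicted$dissim, d$dissim, tolerance = 1e-10)
  expect_equal(unname(f$dimension_weights), 1, tolerance = 1e-6)
})

test_that("anti-correlated predictors get zero weight once the mean is absorbed", {
  set.seed(2)
  d <- random_rdm(6)
  anti <- rdm(2 - d$dissim, d$stimulus_ids, meta = "anti")
  m <- model_spec(rdm_stack(list(anti)), include_confound_mean = TRUE)
  f <- nnls_fit(m, d)
  expect_equal(unname(f$rdm_weights), 0, tolerance = 1e-8)
  # dense grid oracle over (predictor weight, confound weight)
  X <- cbind(anti$dissim, 1)
  grid <- expand.grid(w = seq(0, 2, by = 0.01), c0 = seq(0, 2, by = 0.01))
  objs <- apply(grid, 1, function(g) nnls_objective(X, d$dissim, g))
  expect_lte(f$training_rss, min(objs) + 1e-9)
})

test_that("NNLS equals unconstrained LS when that solution is nonnegative", {
  # two orthogonal data-spanning predictors
  p1 <- c(1, 1, 0, 0); p2 <- c(0, 0, 1, 1)
  r1 <- rdm(c(p1, 0, 0), paste0("s", 1:4))
  r2 <- rdm(c(p2, 0, 0), paste0("s", 1:4))
  d <- rdm(0.3 * r1$dissim + 1.4 * r2$dissim, paste0("s", 1:4))
  m <- model_spec(rdm_stack(list(r1, r2), labels = c("p1", "p2")),
                  include_confound_mean = FALSE)
  f <- nnls_fit(m, d)
  X <- cbind(r1$dissim, r2$dissim)
  ls <- solve(crossprod(X), crossprod(X, d$dissim))
  expect_equal(unname(f$rdm_weights), drop(ls), tolerance = 1e-9)
})

test_that("solver satisfies KKT and matches oracle objectives", {
  set.seed(33)
  for (i in 1:25) {
    n_pred <- sample(2:10, 1)
    m_pairs <- sample(5:45, 1)
    X <- matrix(runif(m_pairs * n_pred), m_pairs, n_pred)
    y <- runif(m_pairs)
    AtA <- crossprod(X); Atb <- drop(crossprod(X, y))
    sol <- nnls_normal(AtA, Atb)
    # KKT: gradient ~ 0 on the support, >= 0 off it
    g <- sol$gradient
    expect_true(all(abs(g[sol$x > 0]) < 1e-7))
    expect_true(all(g[sol$x == 0] > -1e-7))
    # objective matches projected gradient and Lawson-Hanson reference
    obj <- nnls_objective(X, y, sol$x)
    expect_lte(obj, nnls_objective(X, y, nnls_pg(AtA, Atb)) + 1e-6)
    ref <- pracma::lsqnonneg(X, y)
    expect_equal(obj, ref$resid.norm, tolerance = 1e-6)
  }
})

test_that("Eq-style weight scaling: dimension scaled by w scales its RDM by w^2", {
  set.seed(6)
  dims <- toy_dims()
  base <- single_dimension_rdms(dims)
  for (i in 1:5) {
    w <- runif(1, 0.1, 3)
    scaled_vals <- dims$values * w
    # values must stay in [0,1] for the container; compute directly instead
    pi <- pair_indices(4)
    for (k in 1:3) {
      f <- dims$values[k, ] * w
      scaled_rdm <- unname((f[pi[, "i"]] - f[pi[, "j"]])^2)
      expect_equal(scaled_rdm, w^2 * base$rdms[[k]]$dissim, tolerance = 1e-12)
    }
  }
})

test_that("combined-model training RSS never exceeds a sub-model's", {
  set.seed(44)
  for (i in 1:5) {
    dims <- generate_dimension_matrix(12, 6, 6, seed = 100 + i)
    cat_m <- model_spec(single_dimension_rdms(dims$categorical), label = "cat")
    feat_m <- model_spec(single_dimension_rdms(dims$feature), label = "feat")
    comb <- combine_models(cat_m, feat_m)
    d <- rdm(runif(num_pairs(12)), dims$categorical$stimulus_ids)
    mask <- sort(sample(num_pairs(12), 40))
    rss <- vapply(list(cat_m, feat_m, comb), function(m)
      nnls_fit(m, d, pair_mask = mask)$training_rss, numeric(1))
    expect_lte(rss[3], rss[1] + 1e-9)
    expect_lte(rss[3], rss[2] + 1e-9)
  }
})

test_that("cross-validation schemes cover all pairs deterministically", {
  ids <- paste0("s", 1:8)
  one <- build_crossval_scheme(ids, heldout_size = 8, seed = 5)
  expect_length(one$folds, 1L)
  expect_error(build_crossval_scheme(ids, heldout_size = 1, seed = 5),
               "heldout_size")
  s1 <- build_crossval_scheme(paste0("s", 1:20), 4, seed = 9)
  s2 <- build_crossval_scheme(paste0("s", 1:20), 4, seed = 9)
  expect_identical(s1$folds, s2$folds)
  # coverage: every pair co-occurs in some held-out set
  covered <- matrix(FALSE, 20, 20)
  for (f in s1$folds) {
    idx <- match(f, paste0("s", 1:20))
    covered[idx, idx] <- TRUE
  }
  expect_true(all(covered[upper.tri(covered)]))
})

test_that("cross-validated prediction reproduces model-true tie-free data", {
  set.seed(10)
  n <- 12
  preds <- lapply(1:4, function(k) random_rdm(n, meta = paste0("p", k)))
  preds <- lapply(preds, function(r) rdm(r$dissim, paste0("s", 1:n), r$meta))
  w_true <- c(0.5, 1.2, 0, 2)
  y <- Reduce(`+`, Map(function(r, w) w * r$dissim, preds, w_true)) + 0.3
  d <- rdm(y, paste0("s", 1:n))
  m <- model_spec(rdm_stack(preds), include_confound_mean = TRUE)
  scheme <- build_crossval_scheme(d$stimulus_ids, 4, seed = 77)
  cv <- crossval_predict(m, d, scheme)
  expect_equal(cv$predicted$dissim, y, tolerance = 1e-6)
  expect_true(cv$cross_validated)
})

test_that("a confound-only model predicts each fold's training mean", {
  set.seed(15)
  n <- 8
  d <- random_rdm(n)
  d <- rdm(d$dissim, paste0("s", 1:n))
  const <- rdm(rep(1, num_pairs(n)), d$stimulus_ids, meta = "const")
  m <- model_spec(rdm_stack(list(const)), include_confound_mean = FALSE)
  scheme <- build_crossval_scheme(d$stimulus_ids, 4, seed = 3)
  cv <- crossval_predict(m, d, scheme)
  # single-parameter LS oracle, averaged over the folds that predict a pair
  pi <- pair_indices(n)
  pred_sum <- numeric(num_pairs(n)); cnt <- integer(num_pairs(n))
  for (fold in scheme$folds) {
    held <- match(fold, d$stimulus_ids)
    train <- !(pi[, "i"] %in% held | pi[, "j"] %in% held)
    test <- (pi[, "i"] %in% held) & (pi[, "j"] %in% held)
    pred_sum[test] <- pred_sum[test] + mean(d$dissim[train])
    cnt[test] <- cnt[test] + 1L
  }
  expect_equal(cv$predicted$dissim, pred_sum / cnt, tolerance = 1e-9)
})

test_that("prediction is equivariant under joint stimulus relabeling", {
  set.seed(20)
  n <- 10
  dims <- generate_dimension_matrix(n, 5, 5, seed = 8)
  m <- model_spec(single_dimension_rdms(dims$categorical))
  d <- rdm(runif(num_pairs(n)), dims$categorical$stimulus_ids)
  scheme <- build_crossval_scheme(d$stimulus_ids, 4, seed = 2)
  cv1 <- crossval_predict(m, d, scheme)
  perm <- sample(n)
  d_p <- from_square(to_square(d)[perm, perm])
  dims_p <- dimension_matrix(dims$categorical$values[, perm],
                             dimension_labels = dims$categorical$dimension_labels,
                             stimulus_ids = d_p$stimulus_ids)
  m_p <- model_spec(single_dimension_rdms(dims_p))
  scheme_p <- scheme
  scheme_p$stimulus_ids <- d_p$stimulus_ids
  scheme_p$folds <- lapply(scheme$folds, function(f)
    d_p$stimulus_ids[match(f, d$stimulus_ids[perm])])
  cv2 <- crossval_predict(m_p, d_p, scheme_p)
  expect_equal(to_square(cv2$predicted),
               to_square(cv1$predicted)[perm, perm], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("equal-weights predictions sum the single-dimension RDMs", {
  set.seed(25)
  r <- random_rdm(5)
  m1 <- model_spec(rdm_stack(list(r)))
  expect_equal(equal_weights_prediction(m1)$dissim, r$dissim)
  a <- rdm(c(1, 0, 1, 0, 1, 0, 1, 0, 1, 1), paste0("s", 1:5))
  b <- rdm(1 - a$dissim, paste0("s", 1:5))
  m2 <- model_spec(rdm_stack(list(a, b), labels = c("a", "b")))
  expect_equal(equal_weights_prediction(m2)$dissim, rep(1, 10))
  m3 <- model_spec(rdm_stack(list(r, r, r), labels = c("1", "2", "3")))
  expect_equal(equal_weights_prediction(m3)$dissim, 3 * r$dissim)
})
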