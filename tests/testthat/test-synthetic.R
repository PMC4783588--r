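test_that("generated categories form a nesting tree", {
  dims <- generate_dimension_matrix(30, 20, 10, seed = 1)
  vals <- dims$categorical$values
  supp <- lapply(seq_len(nrow(vals)), function(k) which(vals[k, ] > 0))
  # for every pair of categories: disjoint or nested (a laminar family)
  for (a in seq_along(supp)) for (b in seq_along(supp)) {
    if (a >= b) next
    inter <- length(intersect(supp[[a]], supp[[b]]))
    expect_true(inter == 0 || inter == length(supp[[a]]) ||
                  inter == length(supp[[b]]))
  }
  expect_true(all(vals %in% c(0, 1)))
})

test_that("feature-category correlation spans its limits", {
  d0 <- generate_dimension_matrix(40, 10, 12, feature_category_corr = 0,
                                  prop_related = 1, seed = 2)
  cc <- abs(cor(t(d0$feature$values), t(d0$categorical$values)))
  expect_lt(mean(cc), 0.25)
  d1 <- generate_dimension_matrix(40, 10, 12, feature_category_corr = 1,
                                  prop_related = 1, seed = 3)
  rel <- attr(d1$feature, "related_to")
  for (f in seq_len(12))
    expect_equal(unname(d1$feature$values[f, ]),
                 unname(d1$categorical$values[rel[f], ]))
  # intermediate targets land in between on average
  dm <- generate_dimension_matrix(60, 10, 20, feature_category_corr = 0.85,
                                  prop_related = 1, seed = 4)
  relm <- attr(dm$feature, "related_to")
  rr <- vapply(seq_len(20), function(f)
    cor(dm$feature$values[f, ], dm$categorical$values[relm[f], ]), numeric(1))
  expect_gt(mean(rr), 0.6)
})

test_that("target RDMs follow the squared-weight forward model", {
  dims <- toy_dims()
  stack <- single_dimension_rdms(dims)
  w1 <- c(1, 0, 0)
  t1 <- generate_target_rdm(ground_truth(dims, w1))
  expect_equal(t1$dissim, stack$rdms[[1]]$dissim)
  # doubling a dimension weight quadruples its contribution
  t2 <- generate_target_rdm(ground_truth(dims, c(2, 0, 0)))
  expect_equal(t2$dissim, 4 * t1$dissim)
  t0 <- generate_target_rdm(ground_truth(dims, c(0, 0, 0)), offset = 0.5)
  expect_equal(t0$dissim, rep(0.5, 6))
})

test_that("noiseless patterns reproduce the rescaled target exactly", {
  set.seed(7)
  dims <- generate_dimension_matrix(16, 10, 8, seed = 11)
  comb <- dimension_matrix(rbind(dims$categorical$values, dims$feature$values),
                           stimulus_ids = dims$categorical$stimulus_ids)
  w <- numeric(nrow(comb$values)); w[sample(nrow(comb$values), 5)] <- runif(5, 0.5, 1.5)
  target <- generate_target_rdm(ground_truth(comb, w))
  pats <- generate_subject_patterns(target, 2, 20, noise_sd = 0, seed = 13)
  scaled <- attr(pats, "scaled_target")
  for (p in pats)
    expect_lt(max(abs(rdm_from_patterns(p)$dissim - scaled$dissim)), 1e-6)
  expect_lt(attr(pats, "projection_error"), 1e-8)
})

test_that("noise degrades subject RDM fidelity monotonically on average", {
  set.seed(8)
  target <- planar_rdm(12, seed = 3)
  taus <- vapply(c(0, 0.5, 2), function(ns) {
    mean(vapply(1:4, function(s) {
      pats <- generate_subject_patterns(target, 1, 16, noise_sd = ns,
                                        seed = 100 + s)
      kendall_tau_a(rdm_from_patterns(pats[[1]])$dissim, target$dissim)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(taus[1], taus[2])
  expect_gt(taus[2], taus[3])
})

test_that("noisy subjects share signal: ceiling lower bound drops below 1", {
  set.seed(9)
  target <- planar_rdm(10, seed = 5)
  pats <- generate_subject_patterns(target, 4, 14, noise_sd = 1, seed = 77)
  stack <- rdm_stack(lapply(pats, rdm_from_patterns),
                     labels = paste0("s", 1:4))
  nc <- noise_ceiling(stack)
  expect_lt(nc$lower, 1)
  expect_gt(nc$upper, 0)
})

test_that("vote simulation recovers dimensions when clean, not when random", {
  dims <- generate_dimension_matrix(24, 10, 6, seed = 21)$categorical
  votes0 <- generate_vote_tensor(dims, 15, 8, flip_rate = 0, seed = 31)
  kept <- filter_generated_descriptions(votes0$generation, 3)
  expect_setequal(kept, dims$dimension_labels)
  rec <- validate_descriptions(votes0$validation, 6)
  expect_equal(unname(rec$values[dims$dimension_labels, ]),
               unname(dims$values))
  recovery_rate <- function(flip) {
    v <- generate_vote_tensor(dims, 15, 8, flip_rate = flip, seed = 33)
    rec <- tryCatch(validate_descriptions(v$validation, 6),
                    error = function(e) NULL)
    if (is.null(rec)) return(0)
    common <- intersect(rec$dimension_labels, dims$dimension_labels)
    if (length(common) == 0) return(0)
    mean(rec$values[common, ] == dims$values[common, ])
  }
  r0 <- recovery_rate(0); r25 <- recovery_rate(0.25); r50 <- recovery_rate(0.5)
  expect_equal(r0, 1)
  expect_gte(r25, r50 - 0.05)
  expect_lt(r50, 0.95)
})

test_that("simulated arrangement trials cover all pairs and aggregate back", {
  target <- planar_rdm(12, seed = 9)
  j <- generate_arrangement_trials(target, n_trials = 6, subset_size = 6,
                                   placement_noise = 0, seed = 41)
  cov <- coverage_report(j)
  expect_true(all(cov$n_trials >= 1))
  agg <- aggregate_trials(j)
  expect_gt(kendall_tau_a(agg$dissim, target$dissim), 0.99)
})

test_that("scenario generation is deterministic and validates inputs", {
  cfg <- scenario_config("it_like", n_stimuli = 16, seed = 5, noise_sd = 0.5)
  a <- suppressMessages(suppressWarnings(run_scenario(cfg)))
  b <- suppressMessages(suppressWarnings(run_scenario(cfg)))
  expect_identical(a$data_rdm$dissim, b$data_rdm$dissim)
  expect_identical(a$truth$dimension_weights, b$truth$dimension_weights)
  expect_error(scenario_config("galaxy", seed = 1), "arg")
  expect_error(scenario_config("it_like", seed = 1, bogus = 2), "unknown")
  r <- a$target
  expect_length(r$dissim, num_pairs(16))
  expect_true(all(r$dissim >= 0))
})

test_that("null scenarios carry no shared structure", {
  cfg <- scenario_config("null", n_stimuli = 14, seed = 8)
  sc <- suppressWarnings(run_scenario(cfg))
  expect_true(all(sc$truth$rdm_weights == 0))
  taus <- vapply(sc$subject_rdms$rdms[-1], function(r)
    kendall_tau_a(sc$subject_rdms$rdms[[1]]$dissim, r$dissim), numeric(1))
  expect_lt(max(abs(taus)), 0.5)
})
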