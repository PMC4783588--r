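test_that("tau-a matches hand-enumerated examples and handles ties", {
  expect_equal(kendall_tau_a(1:5, 1:5), 1)
  expect_equal(kendall_tau_a(1:5, 5:1), -1)
  expect_equal(kendall_tau_a(c(1, 2, 3, 4), c(1, 3, 2, 4)), 4 / 6)
  # ties contribute zero to the numerator, full pair count in denominator
  expect_equal(kendall_tau_a(c(1, 1, 2), c(1, 2, 3)), tau_a_enum(c(1, 1, 2), c(1, 2, 3)))
  expect_warning(t0 <- kendall_tau_a(c(2, 2, 2), 1:3), "constant")
  expect_equal(t0, 0)
  expect_error(kendall_tau_a(1:3, 1:4), "equal length")
})

test_that("fast tau-a equals the enumeration oracle on random vectors", {
  set.seed(50)
  for (i in 1:100) {
    m <- sample(3:60, 1)
    x <- if (i %% 2) rnorm(m) else sample(1:8, m, replace = TRUE)
    y <- if (i %% 3) rnorm(m) else sample(1:5, m, replace = TRUE)
    expect_equal(rdmfit:::.tau_a_cpp(x, y), tau_a_enum(x, y), tolerance = 1e-12)
  }
})

test_that("model evaluation averages per-subject tau-a", {
  set.seed(60)
  pred <- random_rdm(8)
  flipped <- rdm(max(pred$dissim) - pred$dissim, pred$stimulus_ids)
  subj <- rdm_stack(list(pred, flipped), labels = c("s1", "s2"))
  ev <- evaluate_model(pred, subj)
  expect_equal(unname(ev$per_subject_tau), c(1, -1))
  expect_equal(ev$mean_tau, mean(ev$per_subject_tau))
  ev_r <- evaluate_model(flipped, rdm_stack(list(pred)))
  expect_equal(ev_r$mean_tau, -1)
})

test_that("randomization test is exact for small n and calibrated for large", {
  set.seed(70)
  d <- random_rdm(5)
  # exhaustive on n = 5: p computed over all 120 permutations
  out <- randomization_test(d, d, n_perm = 999)
  expect_true(out$exhaustive)
  manual <- {
    sq <- to_square(d)
    perms <- rdmfit:::all_perms(5)
    taus <- vapply(perms, function(p) {
      m <- sq[p, p]; rdmfit:::.tau_a_cpp(d$dissim, m[upper.tri(m)])
    }, numeric(1))
    mean(taus >= 1 - 1e-12)
  }
  expect_equal(out$p, manual)
  # Monte-Carlo branch with a self-match on a bigger RDM: p at its minimum
  d2 <- random_rdm(12)
  out2 <- randomization_test(d2, d2, n_perm = 199, seed = 4, exhaustive = FALSE)
  expect_equal(out2$p, 1 / 200)
  expect_warning(
    out3 <- randomization_test(d2, rdm(rep(1, 66), d2$stimulus_ids), n_perm = 99,
                               seed = 1),
    "constant")
  expect_equal(out3$p, 1)
})

test_that("bootstrap comparison separates degenerate model pairs", {
  set.seed(80)
  d <- random_rdm(16)
  subj <- rdm_stack(list(d), labels = "s1")
  good <- d
  bad <- rdm(max(d$dissim) - d$dissim + min(d$dissim), d$stimulus_ids)
  cmp <- bootstrap_compare(list(good = good, bad = bad, good2 = good),
                           subj, n_boot = 199, seed = 5)
  pr <- cmp$pairs
  gb <- pr[pr$model_a == "good" & pr$model_b == "bad", ]
  expect_gt(gb$tau_diff, 0)
  expect_equal(gb$p, 2 / 200, tolerance = 1e-12)
  gg <- pr[pr$model_a == "good" & pr$model_b == "good2", ]
  expect_equal(gg$tau_diff, 0)
  expect_equal(gg$p, 1)
  # symmetry: reversing the model order negates differences, keeps p
  cmp2 <- bootstrap_compare(list(bad = bad, good = good), subj,
                            n_boot = 99, seed = 5)
  cmp3 <- bootstrap_compare(list(good = good, bad = bad), subj,
                            n_boot = 99, seed = 5)
  expect_equal(cmp2$pairs$tau_diff, -cmp3$pairs$tau_diff)
  expect_equal(cmp2$pairs$p, cmp3$pairs$p)
})

test_that("BH step-up rejects the documented set", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06)
  expect_identical(fdr_bh(p, 0.05), c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_false(any(fdr_bh(rep(1, 5), 0.05)))
  expect_true(all(fdr_bh(rep(0, 5), 0.05)))
  # rejections are monotone in q
  set.seed(90)
  pv <- runif(20)
  r1 <- fdr_bh(pv, 0.02); r2 <- fdr_bh(pv, 0.1)
  expect_true(all(r2[r1]))
})

test_that("noise ceiling brackets performance, lower <= upper", {
  set.seed(95)
  base <- random_rdm(10)
  same <- rdm_stack(list(base, base, base), labels = paste0("s", 1:3))
  nc <- noise_ceiling(same)
  expect_equal(nc$lower, 1)
  expect_equal(nc$upper, 1)
  for (i in 1:5) {
    noisy <- rdm_stack(lapply(1:4, function(s)
      rdm(base$dissim + rnorm(45, sd = 0.3), base$stimulus_ids)),
      labels = paste0("s", 1:4))
    nc2 <- noise_ceiling(noisy)
    expect_lte(nc2$lower, nc2$upper)
    expect_lt(nc2$lower, 1)
  }
  expect_error(noise_ceiling(rdm_stack(list(base))), "2 subjects")
})

test_that("noise ceiling brackets the true generating RDM's performance", {
  set.seed(97)
  base <- random_rdm(14)
  hit <- 0
  for (i in 1:10) {
    subj <- rdm_stack(lapply(1:6, function(s)
      rdm(base$dissim + rnorm(length(base$dissim), sd = 0.4),
          base$stimulus_ids)), labels = paste0("s", 1:6))
    nc <- noise_ceiling(subj)
    true_tau <- evaluate_model(base, subj)$mean_tau
    hit <- hit + (true_tau >= nc$lower - 0.05 && true_tau <= nc$upper + 0.05)
  }
  expect_gte(hit, 8)
})

test_that("single-dimension screening recovers planted dimensions", {
  set.seed(99)
  dims <- generate_dimension_matrix(24, 8, 4, seed = 41)$categorical
  stack <- single_dimension_rdms(dims)
  # plant signal on the two best-supported divisions
  planted <- order(-rowSums(dims$values))[1:2]
  w <- numeric(8); w[planted] <- 1.5
  truth <- ground_truth(dims, w)
  data <- generate_target_rdm(truth)
  data$dissim <- data$dissim + rnorm(length(data$dissim), sd = 0.1)
  scr <- single_dimension_screen(stack, data, n_boot = 500, seed = 7)
  expect_true(all(scr$significant[planted]))
  expect_gt(min(scr$tau[planted]), 0.2)
  # a constant dimension screens as tau 0, not significant
  cdim <- dimension_matrix(rbind(const = rep(1, 24)),
                           stimulus_ids = dims$stimulus_ids)
  scr2 <- single_dimension_screen(single_dimension_rdms(cdim), data,
                                  n_boot = 100, seed = 8)
  expect_equal(scr2$tau, 0)
  expect_false(scr2$significant)
})
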