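make_votes <- function(marks, phase, n_subj) {
  # marks: list(description = list(stimulus = subjects-who-marked))
  descs <- names(marks)
  stims <- sort(unique(unlist(lapply(marks, names))))
  v <- array(0L, c(length(descs), length(stims), n_subj),
             dimnames = list(descs, stims, paste0("subj", seq_len(n_subj))))
  for (d in descs) for (s in names(marks[[d]]))
    v[d, s, marks[[d]][[s]]] <- 1L
  description_votes(v, phase = phase)
}

test_that("generation filtering counts distinct subjects per description", {
  gv <- make_votes(list(
    popular = list(img1 = 1:2, img2 = 3),     # 3 distinct subjects
    niche = list(img1 = c(4, 5)),             # 2 subjects
    solo = list(img2 = 7)), "generation", 15)
  expect_identical(filter_generated_descriptions(gv, 3), "popular")
  expect_setequal(filter_generated_descriptions(gv, 1),
                  c("popular", "niche", "solo"))
  # per-image counting: "popular" only has 2 on img1, 1 on img2
  expect_identical(filter_generated_descriptions(gv, 3, per_image = TRUE),
                   character(0))
  expect_error(filter_generated_descriptions(
    make_votes(list(a = list(i = 1)), "validation", 8), 3), "generation")
})

test_that("validation thresholds votes at six of eight and prunes", {
  vv <- make_votes(list(
    strong = list(img1 = 1:6, img2 = 1:5),    # img1 passes, img2 fails
    weak = list(img1 = 1:5),                  # never passes -> removed
    both = list(img1 = 1:8, img2 = 2:7)), "validation", 8)
  dm <- validate_descriptions(vv, 6)
  expect_setequal(dm$dimension_labels, c("strong", "both"))
  expect_equal(unname(dm$values["strong", c("img1", "img2")]), c(1, 0))
  expect_equal(unname(dm$values["both", c("img1", "img2")]), c(1, 1))
  expect_error(validate_descriptions(vv, 9), "exceeds")
  dm2 <- validate_descriptions(vv, 6, exclude = "strong")
  expect_identical(dm2$dimension_labels, "both")
})

test_that("correlated dimensions merge iteratively into means", {
  v <- c(1, 0, 1, 0, 1, 0)
  dm <- dimension_matrix(rbind(a = v, b = v, c = c(0, 1, 1, 0, 0, 1)),
                         stimulus_ids = paste0("s", 1:6))
  out <- merge_correlated_dimensions(dm, 0.9)
  expect_identical(sort(out$dimension_labels), sort(c("a/b", "c")))
  expect_equal(unname(out$values["a/b", ]), v)
  # three mutually identical vectors: two merges, traced oracle = v
  dm3 <- dimension_matrix(rbind(a = v, b = v, c = v),
                          stimulus_ids = paste0("s", 1:6))
  out3 <- merge_correlated_dimensions(dm3, 0.9)
  expect_equal(nrow(out3$values), 1L)
  expect_equal(unname(out3$values[1, ]), v)
  expect_setequal(out3$merge_groups[[1]], c("a", "b", "c"))
  # r = 0.5 pair stays untouched
  half <- dimension_matrix(rbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0)),
                           stimulus_ids = paste0("s", 1:4))
  expect_identical(merge_correlated_dimensions(half, 0.9)$values, half$values)
})

test_that("merging terminates below threshold on random matrices", {
  set.seed(5)
  for (i in 1:8) {
    vals <- matrix(rbinom(12 * 20, 1, 0.4), 12, 20)
    vals[apply(vals, 1, sd) == 0, 1] <- 1   # avoid constant rows
    dm <- dimension_matrix(vals, stimulus_ids = paste0("s", 1:20))
    out <- merge_correlated_dimensions(dm, 0.7)
    expect_lte(nrow(out$values), nrow(dm$values))
    cc <- suppressWarnings(cor(t(out$values)))
    diag(cc) <- NA
    expect_lte(max(cc, na.rm = TRUE), 0.7 + 1e-12)
  }
})

test_that("single-dimension RDMs are squared value differences", {
  dm <- dimension_matrix(rbind(d = c(1, 0, 1)), stimulus_ids = paste0("s", 1:3))
  st <- single_dimension_rdms(dm)
  expect_equal(st$rdms[[1]]$dissim, c(1, 0, 1))   # pairs (1,2),(1,3),(2,3)
  const <- dimension_matrix(rbind(d = c(1, 1, 1)), stimulus_ids = paste0("s", 1:3))
  expect_equal(single_dimension_rdms(const)$rdms[[1]]$dissim, c(0, 0, 0))
  merged <- dimension_matrix(rbind(d = c(0.5, 1, 0.5)),
                             stimulus_ids = paste0("s", 1:3))
  expect_equal(single_dimension_rdms(merged)$rdms[[1]]$dissim,
               c(0.25, 0, 0.25))
  # binary matrices only ever yield 0/1 entries, 1 exactly across the divide
  dims <- toy_dims()
  sdr <- single_dimension_rdms(dims)
  pi <- pair_indices(4)
  for (k in 1:3) {
    f <- dims$values[k, ]
    expect_equal(sdr$rdms[[k]]$dissim,
                 as.numeric(f[pi[, "i"]] != f[pi[, "j"]]))
  }
})

test_that("stimulus permutation permutes single-dimension RDMs consistently", {
  set.seed(9)
  dims <- toy_dims()
  perm <- sample(4)
  permuted <- dimension_matrix(dims$values[, perm],
                               dimension_labels = dims$dimension_labels,
                               stimulus_ids = dims$stimulus_ids[perm])
  sq1 <- to_square(single_dimension_rdms(dims)$rdms[[2]])
  sq2 <- to_square(single_dimension_rdms(permuted)$rdms[[2]])
  expect_equal(unname(sq2), unname(sq1[perm, perm]))
})

test_that("labels-per-image statistics use the population SD", {
  id <- dimension_matrix(diag(3), stimulus_ids = paste0("s", 1:3))
  expect_equal(labels_per_image_stats(id), c(mean = 1, sd = 0))
  ones <- dimension_matrix(matrix(1, 5, 4), stimulus_ids = paste0("s", 1:4))
  expect_equal(labels_per_image_stats(ones), c(mean = 5, sd = 0))
  m <- dimension_matrix(rbind(c(1, 1, 1), c(0, 1, 1), c(0, 0, 1)),
                        stimulus_ids = paste0("s", 1:3))
  expect_equal(labels_per_image_stats(m),
               c(mean = 2, sd = sqrt(mean((c(1, 2, 3) - 2)^2))))
})

test_that("dimension matrices and vote tensors round-trip through files", {
  dims <- merge_correlated_dimensions(
    dimension_matrix(rbind(a = c(1, 0, 1, 0), b = c(1, 0, 1, 0),
                           c = c(0, 1, 0, 1)),
                     stimulus_ids = paste0("s", 1:4)), 0.9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dimension_matrix(dims, f)
  back <- read_dimension_matrix(f)
  expect_equal(unname(back$values), unname(dims$values))
  expect_identical(back$dimension_labels, dims$dimension_labels)
  expect_identical(back$merge_groups[[which(back$dimension_labels == "a/b")]],
                   c("a", "b"))

  gv <- make_votes(list(a = list(s1 = 1:3, s2 = 2), b = list(s2 = 1:2)),
                   "generation", 5)
  fv <- withr::local_tempfile(fileext = ".csv")
  write_votes(gv, fv)
  back_v <- read_votes(fv, phase = "generation",
                       descriptions = gv$descriptions,
                       stimulus_ids = gv$stimulus_ids,
                       subjects = gv$subjects)
  expect_identical(back_v$votes, gv$votes)
})
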