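mk_causal <- function(g, t_start = 0, label = 0L)
  structure(list(g = g, order = 2L, t_start = t_start, trial_id = 1L,
                 label = label), class = "causal_matrix")

test_that("hybrid networks concatenate blocks and slice back exactly", {
  gs <- mk_causal(matrix(0, 62, 62))
  cs <- coupling_matrix(matrix(0, 62, 18), t_start = 0, trial_id = 1L)
  h <- hybrid(gs, cs)
  expect_equal(dim(h$h), c(62L, 80L))
  expect_true(all(h$h == 0))
  g2 <- matrix(rnorm(16), 4, 4); c2 <- matrix(rnorm(8), 4, 2)
  h2 <- hybrid(mk_causal(abs(g2)), coupling_matrix(c2, t_start = 0, trial_id = 1L))
  expect_equal(h2$h[, 1:4], abs(g2))
  expect_equal(h2$h[, 5:6], abs(c2))
  cs_other <- coupling_matrix(c2, t_start = 1.5, trial_id = 1L)
  expect_error(hybrid(mk_causal(abs(g2)), cs_other), class = "hbnet_alignment_error")
})

test_that("vectorization is row-major, length c*(c+d), and reversible", {
  m <- matrix(c(1, 4, 2, 5, 3, 6), 2, 3)   # [[1,2,3],[4,5,6]]
  expect_equal(vectorize_network(m), c(1, 2, 3, 4, 5, 6))
  h <- hybrid(mk_causal(matrix(rnorm(62^2), 62)),
              coupling_matrix(matrix(rnorm(62 * 18), 62), t_start = 0, trial_id = 1L))
  v <- vectorize_network(h)
  expect_length(v, 4960)
  expect_equal(matrix(v, 62, 80, byrow = TRUE), h$h)
  bad <- matrix(NaN, 2, 2)
  expect_error(vectorize_network(bad), class = "hbnet_data_error")
})

test_that("feature sets have the advertised dimensionality per kind", {
  causal <- lapply(1:10, function(i) mk_causal(matrix(runif(9), 3), label = i %% 2))
  coupling <- lapply(1:10, function(i)
    coupling_matrix(matrix(runif(6), 3, 2), t_start = (i - 1) * 1.5,
                    trial_id = 1L, label = i %% 2))
  for (i in 1:10) causal[[i]]$t_start <- (i - 1) * 1.5
  expect_equal(ncol(feature_set(causal = causal, kind = "SG")$x), 9)
  expect_equal(ncol(feature_set(coupling = coupling, kind = "SC")$x), 6)
  expect_equal(ncol(feature_set(causal, coupling, kind = "SG_SC")$x), 15)
  expect_error(feature_set(coupling = coupling, kind = "SG"),
               class = "hbnet_capability_error")
  expect_error(feature_set(causal = causal, kind = "SC"),
               class = "hbnet_capability_error")
})

sep_features <- function(n_per = 50, k = 2, gap = 6, dim = 5, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(k) - 1L, function(cl)
    matrix(rnorm(n_per * dim, mean = gap * cl), n_per, dim)))
  structure(list(x = x, labels = rep(seq_len(k) - 1L, each = n_per),
                 feature_kind = "SG", subject = NA_character_),
            class = "feature_set")
}

test_that("well-separated clouds are classified nearly perfectly by both classifiers", {
  fs <- sep_features()
  for (clf in c("svm_linear", "knn10")) {
    ev <- evaluate_features(fs, clf, seed = 2)
    expect_gte(ev$accuracy_mean, 0.99)
    expect_equal(unname(rowSums(ev$confusion)), c(1, 1), tolerance = 1e-10)
  }
})

test_that("label permutation drops a 4-class problem to chance", {
  set.seed(7)
  fs <- sep_features(n_per = 50, k = 4, gap = 6)
  fs$labels <- sample(fs$labels)
  ev <- evaluate_features(fs, "svm_linear", seed = 3)
  expect_gte(ev$accuracy_mean, 0.15)
  expect_lte(ev$accuracy_mean, 0.35)
})

test_that("accuracy is invariant to a feature-column permutation", {
  fs <- sep_features(n_per = 30, k = 3, gap = 2, dim = 8, seed = 5)
  perm <- sample(8)
  fs_p <- fs; fs_p$x <- fs$x[, perm]
  a1 <- evaluate_features(fs, "svm_linear", seed = 4)$accuracy_mean
  a2 <- evaluate_features(fs_p, "svm_linear", seed = 4)$accuracy_mean
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("protocol errors are explicit", {
  fs <- sep_features(n_per = 3, k = 2)
  expect_error(evaluate_features(fs, "svm_linear", k_folds = 5),
               class = "hbnet_protocol_error")
  one <- sep_features(n_per = 20, k = 2)
  one$labels <- rep(0L, 40)
  expect_error(evaluate_features(one, "svm_linear"), class = "hbnet_protocol_error")
})

test_that("tidy, glance, as_tibble and autoplot expose the evaluation", {
  fs <- sep_features()
  ev <- evaluate_features(fs, "knn10", seed = 6)
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)       # 2x2 confusion cells
  gl <- glance(ev)
  expect_equal(gl$classifier, "knn10")
  expect_equal(gl$n_samples, 100)
  tb <- as_tibble(fs)
  expect_equal(dim(tb), c(100L, 6L))
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(autoplot(mk_causal(matrix(runif(9), 3))), "ggplot")
  expect_s3_class(autoplot(coupling_matrix(matrix(runif(6), 3, 2))), "ggplot")
})
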