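# quick synthetic classification table: two informative columns + noise
make_table <- function(n = 40, p = 8, sep = 3, seed = 51) {
  set.seed(seed)
  y <- rep(c("neg", "pos"), length.out = n)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("v%02d", 1:p)))
  x[, 1] <- x[, 1] + sep * (y == "pos")
  x[, 2] <- x[, 2] - sep * (y == "pos")
  list(x = x, y = y)
}

test_that("outer folds partition 94 subjects into sizes 9 or 10", {
  d <- make_table(n = 94, sep = 5, seed = 52)
  r <- nested_cv(d$x, d$y, "knn", cv_config(10, 9, seed = 1, knn_grid = c(1, 3)),
                 positive_class = "pos")
  sizes <- vapply(r$folds, function(f) length(f$test_idx), 0L)
  expect_setequal(unique(sizes), c(9L, 10L))
  expect_equal(sum(sizes), 94L)
  all_idx <- sort(unlist(lapply(r$folds, `[[`, "test_idx")))
  expect_equal(all_idx, 1:94)                      # disjoint and exhaustive
  # stratification: per-fold positive count within 1 of proportional share
  for (f in r$folds) {
    pos <- sum(d$y[f$test_idx] == "pos")
    expect_lte(abs(pos - length(f$test_idx) * mean(d$y == "pos")), 1)
  }
})

test_that("an oracle feature drives outer accuracy to 1", {
  set.seed(53)
  y <- rep(c("neg", "pos"), each = 15)
  x <- cbind(oracle = as.numeric(y == "pos"),
             matrix(rnorm(30 * 5), 30, 5))
  colnames(x) <- sprintf("v%d", 1:6)
  for (clf in c("knn", "svm")) {
    r <- nested_cv(x, y, clf,
                   cv_config(5, 3, seed = 2, knn_grid = c(1, 3, 5),
                             selection_k = 1L),
                   positive_class = "pos")
    expect_equal(r$accuracy, 1, info = clf)
  }
})

test_that("study fold designs are accepted and sized correctly", {
  expect_s3_class(cv_config(10L, 9L), "cv_config")
  expect_s3_class(cv_config(5L, 4L), "cv_config")
  expect_error(cv_config(1L, 9L), ">= 2")
  d <- make_table(n = 34, sep = 5, seed = 54)
  r <- nested_cv(d$x, d$y, "knn", cv_config(5, 4, seed = 3, knn_grid = c(1, 3)),
                 positive_class = "pos")
  expect_length(r$folds, 5)
  expect_equal(r$n, 34L)
})

test_that("in-fold selection and tuning never see outer-test rows", {
  d <- make_table(n = 40, p = 12, sep = 1.5, seed = 55)
  cfg <- cv_config(4, 3, seed = 7, knn_grid = c(1, 3, 5), selection_k = 4L)
  base <- nested_cv(d$x, d$y, "knn", cfg, positive_class = "pos")
  for (f in seq_along(base$folds)) {
    mut <- d$x
    idx <- base$folds[[f]]$test_idx
    set.seed(100 + f)
    mut[idx, ] <- matrix(rnorm(length(idx) * ncol(mut), sd = 50),
                         length(idx))
    pert <- nested_cv(mut, d$y, "knn", cfg, positive_class = "pos")
    expect_identical(pert$folds[[f]]$selected_features,
                     base$folds[[f]]$selected_features)
    expect_identical(pert$folds[[f]]$hyperparameters,
                     base$folds[[f]]$hyperparameters)
  }
})

test_that("balanced resampling returns 34-subject sets from the 17/33 design", {
  minority <- sprintf("asd%02d", 1:17)
  majority <- sprintf("no%02d", 1:33)
  sets <- balanced_resample(minority, majority, repeats = 5, seed = 4)
  expect_length(sets, 5)
  for (s in sets) {
    expect_length(s, 34)
    expect_true(all(minority %in% s))
    drawn <- setdiff(s, minority)
    expect_length(drawn, 17)
    expect_false(anyDuplicated(drawn) > 0)
    expect_true(all(drawn %in% majority))
  }
  expect_identical(sets, balanced_resample(minority, majority, 5, seed = 4))
  expect_false(identical(sets, balanced_resample(minority, majority, 5,
                                                 seed = 5)))
  eq <- balanced_resample(minority, minority, 1, seed = 1)[[1]]
  expect_setequal(eq, minority)
  expect_error(balanced_resample(majority, minority), "larger")
})

test_that("metrics follow their defining ratios and identities", {
  m <- compute_metrics(list(tp = 1, tn = 1, fp = 0, fn = 0))
  expect_equal(unlist(m), c(accuracy = 1, sensitivity = 1, specificity = 1))
  m2 <- compute_metrics(list(tp = 3, tn = 2, fp = 1, fn = 2))
  expect_equal(m2$accuracy, 0.625)
  expect_equal(m2$sensitivity, 0.6)
  expect_equal(m2$specificity, 2 / 3, tolerance = 1e-12)
  allpos <- compute_metrics(list(tp = 5, tn = 0, fp = 3, fn = 0))
  expect_equal(allpos$specificity, 0)
  undef <- compute_metrics(list(tp = 0, tn = 4, fp = 0, fn = 0))
  expect_true(is.na(undef$sensitivity))
  # identities on a real report
  d <- make_table(n = 30, sep = 1, seed = 56)
  r <- nested_cv(d$x, d$y, "knn", cv_config(3, 2, seed = 5, knn_grid = c(3)),
                 positive_class = "pos")
  cc <- r$confusion
  expect_equal(r$accuracy * r$n, cc$tp + cc$tn)
  expect_equal(r$sensitivity * (cc$tp + cc$fn), cc$tp)
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, r$n)
})

test_that("permuted labels give chance-level accuracy", {
  d <- make_table(n = 60, sep = 3, seed = 57)
  set.seed(58)
  yperm <- sample(d$y)
  r <- nested_cv(d$x, yperm, "knn",
                 cv_config(5, 3, seed = 6, knn_grid = c(1, 5, 11)),
                 positive_class = "pos")
  band <- qbinom(c(0.005, 0.995), 60, 0.5) / 60
  expect_gte(r$accuracy, band[1])
  expect_lte(r$accuracy, band[2])
})
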