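test_that("energy is the sum of squares with quadratic homogeneity", {
  expect_equal(imf_energy(rep(0, 10)), 0)
  expect_equal(imf_energy(c(1, 2, 3)), 14)
  set.seed(21)
  x <- rnorm(200)
  expect_equal(imf_energy(3 * x), 9 * imf_energy(x))
  expect_equal(imf_energy(x), sum(x * x), tolerance = 1e-12)
  expect_error(imf_energy(numeric(0)), "empty")
})

test_that("Shannon entropy follows the unnormalised x^2 log x^2 form", {
  expect_equal(shannon_entropy(rep(0, 5)), 0)
  expect_equal(shannon_entropy(c(1, 1)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2), tolerance = 1e-12)
  set.seed(22)
  x <- rnorm(100)
  brute <- -sum(ifelse(x^2 > 0, x^2 * log(x^2), 0))
  expect_equal(shannon_entropy(x), brute, tolerance = 1e-12)
})

test_that("statistical features match closed forms and conventions", {
  s <- statistical_features(c(-1, 0, 1))
  expect_equal(s[["mean"]], 0)
  expect_equal(s[["skewness"]], 0)
  s2 <- statistical_features(c(1, 2, 3, 4))
  expect_equal(s2[["mean"]], 2.5)
  expect_equal(s2[["moment"]], 2.5625)   # ((1.5^4 + 0.5^4) * 2) / 4
  expect_equal(s2[["std"]], sd(1:4))
  s3 <- statistical_features(rep(7, 10))
  expect_equal(unname(s3[c("std", "skewness", "moment")]), c(0, 0, 0))
  set.seed(23)
  x <- rexp(150)
  s4 <- statistical_features(x)
  d <- x - mean(x)
  expect_equal(s4[["skewness"]], mean(d^3) / mean(d^2)^1.5, tolerance = 1e-12)
  expect_equal(s4[["moment"]], mean(d^4), tolerance = 1e-12)
  expect_error(statistical_features(1), "2 samples")
})

# fabricate a decomposition set: per condition, per channel, IMFs drawn
# deterministically from a seed so assembly can be checked cell by cell
fake_decomps <- function(n_channels, seed = 1, n = 40L) {
  set.seed(seed)
  out <- list()
  for (cond in erp_conditions()) {
    out[[cond]] <- lapply(seq_len(n_channels), function(ch) {
      imfs <- lapply(1:3, function(j) rnorm(n))
      structure(list(imfs = imfs, residual = rnorm(n), source_length = n,
                     sift_counts = c(1L, 1L, 1L)),
                class = "imf_decomposition")
    })
  }
  out
}

test_that("feature assembly yields 108 labelled columns in canonical order", {
  dec <- fake_decomps(3)
  fm <- assemble_features(dec, subject_id = "X")
  expect_equal(dim(fm$values), c(3L, 108L))
  expect_false(anyDuplicated(fm$column_labels) > 0)
  # condition-major, then IMF, then feature
  expect_equal(fm$column_labels[1], "direct_gaze|imf1|energy")
  expect_equal(fm$column_labels[7], "direct_gaze|imf2|energy")
  expect_equal(fm$column_labels[19], "averted_gaze|imf1|energy")
  info <- parse_feature_labels(fm$column_labels)
  expect_equal(unique(info$condition), erp_conditions())
  # spot-check cells against the single-feature operations
  expect_equal(unname(fm$values[2, "face|imf3|energy"]),
               imf_energy(dec[["face"]][[2]]$imfs[[3]]))
  expect_equal(unname(fm$values[1, "noise|imf2|skewness"]),
               statistical_features(dec[["noise"]][[1]]$imfs[[2]])[["skewness"]])
  # determinism
  fm2 <- assemble_features(fake_decomps(3), subject_id = "Y")
  expect_equal(unname(fm$values), unname(fm2$values))
})

test_that("assembly reports missing cells", {
  dec <- fake_decomps(2)
  expect_error(assemble_features(dec[-1]), "direct_gaze")
  dec$face[[2]] <- NULL
  expect_error(assemble_features(dec), "face")
})

test_that("short decompositions pad missing IMFs with zero features", {
  dec <- fake_decomps(1)
  dec$noise[[1]]$imfs <- dec$noise[[1]]$imfs[1]   # only IMF1 extracted
  fm <- assemble_features(dec)
  expect_equal(unname(fm$values[1, "noise|imf3|energy"]), 0)
  expect_equal(unname(fm$values[1, "noise|imf2|std"]), 0)
})

test_that("max-across-channels reduction is a signed, permutation-invariant max", {
  dec <- fake_decomps(4)
  fm <- assemble_features(dec)
  fv <- reduce_max_across_channels(fm)
  expect_equal(unname(fv$values), unname(apply(fm$values, 2, max)))
  expect_true(all(fm$values[cbind(fv$argmax_channel,
                                  seq_len(108))] == fv$values))
  # permuting channels leaves values unchanged
  perm <- fm
  perm$values <- fm$values[c(3, 1, 4, 2), ]
  expect_equal(reduce_max_across_channels(perm)$values, fv$values)
  # signed max: all-negative column keeps the least-negative value
  m <- structure(list(subject_id = "s",
                      values = matrix(c(-3, -1), 2, 1,
                                      dimnames = list(NULL, "c|imf1|mean")),
                      column_labels = "c|imf1|mean"),
                 class = "feature_matrix")
  expect_equal(unname(reduce_max_across_channels(m)$values), -1)
  single <- structure(list(subject_id = "s",
                           values = fm$values[1, , drop = FALSE],
                           column_labels = fm$column_labels),
                      class = "feature_matrix")
  expect_equal(unname(reduce_max_across_channels(single)$values),
               unname(fm$values[1, ]))
})
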