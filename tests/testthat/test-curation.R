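rec <- function(id, ..., smiles = "CCO", class = NA_character_)
  bcf_record(id, smiles, c(...), class_label = class)

test_that("replicate averaging collapses per-chemical measurements", {
  out <- average_replicates(list(rec("a", 1.0, 2.0), rec("b", 3.3)))
  expect_equal(out[[1L]]$logbcf_mean, 1.5)
  expect_equal(out[[2L]]$logbcf_mean, 3.3)
  out <- average_replicates(list(rec("a", -1.0), rec("a", 0.0), rec("a", 4.0)))
  expect_length(out, 1L)
  expect_equal(out[[1L]]$logbcf_mean, 1.0)
  expect_error(average_replicates(list(rec("empty"))), "empty")
})

test_that("class discretization is strict at the regulatory threshold", {
  lab <- function(v) discretize(list(rec("x", v)))[[1L]]$class_label
  expect_equal(lab(3.31), "B")
  expect_equal(lab(3.30), "not-B")
  expect_equal(lab(-1.7), "not-B")
  expect_equal(lab(5.88), "B")
})

test_that("discretization is monotone in the mean response", {
  set.seed(1)
  v <- sort(runif(50, 2, 5))
  labs <- vapply(v, function(x)
    discretize(list(rec("x", x)))[[1L]]$class_label, character(1L))
  expect_true(all(diff(labs == "B") >= 0))   # never B -> not-B as v rises
})

test_that("response-ranked split reproduces the published partition sizes", {
  s <- response_ranked_split(seq_len(1395))
  expect_equal(length(s$train_idx), 931L)
  expect_equal(length(s$pred_idx), 464L)
  s <- response_ranked_split(seq_len(1379))
  expect_equal(length(s$train_idx), 920L)
  expect_equal(length(s$pred_idx), 459L)
})

test_that("response-ranked split follows the 1-pred/2-train walk", {
  y <- c(a = 10, b = 20, c = 30, d = 40, e = 50)
  s <- response_ranked_split(unname(y))
  expect_equal(s$pred_idx, 2L)                 # the second-smallest
  expect_equal(s$train_idx, c(1L, 3L, 4L, 5L))
  expect_error(response_ranked_split(c(1, 2)), "n >= 3")
})

test_that("splits partition the data with extremes in training", {
  set.seed(3)
  for (n in c(7, 50, 311)) {
    y <- rnorm(n)
    s <- response_ranked_split(y)
    expect_setequal(c(s$train_idx, s$pred_idx), seq_len(n))
    expect_length(intersect(s$train_idx, s$pred_idx), 0L)
    expect_true(which.min(y) %in% s$train_idx)
    expect_true(which.max(y) %in% s$train_idx)
  }
})

test_that("balanced subset thins not-B at the configured stride", {
  recs <- c(lapply(1:4, function(i) rec(sprintf("b%02d", i), 4 + i / 10,
                                        class = "B")),
            lapply(1:12, function(i) rec(sprintf("n%02d", i), i / 10,
                                         class = "not-B")))
  out <- balanced_subset(recs, stride = 6L, offset = 5L)
  labs <- vapply(out$subset, `[[`, character(1L), "class_label")
  expect_equal(sum(labs == "B"), 4L)
  expect_equal(sum(labs == "not-B"), 2L)
  expect_length(out$leftover_notB, 10L)
  # degenerate stride keeps everything
  out <- balanced_subset(recs, stride = 1L, offset = 0L)
  expect_length(out$subset, 16L)
  expect_length(out$leftover_notB, 0L)
})

test_that("strided selection spans the whole not-B response range", {
  set.seed(5)
  y <- sort(runif(600, -1.7, 3.2))
  recs <- c(list(rec("b1", 4.0, class = "B"), rec("b2", 4.5, class = "B")),
            lapply(seq_along(y), function(i)
              rec(sprintf("n%03d", i), y[i], class = "not-B")))
  out <- balanced_subset(recs, stride = 6L, offset = 5L)
  sel <- vapply(out$subset, `[[`, numeric(1L), "logbcf_mean")
  sel_nb <- sel[sel < 3.3]
  breaks <- seq(min(y), max(y), length.out = 11L)
  counts <- table(cut(sel_nb, breaks, include.lowest = TRUE))
  expect_gt(counts[1L], 0L)                    # min bin represented
  expect_gt(counts[length(counts)], 0L)        # max bin represented
})

test_that("euclidean split yields the published prediction-set size", {
  set.seed(11)
  X <- matrix(rnorm(417 * 4), 417)
  labels <- c(rep("B", 225), rep("not-B", 192))
  s <- euclidean_split(X, labels, fraction = 0.30)
  expect_equal(length(s$pred_idx), 125L)
  for (cl in c("B", "not-B")) {
    expect_gt(sum(labels[s$pred_idx] == cl), 0L)
    expect_gt(sum(labels[s$train_idx] == cl), 0L)
  }
  # determinism
  s2 <- euclidean_split(X, labels, fraction = 0.30)
  expect_identical(s, s2)
  # simple fraction arithmetic
  X10 <- matrix(rnorm(20), 10)
  s3 <- euclidean_split(X10, rep(c("B", "not-B"), each = 5L),
                        fraction = 0.5)
  expect_equal(length(s3$pred_idx), 5L)
  expect_error(euclidean_split(X10, c("B", rep("not-B", 9L))),
               "at least 2")
})

test_that("bcf_dataset aligns descriptors, responses and labels", {
  recs <- discretize(list(rec("a", 1.0, smiles = "CCO"),
                          rec("b", 4.0, smiles = "Clc1ccccc1"),
                          rec("c", 2.0, smiles = "CC(=O)C")))
  ds <- bcf_dataset(recs)
  expect_equal(dim(ds$X), c(3L, 9L))
  expect_equal(ds$y, c(1, 4, 2))
  expect_equal(ds$labels, c("not-B", "B", "not-B"))
  ds2 <- bcf_dataset(recs, exclude_ids = "b")
  expect_equal(length(ds2$records), 2L)
  expect_error(bcf_dataset(list(rec("a", 1), rec("a", 2))), "duplicated")
})
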