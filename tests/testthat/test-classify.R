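make_clouds <- function(n_per = 100L, p = 2L, shift = 6, seed = 40L) {
  bcfqsar:::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * p, shift), n_per),
               matrix(rnorm(n_per * p, 0), n_per))
    colnames(X) <- paste0("v", seq_len(p))
    list(X = X, labels = rep(c("B", "not-B"), each = n_per))
  })
}

test_that("LDA separates well-separated clouds perfectly", {
  d <- make_clouds(shift = 6)
  model <- fit_lda(d$X, d$labels)
  expect_equal(mean(predict(model, d$X)$class == d$labels), 1)
})

test_that("with identical means the larger prior wins everywhere", {
  set.seed(41)
  X <- matrix(rnorm(300 * 2), 300)
  labels <- c(rep("B", 250), rep("not-B", 50))
  model <- fit_lda(X, labels)   # proportional priors favour B strongly
  pred <- predict(model, matrix(rnorm(200), 100))$class
  expect_gte(mean(pred == "B"), 0.95)
})

test_that("LDA weights equal the closed form Sigma^-1 (mu_B - mu_nB)", {
  set.seed(42)
  X <- matrix(rnorm(100 * 3), 100, dimnames = list(NULL, c("a", "b", "c")))
  labels <- rep(c("B", "not-B"), 50)
  X[labels == "B", ] <- X[labels == "B", ] + 1.5
  model <- fit_lda(X, labels)
  w <- drop(solve(model$pooled_cov) %*%
              (model$means["positive", ] - model$means["negative", ]))
  expect_equal(unname(model$weights), unname(w), tolerance = 1e-8)
})

test_that("LDA class assignment agrees with the reference implementation", {
  skip_if_not_installed("MASS")
  d <- make_clouds(shift = 1.5, p = 3L, seed = 43L)
  model <- fit_lda(d$X, d$labels)
  ref <- MASS::lda(d$X, grouping = d$labels)
  expect_equal(predict(model, d$X)$class,
               as.character(predict(ref, d$X)$class))
  expect_equal(unname(predict(model, d$X)$posterior),
               unname(predict(ref, d$X)$posterior[, "B"]),
               tolerance = 1e-8)
})

test_that("confusion counts and percentages follow the hand example", {
  truth <- c(rep("B", 5), rep("not-B", 5))
  pred <- c("B", "B", "B", "not-B", "not-B",
            "B", "not-B", "not-B", "not-B", "not-B")
  cm <- confusion(truth, pred)
  expect_equal(cm$TP, 3); expect_equal(cm$FN, 2)
  expect_equal(cm$FP, 1); expect_equal(cm$TN, 4)
  pct <- confusion_percent(cm)
  expect_equal(unname(rowSums(pct)), c(100, 100))
  m <- classification_metrics(cm)
  expect_equal(unname(m$percent), c(70, 75, 60, 80))
  # all-correct and perfect matrices
  cm0 <- confusion(truth, truth)
  expect_equal(cm0$FP + cm0$FN, 0)
  expect_equal(unname(classification_metrics(cm0)$percent),
               c(100, 100, 100, 100))
  expect_error(confusion(c("B", "weird"), c("B", "B2")), "unknown label")
})

test_that("metrics with empty denominators are undefined, not zero", {
  m <- classification_metrics(confusion_matrix(TP = 0, TN = 5, FP = 0,
                                               FN = 0))
  expect_true(is.na(m$raw[["P"]]))
  expect_true(is.na(m$raw[["Sn"]]))
  expect_equal(m$raw[["Sp"]], 1)
})

test_that("printed training/prediction tables are reproduced from rates", {
  # linear discriminant tables: sizes 162/130 train, 63/62 prediction
  lda_tr <- classification_metrics(confusion_from_rates(88, 15, 162, 130))
  expect_equal(unname(lda_tr$percent), c(87, 88, 88, 85))
  lda_pr <- classification_metrics(confusion_from_rates(90, 23, 63, 62))
  expect_equal(unname(lda_pr$percent), c(84, 80, 90, 77))
  ann_tr <- classification_metrics(confusion_from_rates(90, 11, 162, 130))
  expect_equal(unname(ann_tr$percent), c(90, 91, 90, 89))
  ann_pr <- classification_metrics(confusion_from_rates(89, 23, 63, 62))
  expect_equal(unname(ann_pr$percent), c(83, 80, 89, 77))
})

test_that("AUC is the Mann-Whitney concordance probability", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c("B", "B", "not-B", "not-B"))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1),
                       c("B", "B", "not-B", "not-B"))$auc, 0.75)
  expect_error(roc_auc(1:3, rep("B", 3)), "both classes")
})

test_that("AUC matches the curve integral and a reference implementation", {
  set.seed(44)
  scores <- c(rnorm(60, 1), rnorm(80, 0))
  labels <- c(rep("B", 60), rep("not-B", 80))
  r <- roc_auc(scores, labels)
  trap <- sum(diff(r$curve$fpr) *
                (head(r$curve$tpr, -1) + tail(r$curve$tpr, -1)) / 2)
  expect_equal(r$auc, trap, tolerance = 1e-10)
  skip_if_not_installed("pROC")
  ref <- suppressMessages(pROC::auc(labels, scores, levels = c("not-B", "B"),
                                    direction = "<"))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-10)
})

test_that("AUC is invariant under monotone transforms and ~0.5 on noise", {
  set.seed(45)
  scores <- rnorm(300)
  labels <- sample(c("B", "not-B"), 300, replace = TRUE)
  expect_equal(roc_auc(scores, labels)$auc,
               roc_auc(exp(scores), labels)$auc, tolerance = 1e-12)
  big_scores <- rnorm(2000)
  big_labels <- sample(c("B", "not-B"), 2000, replace = TRUE)
  expect_lt(abs(roc_auc(big_scores, big_labels)$auc - 0.5), 0.05)
})

test_that("swapping class labels swaps sensitivity and specificity", {
  d <- make_clouds(shift = 1.2, seed = 46L)
  model <- fit_lda(d$X, d$labels, priors = "equal")
  pred <- predict(model, d$X)$class
  m1 <- classification_metrics(confusion(d$labels, pred))
  swap <- function(v) ifelse(v == "B", "not-B", "B")
  m2 <- classification_metrics(confusion(swap(d$labels), swap(pred)))
  expect_equal(m1$raw[["Sn"]], m2$raw[["Sp"]])
  expect_equal(m1$raw[["Sp"]], m2$raw[["Sn"]])
})

test_that("the standardization AD check flags what it should", {
  d <- make_clouds(seed = 47L)
  model <- fit_lda(d$X, d$labels)
  at_mean <- matrix(model$train_mean, 1,
                    dimnames = list(NULL, model$vars))
  expect_true(ad_check(model, at_mean)$in_domain)
  off <- at_mean
  off[1, "v1"] <- model$train_mean["v1"] + 5 * model$train_sd["v1"]
  res <- ad_check(model, off)
  expect_false(res$in_domain)
  expect_equal(res$offending, "v1")
})

test_that("AD flag rate matches the Gaussian tail expectation", {
  set.seed(48)
  n <- 4000L
  Xtr <- matrix(rnorm(1000 * 4), 1000, dimnames = list(NULL, paste0("v", 1:4)))
  model <- list(train_mean = colMeans(Xtr), train_sd = apply(Xtr, 2, sd),
                vars = paste0("v", 1:4))
  Xnew <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("v", 1:4)))
  frac <- mean(!ad_check(model, Xnew)$in_domain)
  p_expect <- 1 - (1 - 2 * pnorm(-3))^4
  expect_lt(abs(frac - p_expect), 0.01)
})
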