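# Two-class linear discriminant analysis for B / not-B assignment,
# classification metrics, ROC/AUC and the standardization-based
# applicability-domain check.

#' Fit a two-class pooled-covariance LDA
#'
#' Classical linear discriminant analysis with priors proportional to
#' class sizes by default: discriminant weights `w = S^-1 (mu_B - mu_nB)`
#' with `S` the pooled within-class covariance; the decision threshold
#' incorporates `ln(prior_B / prior_nB)`, so with proportional priors it
#' shifts by the log class-size ratio. Posterior probabilities for the
#' positive class are available per record. The positive class is `"B"`
#' when present, otherwise the alphabetically later label.
#'
#' @param X numeric feature matrix (named columns).
#' @param labels class labels, exactly two distinct values, each with at
#'   least 2 members.
#' @param priors `"proportional"` (default), `"equal"`, or a named numeric
#'   vector summing to 1.
#' @return an `lda_model`: class means, pooled covariance, priors, weights,
#'   threshold, training mean/sd per variable (for the domain check).
#' @export
fit_lda <- function(X, labels, priors = "proportional") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L) stop("labels must contain exactly two classes",
                             call. = FALSE)
  positive <- if ("B" %in% lv) "B" else lv[2L]
  negative <- setdiff(lv, positive)
  n_pos <- sum(labels == positive); n_neg <- sum(labels == negative)
  if (min(n_pos, n_neg) < 2L)
    stop("each class needs at least 2 members", call. = FALSE)
  if (identical(priors, "proportional")) {
    pr <- c(n_pos, n_neg) / (n_pos + n_neg)
  } else if (identical(priors, "equal")) {
    pr <- c(0.5, 0.5)
  } else {
    stopifnot(is.numeric(priors), length(priors) == 2L,
              abs(sum(priors) - 1) < 1e-8,
              all(c(positive, negative) %in% names(priors)))
    pr <- unname(priors[c(positive, negative)])
  }
  mu_pos <- colMeans(X[labels == positive, , drop = FALSE])
  mu_neg <- colMeans(X[labels == negative, , drop = FALSE])
  S <- (stats::cov(X[labels == positive, , drop = FALSE]) * (n_pos - 1L) +
        stats::cov(X[labels == negative, , drop = FALSE]) * (n_neg - 1L)) /
       (n_pos + n_neg - 2L)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("singular pooled covariance; consider pre-reduction of the ",
         "descriptors", call. = FALSE))
  w <- drop(Sinv %*% (mu_pos - mu_neg))
  # discriminant d(x) = w'x - w'(mu_pos+mu_neg)/2 + ln(pr_pos/pr_neg); B iff d > 0
  threshold <- sum(w * (mu_pos + mu_neg)) / 2 - log(pr[1L] / pr[2L])
  structure(list(
    positive = positive, negative = negative,
    means = rbind(positive = mu_pos, negative = mu_neg),
    pooled_cov = S, priors = stats::setNames(pr, c(positive, negative)),
    weights = w, threshold = threshold,
    train_mean = colMeans(X), train_sd = apply(X, 2L, stats::sd),
    n = c(positive = n_pos, negative = n_neg), vars = colnames(X)
  ), class = "lda_model")
}

#' @export
predict.lda_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  missing <- setdiff(object$vars, colnames(X))
  if (length(missing) && ncol(X) == length(object$vars) &&
      is.null(colnames(X))) colnames(X) <- object$vars
  else if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  d <- drop(X[, object$vars, drop = FALSE] %*% object$weights) -
    object$threshold
  posterior <- 1 / (1 + exp(-d))
  list(class = ifelse(d > 0, object$positive, object$negative),
       discriminant = d, posterior = posterior)
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %s vs %s; n = %d/%d; priors %.2f/%.2f\n",
              x$positive, x$negative, x$n[1L], x$n[2L],
              x$priors[1L], x$priors[2L]))
  cat("  variables:", paste(x$vars, collapse = ", "), "\n")
  invisible(x)
}

#' Confusion matrix (positives = B)
#'
#' Exact integer counts of true/false positives and negatives.
#'
#' @param labels_true,labels_pred class labels, equal length.
#' @param positive the positive class (default `"B"`).
#' @return a `confusion_matrix`: list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(labels_true, labels_pred, positive = "B") {
  if (length(labels_true) != length(labels_pred))
    stop("length mismatch", call. = FALSE)
  known <- unique(c(labels_true, labels_pred))
  if (length(known) > 2L)
    stop("unknown label(s): ",
         paste(setdiff(known, c(positive, "not-B")), collapse = ", "),
         call. = FALSE)
  is_pos_t <- labels_true == positive
  is_pos_p <- labels_pred == positive
  confusion_matrix(TP = sum(is_pos_t & is_pos_p),
                   TN = sum(!is_pos_t & !is_pos_p),
                   FP = sum(!is_pos_t & is_pos_p),
                   FN = sum(is_pos_t & !is_pos_p))
}

#' @rdname confusion
#' @param TP,TN,FP,FN non-negative counts.
#' @export
confusion_matrix <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN),
            class = "confusion_matrix")
}

#' Rebuild a confusion matrix from row percentages and class sizes
#'
#' The published confusion tables print percentages per true class
#' (correct assignment and misclassification rates). Given those rates and
#' the class sizes this reconstructs the underlying counts; counts may be
#' fractional when a percentage does not divide the class size evenly,
#' which is intended — metrics computed from them round back to the
#' printed integer percentages.
#'
#' @param sens_pct percentage of true-B assigned B.
#' @param fpr_pct percentage of true-not-B assigned B.
#' @param n_pos,n_neg class sizes (B, not-B).
#' @return a `confusion_matrix` (possibly fractional counts).
#' @examples
#' cm <- confusion_from_rates(88, 15, 162, 130)
#' classification_metrics(cm)$percent  # Ac 87, P 88, Sn 88, Sp 85
#' @export
confusion_from_rates <- function(sens_pct, fpr_pct, n_pos, n_neg) {
  confusion_matrix(TP = sens_pct / 100 * n_pos,
                   FN = (100 - sens_pct) / 100 * n_pos,
                   FP = fpr_pct / 100 * n_neg,
                   TN = (100 - fpr_pct) / 100 * n_neg)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>\n")
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(assigned = c("B", "not-B"),
                              true = c("B", "not-B")))
  print(m)
  invisible(x)
}

#' Row-percentage view of a confusion matrix
#'
#' Percentages normalized by true class, the presentation used by the
#' published confusion tables; each true class row sums to 100.
#'
#' @param cm a `confusion_matrix`.
#' @return 2x2 matrix of percentages (true class in rows).
#' @export
confusion_percent <- function(cm) {
  n_pos <- cm$TP + cm$FN; n_neg <- cm$TN + cm$FP
  matrix(c(100 * cm$TP / n_pos, 100 * cm$FN / n_pos,
           100 * cm$FP / n_neg, 100 * cm$TN / n_neg),
         2, 2, byrow = TRUE,
         dimnames = list(true = c("B", "not-B"),
                         assigned = c("B", "not-B")))
}

#' Classification quality metrics
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, precision `TP/(TP+FP)`, sensitivity
#' `TP/(TP+FN)` and specificity `TN/(TN+FP)`. A metric whose denominator
#' is zero is reported as `NA` (undefined), not 0. Percentages are rounded
#' half away from zero to match the printed tables.
#'
#' @param cm a `confusion_matrix`.
#' @return list with `raw` (proportions) and `percent` (integer percent),
#'   each named `Ac`, `P`, `Sn`, `Sp`.
#' @export
classification_metrics <- function(cm) {
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  raw <- c(Ac = safe(cm$TP + cm$TN, cm$TP + cm$FP + cm$TN + cm$FN),
           P  = safe(cm$TP, cm$TP + cm$FP),
           Sn = safe(cm$TP, cm$TP + cm$FN),
           Sp = safe(cm$TN, cm$TN + cm$FP))
  list(raw = raw, percent = as_percent(raw))
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney probability that a random positive scores above
#' a random negative (ties count one half); the returned curve holds
#' (FPR, TPR) at every distinct threshold and integrates to the same AUC
#' by the trapezoidal rule.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels class labels; @param positive the positive class.
#' @return list with `auc` and `curve` (data frame `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels, positive = "B") {
  is_pos <- labels == positive
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    fpr = vapply(thr, function(t) sum(scores[!is_pos] >= t) / n0,
                 numeric(1L)),
    tpr = vapply(thr, function(t) sum(scores[is_pos] >= t) / n1,
                 numeric(1L)))
  list(auc = auc, curve = curve)
}

#' Standardization-based applicability domain check
#'
#' Standardizes each new record with the model's training mean and
#' standard deviation per variable and flags it out of domain when any
#' |z| exceeds `z_threshold` (default 3); offending variables are listed.
#' A variable with zero training standard deviation is skipped with a
#' warning.
#'
#' @param model an `lda_model` (or any list with `train_mean`, `train_sd`,
#'   `vars`).
#' @param X_new new feature rows.
#' @param z_threshold standardized-value cut-off.
#' @return data frame with `in_domain` and `offending` (comma-separated
#'   variable names, `""` when in domain).
#' @export
ad_check <- function(model, X_new, z_threshold = 3) {
  X <- as.matrix(X_new)
  vars <- model$vars
  usable <- vars[model$train_sd[vars] > 0]
  if (length(usable) < length(vars))
    warning("zero training sd; skipped: ",
            paste(setdiff(vars, usable), collapse = ", "))
  Z <- sweep(sweep(X[, usable, drop = FALSE], 2L, model$train_mean[usable]),
             2L, model$train_sd[usable], `/`)
  offending <- apply(Z, 1L, function(z)
    paste(usable[abs(z) > z_threshold], collapse = ","))
  data.frame(in_domain = !nzchar(offending), offending = offending,
             stringsAsFactors = FALSE)
}

#' Classification validation report
#'
#' Confusion matrix, Ac/P/Sn/Sp and AUC for training and (optionally)
#' prediction partitions of a fitted classifier.
#'
#' @param model an `lda_model`.
#' @param X,labels training data; @param X_ext,labels_ext prediction data.
#' @return a `classification_report` list.
#' @export
validate_classification <- function(model, X, labels,
                                    X_ext = NULL, labels_ext = NULL) {
  score_set <- function(Xs, ls) {
    pr <- predict(model, Xs)
    cm <- confusion(ls, pr$class, positive = model$positive)
    list(confusion = cm, percent = confusion_percent(cm),
         metrics = classification_metrics(cm),
         auc = roc_auc(pr$posterior, ls, positive = model$positive)$auc)
  }
  rep <- list(training = score_set(X, labels))
  if (!is.null(X_ext)) rep$prediction <- score_set(X_ext, labels_ext)
  class(rep) <- "classification_report"
  rep
}

#' @export
print.classification_report <- function(x, ...) {
  for (part in names(x)) {
    m <- x[[part]]$metrics$percent
    cat(sprintf("%-10s Ac %d  P %d  Sn %d  Sp %d  AUC %.2f\n",
                part, m["Ac"], m["P"], m["Sn"], m["Sp"], x[[part]]$auc))
  }
  invisible(x)
}
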