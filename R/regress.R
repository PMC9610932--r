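# Ordinary-least-squares modelling of log BCF, the frozen published
# six-descriptor equation, and the regression validation suite.

#' Fit a multiple linear regression by ordinary least squares
#'
#' @param X numeric matrix or data frame of predictors (named columns).
#' @param y numeric response, `length(y) == nrow(X)`.
#' @return an `mlr_model`: list with `intercept`, named `coefficients`,
#'   and the training `X`, `y` (kept for leverage and validation).
#' @examples
#' m <- fit_ols(cbind(x = 0:2), c(1, 3, 5))
#' coef(m)  # intercept 1, slope 2
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n <= p + 1L) stop("need more rows than predictors plus intercept",
                        call. = FALSE)
  X1 <- cbind(`(Intercept)` = 1, X)
  qr_ <- qr(X1)
  if (qr_$rank < ncol(X1)) {
    drop_cols <- colnames(X1)[qr_$pivot[(qr_$rank + 1L):ncol(X1)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_, y)
  structure(list(intercept = unname(beta[1L]),
                 coefficients = beta[-1L],
                 X = X, y = y),
            class = "mlr_model")
}

#' @export
coef.mlr_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
predict.mlr_model <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$X else as.matrix(newdata)
  vars <- names(object$coefficients)
  if (is.null(colnames(X)) && ncol(X) == length(vars)) colnames(X) <- vars
  missing <- setdiff(vars, colnames(X))
  if (length(missing))
    stop("missing descriptor column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  drop(object$intercept + X[, vars, drop = FALSE] %*% object$coefficients)
}

#' @export
print.mlr_model <- function(x, ...) {
  cat("<mlr_model>", sprintf("n = %d, p = %d", nrow(x$X),
                             length(x$coefficients)), "\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' Printed intercept of the published six-descriptor equation
#'
#' The coefficients are stored exactly as printed (2 decimal places) and
#' are never re-fit.
#' @export
EQ1_INTERCEPT <- -1.44

#' Printed slopes of the published six-descriptor equation
#' @export
EQ1_COEFFICIENTS <- c(MWC4 = 0.80, SubFPC171 = 0.24, SubFPC295 = -0.10,
                      maxHBd = -1.19, maxdO = -0.06, IC0 = -0.51)

#' The published six-descriptor log BCF model
#'
#' Returns the frozen published regression equation
#' `log BCF = -1.44 + 0.80 MWC4 + 0.24 SubFPC171 - 0.10 SubFPC295
#'  - 1.19 maxHBd - 0.06 maxdO - 0.51 IC0`
#' as an `mlr_model` without training data (leverage-based domain checks
#' need a user-supplied training reference).
#'
#' @return an `mlr_model` with the printed intercept and coefficients.
#' @export
published_model <- function() {
  structure(list(intercept = EQ1_INTERCEPT,
                 coefficients = EQ1_COEFFICIENTS,
                 X = NULL, y = NULL),
            class = "mlr_model")
}

#' Predict log BCF with the published equation
#'
#' Evaluates the frozen published coefficients on a descriptor vector or a
#' descriptor matrix; the coefficients are constants, never re-fit.
#'
#' @param d a named numeric vector (e.g. from [compute_descriptors()]) or a
#'   matrix/data frame with the six descriptor columns `MWC4`, `SubFPC171`,
#'   `SubFPC295`, `maxHBd`, `maxdO`, `IC0`.
#' @return predicted log BCF (numeric).
#' @examples
#' zero <- setNames(numeric(6), names(EQ1_COEFFICIENTS))
#' predict_published(zero)  # the printed intercept, -1.44
#' @export
predict_published <- function(d) {
  vars <- names(EQ1_COEFFICIENTS)
  if (is.null(dim(d))) {
    missing <- setdiff(vars, names(d))
    if (length(missing))
      stop("missing descriptor(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    vals <- as.numeric(d[vars])
    if (any(!is.finite(vals)))
      stop("non-finite descriptor value(s)", call. = FALSE)
    return(EQ1_INTERCEPT + sum(EQ1_COEFFICIENTS * vals))
  }
  X <- as.matrix(d)
  missing <- setdiff(vars, colnames(X))
  if (length(missing))
    stop("missing descriptor column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  drop(EQ1_INTERCEPT + X[, vars, drop = FALSE] %*% EQ1_COEFFICIENTS)
}

#' Root mean squared error
#'
#' `sqrt(mean((y - yhat)^2))`, the error metric used for training
#' (RMSE_Tr), cross-validation (RMSE_cv) and external (RMSE_Ext) sets.
#'
#' @param y observed values.
#' @param yhat predicted values, same length.
#' @return a non-negative number.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  if (length(y) == 0L) stop("empty vectors", call. = FALSE)
  sqrt(mean((y - yhat)^2))
}

#' Determination coefficient on a scored set
#'
#' `1 - SS_res / SS_tot` with `SS_tot` centred on the scored set's mean.
#'
#' @param y observed; @param yhat predicted.
#' @return R-squared (at most 1; can be negative on external sets).
#' @export
r_squared <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Leave-one-out cross-validated Q^2
#'
#' `1 - PRESS / SS_tot`, each prediction coming from a model fit without
#' that row. Computed through the hat-matrix identity
#' `e_loo = e / (1 - h)`, which agrees with literally refitting n models.
#'
#' @param X predictors; @param y response.
#' @return Q^2_loo.
#' @export
q2_loo <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 2L) stop("q2_loo needs n > p + 2", call. = FALSE)
  model <- fit_ols(X, y)
  h <- leverage_values(model, X)
  if (any(h >= 1 - 1e-12))
    stop("leave-one-out refit singular at row ",
         which(h >= 1 - 1e-12)[1L], call. = FALSE)
  resid <- y - predict(model)
  press <- sum((resid / (1 - h))^2)
  1 - press / sum((y - mean(y))^2)
}

#' k-fold cross-validated RMSE
#'
#' Shuffles rows with the given seed, cuts k near-equal contiguous folds,
#' refits on each training complement and pools the out-of-fold squared
#' errors into one RMSE (per-fold RMSEs are also returned).
#'
#' @param X predictors; @param y response.
#' @param k number of folds (default 5).
#' @param seed RNG seed for the fold shuffle.
#' @return list with `rmse_cv` (pooled), `per_fold`, `folds`, `seed`.
#' @export
kfold_cv <- function(X, y, k = 5L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 2L || k > n) stop("need 2 <= k <= n", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  fold_id <- integer(n)
  # contiguous chunking of the shuffled order into near-equal folds
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold_of_pos <- rep(seq_len(k), sizes)
  fold_id[perm] <- fold_of_pos
  sq_err <- numeric(0)
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    test <- which(fold_id == f)
    model <- fit_ols(X[-test, , drop = FALSE], y[-test])
    pred <- predict(model, X[test, , drop = FALSE])
    per_fold[f] <- rmse(y[test], pred)
    sq_err <- c(sq_err, (y[test] - pred)^2)
  }
  list(rmse_cv = sqrt(mean(sq_err)), per_fold = per_fold,
       folds = fold_id, seed = seed)
}

#' Y-scrambling (response permutation) check
#'
#' Refits the model against permuted responses and averages the resulting
#' training R-squared over `n_perm` permutations; a mean close to zero
#' indicates absence of chance correlation.
#'
#' @param X predictors; @param y response.
#' @param n_perm number of permutations (default 50).
#' @param seed RNG seed.
#' @param perms optional list of explicit permutations overriding the
#'   seeded draw (used for degenerate controls).
#' @return list with `r2_yscr` (mean), `sd`, `r2_values`, `seed`.
#' @export
y_scramble <- function(X, y, n_perm = 50L, seed = 1L, perms = NULL) {
  X <- as.matrix(X)
  stopifnot(n_perm >= 1L)
  if (is.null(perms))
    perms <- with_seed(seed, replicate(n_perm, sample.int(length(y)),
                                       simplify = FALSE))
  r2 <- vapply(perms, function(p) {
    m <- fit_ols(X, y[p])
    r_squared(y[p], predict(m))
  }, numeric(1L))
  list(r2_yscr = mean(r2), sd = stats::sd(r2), r2_values = r2, seed = seed)
}

# Hat values of rows of `X_new` under the model's training design.
leverage_values <- function(model, X_new = NULL) {
  if (is.null(model$X)) stop("model carries no training data", call. = FALSE)
  vars <- names(model$coefficients)
  Xt <- cbind(1, model$X[, vars, drop = FALSE])
  Xn <- Xt
  if (!is.null(X_new)) {
    Xn <- as.matrix(X_new)
    if (is.null(colnames(Xn)) && ncol(Xn) == length(vars))
      colnames(Xn) <- vars
    Xn <- cbind(1, Xn[, vars, drop = FALSE])
  }
  XtXi <- solve(crossprod(Xt))
  rowSums((Xn %*% XtXi) * Xn)
}

#' Williams-plot applicability domain analysis
#'
#' Computes per-compound leverage `h = x (X'X)^-1 x'` against the model's
#' training design and standardized residuals, and flags structural
#' outliers (`h > h*`, `h* = 3(p+1)/n_train`) and response outliers
#' (|standardized residual| above `resid_threshold`). Residuals are
#' cross-validated (leave-one-out) by default for the training set; plain
#' standardized residuals are available via `residual_type = "raw"`.
#'
#' @param model an `mlr_model` carrying training data.
#' @param X_new optional new descriptor rows (default: the training set).
#' @param y_new observed responses for `X_new` (required for residuals on
#'   new data).
#' @param resid_threshold flag limit in standard-deviation units
#'   (default 2.5; the printed response-outlier discussion uses 3).
#' @param residual_type `"loo"` (cross-validated, training only) or
#'   `"raw"`.
#' @return a data frame with `h`, `std_residual`, `structural_outlier`,
#'   `response_outlier`; `h_star` attached as an attribute.
#' @export
williams <- function(model, X_new = NULL, y_new = NULL,
                     resid_threshold = 2.5,
                     residual_type = c("loo", "raw")) {
  residual_type <- match.arg(residual_type)
  n_train <- nrow(model$X)
  p <- length(model$coefficients)
  h_star <- 3 * (p + 1) / n_train
  on_training <- is.null(X_new)
  h <- leverage_values(model, X_new)
  std_res <- rep(NA_real_, length(h))
  if (on_training) {
    e <- model$y - predict(model)
    s <- sqrt(sum(e^2) / (n_train - p - 1L))
    if (residual_type == "loo") {
      e_loo <- e / (1 - h)
      std_res <- e_loo / sqrt(sum(e_loo^2) / (n_train - p - 1L))
    } else {
      std_res <- e / (s * sqrt(1 - h))
    }
  } else if (!is.null(y_new)) {
    e <- y_new - predict(model, X_new)
    s <- sqrt(sum((model$y - predict(model))^2) / (n_train - p - 1L))
    std_res <- e / s
  }
  out <- data.frame(
    h = h, std_residual = std_res,
    structural_outlier = h > h_star,
    response_outlier = !is.na(std_res) & abs(std_res) > resid_threshold)
  attr(out, "h_star") <- h_star
  attr(out, "resid_threshold") <- resid_threshold
  out
}

#' Leverage cut-off of the Williams plot
#'
#' `h* = 3 (p + 1) / n`; with the published training size (n = 920, p = 6)
#' this reproduces the printed 0.023.
#'
#' @param n_train training-set size; @param p number of model variables.
#' @return the cut-off value.
#' @examples
#' round(h_star(920, 6), 3)  # 0.023
#' @export
h_star <- function(n_train, p) 3 * (p + 1) / n_train

#' Full regression validation report
#'
#' Assembles the fitting and validation statistics reported for the
#' regression models: training R^2 and RMSE, Q^2_loo, k-fold RMSE_cv,
#' Y-scramble mean R^2, external R^2/RMSE when a prediction set is given,
#' and the Williams-plot table for the training set.
#'
#' @param X,y training descriptors and response.
#' @param X_ext,y_ext optional external (prediction) set.
#' @param k folds for cross-validation; @param n_perm Y-scramble count.
#' @param seed RNG seed used for fold assignment and permutations.
#' @return a `regression_report` list.
#' @export
validate_regression <- function(X, y, X_ext = NULL, y_ext = NULL,
                                k = 5L, n_perm = 50L, seed = 1L) {
  X <- as.matrix(X)
  model <- fit_ols(X, y)
  cv <- kfold_cv(X, y, k = k, seed = seed)
  ys <- y_scramble(X, y, n_perm = n_perm, seed = seed)
  wil <- williams(model)
  rep <- list(
    model = model,
    n_train = nrow(X), p = ncol(X),
    R2 = r_squared(y, predict(model)),
    Q2_loo = q2_loo(X, y),
    RMSE_tr = rmse(y, predict(model)),
    RMSE_cv_test = cv$rmse_cv, cv = cv,
    R2_yscr = ys$r2_yscr, yscramble = ys,
    williams = wil, h_star = attr(wil, "h_star"),
    seed = seed
  )
  if (!is.null(X_ext)) {
    pred_ext <- predict(model, X_ext)
    rep$RMSE_ext <- rmse(y_ext, pred_ext)
    rep$R2_ext <- r_squared(y_ext, pred_ext)
    rep$n_pred <- nrow(as.matrix(X_ext))
  }
  class(rep) <- "regression_report"
  rep
}

#' @export
print.regression_report <- function(x, ...) {
  cat("<regression_report>\n")
  cat(sprintf("  n_tr = %d, p = %d\n", x$n_train, x$p))
  cat(sprintf("  R2 = %.2f; Q2_loo = %.2f; RMSE_Tr = %.2f; RMSE_cv = %.2f",
              x$R2, x$Q2_loo, x$RMSE_tr, x$RMSE_cv_test))
  if (!is.null(x$RMSE_ext))
    cat(sprintf("; RMSE_Ext = %.2f; R2_ext = %.2f", x$RMSE_ext, x$R2_ext))
  cat(sprintf("; R2-YScr = %.2f\n", x$R2_yscr))
  cat(sprintf("  h* = %.3f\n", x$h_star))
  invisible(x)
}
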