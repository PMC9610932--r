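# Variable pre-reduction and the two selection engines: step-up subset
# selection for regression and a genetic algorithm for LDA classification.

#' Descriptor pre-reduction
#'
#' Drops constant / near-constant columns (at most two distinct values or
#' variance below `const_tol`), then greedily removes one column of every
#' pair whose absolute Pearson correlation exceeds the kind-specific
#' threshold (0.80 for continuous descriptors, 0.95 for fingerprint
#' counts), keeping the column with the larger variance (ties broken by
#' name, the lexicographically smaller name surviving). Every removal is
#' logged with its cause.
#'
#' @param X numeric matrix or data frame with named columns.
#' @param kind character vector, one of `"descriptor"` / `"fingerprint"`
#'   per column (default all `"descriptor"`).
#' @param const_tol variance threshold for near-constant columns.
#' @param corr_threshold_desc,corr_threshold_fp correlation limits per kind.
#' @return list with `X` (reduced matrix) and `log` (data frame with
#'   `column`, `cause`).
#' @export
prereduce <- function(X, kind = NULL, const_tol = 1e-8,
                      corr_threshold_desc = 0.80,
                      corr_threshold_fp = 0.95) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(kind)) kind <- rep("descriptor", ncol(X))
  stopifnot(length(kind) == ncol(X), all(kind %in% c("descriptor",
                                                     "fingerprint")))
  names(kind) <- colnames(X)
  log_col <- character(0); log_cause <- character(0)
  drop_log <- function(col, cause) {
    log_col <<- c(log_col, col); log_cause <<- c(log_cause, cause)
  }

  variances <- apply(X, 2L, stats::var)
  n_distinct <- apply(X, 2L, function(col) length(unique(col)))
  const <- variances <= const_tol | n_distinct <= 2L
  for (col in colnames(X)[const]) drop_log(col, "constant")
  X <- X[, !const, drop = FALSE]
  if (ncol(X) == 0L) stop("all columns removed in pre-reduction",
                          call. = FALSE)
  variances <- variances[colnames(X)]

  thr_of <- function(a, b) {
    if (kind[a] == "fingerprint" && kind[b] == "fingerprint")
      corr_threshold_fp else corr_threshold_desc
  }
  repeat {
    if (ncol(X) < 2L) break
    C <- abs(stats::cor(X))
    diag(C) <- 0
    worst <- NULL; worst_r <- -1
    for (a in seq_len(ncol(X) - 1L)) for (b in (a + 1L):ncol(X)) {
      if (C[a, b] > thr_of(colnames(X)[a], colnames(X)[b]) &&
          C[a, b] > worst_r) {
        worst <- c(a, b); worst_r <- C[a, b]
      }
    }
    if (is.null(worst)) break
    na <- colnames(X)[worst[1L]]; nb <- colnames(X)[worst[2L]]
    victim <- if (variances[na] < variances[nb]) na
              else if (variances[nb] < variances[na]) nb
              else max(na, nb)     # tie: keep the smaller name
    drop_log(victim, sprintf("correlation %.2f with %s", worst_r,
                             setdiff(c(na, nb), victim)))
    X <- X[, colnames(X) != victim, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("all columns removed in pre-reduction",
                          call. = FALSE)
  list(X = X,
       log = data.frame(column = log_col, cause = log_cause,
                        stringsAsFactors = FALSE))
}

#' Step-up (forward beam) variable subset selection
#'
#' Builds a population of regression models of increasing size: the
#' `keep_per_size` best single variables by fitness (training R-squared)
#' form size 1; every retained size s-1 model is extended by each unused
#' variable, candidate sets are deduplicated, and the best `keep_per_size`
#' are retained at size s. With the published settings (50 models per
#' size, sizes 1-10) the population capacity is 500 models.
#'
#' @param X predictor matrix; @param y response.
#' @param max_size largest model size (default 10).
#' @param keep_per_size models kept per size (default 50).
#' @return a `stepup_population`: list with `models` (per size, a list of
#'   `list(vars, fitness)` sorted by decreasing fitness), `fitness_name`,
#'   `capacity`.
#' @export
step_up_vss <- function(X, y, max_size = 10L, keep_per_size = 50L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (ncol(X) < max_size)
    stop("need at least max_size columns", call. = FALSE)
  ratio <- n / max_size
  if (ratio < 1) stop("fewer rows than the largest model size",
                      call. = FALSE)
  if (ratio < 5)
    warning("objects/variables ratio below 5 at the largest model size")

  fitness_of <- function(vars) {
    m <- stats::.lm.fit(cbind(1, X[, vars, drop = FALSE]), y)
    1 - sum(m$residuals^2) / sum((y - mean(y))^2)
  }
  all_vars <- colnames(X)
  levels <- vector("list", max_size)
  # size 1
  f1 <- vapply(all_vars, function(v) fitness_of(v), numeric(1L))
  ord <- order(-f1, all_vars)
  keep <- head(ord, keep_per_size)
  levels[[1L]] <- lapply(keep, function(i)
    list(vars = all_vars[i], fitness = unname(f1[i])))
  # sizes 2..max_size
  for (s in seq_len(max_size)[-1L]) {
    seen <- character(0)
    cand_vars <- list(); cand_fit <- numeric(0)
    for (mod in levels[[s - 1L]]) {
      for (v in setdiff(all_vars, mod$vars)) {
        vars <- sort(c(mod$vars, v))
        key <- paste(vars, collapse = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        cand_vars[[length(cand_vars) + 1L]] <- vars
        cand_fit <- c(cand_fit, fitness_of(vars))
      }
    }
    ord <- order(-cand_fit,
                 vapply(cand_vars, paste, character(1L), collapse = "|"))
    keep <- head(ord, keep_per_size)
    levels[[s]] <- lapply(keep, function(i)
      list(vars = cand_vars[[i]], fitness = cand_fit[i]))
  }
  structure(list(models = levels, fitness_name = "R2",
                 capacity = keep_per_size * max_size,
                 keep_per_size = keep_per_size, max_size = max_size),
            class = "stepup_population")
}

#' @export
print.stepup_population <- function(x, ...) {
  n_models <- sum(lengths(x$models))
  cat(sprintf("<stepup_population> %d models (capacity %d), sizes 1-%d\n",
              n_models, x$capacity, x$max_size))
  best <- best_model(x)
  cat(sprintf("  best: {%s} %s = %.3f\n", paste(best$vars, collapse = ", "),
              x$fitness_name, best$fitness))
  invisible(x)
}

#' Best model of a step-up population
#' @param pop a `stepup_population`.
#' @param size restrict to one model size (default: best overall fitness).
#' @return `list(vars, fitness)`.
#' @export
best_model <- function(pop, size = NULL) {
  models <- if (is.null(size)) unlist(pop$models, recursive = FALSE)
            else pop$models[[size]]
  models[[which.max(vapply(models, `[[`, numeric(1L), "fitness"))]]
}

#' Genetic-algorithm configuration
#'
#' Defaults follow the published GA settings: 500 iterations, population
#' 100, mutation probability 0.3, at most 4 variables per model.
#'
#' @param iterations,population,mutation_prob,max_vars,seed GA controls.
#' @return a `ga_config` list.
#' @export
ga_config <- function(iterations = 500L, population = 100L,
                      mutation_prob = 0.3, max_vars = 4L, seed = 1L) {
  stopifnot(iterations >= 0L, population >= 2L,
            mutation_prob >= 0, mutation_prob <= 1, max_vars >= 1L)
  structure(list(iterations = as.integer(iterations),
                 population = as.integer(population),
                 mutation_prob = mutation_prob,
                 max_vars = as.integer(max_vars), seed = seed),
            class = "ga_config")
}

#' Genetic-algorithm variable selection for LDA
#'
#' Evolves variable subsets of size at most `cfg$max_vars` for a two-class
#' linear discriminant model: tournament selection (size 2), one-point
#' crossover on the inclusion bitstring, per-gene mutation at
#' `cfg$mutation_prob`, elitism of 1 and repair of over-long subsets.
#' Fitness is LDA training accuracy with a 5-fold cross-validated accuracy
#' tie-break; evaluations are memoized per subset. Seeded and reproducible.
#'
#' @param X feature matrix; @param labels binary class labels (`B`/`not-B`).
#' @param cfg a [ga_config()].
#' @return list with `vars` (best subset), `fitness` (training accuracy),
#'   `cv_accuracy`, `history` (best fitness per generation).
#' @export
ga_select <- function(X, labels, cfg = ga_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  if (p < cfg$max_vars) stop("need at least max_vars columns", call. = FALSE)
  if (length(unique(labels)) != 2L)
    stop("labels must contain exactly two classes", call. = FALSE)

  n <- nrow(X)
  positive <- if ("B" %in% labels) "B" else sort(unique(labels))[2L]
  is_pos <- labels == positive
  fold_id <- rep(seq_len(5L), length.out = n)  # fixed folds: memo stays pure
  evaluator <- lda_subset_evaluator(X, is_pos, fold_id)

  memo_scores <- new.env(parent = emptyenv(), hash = TRUE)
  memo_fits <- new.env(parent = emptyenv(), hash = TRUE)
  score_keys <- function(keys) {
    out <- numeric(length(keys))
    for (idx in seq_along(keys)) {
      key <- keys[idx]
      hit <- memo_scores[[key]]
      if (is.null(hit)) {
        fit <- evaluator(key)
        memo_fits[[key]] <- fit
        hit <- fit[1L] + 1e-6 * fit[2L]   # CV accuracy as tie-break
        memo_scores[[key]] <- hit
      }
      out[idx] <- hit
    }
    out
  }
  key_of <- function(pop) apply(pop, 1L, function(r)
    paste(which(r), collapse = ","))

  with_seed(cfg$seed, {
    pop <- t(vapply(seq_len(cfg$population), function(i) {
      k <- sample.int(cfg$max_vars, 1L)
      mask <- rep(FALSE, p)
      mask[sample.int(p, k)] <- TRUE
      mask
    }, logical(p)))
    scores <- score_keys(key_of(pop))
    history <- numeric(0)
    npop <- cfg$population
    for (gen in seq_len(max(cfg$iterations, 0L))) {
      elite <- which.max(scores)
      n_child <- npop - 1L
      # vectorized tournament selection (size 2)
      duel <- matrix(sample.int(npop, 4L * n_child, replace = TRUE),
                     ncol = 4L)
      pa <- ifelse(scores[duel[, 1L]] >= scores[duel[, 2L]],
                   duel[, 1L], duel[, 2L])
      pb <- ifelse(scores[duel[, 3L]] >= scores[duel[, 4L]],
                   duel[, 3L], duel[, 4L])
      # one-point crossover, vectorized over children
      cuts <- sample.int(p - 1L, n_child, replace = TRUE)
      take_a <- outer(cuts, seq_len(p), `>=`)
      children <- ifelse(take_a, pop[pa, , drop = FALSE],
                         pop[pb, , drop = FALSE])
      # per-gene mutation
      flip <- matrix(stats::runif(n_child * p) < cfg$mutation_prob,
                     n_child, p)
      children <- xor(children, flip)
      # repair: at most max_vars, at least one variable
      sizes <- rowSums(children)
      for (r in which(sizes > cfg$max_vars)) {
        on <- which(children[r, ])
        children[r, sample(on, sizes[r] - cfg$max_vars)] <- FALSE
      }
      for (r in which(sizes == 0L))
        children[r, sample.int(p, 1L)] <- TRUE
      pop <- rbind(pop[elite, , drop = FALSE], children)
      scores <- score_keys(key_of(pop))
      history <- c(history, max(scores))
    }
    best <- which.max(scores)
    best_fit <- memo_fits[[key_of(pop)[best]]]
    list(vars = colnames(X)[pop[best, ]], fitness = best_fit[1L],
         cv_accuracy = best_fit[2L], history = history, config = cfg)
  })
}

# Lean two-class LDA fitness used inside the GA: training accuracy plus
# deterministic 5-fold cross-validated accuracy for one variable subset
# (key = comma-joined column indices). Falls back to accuracy 0 when the
# pooled covariance is singular.
lda_subset_evaluator <- function(X, is_pos, fold_id) {
  n <- length(is_pos)
  n_pos <- sum(is_pos); n_neg <- n - n_pos
  function(key) {
    vars <- as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
    Xs <- X[, vars, drop = FALSE]
    acc_of <- function(train, test) {
      xp <- Xs[train & is_pos, , drop = FALSE]
      xn <- Xs[train & !is_pos, , drop = FALSE]
      np <- nrow(xp); nn <- nrow(xn)
      if (np < 2L || nn < 2L) return(NA_real_)
      mp <- colMeans(xp); mn <- colMeans(xn)
      S <- (crossprod(sweep(xp, 2L, mp)) + crossprod(sweep(xn, 2L, mn))) /
        (np + nn - 2L)
      w <- tryCatch(solve(S, mp - mn), error = function(e) NULL)
      if (is.null(w)) return(NA_real_)
      thr <- sum(w * (mp + mn)) / 2 - log(np / nn)
      d <- drop(Xs[test, , drop = FALSE] %*% w) - thr
      mean((d > 0) == is_pos[test])
    }
    all_rows <- rep(TRUE, n)
    acc <- acc_of(all_rows, all_rows)
    if (is.na(acc)) return(c(0, 0))
    cv_correct <- 0
    for (f in unique(fold_id)) {
      test <- fold_id == f
      a <- acc_of(!test, test)
      if (!is.na(a)) cv_correct <- cv_correct + a * sum(test)
    }
    c(acc, cv_correct / n)
  }
}
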