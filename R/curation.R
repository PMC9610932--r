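# Dataset curation: replicate averaging, regulatory class discretization,
# balanced-subset construction and the two split procedures.

#' Average replicate log BCF measurements per chemical
#'
#' Collapses records sharing an id into one record whose `logbcf_mean` is
#' the arithmetic mean of all measurements for that chemical.
#'
#' @param records list of `bcf_record`.
#' @return list of `bcf_record`, one per unique id, in first-seen order.
#' @export
average_replicates <- function(records) {
  ids <- vapply(records, function(r) r$id, character(1L))
  out <- list()
  for (id in unique(ids)) {
    group <- records[ids == id]
    vals <- unlist(lapply(group, function(r) r$logbcf_values))
    if (length(vals) == 0L)
      stop("record '", id, "' has no log BCF values", call. = FALSE)
    out[[length(out) + 1L]] <- bcf_record(
      id = id, smiles = group[[1L]]$smiles, logbcf_values = vals,
      class_label = group[[1L]]$class_label)
  }
  out
}

#' Discretize log BCF into regulatory B / not-B classes
#'
#' Applies the REACH bioaccumulation cut-off: a chemical is labelled `B`
#' iff its mean log BCF is strictly greater than the threshold (default
#' 3.30, i.e. BCF > 2000), `not-B` otherwise.
#'
#' @param records list of `bcf_record` with `logbcf_mean` present.
#' @param threshold class cut-off on the log10 scale (default 3.30).
#' @return the records with `class_label` filled in.
#' @examples
#' r <- bcf_record("x", "CCO", 3.31)
#' discretize(list(r))[[1]]$class_label  # "B"
#' @export
discretize <- function(records, threshold = 3.30) {
  lapply(records, function(r) {
    if (is.na(r$logbcf_mean))
      stop("record '", r$id, "' has no mean log BCF", call. = FALSE)
    r$class_label <- if (r$logbcf_mean > threshold) "B" else "not-B"
    r
  })
}

#' Response-ranked training/prediction split
#'
#' Sorts the responses in increasing order (stable; ties broken by `ids`
#' when given), assigns the first and the last chemical to the training
#' set, then walks the remaining sorted sequence assigning one chemical to
#' the prediction set followed by two to the training set; any leftover
#' chemicals at the end go to training. This reproduces the published
#' partition sizes 931/464 at n = 1395 and 920/459 at n = 1379.
#'
#' @param y numeric response vector (n >= 3).
#' @param ids optional character tie-break keys, same length as `y`.
#' @return a `split_plan`: list with integer index vectors `train_idx` and
#'   `pred_idx` partitioning `seq_along(y)`.
#' @export
response_ranked_split <- function(y, ids = NULL) {
  n <- length(y)
  if (n < 3L) stop("response_ranked_split needs n >= 3", call. = FALSE)
  ord <- if (is.null(ids)) order(y) else order(y, ids)
  train <- c(ord[1L], ord[n])
  inner <- ord[-c(1L, n)]
  pred <- integer(0)
  k <- 1L
  while (k <= length(inner)) {
    if (k + 2L <= length(inner)) {
      pred <- c(pred, inner[k])
      train <- c(train, inner[k + 1L], inner[k + 2L])
    } else {
      train <- c(train, inner[k:length(inner)])   # leftover -> training
      break
    }
    k <- k + 3L
  }
  split_plan(train, pred, n)
}

split_plan <- function(train_idx, pred_idx, n) {
  train_idx <- sort(unique(as.integer(train_idx)))
  pred_idx <- sort(unique(as.integer(pred_idx)))
  stopifnot(length(intersect(train_idx, pred_idx)) == 0L,
            setequal(c(train_idx, pred_idx), seq_len(n)))
  structure(list(train_idx = train_idx, pred_idx = pred_idx, n = n),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d training / %d prediction (n = %d)\n",
              length(x$train_idx), length(x$pred_idx), x$n))
  invisible(x)
}

#' Class-balanced modelling subset
#'
#' Keeps every B record and thins the (much larger) not-B class: not-B
#' records are sorted by increasing mean log BCF and sampled at a fixed
#' stride so the selection spans the whole not-B response range. The
#' not-B records left out form an additional external evaluation set.
#' The default stride 6 starting at sorted position 6 selects about one
#' not-B chemical in six, matching the published subset proportions
#' (192 of 1154); a literal "one in five" is available via `stride = 5`.
#'
#' @param records list of `bcf_record` with class labels.
#' @param stride keep every `stride`-th sorted not-B record.
#' @param offset 0-based sorted index of the first selected not-B record
#'   (default `stride - 1`, i.e. positions stride, 2*stride, ...).
#' @return list with `subset` (balanced records) and `leftover_notB`.
#' @export
balanced_subset <- function(records, stride = 6L, offset = stride - 1L) {
  labels <- vapply(records, function(r) r$class_label, character(1L))
  if (anyNA(labels)) stop("all records need class labels", call. = FALSE)
  if (!all(c("B", "not-B") %in% labels))
    stop("both classes must be present", call. = FALSE)
  stopifnot(stride >= 1L, offset >= 0L)
  b_rec <- records[labels == "B"]
  nb_rec <- records[labels == "not-B"]
  means <- vapply(nb_rec, function(r) r$logbcf_mean, numeric(1L))
  ids <- vapply(nb_rec, function(r) r$id, character(1L))
  ord <- order(means, ids)
  sel_pos <- seq.int(offset + 1L, length(ord), by = stride)
  sel <- ord[sel_pos]
  list(subset = c(b_rec, nb_rec[sel]),
       leftover_notB = nb_rec[setdiff(ord, sel)])
}

#' Structure-based (Euclidean) split for classification
#'
#' Deterministic stand-in for the similarity-based partitioning used to
#' hold out 30% of the balanced subset: descriptors are standardized,
#' records of each class are ranked by Euclidean distance to their class
#' centroid, and every `round(1/fraction)`-th record along that ranking
#' goes to the prediction set, so both partitions cover each class's
#' structural range. Selection is truncated (or padded from the ranking)
#' so the prediction set has exactly `floor(fraction * n)` records, with
#' both classes represented in both partitions.
#'
#' @param X numeric feature matrix.
#' @param labels character vector (`B` / `not-B`), length `nrow(X)`.
#' @param fraction fraction of records for the prediction set (0 < f < 1).
#' @return a `split_plan`.
#' @export
euclidean_split <- function(X, labels, fraction = 0.30) {
  stopifnot(is.matrix(X) || is.data.frame(X))
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(labels) == n, fraction > 0, fraction < 1)
  classes <- unique(labels)
  if (any(table(labels) < 2L))
    stop("every class needs at least 2 members", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  sds[sds == 0] <- 1
  Z <- scale(X, center = TRUE, scale = sds)
  n_pred <- floor(fraction * n)
  stride <- max(2L, round(1 / fraction))

  # per-class centroid-distance ranking
  rank_of <- rep(NA_integer_, n)
  for (cl in classes) {
    idx <- which(labels == cl)
    centroid <- colMeans(Z[idx, , drop = FALSE])
    d <- sqrt(rowSums((Z[idx, , drop = FALSE] -
                         matrix(centroid, length(idx), ncol(Z),
                                byrow = TRUE))^2))
    rank_of[idx[order(d, idx)]] <- seq_along(idx)
  }
  # strided picks per class, proportional to class size
  pred <- integer(0)
  for (cl in classes) {
    idx <- which(labels == cl)
    ord <- idx[order(rank_of[idx])]
    take <- ord[seq_along(ord) %% stride == 0L]
    pred <- c(pred, take)
  }
  # trim or pad deterministically to exactly n_pred, keeping classes present
  pred <- pred[order(rank_of[pred], pred)]
  if (length(pred) > n_pred) pred <- pred[seq_len(n_pred)]
  else if (length(pred) < n_pred) {
    pool <- setdiff(order(rank_of, seq_len(n)), pred)
    pool <- pool[labels[pool] %in% classes]
    # never empty a class's training side
    extra <- integer(0)
    for (cand in pool) {
      if (length(pred) + length(extra) >= n_pred) break
      cl <- labels[cand]
      train_left <- sum(labels == cl) -
        sum(labels[c(pred, extra)] == cl) - 1L
      if (train_left >= 1L) extra <- c(extra, cand)
    }
    pred <- c(pred, extra)
  }
  for (cl in classes) {
    if (!any(labels[pred] == cl) || all(which(labels == cl) %in% pred))
      stop("class '", cl, "' not represented in both partitions",
           call. = FALSE)
  }
  split_plan(setdiff(seq_len(n), pred), pred, n)
}

#' Assemble a modelling dataset from records
#'
#' Computes the descriptor matrix for curated records and aligns it with
#' the mean responses and class labels.
#'
#' @param records list of `bcf_record` (unique ids).
#' @param exclude_ids ids to drop (e.g. a published outlier list).
#' @param smarts passed to [descriptor_matrix()].
#' @return a `bcf_dataset`: list with `records`, `X`, `y`, `labels`, `ids`.
#' @export
bcf_dataset <- function(records, exclude_ids = character(0),
                        smarts = list()) {
  ids <- vapply(records, function(r) r$id, character(1L))
  if (anyDuplicated(ids)) stop("duplicated ids; run average_replicates first",
                               call. = FALSE)
  keep <- !ids %in% exclude_ids
  records <- records[keep]
  ids <- ids[keep]
  X <- descriptor_matrix(records, smarts)
  structure(list(
    records = records, ids = ids, X = X,
    y = vapply(records, function(r) r$logbcf_mean, numeric(1L)),
    labels = vapply(records, function(r) r$class_label, character(1L))
  ), class = "bcf_dataset")
}

#' @export
print.bcf_dataset <- function(x, ...) {
  cat(sprintf("<bcf_dataset> %d chemicals, %d descriptors\n",
              length(x$records), ncol(x$X)))
  if (!all(is.na(x$labels)))
    cat(sprintf("  classes: %s\n",
                paste(names(table(x$labels)), table(x$labels),
                      sep = "=", collapse = ", ")))
  invisible(x)
}
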