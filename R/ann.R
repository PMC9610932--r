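# Multilayer perceptron trained by resilient backpropagation, replicating
# the neural-network settings used alongside the linear models.

#' ANN configuration
#'
#' Defaults follow the published settings: regression uses one hidden
#' layer of 10 neurons and 1000 iterations; classification uses one hidden
#' layer of 20 neurons and 250 iterations; the random seed defaults to 10.
#'
#' @param task `"regression"` or `"classification"`.
#' @param hidden_layers number of hidden layers (only 1 is supported).
#' @param neurons hidden neurons per layer.
#' @param iterations training epochs.
#' @param seed weight-initialization seed.
#' @return an `ann_config` list.
#' @export
ann_config <- function(task = c("regression", "classification"),
                       hidden_layers = 1L,
                       neurons = if (task == "regression") 10L else 20L,
                       iterations = if (task == "regression") 1000L else 250L,
                       seed = 10L) {
  task <- match.arg(task)
  stopifnot(hidden_layers == 1L, neurons >= 1L, iterations >= 1L)
  structure(list(task = task, hidden_layers = 1L,
                 neurons = as.integer(neurons),
                 iterations = as.integer(iterations), seed = seed),
            class = "ann_config")
}

#' Min-max response normalization
#'
#' Scales the numerical response between zero and one using the TRAINING
#' minimum and maximum only; the returned inverse restores the original
#' scale. Values outside the training range map outside [0, 1] and invert
#' correctly, as required when the trained net is applied externally.
#'
#' @param y numeric training response with `max(y) > min(y)`.
#' @return list with `y01`, `forward(v)`, `inverse(v01)`, `min`, `max`.
#' @export
normalize_response <- function(y) {
  lo <- min(y); hi <- max(y)
  if (hi <= lo) stop("constant response cannot be normalized", call. = FALSE)
  forward <- function(v) (v - lo) / (hi - lo)
  inverse <- function(v01) v01 * (hi - lo) + lo
  list(y01 = forward(y), forward = forward, inverse = inverse,
       min = lo, max = hi)
}

#' Train a one-hidden-layer MLP with resilient backpropagation
#'
#' Fully connected network with sigmoid hidden activations and a linear
#' (regression) or sigmoid (classification) output, trained full-batch by
#' sign-based resilient backpropagation: per-weight step sizes grow by
#' eta+ = 1.2 when the gradient keeps its sign and shrink by eta- = 0.5
#' when it flips, bounded in [1e-6, 50]. An improvement guard rejects an
#' epoch that would increase the loss (weights revert, step sizes shrink),
#' so the recorded training loss is non-increasing by construction.
#' Deterministic given the configuration and data.
#'
#' @param X numeric feature matrix; inputs are standardized internally.
#' @param y numeric response in [0, 1] for regression (see
#'   [normalize_response()]) or class labels for classification.
#' @param cfg an [ann_config()].
#' @return an `mlp_model` with weights, loss trace and scaling info.
#' @export
train_mlp <- function(X, y, cfg = ann_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(!is.finite(X))) stop("non-finite inputs", call. = FALSE)
  n <- nrow(X); p <- ncol(X); h <- cfg$neurons
  classification <- cfg$task == "classification"
  if (classification) {
    lv <- sort(unique(as.character(y)))
    if (length(lv) != 2L) stop("classification needs two classes",
                               call. = FALSE)
    positive <- if ("B" %in% lv) "B" else lv[2L]
    negative <- setdiff(lv, positive)
    target <- as.numeric(as.character(y) == positive)
  } else {
    target <- as.numeric(y)
    positive <- NULL; negative <- NULL
  }
  mu <- colMeans(X); sdv <- apply(X, 2L, stats::sd); sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, `/`)
  Z1 <- cbind(1, Z)

  sigmoid <- function(v) 1 / (1 + exp(-v))
  forward <- function(W1, W2) {
    H <- sigmoid(Z1 %*% W1)            # n x h
    H1 <- cbind(1, H)
    out <- drop(H1 %*% W2)
    if (classification) out <- sigmoid(out)
    list(H = H, H1 = H1, out = out)
  }
  loss_of <- function(out) mean((out - target)^2)

  eta_plus <- 1.2; eta_minus <- 0.5
  step_min <- 1e-6; step_max <- 50
  with_seed(cfg$seed, {
    W1 <- matrix(stats::runif((p + 1L) * h, -0.5, 0.5), p + 1L, h)
    W2 <- stats::runif(h + 1L, -0.5, 0.5)
    s1 <- matrix(0.1, p + 1L, h); s2 <- rep(0.1, h + 1L)
    g1_prev <- matrix(0, p + 1L, h); g2_prev <- rep(0, h + 1L)
    fw <- forward(W1, W2)
    loss <- loss_of(fw$out)
    trace <- numeric(cfg$iterations)
    for (it in seq_len(cfg$iterations)) {
      err <- fw$out - target                       # n
      dout <- if (classification) err * fw$out * (1 - fw$out) else err
      g2 <- drop(crossprod(fw$H1, dout)) * (2 / n)
      dh <- (dout %*% t(W2[-1L])) * fw$H * (1 - fw$H)
      g1 <- crossprod(Z1, dh) * (2 / n)
      upd <- function(g, g_prev, s) {
        sgn <- sign(g * g_prev)
        s <- ifelse(sgn > 0, pmin(s * eta_plus, step_max),
                    ifelse(sgn < 0, pmax(s * eta_minus, step_min), s))
        list(delta = -sign(g) * s, s = s)
      }
      u1 <- upd(g1, g1_prev, s1); u2 <- upd(g2, g2_prev, s2)
      W1_new <- W1 + u1$delta; W2_new <- W2 + u2$delta
      fw_new <- forward(W1_new, W2_new)
      loss_new <- loss_of(fw_new$out)
      if (!is.finite(loss_new))
        stop("training diverged at iteration ", it, call. = FALSE)
      if (loss_new <= loss) {
        W1 <- W1_new; W2 <- W2_new
        s1 <- u1$s; s2 <- u2$s
        g1_prev <- g1; g2_prev <- g2
        fw <- fw_new; loss <- loss_new
      } else {
        # improvement guard: reject the step, shrink all step sizes
        s1 <- pmax(s1 * eta_minus, step_min)
        s2 <- pmax(s2 * eta_minus, step_min)
        g1_prev <- matrix(0, p + 1L, h); g2_prev <- rep(0, h + 1L)
      }
      trace[it] <- loss
    }
    structure(list(W1 = W1, W2 = W2, mu = mu, sd = sdv,
                   task = cfg$task, positive = positive,
                   negative = negative,
                   loss_trace = trace, config = cfg, vars = colnames(X)),
              class = "mlp_model")
  })
}

#' @export
predict.mlp_model <- function(object, newdata, type = c("response", "class"),
                              ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (!is.null(colnames(X)) && all(object$vars %in% colnames(X)))
    X <- X[, object$vars, drop = FALSE]
  Z1 <- cbind(1, sweep(sweep(X, 2L, object$mu), 2L, object$sd, `/`))
  H1 <- cbind(1, 1 / (1 + exp(-(Z1 %*% object$W1))))
  out <- drop(H1 %*% object$W2)
  if (object$task == "classification") {
    post <- 1 / (1 + exp(-out))
    if (type == "class")
      return(ifelse(post > 0.5, object$positive, object$negative))
    return(post)
  }
  out
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %s: %d inputs, %d hidden neurons, %d epochs, final loss %.4g\n",
              x$task, length(x$vars), ncol(x$W1),
              length(x$loss_trace), x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}
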