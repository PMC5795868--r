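#' One-hot encode cluster-index pattern rows
#'
#' Each channel's cluster index in `[0, K-1]` becomes a K-length indicator
#' block, giving `n_channels * K` binary inputs per window — the input
#' encoding of the pattern classifier.
#'
#' @param indices Integer matrix (windows x channels) of cluster indices.
#' @param K Mixture size the indices refer to.
#' @return Numeric matrix `n_windows x (n_channels * K)`.
#' @export
encode_onehot <- function(indices, K = attr(indices, "K")) {
  if (is.null(K)) stop("K must be supplied")
  n <- nrow(indices); nc <- ncol(indices)
  if (any(indices < 0 | indices >= K))
    stop("cluster index outside [0, K-1]")
  X <- matrix(0, n, nc * K)
  for (c in seq_len(nc))
    X[cbind(seq_len(n), (c - 1L) * K + indices[, c] + 1L)] <- 1
  X
}

#' Train the spatial-pattern motion classifier
#'
#' A single-hidden-layer feed-forward network (tanh hidden units, softmax
#' output) trained by seeded mini-batch gradient descent on the cross-entropy
#' loss, taking one-hot encoded cluster-index patterns as input.  Identical
#' data and seed reproduce identical weights.
#'
#' @param indices Integer matrix (windows x channels) of cluster indices,
#'   e.g. from [discretize()].
#' @param labels Per-window class labels (factor or character); taken from
#'   the `"labels"` attribute of `indices` when omitted.
#' @param K Mixture size (attribute `"K"` of `indices` when omitted).
#' @param hidden Hidden-layer size (default 20).
#' @param epochs Training epochs (default 60).
#' @param lr Learning rate (default 0.2).
#' @param batch_size Mini-batch size (default 64).
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return An object of class `pattern_net`: weight matrices `W1`, `b1`,
#'   `W2`, `b2`, the class levels, `K`, `n_channels`, and the per-epoch
#'   full-data cross-entropy in `loss`.
#' @export
train_classifier <- function(indices, labels = attr(indices, "labels"),
                             K = attr(indices, "K"), hidden = 20,
                             epochs = 60, lr = 0.2, batch_size = 64,
                             seed = 0L) {
  if (is.null(labels)) stop("labels are required")
  labels <- droplevels(as.factor(labels))
  M <- nlevels(labels)
  if (M < 2) stop("training needs at least two classes")
  tab <- table(labels)
  if (min(tab) < 10)
    stop("class '", names(tab)[which.min(tab)],
         "' has fewer than 10 examples")
  X <- encode_onehot(indices, K)
  n <- nrow(X); d <- ncol(X)
  Y <- matrix(0, n, M)
  Y[cbind(seq_len(n), as.integer(labels))] <- 1

  set.seed(seed)
  W1 <- matrix(stats::rnorm(d * hidden, sd = 1 / sqrt(d)), d, hidden)
  b1 <- numeric(hidden)
  # zero output layer: training is then exactly equivariant under a
  # permutation of the class order (scores permute, nothing else changes)
  W2 <- matrix(0, hidden, M)
  b2 <- numeric(M)

  softmax <- function(Z) {
    Z <- Z - apply(Z, 1, max)
    E <- exp(Z)
    E / rowSums(E)
  }
  full_loss <- function() {
    H <- tanh(sweep(X %*% W1, 2, b1, "+"))
    P <- softmax(sweep(H %*% W2, 2, b2, "+"))
    -mean(log(pmax(rowSums(P * Y), 1e-300)))
  }

  loss <- numeric(epochs)
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    for (s in seq(1, n, by = batch_size)) {
      i <- ord[s:min(s + batch_size - 1, n)]
      Xb <- X[i, , drop = FALSE]; Yb <- Y[i, , drop = FALSE]
      H <- tanh(sweep(Xb %*% W1, 2, b1, "+"))
      P <- softmax(sweep(H %*% W2, 2, b2, "+"))
      G2 <- (P - Yb) / length(i)               # dL/dZ2
      dW2 <- crossprod(H, G2)
      db2 <- colSums(G2)
      G1 <- (G2 %*% t(W2)) * (1 - H^2)         # dL/dZ1
      dW1 <- crossprod(Xb, G1)
      db1 <- colSums(G1)
      W2 <- W2 - lr * dW2; b2 <- b2 - lr * db2
      W1 <- W1 - lr * dW1; b1 <- b1 - lr * db1
    }
    loss[e] <- full_loss()
    if (!is.finite(loss[e]))
      stop("non-finite training loss at epoch ", e)
  }

  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 classes = levels(labels), K = K,
                 n_channels = ncol(indices), hidden = hidden,
                 loss = loss, seed = seed, epochs = epochs, lr = lr,
                 batch_size = batch_size),
            class = "pattern_net")
}

#' @export
print.pattern_net <- function(x, ...) {
  cat(sprintf(
    "pattern_net: %d-ch x K=%d one-hot -> %d tanh -> %d softmax\n",
    x$n_channels, x$K, x$hidden, length(x$classes)))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  final training cross-entropy: %.4g (%d epochs)\n",
              x$loss[length(x$loss)], length(x$loss)))
  invisible(x)
}

#' @export
plot.pattern_net <- function(x, ...) {
  graphics::plot(seq_along(x$loss), x$loss, type = "l",
                 xlab = "epoch", ylab = "cross-entropy",
                 main = "pattern_net training loss")
  invisible(x)
}

#' Predict motions from pattern rows
#'
#' @param object A [train_classifier()] fit.
#' @param indices Integer matrix (windows x channels) of cluster indices
#'   with the same channel count and K as the training data.
#' @param type `"class"` for labels (ties toward the earlier class order)
#'   or `"prob"` for the per-window class scores (rows sum to 1).
#' @param ... Unused.
#' @return Factor of predicted labels, or a score matrix.
#' @export
predict.pattern_net <- function(object, indices,
                                type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (ncol(indices) != object$n_channels)
    stop("indices have ", ncol(indices), " channels; model expects ",
         object$n_channels)
  X <- encode_onehot(indices, object$K)
  H <- tanh(sweep(X %*% object$W1, 2, object$b1, "+"))
  Z <- sweep(H %*% object$W2, 2, object$b2, "+")
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z) / rowSums(exp(Z))
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

#' Nearest-centroid baseline classifier
#'
#' Classifies a pattern row by the nearest class centroid in one-hot space —
#' a sanity baseline for the network.
#'
#' @inheritParams train_classifier
#' @return An object of class `pattern_centroid` with a `predict` method.
#' @export
centroid_classifier <- function(indices, labels = attr(indices, "labels"),
                                K = attr(indices, "K")) {
  labels <- droplevels(as.factor(labels))
  X <- encode_onehot(indices, K)
  cent <- t(vapply(levels(labels), function(m)
    colMeans(X[labels == m, , drop = FALSE]), numeric(ncol(X))))
  structure(list(centroids = cent, classes = levels(labels), K = K,
                 n_channels = ncol(indices)),
            class = "pattern_centroid")
}

#' @export
predict.pattern_centroid <- function(object, indices, ...) {
  X <- encode_onehot(indices, object$K)
  d2 <- outer(rowSums(X^2), rowSums(object$centroids^2), "+") -
    2 * X %*% t(object$centroids)
  factor(object$classes[max.col(-d2, ties.method = "first")],
         levels = object$classes)
}

#' Majority-vote smoothing of a decision stream
#'
#' Replaces each decision by the modal label of the trailing `vote_span`
#' decisions (a causal window, so usable online).  Ties keep the previous
#' smoothed output; a tie at the very first window falls back to the
#' earliest class in the level order.  Output length equals input length.
#'
#' @param labels Factor or character vector of per-window decisions.
#' @param vote_span Odd window length in decisions (default 41, about 205 ms
#'   at a 5 ms step).
#' @return Smoothed labels (factor with the input's levels).
#' @export
majority_vote <- function(labels, vote_span = 41) {
  if (vote_span < 1) stop("vote_span must be >= 1")
  if (vote_span %% 2 == 0) stop("vote_span must be odd")
  f <- if (is.factor(labels)) labels else factor(labels,
                                                 levels = unique(labels))
  code <- as.integer(f)
  nl <- nlevels(f)
  n <- length(code)
  out <- integer(n)
  counts <- integer(nl)
  for (t in seq_len(n)) {
    counts[code[t]] <- counts[code[t]] + 1L
    if (t > vote_span) {
      old <- code[t - vote_span]
      counts[old] <- counts[old] - 1L
    }
    mx <- max(counts)
    win <- which(counts == mx)
    out[t] <- if (length(win) == 1L) win
    else if (t > 1L && out[t - 1L] %in% win) out[t - 1L]
    else win[1L]
  }
  factor(levels(f)[out], levels = levels(f))
}

#' Confusion matrix and accuracy
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Optional class set; defaults to the union of levels.
#' @return An object of class `semg_eval`: `confusion` (rows = truth,
#'   columns = predicted), `accuracy`, `per_class` accuracy (recall), `n`.
#' @export
evaluate <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted))
    stop("truth and predicted have different lengths (",
         length(truth), " vs ", length(predicted), ")")
  if (is.null(classes))
    classes <- union(levels(as.factor(truth)), levels(as.factor(predicted)))
  bad <- setdiff(unique(c(as.character(truth), as.character(predicted))),
                 classes)
  if (length(bad)) stop("label outside the class set: ", bad[1])
  t <- factor(as.character(truth), levels = classes)
  p <- factor(as.character(predicted), levels = classes)
  cm <- table(truth = t, predicted = p)
  per <- diag(cm) / pmax(rowSums(cm), 1L)
  structure(list(confusion = cm,
                 accuracy = sum(diag(cm)) / length(t),
                 per_class = per, n = length(t)),
            class = "semg_eval")
}

#' @export
print.semg_eval <- function(x, ...) {
  cat(sprintf("semg_eval: overall accuracy %.4f on %d windows\n",
              x$accuracy, x$n))
  print(x$confusion)
  cat("per-class accuracy:\n")
  print(round(x$per_class, 4))
  invisible(x)
}
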