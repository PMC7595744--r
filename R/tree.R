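# Single CART classification tree, grown to purity with Gini impurity and
# a random feature subset evaluated at each node (the bagged-ensemble base
# learner). Ties are broken deterministically: lowest feature index, then
# lowest threshold; leaf votes tie-break to the lowest class index.

# best split of one feature column: returns list(score, threshold) or NULL
.best_split_feature <- function(x, y, n_class) {
  ord <- order(x, method = "radix")
  xs <- x[ord]
  ys <- y[ord]
  n <- length(xs)
  valid <- which(xs[-n] < xs[-1])  # split between distinct values only
  if (!length(valid)) return(NULL)
  cum <- matrix(0, n, n_class)
  for (k in seq_len(n_class)) cum[, k] <- cumsum(ys == k)
  tot <- cum[n, ]
  nl <- valid
  nr <- n - nl
  cl <- cum[valid, , drop = FALSE]
  cr <- rep(tot, each = length(valid)) - cl
  dim(cr) <- dim(cl)
  gini_l <- 1 - rowSums((cl / nl)^2)
  gini_r <- 1 - rowSums((cr / nr)^2)
  score <- nl * gini_l + nr * gini_r
  best <- which.min(score)  # first minimum = lowest threshold
  list(score = score[best],
       threshold = (xs[valid[best]] + xs[valid[best] + 1]) / 2)
}

#' Grow a single classification tree
#'
#' CART with Gini impurity: at each node `m_try` randomly chosen features
#' are evaluated and the split minimizing the weighted child impurity is
#' taken; nodes are grown until pure or containing fewer than 2 samples.
#' Tie-breaks (equal-score splits, leaf vote ties) are deterministic so a
#' tree is fully reproducible from the RNG state.
#'
#' @param x Numeric feature matrix (rows = subjects).
#' @param y Integer class vector (1..K) or factor.
#' @param m_try Features tried per node; default `ceiling(sqrt(ncol(x)))`.
#' @param n_class Number of classes.
#' @return Object of class `decision_tree`: parallel node vectors
#'   `feature`, `threshold`, `left`, `right`, `pred` (-1 feature marks a
#'   leaf; `pred` is the leaf class).
#' @export
grow_tree <- function(x, y, m_try = ceiling(sqrt(ncol(x))),
                      n_class = max(as.integer(y))) {
  y <- as.integer(y)
  p <- ncol(x)
  feature <- integer(0); threshold <- numeric(0)
  left <- integer(0); right <- integer(0); pred <- integer(0)
  new_node <- function() {
    feature[length(feature) + 1L] <<- -1L
    threshold[length(threshold) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- 0L
    right[length(right) + 1L] <<- 0L
    pred[length(pred) + 1L] <<- 0L
    length(feature)
  }
  build <- function(idx) {
    node <- new_node()
    ys <- y[idx]
    counts <- tabulate(ys, n_class)
    if (length(idx) < 2L || sum(counts > 0L) == 1L) {
      pred[node] <<- which.max(counts)  # tie -> lowest class index
      return(node)
    }
    feats <- sort(sample.int(p, min(m_try, p)))
    best <- NULL
    for (f in feats) {
      cand <- .best_split_feature(x[idx, f], ys, n_class)
      if (!is.null(cand) &&
          (is.null(best) || cand$score < best$score - 1e-12)) {
        best <- cand
        best$feature <- f
      }
    }
    if (is.null(best)) {  # all tried features constant on this node
      pred[node] <<- which.max(counts)
      return(node)
    }
    go_left <- x[idx, best$feature] <= best$threshold
    feature[node] <<- best$feature
    threshold[node] <<- best$threshold
    l <- build(idx[go_left])
    r <- build(idx[!go_left])
    left[node] <<- l
    right[node] <<- r
    node
  }
  build(seq_len(nrow(x)))
  structure(list(feature = feature, threshold = threshold, left = left,
                 right = right, pred = pred, n_class = n_class),
            class = "decision_tree")
}

#' Predict classes with a single tree
#' @param object A `decision_tree`.
#' @param newdata Numeric feature matrix.
#' @param ... Unused.
#' @return Integer class predictions (1..K).
#' @export
predict.decision_tree <- function(object, newdata, ...) {
  n <- nrow(newdata)
  out <- integer(n)
  for (i in seq_len(n)) {
    node <- 1L
    while (object$feature[node] != -1L) {
      node <- if (newdata[i, object$feature[node]] <= object$threshold[node]) {
        object$left[node]
      } else {
        object$right[node]
      }
    }
    out[i] <- object$pred[node]
  }
  out
}
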