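# In-package classifiers backing cv_classifiers. The environment ships no
# random-forest or naive-Bayes implementation, so a compact, seedable
# version of each is provided here: a bagged forest of Gini-grown
# classification trees (mtry random features per node, grown to purity)
# and a Gaussian naive Bayes. Scores are class-1 probabilities suitable
# for AUC ranking.

rf_fit <- function(X, y, ntree = 100, mtry = max(1L, floor(sqrt(ncol(X)))),
                   min_node = 1L, max_depth = 25L) {
  stopifnot(is.matrix(X), is.logical(y), nrow(X) == length(y))
  trees <- vector("list", ntree)
  n <- nrow(X)
  for (t in seq_len(ntree)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- grow_tree(X, as.numeric(y), idx, mtry, min_node, max_depth)
  }
  structure(list(trees = trees, mtry = mtry), class = "rnvg_rf")
}

rf_predict <- function(fit, X) {
  stopifnot(inherits(fit, "rnvg_rf"))
  preds <- vapply(fit$trees, function(tr) predict_tree(tr, X),
                  numeric(nrow(X)))
  if (nrow(X) == 1L) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

grow_tree <- function(X, y, idx, mtry, min_node, depth_left) {
  yv <- y[idx]
  p1 <- mean(yv)
  if (length(idx) <= min_node || p1 == 0 || p1 == 1 || depth_left <= 0) {
    return(list(leaf = TRUE, prob = p1))
  }
  feats <- sample.int(ncol(X), mtry)
  best <- NULL
  best_score <- Inf
  for (f in feats) {
    v <- X[idx, f]
    o <- order(v)
    vs <- v[o]; ys <- yv[o]
    n <- length(vs)
    cut_ok <- vs[-n] < vs[-1]
    if (!any(cut_ok)) next
    c1 <- cumsum(ys)[-n]
    nl <- seq_len(n - 1)
    nr <- n - nl
    pl <- c1 / nl
    pr <- (sum(ys) - c1) / nr
    gini <- nl * pl * (1 - pl) + nr * pr * (1 - pr)  # scaled by n/2
    gini[!cut_ok] <- Inf
    j <- which.min(gini)
    if (gini[j] < best_score) {
      best_score <- gini[j]
      best <- list(feat = f, thr = (vs[j] + vs[j + 1]) / 2)
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, prob = p1))
  left <- idx[X[idx, best$feat] <= best$thr]
  right <- idx[X[idx, best$feat] > best$thr]
  if (!length(left) || !length(right)) return(list(leaf = TRUE, prob = p1))
  list(leaf = FALSE, feat = best$feat, thr = best$thr,
       left = grow_tree(X, y, left, mtry, min_node, depth_left - 1L),
       right = grow_tree(X, y, right, mtry, min_node, depth_left - 1L))
}

predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  route <- function(node, rows) {
    if (!length(rows)) return()
    if (node$leaf) {
      out[rows] <<- node$prob
      return()
    }
    go_left <- X[rows, node$feat] <= node$thr
    route(node$left, rows[go_left])
    route(node$right, rows[!go_left])
  }
  route(tree, seq_len(nrow(X)))
  out
}

nb_fit <- function(X, y) {
  stopifnot(is.matrix(X), is.logical(y))
  sd_floor <- 1e-6
  stats_for <- function(rows) {
    list(mean = colMeans(X[rows, , drop = FALSE]),
         sd = pmax(apply(X[rows, , drop = FALSE], 2, sd), sd_floor))
  }
  structure(list(pos = stats_for(y), neg = stats_for(!y),
                 prior = mean(y)), class = "rnvg_nb")
}

nb_predict <- function(fit, X) {
  stopifnot(inherits(fit, "rnvg_nb"))
  ll <- function(st) {
    m <- matrix(0, nrow(X), ncol(X))
    for (j in seq_len(ncol(X))) {
      m[, j] <- dnorm(X[, j], st$mean[j], st$sd[j], log = TRUE)
    }
    rowSums(m)
  }
  lp <- ll(fit$pos) + log(fit$prior)
  ln <- ll(fit$neg) + log(1 - fit$prior)
  1 / (1 + exp(ln - lp))
}
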