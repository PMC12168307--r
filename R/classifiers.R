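# The 13 classifier families of the model grid. Eight follow the named
# methods (logistic regression, random forest, GBDT, KNN, PLS-DA, QDA,
# SGD-logistic, linear SVM) and five are conventional additions (decision
# tree, extra trees, AdaBoost, Gaussian naive Bayes, LDA). glm and MASS
# provide logistic/LDA/QDA; the tree ensembles, KNN, PLS, SGD and SVM are
# implemented here because no tree/kernel package is available in the
# dependency closure. All learners expose fit(x, y01, seed) -> model and
# score(model, x) -> numeric (larger = more class-1); hyperparameters are
# fixed (no inner tuning).

CLASSIFIER_NAMES <- c("logistic", "random_forest", "gbdt", "knn", "plsda",
                      "qda", "sgd", "svm_linear", "decision_tree",
                      "extra_trees", "adaboost", "naive_bayes", "lda")

## ---- small CART-style tree ------------------------------------------------

# Recursive axis-aligned binary tree. criterion: weighted gini (classification
# on y in {0,1}) or variance (regression). mtry features per node; random
# splits draw one uniform threshold per candidate feature (extra-trees style).
grow_tree <- function(x, y, w, depth, min_leaf, mtry, random_split, regression) {
  n <- length(y)
  node_value <- sum(w * y) / sum(w)
  if (depth == 0L || n < 2L * min_leaf ||
      (!regression && (node_value == 0 || node_value == 1))) {
    return(list(leaf = TRUE, value = node_value))
  }
  p <- ncol(x)
  feats <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
  best <- list(score = -Inf)
  parent_imp <- if (regression) {
    sum(w * (y - node_value)^2)
  } else {
    sum(w) * node_value * (1 - node_value)
  }
  for (j in feats) {
    xs <- x[, j]
    ux <- unique(xs)
    if (length(ux) < 2L) next
    thr <- if (random_split) {
      stats::runif(1, min(xs), max(xs))
    } else {
      ord <- order(xs)
      mids <- (xs[ord][-1] + xs[ord][-n]) / 2
      mids <- unique(mids[diff(xs[ord]) > 0])
      if (length(mids) > 24L) mids <- stats::quantile(mids, seq(0.02, 0.98, length.out = 24L), names = FALSE)
      mids
    }
    for (tv in thr) {
      left <- xs <= tv
      nl <- sum(left); nr <- n - nl
      if (nl < min_leaf || nr < min_leaf) next
      wl <- sum(w[left]); wr <- sum(w[!left])
      if (wl <= 0 || wr <= 0) next
      ml <- sum(w[left] * y[left]) / wl
      mr <- sum(w[!left] * y[!left]) / wr
      imp <- if (regression) {
        sum(w[left] * (y[left] - ml)^2) + sum(w[!left] * (y[!left] - mr)^2)
      } else {
        wl * ml * (1 - ml) + wr * mr * (1 - mr)
      }
      gain <- parent_imp - imp
      if (gain > best$score) best <- list(score = gain, j = j, thr = tv, left = left)
    }
  }
  if (!is.finite(best$score) || best$score <= 1e-12) {
    return(list(leaf = TRUE, value = node_value))
  }
  l <- best$left
  list(leaf = FALSE, j = best$j, thr = best$thr,
       left = grow_tree(x[l, , drop = FALSE], y[l], w[l], depth - 1L, min_leaf,
                        mtry, random_split, regression),
       right = grow_tree(x[!l, , drop = FALSE], y[!l], w[!l], depth - 1L,
                         min_leaf, mtry, random_split, regression))
}

predict_tree <- function(tree, x) {
  out <- numeric(nrow(x))
  rec <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (node$leaf) { out[idx] <<- node$value; return() }
    l <- x[idx, node$j] <= node$thr
    rec(node$left, idx[l]); rec(node$right, idx[!l])
  }
  rec(tree, seq_len(nrow(x)))
  out
}

## ---- individual learners --------------------------------------------------

fit_logistic <- function(x, y, seed) {
  fit <- suppressWarnings(stats::glm.fit(cbind(1, x), y, family = stats::binomial()))
  co <- fit$coefficients
  co[is.na(co)] <- 0
  list(coef = co)
}
score_logistic <- function(m, x) as.vector(stats::plogis(cbind(1, x) %*% m$coef))

fit_lda <- function(x, y, seed) MASS::lda(x, grouping = factor(y))
score_lda <- function(m, x) as.vector(stats::predict(m, x)$posterior[, "1"])

fit_qda <- function(x, y, seed) MASS::qda(x, grouping = factor(y))
score_qda <- function(m, x) as.vector(stats::predict(m, x)$posterior[, "1"])

fit_nb <- function(x, y, seed) {
  list(mu0 = colMeans(x[y == 0, , drop = FALSE]),
       mu1 = colMeans(x[y == 1, , drop = FALSE]),
       sd0 = pmax(apply(x[y == 0, , drop = FALSE], 2, stats::sd), 1e-6),
       sd1 = pmax(apply(x[y == 1, , drop = FALSE], 2, stats::sd), 1e-6),
       prior1 = mean(y))
}
score_nb <- function(m, x) {
  ll1 <- rowSums(sweep(stats::dnorm(sweep(sweep(x, 2, m$mu1), 2, m$sd1, "/"),
                                    log = TRUE), 2, log(m$sd1), "-")) + log(m$prior1)
  ll0 <- rowSums(sweep(stats::dnorm(sweep(sweep(x, 2, m$mu0), 2, m$sd0, "/"),
                                    log = TRUE), 2, log(m$sd0), "-")) + log(1 - m$prior1)
  as.vector(stats::plogis(ll1 - ll0))
}

fit_knn <- function(x, y, seed) list(x = x, y = y, k = 5L)
score_knn <- function(m, x) {
  k <- min(m$k, nrow(m$x))
  d2 <- outer(rowSums(x^2), rep(1, nrow(m$x))) +
    outer(rep(1, nrow(x)), rowSums(m$x^2)) - 2 * x %*% t(m$x)
  apply(d2, 1, function(dd) mean(m$y[order(dd)[seq_len(k)]]))
}

fit_plsda <- function(x, y, seed) {
  # NIPALS PLS1 on centred data, up to 2 components
  yc <- y - mean(y)
  xc <- sweep(x, 2, colMeans(x))
  ncomp <- min(2L, ncol(x), nrow(x) - 1L)
  W <- P <- matrix(0, ncol(x), ncomp); qv <- numeric(ncomp)
  Xr <- xc; yr <- yc
  for (h in seq_len(ncomp)) {
    w <- as.vector(t(Xr) %*% yr)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- h - 1L; break }
    w <- w / nw
    t_ <- as.vector(Xr %*% w)
    tt <- sum(t_^2)
    p_ <- as.vector(t(Xr) %*% t_) / tt
    q_ <- sum(yr * t_) / tt
    W[, h] <- w; P[, h] <- p_; qv[h] <- q_
    Xr <- Xr - outer(t_, p_); yr <- yr - q_ * t_
  }
  if (ncomp == 0L) return(list(beta = rep(0, ncol(x)), x_mean = colMeans(x),
                               y_mean = mean(y)))
  W <- W[, seq_len(ncomp), drop = FALSE]; P <- P[, seq_len(ncomp), drop = FALSE]
  beta <- W %*% solve(t(P) %*% W, qv[seq_len(ncomp)])
  list(beta = as.vector(beta), x_mean = colMeans(x), y_mean = mean(y))
}
score_plsda <- function(m, x) {
  as.vector(sweep(x, 2, m$x_mean) %*% m$beta) + m$y_mean
}

fit_sgd <- function(x, y, seed) {
  # full-batch gradient descent on logistic loss (deterministic)
  xb <- cbind(1, x)
  w <- rep(0, ncol(xb))
  lr <- 0.5
  for (it in seq_len(300L)) {
    p <- stats::plogis(as.vector(xb %*% w))
    g <- as.vector(t(xb) %*% (p - y)) / nrow(xb)
    w <- w - lr * g
  }
  list(coef = w)
}
score_sgd <- function(m, x) as.vector(stats::plogis(cbind(1, x) %*% m$coef))

fit_svm <- function(x, y, seed) {
  # Pegasos primal sub-gradient solver for the linear soft-margin SVM
  yy <- ifelse(y == 1, 1, -1)
  lambda <- 0.01
  w <- rep(0, ncol(x)); b <- 0
  with_seed(seed, {
    for (t in seq_len(4000L)) {
      i <- sample.int(nrow(x), 1L)
      eta <- 1 / (lambda * t)
      marg <- yy[i] * (sum(w * x[i, ]) + b)
      w <- (1 - eta * lambda) * w
      if (marg < 1) {
        w <- w + eta * yy[i] * x[i, ]
        b <- b + eta * yy[i]
      }
    }
  })
  list(w = w, b = b)
}
score_svm <- function(m, x) as.vector(x %*% m$w + m$b)

fit_decision_tree <- function(x, y, seed) {
  with_seed(seed, grow_tree(x, y, rep(1, length(y)), 3L, 5L, ncol(x), FALSE, FALSE))
}
score_decision_tree <- function(m, x) predict_tree(m, x)

fit_forest <- function(x, y, seed, n_trees, random_split, bootstrap) {
  mtry <- max(1L, ceiling(sqrt(ncol(x))))
  with_seed(seed, {
    lapply(seq_len(n_trees), function(i) {
      idx <- if (bootstrap) sample.int(nrow(x), replace = TRUE) else seq_len(nrow(x))
      grow_tree(x[idx, , drop = FALSE], y[idx], rep(1, length(idx)), 4L, 2L,
                mtry, random_split, FALSE)
    })
  })
}
fit_random_forest <- function(x, y, seed) fit_forest(x, y, seed, 60L, FALSE, TRUE)
fit_extra_trees <- function(x, y, seed) fit_forest(x, y, seed, 60L, TRUE, FALSE)
score_forest <- function(m, x) rowMeans(vapply(m, predict_tree, numeric(nrow(x)), x = x))

fit_gbdt <- function(x, y, seed) {
  # gradient boosting with depth-2 regression trees on the logistic gradient
  nu <- 0.1
  f0 <- stats::qlogis(pmin(pmax(mean(y), 0.05), 0.95))
  fx <- rep(f0, length(y))
  trees <- vector("list", 50L)
  with_seed(seed, {
    for (b in seq_len(50L)) {
      resid <- y - stats::plogis(fx)
      tr <- grow_tree(x, resid, rep(1, length(y)), 2L, 3L, ncol(x), FALSE, TRUE)
      trees[[b]] <- tr
      fx <- fx + nu * predict_tree(tr, x)
    }
  })
  list(f0 = f0, nu = nu, trees = trees)
}
score_gbdt <- function(m, x) {
  fx <- rep(m$f0, nrow(x))
  for (tr in m$trees) fx <- fx + m$nu * predict_tree(tr, x)
  as.vector(stats::plogis(fx))
}

fit_adaboost <- function(x, y, seed) {
  # SAMME with depth-1 stumps; weighted gini splits
  yy <- ifelse(y == 1, 1, -1)
  n <- length(y)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric()
  with_seed(seed, {
    for (b in seq_len(40L)) {
      st <- grow_tree(x, y, w, 1L, 1L, ncol(x), FALSE, FALSE)
      pred <- ifelse(predict_tree(st, x) >= 0.5, 1, -1)
      err <- sum(w[pred != yy])
      if (err >= 0.5 || err <= 1e-10) {
        if (err <= 1e-10) { stumps[[b]] <- st; alphas[b] <- 5 }
        break
      }
      a <- 0.5 * log((1 - err) / err)
      stumps[[b]] <- st; alphas[b] <- a
      w <- w * exp(-a * yy * pred)
      w <- w / sum(w)
    }
  })
  list(stumps = stumps, alphas = alphas)
}
score_adaboost <- function(m, x) {
  if (length(m$stumps) == 0L) return(rep(0, nrow(x)))
  s <- rep(0, nrow(x))
  for (b in seq_along(m$stumps)) {
    s <- s + m$alphas[b] * ifelse(predict_tree(m$stumps[[b]], x) >= 0.5, 1, -1)
  }
  s
}

## ---- dispatch --------------------------------------------------------------

#' Fit one of the 13 grid classifiers
#'
#' @param name classifier name (see `CLASSIFIER_NAMES`).
#' @param x numeric matrix (train).
#' @param y01 0/1 labels.
#' @param seed RNG seed for stochastic learners.
#' @return opaque model object for [score_classifier()].
#' @export
fit_classifier <- function(name, x, y01, seed = 1L) {
  fn <- switch(name,
               logistic = fit_logistic, random_forest = fit_random_forest,
               gbdt = fit_gbdt, knn = fit_knn, plsda = fit_plsda,
               qda = fit_qda, sgd = fit_sgd, svm_linear = fit_svm,
               decision_tree = fit_decision_tree, extra_trees = fit_extra_trees,
               adaboost = fit_adaboost, naive_bayes = fit_nb, lda = fit_lda,
               stop("unknown classifier: ", name))
  structure(list(name = name, model = fn(x, y01, seed)), class = "renalrad_clf")
}

#' Score a fitted grid classifier
#'
#' @param clf object from [fit_classifier()].
#' @param x numeric matrix (test).
#' @return numeric scores, larger meaning more likely class 1.
#' @export
score_classifier <- function(clf, x) {
  fn <- switch(clf$name,
               logistic = score_logistic, random_forest = score_forest,
               gbdt = score_gbdt, knn = score_knn, plsda = score_plsda,
               qda = score_qda, sgd = score_sgd, svm_linear = score_svm,
               decision_tree = score_decision_tree, extra_trees = score_forest,
               adaboost = score_adaboost, naive_bayes = score_nb, lda = score_lda)
  fn(clf$model, x)
}
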