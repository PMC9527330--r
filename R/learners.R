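## Base learners for the soft-voting ensemble. No SVM or tree library is
## assumed: the SVM is a least-squares SVM (RBF kernel, one-vs-rest, solved
## as a regularized linear system) with Platt-style probability calibration,
## and the boosted trees are an own weighted CART-style learner driven by
## SAMME. Logistic regression is ridge-penalized multinomial glmnet.

## ---- feature scaling (training-fold statistics only) ----------------------

fit_scaler <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(mean = m, sd = s)
}

apply_scaler <- function(scaler, x) {
  sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, "/")
}

## ---- RBF kernel ------------------------------------------------------------

rbf_kernel <- function(x, y = x, gamma) {
  sq <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  exp(-gamma * pmax(sq, 0))
}

resolve_gamma <- function(gamma, x) {
  if (identical(gamma, "scale")) {
    v <- stats::var(as.vector(x))
    if (!is.finite(v) || v < 1e-12) v <- 1
    1 / (ncol(x) * v)
  } else as.numeric(gamma)
}

## ---- least-squares SVM -----------------------------------------------------

## One-vs-rest LS-SVM: for each class solve
##   [ 0   1'      ] [b    ]   [0]
##   [ 1   K + D/C ] [alpha] = [y]
## with y in {-1,+1} and D = diag(1/obs_w). Platt sigmoids fitted on the
## training decision values give calibrated per-class probabilities which
## are then normalized to a probability vector.
lssvm_fit <- function(x, y, C = 1, gamma = "scale", obs_w = NULL) {
  y <- droplevels(as.factor(y))
  classes <- levels(y)
  if (length(classes) < 2) stopf("single-class training set")
  n <- nrow(x)
  g <- resolve_gamma(gamma, x)
  K <- rbf_kernel(x, gamma = g)
  d <- if (is.null(obs_w)) rep(1 / C, n) else 1 / (C * obs_w)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(d, n)))
  Y <- vapply(classes, function(cl) ifelse(y == cl, 1, -1), numeric(n))
  sol <- solve(A, rbind(0, Y))
  b <- sol[1, ]; alpha <- sol[-1, , drop = FALSE]
  f_train <- K %*% alpha + matrix(b, n, length(classes), byrow = TRUE)
  platt <- lapply(seq_along(classes), function(k)
    platt_fit(f_train[, k], y == classes[k]))
  structure(list(x = x, alpha = alpha, b = b, gamma = g,
                 classes = classes, platt = platt),
            class = "fferg_lssvm")
}

lssvm_predict <- function(model, newx) {
  K <- rbf_kernel(newx, model$x, model$gamma)
  f <- K %*% model$alpha +
    matrix(model$b, nrow(newx), length(model$classes), byrow = TRUE)
  p <- vapply(seq_along(model$classes), function(k)
    platt_predict(model$platt[[k]], f[, k]), numeric(nrow(newx)))
  p <- matrix(p, nrow(newx), dimnames = list(NULL, model$classes))
  p / rowSums(p)
}

## Platt (1999) sigmoid fit with regularized targets: damped Newton with
## backtracking on the cross-entropy (undamped steps diverge when decision
## values are near-separated with little within-class spread)
platt_fit <- function(f, pos) {
  n_pos <- sum(pos); n_neg <- sum(!pos)
  t <- ifelse(pos, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  nll <- function(ab) {
    z <- ab[1] * f + ab[2]
    ## -sum(t*log(p) + (1-t)*log(1-p)) with p = sigmoid(-z), stable branches
    sum(ifelse(z > 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  ab <- c(0, log((n_neg + 1) / (n_pos + 1)))
  obj <- nll(ab)
  for (it in 1:100) {
    z <- ab[1] * f + ab[2]
    p <- 1 / (1 + exp(z))
    d1 <- t - p
    grad <- c(sum(d1 * f), sum(d1))
    w <- p * (1 - p)
    H <- matrix(c(sum(w * f * f), sum(w * f), sum(w * f), sum(w)), 2) +
      diag(1e-10, 2)
    step <- solve(H, grad)
    lam <- 1
    repeat {
      cand <- ab - lam * step
      cobj <- nll(cand)
      if (cobj <= obj + 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    if (lam < 1e-8) break
    done <- max(abs(lam * step)) < 1e-10 || obj - cobj < 1e-12
    ab <- cand; obj <- cobj
    if (done) break
  }
  ab
}

platt_predict <- function(ab, f) {
  pmin(pmax(1 / (1 + exp(ab[1] * f + ab[2])), 1e-12), 1 - 1e-12)
}

## ---- weighted decision trees + SAMME AdaBoost ------------------------------

## Best weighted Gini split over all features for the rows in `idx`.
## Returns NULL when no impurity-reducing split exists.
best_split <- function(x, y_int, w, idx, n_class) {
  n <- length(idx)
  if (n < 2) return(NULL)
  best <- NULL; best_imp <- Inf
  wtot <- sum(w[idx])
  base_counts <- vapply(seq_len(n_class), function(k)
    sum(w[idx][y_int[idx] == k]), numeric(1))
  base_imp <- wtot * (1 - sum((base_counts / wtot)^2))
  for (j in seq_len(ncol(x))) {
    xv <- x[idx, j]
    o <- order(xv)
    xs <- xv[o]
    ## candidate split points: between distinct consecutive values
    distinct <- which(diff(xs) > 0)
    if (!length(distinct)) next
    ys <- y_int[idx][o]; ws <- w[idx][o]
    cl <- matrix(0, n, n_class)
    cl[cbind(seq_len(n), ys)] <- ws
    cum <- apply(cl, 2, cumsum)              # n x K left class weights
    wl <- rowSums(cum)
    wr <- wtot - wl
    gl <- 1 - rowSums((cum / wl)^2)
    cumr <- -sweep(cum, 2, cum[n, ])
    gr <- 1 - rowSums((cumr / wr)^2)
    imp <- wl * gl + wr * gr
    imp_c <- imp[distinct]
    mbest <- which.min(imp_c)
    if (imp_c[mbest] < best_imp - 1e-14) {
      best_imp <- imp_c[mbest]
      i <- distinct[mbest]
      best <- list(feature = j, threshold = (xs[i] + xs[i + 1]) / 2,
                   impurity = imp_c[mbest])
    }
  }
  if (is.null(best) || best_imp >= base_imp - 1e-12) return(NULL)
  best
}

node_class <- function(y_int, w, idx, n_class) {
  cnt <- vapply(seq_len(n_class), function(k)
    sum(w[idx][y_int[idx] == k]), numeric(1))
  which.max(cnt)
}

## depth-limited weighted classification tree, stored as a nested list
tree_fit <- function(x, y_int, w, n_class, depth) {
  build <- function(idx, d) {
    leaf <- list(leaf = TRUE, class = node_class(y_int, w, idx, n_class))
    if (d <= 0 || length(unique(y_int[idx])) < 2) return(leaf)
    sp <- best_split(x, y_int, w, idx, n_class)
    if (is.null(sp)) return(leaf)
    left <- idx[x[idx, sp$feature] <= sp$threshold]
    right <- setdiff(idx, left)
    if (!length(left) || !length(right)) return(leaf)
    list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
         left = build(left, d - 1), right = build(right, d - 1))
  }
  build(seq_len(nrow(x)), depth)
}

tree_predict <- function(node, x) {
  n <- nrow(x)
  out <- integer(n)
  recurse <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$class; return() }
    go_left <- x[idx, node$feature] <= node$threshold
    recurse(node$left, idx[go_left])
    recurse(node$right, idx[!go_left])
  }
  recurse(node, seq_len(n))
  out
}

## SAMME AdaBoost with depth-limited trees
ada_fit <- function(x, y, depth = 1L, n_estimators = 50L, obs_w = NULL) {
  y <- droplevels(as.factor(y))
  classes <- levels(y)
  K <- length(classes)
  if (K < 2) stopf("single-class training set")
  y_int <- as.integer(y)
  n <- nrow(x)
  w <- if (is.null(obs_w)) rep(1 / n, n) else obs_w / sum(obs_w)
  trees <- list(); alphas <- numeric()
  for (m in seq_len(n_estimators)) {
    tr <- tree_fit(x, y_int, w, K, depth)
    pred <- tree_predict(tr, x)
    err <- sum(w[pred != y_int])
    if (err <= 1e-12) {           # perfect learner: dominate the vote, stop
      trees[[length(trees) + 1]] <- tr
      alphas <- c(alphas, log(1e12) + log(K - 1))
      break
    }
    if (err >= 1 - 1 / K) break   # no better than chance: stop boosting
    a <- log((1 - err) / err) + log(K - 1)
    trees[[length(trees) + 1]] <- tr
    alphas <- c(alphas, a)
    w <- w * exp(a * (pred != y_int))
    w <- w / sum(w)
  }
  if (!length(trees)) {           # degenerate: constant majority model
    trees <- list(list(leaf = TRUE, class = node_class(y_int, rep(1, n),
                                                       seq_len(n), K)))
    alphas <- 1
  }
  structure(list(trees = trees, alphas = alphas, classes = classes),
            class = "fferg_ada")
}

ada_predict <- function(model, newx) {
  K <- length(model$classes)
  votes <- matrix(0, nrow(newx), K, dimnames = list(NULL, model$classes))
  for (m in seq_along(model$trees)) {
    pred <- tree_predict(model$trees[[m]], newx)
    votes[cbind(seq_len(nrow(newx)), pred)] <-
      votes[cbind(seq_len(nrow(newx)), pred)] + model$alphas[m]
  }
  p <- votes / pmax(rowSums(votes), 1e-300)
  ## soften pure votes slightly so probabilities stay informative
  (p + 1e-6) / rowSums(p + 1e-6)
}

## ---- logistic regression (ridge-penalized multinomial) ---------------------

lr_fit <- function(x, y, C = 1, obs_w = NULL) {
  y <- droplevels(as.factor(y))
  classes <- levels(y)
  if (length(classes) < 2) stopf("single-class training set")
  fam <- if (length(classes) == 2) "binomial" else "multinomial"
  lam <- 1 / (C * nrow(x))
  ## glmnet warns on small classes in inner CV folds; expected here
  fit <- suppressWarnings(
    glmnet::glmnet(x, y, family = fam, alpha = 0,
                   lambda = lam * c(100, 10, 1), standardize = FALSE,
                   weights = if (is.null(obs_w)) rep(1, nrow(x)) else obs_w))
  structure(list(fit = fit, lambda = lam, classes = classes),
            class = "fferg_lr")
}

lr_predict <- function(model, newx) {
  p <- stats::predict(model$fit, newx, s = model$lambda, type = "response")
  if (length(dim(p)) == 3) p <- p[, , 1]
  else p <- cbind(1 - p[, 1], p[, 1])     # binomial: P(second level)
  colnames(p) <- model$classes
  p / rowSums(p)
}

## ---- uniform dispatch used by hyperparameter tuning ------------------------

fit_one_learner <- function(name, x, y, hp, class_weights = FALSE) {
  obs_w <- NULL
  if (isTRUE(class_weights)) {
    yf <- droplevels(as.factor(y))
    tab <- table(yf)
    obs_w <- as.numeric(sum(tab) / (nlevels(yf) * tab[yf]))
  }
  scaler <- fit_scaler(x)
  xs <- apply_scaler(scaler, x)
  m <- switch(name,
    svm = lssvm_fit(xs, y, C = hp$C, gamma = hp$gamma, obs_w = obs_w),
    ada = ada_fit(xs, y, depth = hp$depth, n_estimators = hp$n_estimators,
                  obs_w = obs_w),
    lr  = lr_fit(xs, y, C = hp$C, obs_w = obs_w),
    stopf("unknown learner '%s'", name))
  list(scaler = scaler, model = m, name = name)
}

predict_one_learner <- function(name, fit, newx) {
  xs <- apply_scaler(fit$scaler, newx)
  switch(name,
    svm = lssvm_predict(fit$model, xs),
    ada = ada_predict(fit$model, xs),
    lr  = lr_predict(fit$model, xs))
}
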