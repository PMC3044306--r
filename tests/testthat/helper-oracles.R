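# Independent oracles used across the suite. Nothing here calls the code
# paths it checks: rotations are minimized by grid search + simplex
# refinement, the weight LP by vertex enumeration, the SVC by grid search,
# and ROC by explicit pair counting.

rot_euler <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# Minimum weighted sum of squared distances over proper rigid transforms,
# by dense Euler-angle grid plus Nelder-Mead refinement. Translation is
# closed-form (weighted centroid match) for any rotation.
oracle_min_residual <- function(S, T_, w = NULL) {
  m <- nrow(S)
  if (is.null(w)) w <- rep(1 / m, m)
  sbar <- colSums(S * w) / sum(w)
  tbar <- colSums(T_ * w) / sum(w)
  Sc <- sweep(S, 2, sbar)
  Tc <- sweep(T_, 2, tbar)
  obj <- function(ang) {
    A <- rot_euler(ang[1], ang[2], ang[3])
    sum(w * rowSums((Sc %*% t(A) - Tc)^2))
  }
  best <- Inf
  best_ang <- c(0, 0, 0)
  as_ <- seq(0, 2 * pi, length.out = 19L)[-19L]
  bs_ <- seq(0, pi, length.out = 10L)
  for (a in as_) for (b in bs_) for (c in as_) {
    v <- obj(c(a, b, c))
    if (v < best) { best <- v; best_ang <- c(a, b, c) }
  }
  ref <- stats::optim(best_ang, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  min(best, ref$value)
}

# Global minimum of the WMD hinge-loss objective over (beta on the bounded
# simplex, theta free) by enumerating intersections of m active hyperplanes
# (weight bounds and hinge kinks) with the simplex equality.
oracle_lp_objective <- function(F_, y, C, eps, upper = 2 / ncol(F_)) {
  m <- ncol(F_)
  n <- nrow(F_)
  g <- function(beta, theta) {
    s <- drop(F_ %*% beta)
    loss <- ifelse(y > 0, pmax(0, s - (theta - eps)),
                   pmax(0, (theta + eps) - s))
    sum(C * loss)
  }
  # hyperplanes a . (beta, theta) = c
  planes <- list()
  for (i in seq_len(m)) {
    planes[[length(planes) + 1L]] <- list(a = c(replace(rep(0, m), i, 1), 0), c = 0)
    planes[[length(planes) + 1L]] <- list(a = c(replace(rep(0, m), i, 1), 0), c = upper)
  }
  for (j in seq_len(n)) {
    planes[[length(planes) + 1L]] <- list(a = c(F_[j, ], -1),
                                          c = if (y[j] > 0) -eps else eps)
  }
  simplex_row <- c(rep(1, m), 0)
  best <- Inf
  combos <- utils::combn(length(planes), m)
  for (k in seq_len(ncol(combos))) {
    A <- rbind(simplex_row,
               t(vapply(combos[, k], function(i) planes[[i]]$a, numeric(m + 1))))
    b <- c(1, vapply(combos[, k], function(i) planes[[i]]$c, 0))
    x <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(x)) next
    beta <- x[seq_len(m)]
    if (any(beta < -1e-9) || any(beta > upper + 1e-9)) next
    best <- min(best, g(pmin(pmax(beta, 0), upper), x[m + 1L]))
  }
  best
}

# Grid + Nelder-Mead minimizer of the DSDS SVC objective for <= 2 features.
oracle_svc <- function(X, y, eps = 1, base_cost = 1000, span = 50) {
  X <- as.matrix(X)
  p <- ncol(X)
  obj <- function(par) {
    sitematch::dsds_objective(par[seq_len(p)], par[p + 1L], X, y,
                              epsilon = eps, base_cost = base_cost)
  }
  grid <- seq(-span, span, length.out = 41L)
  best <- Inf; best_par <- rep(0, p + 1L)
  if (p == 1L) {
    for (w1 in grid) for (th in grid) {
      v <- obj(c(w1, th))
      if (v < best) { best <- v; best_par <- c(w1, th) }
    }
  } else {
    coarse <- seq(-span, span, length.out = 15L)
    for (w1 in coarse) for (w2 in coarse) for (th in coarse) {
      v <- obj(c(w1, w2, th))
      if (v < best) { best <- v; best_par <- c(w1, w2, th) }
    }
  }
  ref <- stats::optim(best_par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  ref2 <- stats::optim(ref$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-14))
  list(par = ref2$par, value = min(best, ref$value, ref2$value))
}

# ROC AUC by explicit positive/negative pair counting (ties count 1/2).
oracle_roc_paircount <- function(scores, labels) {
  pos <- scores[labels > 0]
  neg <- scores[labels < 0]
  tot <- 0
  for (sp in pos) for (sn in neg) {
    tot <- tot + (sp > sn) + 0.5 * (sp == sn)
  }
  tot / (length(pos) * length(neg))
}

# Ridge-penalized logistic regression by explicit iteratively reweighted
# least-squares (penalized Newton) updates.
oracle_irls_logistic <- function(scores, y01, lambda = 1e-6, iters = 500L) {
  X <- cbind(1, scores)
  beta <- c(0, 0)
  for (i in seq_len(iters)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- pmax(p * (1 - p), 1e-12)
    grad <- drop(t(X) %*% (y01 - p)) - lambda * beta
    H <- t(X * W) %*% X + lambda * diag(2)
    step <- drop(solve(H, grad))
    beta <- beta + step
    if (max(abs(grad)) < 1e-13) break
  }
  beta
}
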