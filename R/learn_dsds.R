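# Discriminative learning of DSDS coefficients: a cost-weighted soft-margin
# linear support vector classifier over DALI feature vectors,
#   min over (w, theta) of  1/2 ||w||^2 + sum_j C_j * hinge_j
# with hinge_j = max(0, (theta + epsilon) - w.x_j) for positives and
# max(0, w.x_j - (theta - epsilon)) for negatives. With epsilon = 1 this is
# the canonical C-SVC with per-class costs and bias -theta, and is solved
# with libsvm (via e1071), the same solver family the measurement was
# designed around. For general epsilon > 0 the exact rescaling
# w = epsilon * v, theta = epsilon * eta with costs C_j / epsilon reduces to
# the unit-margin problem.

#' Build a DSDS training set from labeled sites
#'
#' @param sites List of labeled `local_site` objects for one template.
#' @param template The `site_template`.
#' @param threshold,envelope DALI score constants.
#' @return List with `features` (n x m(m-1)/2 matrix) and `labels` (+1/-1).
#' @export
dsds_training_features <- function(sites, template, threshold = 0.20,
                                   envelope = 20) {
  labels <- vapply(sites, function(s) as.numeric(s$label), 1)
  feats <- t(vapply(sites, function(s) {
    dali_feature_vector(s, template, threshold, envelope)
  }, numeric(template_size(template) * (template_size(template) - 1L) / 2L)))
  list(features = feats, labels = labels)
}

#' Train DSDS coefficients by a cost-weighted support vector classifier
#'
#' @param features n x p matrix of DALI pair-score features (p = m(m-1)/2).
#' @param labels Vector of +1/-1 labels.
#' @param epsilon Margin (default 1, the canonical unit margin).
#' @param base_cost Cost scale; per-class costs are `base_cost / n+` and
#'   `base_cost / n-` (default 1000).
#' @param template_id Identifier recorded in the returned model.
#' @return A [dsds_model()] with learned `coefficients` and `threshold`.
#' @export
train_dsds <- function(features, labels, epsilon = 1, base_cost = 1000,
                       template_id = "") {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  if (!all(y %in% c(-1, 1)) || length(y) != nrow(X)) {
    stop("labels must be +1/-1, one per row", call. = FALSE)
  }
  if (!any(y > 0) || !any(y < 0)) {
    stop("training-set error: both classes must be present", call. = FALSE)
  }
  if (any(!is.finite(X))) stop("data error: non-finite features", call. = FALSE)
  stopifnot(epsilon > 0)
  n_pos <- sum(y > 0)
  n_neg <- sum(y < 0)
  cw <- c("1" = base_cost / n_pos / epsilon,
          "-1" = base_cost / n_neg / epsilon)
  yf <- factor(y, levels = c(1, -1))
  fit <- e1071::svm(x = X, y = yf, type = "C-classification",
                    kernel = "linear", cost = 1, class.weights = cw,
                    scale = FALSE, tolerance = 1e-6, shrinking = FALSE)
  v <- drop(t(fit$coefs) %*% fit$SV)
  eta <- fit$rho
  # libsvm's decision value v.x - rho is positive for its first class;
  # orient so positives score higher
  dec <- X %*% v - eta
  if (mean(dec[y > 0]) < mean(dec[y < 0])) {
    v <- -v
    eta <- -eta
  }
  dsds_model(coefficients = epsilon * v, threshold = epsilon * eta,
             template_id = template_id)
}

#' Train DSDS from labeled sites
#'
#' Convenience wrapper building the DALI feature matrix and calling
#' [train_dsds()].
#'
#' @inheritParams dsds_training_features
#' @inheritParams train_dsds
#' @return A [dsds_model()].
#' @export
train_dsds_sites <- function(sites, template, epsilon = 1, base_cost = 1000,
                             threshold = 0.20, envelope = 20) {
  tr <- dsds_training_features(sites, template, threshold, envelope)
  train_dsds(tr$features, tr$labels, epsilon = epsilon,
             base_cost = base_cost, template_id = template$template_id)
}

#' Score a site with a trained DSDS model
#'
#' Delegates to [dsds()]; higher values are more template-like.
#'
#' @param model A [dsds_model()].
#' @param site A `local_site` or coordinate matrix.
#' @param template The matching `site_template`.
#' @param threshold,envelope DALI score constants.
#' @return Similarity value.
#' @export
predict_dsds <- function(model, site, template, threshold = 0.20,
                         envelope = 20) {
  dsds(site, template, model, threshold = threshold, envelope = envelope)
}

#' The training objective of [train_dsds()]
#'
#' Exposed for diagnostics and tests: evaluates
#' `1/2 ||w||^2 + sum_j C_j hinge_j` at a given (w, theta).
#'
#' @param w Coefficient vector.
#' @param theta Threshold.
#' @param features,labels Training data as in [train_dsds()].
#' @param epsilon Margin.
#' @param base_cost Cost scale.
#' @return Objective value.
#' @export
dsds_objective <- function(w, theta, features, labels, epsilon = 1,
                           base_cost = 1000) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  C <- ifelse(y > 0, base_cost / sum(y > 0), base_cost / sum(y < 0))
  s <- drop(X %*% w)
  hinge <- ifelse(y > 0, pmax(0, (theta + epsilon) - s),
                  pmax(0, s - (theta - epsilon)))
  0.5 * sum(w^2) + sum(C * hinge)
}
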