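# Metric learning for the weighted mean deviation.
#
# The training objective is a cost-weighted hinge loss on the deviation
# delta_j(beta) relative to a threshold theta with margin epsilon:
#   positives pay  max(0, delta_j - (theta - epsilon))
#   negatives pay  max(0, (theta + epsilon) - delta_j)
# Because delta_j itself minimizes over rigid transforms, the full problem
# is bi-level; it is attacked by alternating two stages: (1) with the
# per-site transforms frozen, delta_j is linear in beta and minimizing the
# total loss over (beta, theta) is a linear program; (2) with beta frozen,
# each site's optimal transform is a weighted Procrustes fit.

#' Per-atom squared-distance features of a site under a fixed transform
#'
#' Element i is `||A s_i + b - t_i||^2`; the deviation delta_j(beta) is
#' exactly `beta %*% features` once the transform is frozen.
#'
#' @param site A `local_site` or coordinate matrix.
#' @param template A `site_template` or coordinate matrix.
#' @param transform A `rigid_transform`.
#' @return Length-m numeric vector of squared distances (Angstrom^2).
#' @export
site_distance_features <- function(site, template, transform) {
  S <- .as_coords(site)
  T_ <- .as_coords(template)
  if (nrow(S) != nrow(T_)) {
    stop("correspondence error: atom counts differ", call. = FALSE)
  }
  rowSums((apply_transform(transform, S) - T_)^2)
}

#' LP stage: optimal importance weights for frozen transforms
#'
#' Solves the linear program
#' `min sum_j C_j xi_j` subject to
#' `xi_j >= beta . f_j - (theta - epsilon)` for positives,
#' `xi_j >= (theta + epsilon) - beta . f_j` for negatives,
#' `xi >= 0`, `beta >= 0`, `sum(beta) = 1`, `beta_i <= upper`, theta free.
#' The default upper bound `2/m` guards against over-fitting.
#'
#' @param feature_matrix n_sites x m matrix of squared-distance features.
#' @param labels Vector of +1/-1 site labels.
#' @param costs Per-site loss weights C_j (defaults to `1/n+` for positives
#'   and `1/n-` for negatives).
#' @param epsilon Non-negative margin (Angstrom^2).
#' @param upper Upper bound on each weight; default `2/m`.
#' @return List with `weights` ([importance_weights()]), `threshold`
#'   (theta), and `objective` (the attained total loss).
#' @export
lp_stage <- function(feature_matrix, labels, costs = NULL, epsilon = 0.01,
                     upper = NULL) {
  F_ <- as.matrix(feature_matrix)
  n <- nrow(F_)
  m <- ncol(F_)
  y <- as.numeric(labels)
  if (!all(y %in% c(-1, 1)) || length(y) != n) {
    stop("labels must be +1/-1, one per site", call. = FALSE)
  }
  if (!any(y > 0) || !any(y < 0)) {
    stop("training-set error: both classes must be present", call. = FALSE)
  }
  if (any(!is.finite(F_))) stop("non-finite features", call. = FALSE)
  if (is.null(costs)) {
    costs <- ifelse(y > 0, 1 / sum(y > 0), 1 / sum(y < 0))
  }
  if (is.null(upper)) upper <- 2 / m
  stopifnot(epsilon >= 0, length(costs) == n)

  # variables x = (beta [m], theta_plus, theta_minus, xi [n]), all >= 0;
  # boot::simplex needs non-negative right-hand sides, so the hinge
  # constraints are written as >= epsilon rows.
  nv <- m + 2L + n
  obj <- c(rep(0, m), 0, 0, costs)
  A2 <- matrix(0, n, nv)
  for (j in seq_len(n)) {
    if (y[j] > 0) {
      A2[j, seq_len(m)] <- -F_[j, ]
      A2[j, m + 1L] <- 1; A2[j, m + 2L] <- -1
    } else {
      A2[j, seq_len(m)] <- F_[j, ]
      A2[j, m + 1L] <- -1; A2[j, m + 2L] <- 1
    }
    A2[j, m + 2L + j] <- 1
  }
  b2 <- rep(epsilon, n)
  A1 <- cbind(diag(m), matrix(0, m, 2L + n))
  b1 <- rep(upper, m)
  A3 <- matrix(c(rep(1, m), rep(0, 2L + n)), 1L)
  # phase-1 feasibility tolerance: start tight, relax if the simplex stalls
  res <- NULL
  for (tol in c(1e-10, 1e-8, 1e-6)) {
    res <- boot::simplex(obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                         A3 = A3, b3 = 1, maxi = FALSE,
                         n.iter = max(200L, 30L * (n + nv)), eps = tol)
    if (res$solved == 1) break
  }
  if (res$solved != 1) {
    stop("numerical error: LP solver did not converge", call. = FALSE)
  }
  beta <- unname(pmin(pmax(res$soln[seq_len(m)], 0), upper))
  beta <- beta / sum(beta)
  theta <- unname(res$soln[m + 1L] - res$soln[m + 2L])
  list(weights = importance_weights(beta),
       threshold = theta,
       objective = unname(res$value))
}

#' Transform stage: weighted Procrustes fit per site
#'
#' Re-optimizes each site's rigid transform for the current importance
#' weights; each site's deviation then attains its definitional minimum for
#' that beta.
#'
#' @param sites List of `local_site` objects (or coordinate matrices).
#' @param template A `site_template` (or coordinate matrix).
#' @param weights An [importance_weights()] or numeric simplex vector.
#' @return List of `rigid_transform` objects, one per site.
#' @export
transform_stage <- function(sites, template, weights) {
  T_ <- .as_coords(template)
  w <- .as_weights(weights, nrow(T_))
  lapply(sites, function(s) superpose(.as_coords(s), T_, w))
}

#' Train a WMD model by the alternating LP / Procrustes algorithm
#'
#' Transforms are initialized by unweighted Kabsch superposition (the UMD
#' transforms, i.e. the uniform-beta starting point); each iteration then
#' solves the weight LP given the transforms and refits the per-site
#' transforms given the weights. Two iterations are the default. The scheme
#' is a surrogate for an intractable bi-level program and is not guaranteed
#' to reach the global optimum; each LP is globally optimal given its
#' transforms.
#'
#' @param sites List of labeled `local_site` objects for one template (site
#'   labels must be +1/-1; at least one of each).
#' @param template The `site_template`.
#' @param iterations Number of LP/transform rounds (default 2).
#' @param epsilon Margin in Angstrom^2 (default 0.01).
#' @param costs Optional per-site loss weights; default `1/n+`, `1/n-` by
#'   class.
#' @return A `wmd_model`: list with `weights`, `threshold`, `epsilon`,
#'   `iterations_used` and `objective_trace` (LP objective after each
#'   iteration).
#' @export
train_wmd <- function(sites, template, iterations = 2L, epsilon = 0.01,
                      costs = NULL) {
  stopifnot(inherits(template, "site_template"), length(sites) >= 2L)
  y <- vapply(sites, function(s) as.numeric(s$label), 1)
  if (anyNA(y) || !all(y %in% c(-1, 1))) {
    stop("training-set error: all sites must carry a +1/-1 label",
         call. = FALSE)
  }
  if (!any(y > 0) || !any(y < 0)) {
    stop("training-set error: need at least one positive and one negative",
         call. = FALSE)
  }
  m <- template_size(template)
  coords <- lapply(sites, .as_coords)
  T_ <- template_coords(template)
  transforms <- lapply(coords, function(S) superpose(S, T_))
  trace <- numeric(0)
  fit <- NULL
  for (it in seq_len(iterations)) {
    F_ <- t(vapply(seq_along(coords), function(j) {
      site_distance_features(coords[[j]], T_, transforms[[j]])
    }, numeric(m)))
    fit <- lp_stage(F_, y, costs = costs, epsilon = epsilon)
    trace <- c(trace, fit$objective)
    transforms <- transform_stage(coords, T_, fit$weights)
  }
  fit$weights$template_id <- template$template_id
  structure(
    list(weights = fit$weights, threshold = fit$threshold,
         epsilon = epsilon, iterations_used = iterations,
         objective_trace = trace),
    class = "wmd_model"
  )
}

#' @export
print.wmd_model <- function(x, ...) {
  cat("wmd_model for", x$weights$template_id, "- beta:",
      paste(round(x$weights$beta, 3), collapse = " "),
      " theta:", round(x$threshold, 3), "\n")
  invisible(x)
}
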