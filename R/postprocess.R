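# Post-processing: converting per-template similarities/deviations into
# confidences comparable across templates. Two calibrations are provided —
# logistic-regression posteriors and a PINTS-style expected-random-match
# frequency for RMSD-type deviations — plus the Direct (no-op) control.

#' Fit a logistic-regression posterior on per-template scores
#'
#' Maximum-likelihood logistic fit of `P(+1 | score) = plogis(a*score + b)`.
#' Under complete separation the MLE diverges; in that case the model is
#' refitted with a small ridge penalty (1e-6) by Newton iteration and a
#' warning is issued, keeping the coefficients bounded and the fit
#' deterministic.
#'
#' @param scores Numeric vector of similarity or deviation values.
#' @param labels Vector of +1/-1 labels (both classes required).
#' @param template_id Identifier recorded in the model.
#' @param orientation `"similarity"` (higher score = more positive) or
#'   `"deviation"`; informational, the fitted slope carries the direction.
#' @return An `lr_model`: list with `slope`, `intercept`, `template_id`,
#'   `orientation`.
#' @export
fit_lr <- function(scores, labels, template_id = "",
                   orientation = c("similarity", "deviation")) {
  orientation <- match.arg(orientation)
  y <- as.numeric(labels)
  if (!any(y > 0) || !any(y < 0)) {
    stop("both classes must be present to fit a posterior", call. = FALSE)
  }
  y01 <- as.integer(y > 0)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y01 ~ scores, family = stats::binomial()),
    warning = function(w) {
      separated <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  co <- stats::coef(fit)
  if (separated || any(!is.finite(co)) || max(abs(co)) > 1e3) {
    warning("complete separation in logistic fit; using ridge-regularized ",
            "coefficients (lambda = 1e-6)", call. = FALSE)
    co <- .ridge_logistic(cbind(1, scores), y01, lambda = 1e-6)
  } else {
    co <- c(co[[1L]], co[[2L]])
  }
  structure(
    list(slope = unname(co[2L]), intercept = unname(co[1L]),
         template_id = template_id, orientation = orientation),
    class = "lr_model"
  )
}

# Newton/IRLS for ridge-penalized logistic regression:
# min -loglik + lambda/2 * ||beta||^2. Strictly convex, unique optimum.
.ridge_logistic <- function(X, y01, lambda = 1e-6, max_iter = 200L,
                            tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(drop(X %*% beta))
    g <- drop(t(X) %*% (y01 - p)) - lambda * beta
    W <- p * (1 - p)
    H <- t(X * W) %*% X + lambda * diag(ncol(X))
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(g)) < tol) break
  }
  c(beta[1L], beta[2L])
}

#' Posterior probability from a fitted logistic model
#'
#' @param model An `lr_model` from [fit_lr()].
#' @param score Numeric score(s).
#' @return Posterior probabilities in (0, 1), monotone in the score.
#' @export
lr_posterior <- function(model, score) {
  stopifnot(inherits(model, "lr_model"))
  stats::plogis(model$slope * score + model$intercept)
}

#' Default size penalty for the PINTS-style significance
#'
#' Larger templates are rarer random matches; the default abundance model
#' discounts the log expected frequency by one order of magnitude per
#' matched atom beyond the first. Pass a different function (or
#' `function(m) 0`) to [pints_logF()] to change or disable it.
#'
#' @param matched_atom_count Number of matched atoms m.
#' @return Non-negative penalty subtracted from the log frequency.
#' @export
pints_size_penalty <- function(matched_atom_count) {
  (matched_atom_count - 1) * log(10)
}

#' Fit a PINTS-style empirical null to negative-site deviations
#'
#' Fits a Gumbel (minimum-type) location-scale model by the method of
#' moments to the negative-site sqrt(WMD) values of one template. The
#' fitted null converts a deviation into an expected number of random
#' matches at least that good; its left tail models the best random
#' matches. This is a documented empirical-null stand-in for the published
#' PINTS significance, whose exact fitted form is not reproduced here.
#'
#' @param negative_deviations Vector of sqrt(WMD) values (Angstrom) of
#'   negative sites; at least 20 required.
#' @param template The `site_template` (used for the matched atom count),
#'   or an integer atom count.
#' @return A `pints_model`: list with `null_location`, `null_scale`,
#'   `matched_atom_count`, `n_negatives`, `template_id`.
#' @export
fit_pints_null <- function(negative_deviations, template) {
  r <- as.numeric(negative_deviations)
  if (length(r) < 20L) {
    stop("fit error: need at least 20 negative deviations, got ",
         length(r), call. = FALSE)
  }
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("fit error: deviations must be finite and non-negative",
         call. = FALSE)
  }
  m <- if (inherits(template, "site_template")) template_size(template)
       else as.integer(template)
  tid <- if (inherits(template, "site_template")) template$template_id else ""
  gamma <- 0.57721566490153286
  scale <- stats::sd(r) * sqrt(6) / pi
  if (scale <= 0) {
    stop("fit error: negative deviations are constant", call. = FALSE)
  }
  loc <- mean(r) + gamma * scale   # Gumbel-min mean is loc - gamma*scale
  structure(
    list(null_location = loc, null_scale = scale,
         matched_atom_count = m, n_negatives = length(r),
         template_id = tid),
    class = "pints_model"
  )
}

# Gumbel-min CDF
.pints_cdf <- function(model, r) {
  1 - exp(-exp((r - model$null_location) / model$null_scale))
}

#' Log expected random-match frequency (PINTS-style)
#'
#' `logF(r) = log(n_neg * P_null(deviation <= r)) - size_penalty(m)`.
#' Strictly increasing in the deviation; for a fixed deviation it decreases
#' with the matched atom count (larger templates are rarer matches). More
#' negative values are more significant; rankings sort ascending.
#'
#' @param model A `pints_model` from [fit_pints_null()].
#' @param deviation sqrt(WMD) value(s) in Angstrom.
#' @param size_penalty Function of the matched atom count returning the
#'   abundance discount; default [pints_size_penalty()].
#' @return Log expected frequency (dimensionless), vectorized.
#' @export
pints_logF <- function(model, deviation, size_penalty = pints_size_penalty) {
  stopifnot(inherits(model, "pints_model"))
  p <- .pints_cdf(model, as.numeric(deviation))
  log(model$n_negatives) + log(pmax(p, 1e-300)) -
    size_penalty(model$matched_atom_count)
}

#' Merge per-template scored sites into one ranked prediction
#'
#' One output row per (site, template) pair: a site matched by several
#' templates keeps one row per template. Sorting is by confidence —
#' descending posterior for `lr`, ascending log frequency for `pints`, raw
#' score for `direct` (descending for similarities, ascending for
#' deviations). Ties break deterministically by (structure_id, residue
#' key, template_id).
#'
#' @param scored data.frame with columns `structure_id`, `residue_key`,
#'   `template_id`, `score`, `confidence` (ignored for direct),
#'   `orientation` (`"similarity"` or `"deviation"`).
#' @param method `"direct"`, `"lr"` or `"pints"`.
#' @return A `ranked_prediction` data.frame with a `rank` column, sorted.
#' @export
merge_rankings <- function(scored, method = c("direct", "lr", "pints")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(scored), nrow(scored) > 0L)
  orient <- unique(scored$orientation)
  if (method == "direct") {
    if (length(orient) > 1L) {
      stop("configuration error: Direct ranking cannot mix similarity and ",
           "deviation measurements across templates", call. = FALSE)
    }
    key <- if (orient == "similarity") -scored$score else scored$score
    scored$confidence <- scored$score
  } else if (method == "lr") {
    key <- -scored$confidence
  } else {
    key <- scored$confidence   # logF, ascending
  }
  ord <- order(key, scored$structure_id, scored$residue_key,
               scored$template_id, method = "radix")
  out <- scored[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("ranked_prediction", "data.frame")
  out
}
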