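# DALI pair scores over intra-set distance matrices, and the MDS and DSDS
# similarity measurements. Everything here is superposition-free: only
# pairwise distances within each structure are compared, so all outputs are
# invariant to rigid transforms of either structure.

#' All pairwise distances of a point set
#'
#' Euclidean distances for all m(m-1)/2 atom pairs, in lexicographic order
#' by atom-index pair (i1 < i2). This fixed order defines the DALI feature
#' ordering everywhere downstream.
#'
#' @param coords m x 3 coordinate matrix (or a site/template object), m >= 2.
#' @return Numeric vector of length m(m-1)/2.
#' @export
pair_distances <- function(coords) {
  X <- .as_coords(coords)
  m <- nrow(X)
  if (m < 2L) stop("degenerate: need at least 2 atoms", call. = FALSE)
  idx <- .pair_index(m)
  sqrt(rowSums((X[idx[, 1L], , drop = FALSE] - X[idx[, 2L], , drop = FALSE])^2))
}

# lexicographic (i1 < i2) pair index table
.pair_index <- function(m) {
  i1 <- rep(seq_len(m - 1L), times = (m - 1L):1L)
  i2 <- unlist(lapply(seq_len(m - 1L), function(i) (i + 1L):m))
  cbind(i1, i2)
}

#' DALI elastic pair score
#'
#' Similarity between one intra-template distance and the corresponding
#' intra-site distance:
#' `phi(dT, dS) = (threshold - |dT - dS| / dstar) * exp(-(dstar/envelope)^2)`
#' with `dstar = (dT + dS)/2`. The singular case `dstar = 0` (both
#' distances zero) is the continuity limit of perfect agreement and scores
#' `threshold`.
#'
#' @param d_template,d_site Non-negative distances in Angstrom (vectorized).
#' @param threshold Similarity threshold constant (default 0.20).
#' @param envelope Distance envelope width in Angstrom (default 20).
#' @return Dimensionless score(s).
#' @export
dali_pair_score <- function(d_template, d_site, threshold = 0.20,
                            envelope = 20) {
  if (any(d_template < 0) || any(d_site < 0)) {
    stop("domain error: distances must be non-negative", call. = FALSE)
  }
  dstar <- (d_template + d_site) / 2
  rel <- ifelse(dstar > 0, abs(d_template - d_site) / pmax(dstar, 1e-300), 0)
  (threshold - rel) * exp(-(dstar / envelope)^2)
}

#' DALI feature vector of a site against a template
#'
#' Element p is the DALI pair score of the template's p-th pair distance
#' against the site's p-th pair distance, ordered as [pair_distances()].
#'
#' @param site A `local_site` or coordinate matrix.
#' @param template A `site_template` or coordinate matrix.
#' @param threshold,envelope DALI score constants, see [dali_pair_score()].
#' @return Numeric vector of length m(m-1)/2.
#' @export
dali_feature_vector <- function(site, template, threshold = 0.20,
                                envelope = 20) {
  dS <- pair_distances(site)
  dT <- pair_distances(template)
  if (length(dS) != length(dT)) {
    stop("correspondence error: site and template atom counts differ",
         call. = FALSE)
  }
  dali_pair_score(dT, dS, threshold = threshold, envelope = envelope)
}

#' Mean DALI score (MDS)
#'
#' Arithmetic mean of the DALI pair scores over all m(m-1)/2 atom pairs.
#' The unlearned control for [dsds()].
#'
#' @inheritParams dali_feature_vector
#' @return Similarity (dimensionless; higher = more template-like).
#' @export
mds <- function(site, template, threshold = 0.20, envelope = 20) {
  mean(dali_feature_vector(site, template, threshold, envelope))
}

#' DSDS model: learned linear coefficients over DALI pair scores
#'
#' @param coefficients Numeric vector of length m(m-1)/2.
#' @param threshold Discrimination threshold theta (diagnostic; ranking uses
#'   the raw linear score).
#' @param template_id Identifier of the matching template.
#' @return A `dsds_model` object.
#' @export
dsds_model <- function(coefficients, threshold = 0, template_id = "") {
  coefficients <- as.numeric(coefficients)
  if (any(!is.finite(coefficients))) {
    stop("model error: non-finite coefficients", call. = FALSE)
  }
  structure(
    list(coefficients = coefficients, threshold = threshold,
         template_id = template_id),
    class = "dsds_model"
  )
}

#' DALI score-based discriminative similarity (DSDS)
#'
#' Inner product of learned coefficients with the DALI feature vector. No
#' bias is added; the model threshold is used only for classification
#' diagnostics, ranking uses the raw value.
#'
#' @inheritParams dali_feature_vector
#' @param model A [dsds_model()] whose coefficient length matches the
#'   template's pair count.
#' @return Similarity (dimensionless).
#' @export
dsds <- function(site, template, model, threshold = 0.20, envelope = 20) {
  stopifnot(inherits(model, "dsds_model"))
  feats <- dali_feature_vector(site, template, threshold, envelope)
  if (length(model$coefficients) != length(feats)) {
    stop("model error: coefficient length ", length(model$coefficients),
         " does not match pair count ", length(feats), call. = FALSE)
  }
  sum(model$coefficients * feats)
}
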