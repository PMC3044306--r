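# Rigid-body superposition and the UMD/WMD deviation measurements.
#
# The deviation of a local site S from a template T is the minimum over
# proper rigid transforms (A, b) of the (weighted) mean of squared distances
# sum_i beta_i * ||A s_i + b - t_i||^2. With uniform weights beta_i = 1/m
# this is UMD, the square of the RMSD.

.as_coords <- function(x) {
  if (inherits(x, "site_template")) return(template_coords(x))
  if (inherits(x, "local_site")) return(site_coords(x))
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  stopifnot(ncol(m) == 3L)
  unname(m)
}

#' Importance weights for a template's atoms
#'
#' Per-atom importance parameters on the probability simplex: non-negative
#' and summing to one. Weights produced by [train_wmd()] additionally obey
#' the over-fitting bound beta_i <= 2/m.
#'
#' @param beta Numeric vector of non-negative weights summing to 1.
#' @param template_id Identifier of the template the weights belong to.
#' @return An `importance_weights` object.
#' @export
importance_weights <- function(beta, template_id = "") {
  beta <- as.numeric(beta)
  if (any(!is.finite(beta)) || any(beta < -1e-9)) {
    stop("invalid weights: entries must be finite and non-negative",
         call. = FALSE)
  }
  beta[beta < 0] <- 0
  if (abs(sum(beta) - 1) > 1e-6) {
    stop("invalid weights: entries must sum to 1", call. = FALSE)
  }
  structure(list(beta = beta / sum(beta), template_id = template_id),
            class = "importance_weights")
}

.as_weights <- function(weights, m) {
  w <- if (inherits(weights, "importance_weights")) weights$beta
       else as.numeric(weights)
  if (length(w) != m) {
    stop("correspondence error: ", length(w), " weights for ", m, " atoms",
         call. = FALSE)
  }
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("invalid weights", call. = FALSE)
  }
  if (sum(w) <= 0) stop("invalid weights: all zero", call. = FALSE)
  w
}

#' Optimal weighted rigid-body superposition (weighted Kabsch/Procrustes)
#'
#' Finds the proper rotation `A` and translation `b` minimizing
#' `sum_i w_i * ||A s_i + b - t_i||^2`, mapping the site onto the template.
#' The closed form uses weight-scaled centroids and the SVD of the weighted
#' cross-covariance; a reflection is corrected by flipping the smallest
#' singular direction so that `det(A) = +1`.
#'
#' @param site_coords m x 3 matrix of site coordinates (Angstrom).
#' @param template_coords m x 3 matrix of template coordinates (Angstrom).
#' @param weights Length-m non-negative vector, not all zero. Uniform by
#'   default.
#' @return A `rigid_transform`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `residual` (the attained weighted sum of
#'   squared distances) and `non_unique` (TRUE when the rotation is not
#'   uniquely determined, e.g. collinear configurations or m = 2).
#' @export
superpose <- function(site_coords, template_coords, weights = NULL) {
  S <- .as_coords(site_coords)
  T_ <- .as_coords(template_coords)
  m <- nrow(S)
  if (nrow(T_) != m) {
    stop("correspondence error: site has ", m, " atoms, template ",
         nrow(T_), call. = FALSE)
  }
  if (m < 2L) stop("need at least 2 atoms to superpose", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / m, m)
  w <- .as_weights(weights, m)
  sbar <- colSums(S * w) / sum(w)
  tbar <- colSums(T_ * w) / sum(w)
  Sc <- sweep(S, 2, sbar)
  Tc <- sweep(T_, 2, tbar)
  H <- t(Sc * w) %*% Tc          # 3x3 weighted cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  A <- sv$v %*% D %*% t(sv$u)
  b <- tbar - as.vector(A %*% sbar)
  resid <- sum(w * rowSums((Sc %*% t(A) - Tc)^2))
  # rotation is non-unique when the configuration is (near-)collinear:
  # second singular value of the covariance vanishes
  non_unique <- m == 2L || sv$d[2L] <= 1e-10 * max(sv$d[1L], 1e-300)
  structure(
    list(rotation = A, translation = b, residual = max(resid, 0),
         non_unique = non_unique),
    class = "rigid_transform"
  )
}

#' Apply a rigid transform to coordinates
#' @param transform A `rigid_transform`.
#' @param coords m x 3 coordinate matrix.
#' @return Transformed m x 3 matrix.
#' @export
apply_transform <- function(transform, coords) {
  sweep(.as_coords(coords) %*% t(transform$rotation), 2,
        -transform$translation)
}

#' Unweighted mean deviation (squared RMSD)
#'
#' The minimum over rigid transforms of the unweighted mean of squared
#' Euclidean distances between corresponding atoms; equal to RMSD squared.
#'
#' @param site A `local_site` or m x 3 coordinate matrix.
#' @param template A `site_template` or m x 3 coordinate matrix.
#' @return Deviation in squared Angstrom.
#' @export
umd <- function(site, template) {
  S <- .as_coords(site)
  superpose(S, template, rep(1 / nrow(S), nrow(S)))$residual
}

#' Weighted mean deviation
#'
#' The minimum over rigid transforms of the importance-weighted sum of
#' squared distances, `min_{A,b} sum_i beta_i ||A s_i + b - t_i||^2`. With
#' uniform weights this equals [umd()].
#'
#' @param site A `local_site` or coordinate matrix.
#' @param template A `site_template` or coordinate matrix.
#' @param weights An [importance_weights()] object or numeric simplex vector.
#' @return Deviation in squared Angstrom.
#' @export
wmd <- function(site, template, weights) {
  S <- .as_coords(site)
  w <- .as_weights(weights, nrow(S))
  if (abs(sum(w) - 1) > 1e-6) {
    stop("invalid weights: importance parameters must sum to 1",
         call. = FALSE)
  }
  superpose(S, template, w)$residual
}
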