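# Evaluation: ROC score, ROC5 score, Sensitivity at 95% specificity,
# percentile ROC curves and the repeated 50/50 split protocol with the
# per-template positive-coverage constraint.

.check_two_classes <- function(labels) {
  y <- as.numeric(labels)
  if (!any(y > 0) || !any(y < 0)) {
    stop("undefined metric: both classes must be present", call. = FALSE)
  }
  y
}

#' ROC score (area under the ROC curve)
#'
#' Computed by the rank (Mann-Whitney) identity: the probability that a
#' random positive scores above a random negative, counting ties as 1/2.
#'
#' @param scores Numeric scores; higher = more positive.
#' @param labels Vector of +1/-1 labels.
#' @return AUC in [0, 1].
#' @export
roc_score <- function(scores, labels) {
  y <- .check_two_classes(labels)
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(y > 0)
  n_neg <- sum(y < 0)
  (sum(r[y > 0]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# ROC curve as cumulative (fp, tp) counts over unique score thresholds,
# descending; ties form one step (diagonal segment).
.roc_steps <- function(scores, labels) {
  y <- as.numeric(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- as.integer(y[ord] > 0)
  block <- cumsum(!duplicated(s))
  tp <- c(0, cumsum(tapply(p, block, sum)))
  fp <- c(0, cumsum(tapply(1 - p, block, sum)))
  cbind(fp = unname(fp), tp = unname(tp))
}

#' ROC curve points
#'
#' @inheritParams roc_score
#' @return data.frame with columns `fpr`, `tpr`, starting at (0,0) and
#'   ending at (1,1); both coordinates non-decreasing.
#' @export
roc_curve <- function(scores, labels) {
  y <- .check_two_classes(labels)
  st <- .roc_steps(scores, y)
  data.frame(fpr = st[, "fp"] / sum(y < 0), tpr = st[, "tp"] / sum(y > 0))
}

#' ROC5 score (area under the ROC curve up to the fifth false positive)
#'
#' Area under the ROC curve truncated at `n_fp` false positives and
#' normalized by `n_fp * n_positives`, so a ranking placing every positive
#' above every negative scores 1. Ties contribute fractionally through the
#' trapezoidal (diagonal-segment) convention. With fewer than `n_fp`
#' negatives, all negatives are used.
#'
#' @inheritParams roc_score
#' @param n_fp Number of false positives to truncate at (default 5).
#' @return Normalized truncated AUC in [0, 1].
#' @export
roc5_score <- function(scores, labels, n_fp = 5L) {
  y <- .check_two_classes(labels)
  n_neg <- sum(y < 0)
  cap <- min(n_fp, n_neg)
  st <- .roc_steps(scores, y)
  fp <- st[, "fp"]
  tp <- st[, "tp"]
  area <- 0
  for (i in seq_len(nrow(st) - 1L)) {
    x0 <- fp[i]; x1 <- fp[i + 1L]
    y0 <- tp[i]; y1 <- tp[i + 1L]
    if (x0 >= cap) break
    if (x1 > cap) {   # clip the segment at the cap
      frac <- (cap - x0) / (x1 - x0)
      y1 <- y0 + frac * (y1 - y0)
      x1 <- cap
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area / (cap * sum(y > 0))
}

#' Sensitivity at a specificity floor
#'
#' True-positive rate at the largest threshold-induced false-positive rate
#' not exceeding `1 - specificity` (conservative step-function convention:
#' the specificity requirement is a floor).
#'
#' @inheritParams roc_score
#' @param specificity Required specificity (default 0.95).
#' @return Sensitivity in [0, 1].
#' @export
sensitivity_at_specificity <- function(scores, labels, specificity = 0.95) {
  y <- .check_two_classes(labels)
  st <- .roc_steps(scores, y)
  fpr <- st[, "fp"] / sum(y < 0)
  tpr <- st[, "tp"] / sum(y > 0)
  ok <- fpr <= (1 - specificity) + 1e-12
  max(tpr[ok])
}

#' Generate repeated 50/50 structure-level splits
#'
#' Structures are split at random into equal halves; each split is then
#' repaired by swapping structures between halves until every template has
#' at least one positive site in the training half. Deterministic given the
#' seed.
#'
#' @param site_table data.frame with one row per detected site: columns
#'   `structure_id`, `template_id`, `label` (+1/-1).
#' @param n_repeats Number of splits (default 30).
#' @param seed Integer seed.
#' @return List of split plans, each a list with `seed`, `train_ids`,
#'   `test_ids`.
#' @export
make_splits <- function(site_table, n_repeats = 30L, seed = 1L) {
  stopifnot(is.data.frame(site_table),
            all(c("structure_id", "template_id", "label") %in%
                  names(site_table)))
  structures <- sort(unique(site_table$structure_id))
  pos <- site_table[site_table$label > 0, , drop = FALSE]
  pos_struct <- split(pos$structure_id, pos$template_id)
  for (tid in names(pos_struct)) {
    if (length(unique(pos_struct[[tid]])) < 2L) {
      stop("split error: template '", tid, "' has fewer than 2 ",
           "positive-bearing structures; coverage constraint unsatisfiable",
           call. = FALSE)
    }
  }
  templates <- names(pos_struct)
  n <- length(structures)
  n_train <- floor(n / 2)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  plans <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    train <- sample(structures, n_train)
    for (guard in seq_len(1000L)) {
      uncovered <- templates[!vapply(templates, function(tid) {
        any(pos_struct[[tid]] %in% train)
      }, TRUE)]
      if (length(uncovered) == 0L) break
      tid <- uncovered[[1L]]
      bring <- sample(unique(pos_struct[[tid]]), 1L)
      # swap out a train structure that is not the sole positive carrier of
      # another template
      removable <- train[vapply(train, function(sid) {
        all(vapply(templates, function(t2) {
          carriers <- intersect(unique(pos_struct[[t2]]), train)
          !(length(carriers) == 1L && carriers == sid)
        }, TRUE))
      }, TRUE)]
      if (length(removable) == 0L) {
        stop("split error: cannot repair coverage for template '", tid, "'",
             call. = FALSE)
      }
      out_sid <- sample(removable, 1L)
      train <- c(setdiff(train, out_sid), bring)
    }
    uncovered <- templates[!vapply(templates, function(tid) {
      any(pos_struct[[tid]] %in% train)
    }, TRUE)]
    if (length(uncovered) > 0L) {
      stop("split error: cannot satisfy coverage for template '",
           uncovered[[1L]], "'", call. = FALSE)
    }
    plans[[r]] <- list(seed = seed + r - 1L,
                       train_ids = sort(train),
                       test_ids = sort(setdiff(structures, train)))
  }
  plans
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Percentile ROC curves across a collection of curves
#'
#' Each curve is linearly interpolated onto a common FPR grid (vertical
#' jumps take the upper value); the requested percentiles of TPR are then
#' taken pointwise across curves.
#'
#' @param curves List of data.frames with columns `fpr`, `tpr`.
#' @param percentiles Percentiles to report (default 25, 50, 75).
#' @param grid FPR grid (default `seq(0, 1, by = 0.01)`).
#' @return data.frame with `fpr` and one `p<q>` column per percentile.
#' @export
aggregate_curves <- function(curves, percentiles = c(25, 50, 75),
                             grid = seq(0, 1, by = 0.01)) {
  if (length(curves) == 0L) stop("no curves to aggregate", call. = FALSE)
  mat <- vapply(curves, function(cv) {
    stats::approx(cv$fpr, cv$tpr, xout = grid, ties = max, rule = 2)$y
  }, numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  out <- data.frame(fpr = grid)
  for (q in percentiles) {
    out[[paste0("p", q)]] <- apply(mat, 1L, stats::quantile, probs = q / 100)
  }
  out
}
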