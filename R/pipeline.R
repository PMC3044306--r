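# End-to-end analyses: single-template search over a structure set,
# multiple-template prediction for one protein, and the repeated-split
# training/evaluation experiment.

.measurements <- c("umd", "wmd", "mds", "dsds")
.orientation_of <- c(umd = "deviation", wmd = "deviation",
                     mds = "similarity", dsds = "similarity")

# score one site with one measurement (model required for wmd/dsds)
.score_site <- function(site, template, measurement, model = NULL) {
  switch(measurement,
    umd = umd(site, template),
    wmd = {
      if (is.null(model)) {
        stop("configuration error: wmd scoring requires a trained wmd_model",
             call. = FALSE)
      }
      wmd(site, template, model$weights)
    },
    mds = mds(site, template),
    dsds = {
      if (is.null(model)) {
        stop("configuration error: dsds scoring requires a trained dsds_model",
             call. = FALSE)
      }
      dsds(site, template, model)
    },
    stop("unknown measurement: ", measurement, call. = FALSE)
  )
}

#' Single template analysis: search structures with one query template
#'
#' Stage 1 runs the local-site search over every structure; stage 2 scores
#' each candidate with the chosen measurement. Candidates are sorted in
#' descending order of similarity (mds/dsds) or ascending order of
#' deviation (umd/wmd).
#'
#' @param template The query `site_template`.
#' @param structures List of `protein_structure` objects or PDB file paths.
#' @param measurement One of `"umd"`, `"wmd"`, `"mds"`, `"dsds"`.
#' @param model Trained `wmd_model` / `dsds_model` for the learned
#'   measurements.
#' @param rmsd_cutoff LSS filter in Angstrom (default 4.0).
#' @return A `ranked_prediction` data.frame: rank, structure_id,
#'   residue_key, template_id, score, rmsd.
#' @export
run_single_template <- function(template, structures,
                                measurement = c("umd", "wmd", "mds", "dsds"),
                                model = NULL, rmsd_cutoff = 4.0) {
  measurement <- match.arg(measurement)
  rows <- list()
  for (s in structures) {
    if (is.character(s)) s <- read_pdb(s)
    sites <- lss_search(s, template, rmsd_cutoff = rmsd_cutoff)
    for (site in sites) {
      rows[[length(rows) + 1L]] <- data.frame(
        structure_id = site$structure_id,
        residue_key = site_residue_key(site),
        template_id = template$template_id,
        score = .score_site(site, template, measurement, model),
        rmsd = site$rmsd,
        orientation = .orientation_of[[measurement]],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(rank = integer(), structure_id = character(),
                      residue_key = character(), template_id = character(),
                      score = numeric(), rmsd = numeric(),
                      orientation = character(), stringsAsFactors = FALSE)
    class(out) <- c("ranked_prediction", "data.frame")
    return(out)
  }
  merge_rankings(do.call(rbind, rows), method = "direct")
}

#' Multiple template analysis: predict active sites in one query protein
#'
#' Three stages per template: local-site search, similarity/deviation
#' computation, and post-processing into cross-template confidences. The
#' merged ranking keeps one row per (site, template) pair. PINTS-style
#' significance applies only to the RMSD-type deviations (umd/wmd);
#' requesting it with mds/dsds is a configuration error.
#'
#' @param protein A `protein_structure` or PDB file path.
#' @param templates List of `site_template` objects.
#' @param measurement Measurement to use for every template.
#' @param models Named list (by template_id) of trained models for wmd/dsds.
#' @param post `"direct"`, `"lr"` or `"pints"`.
#' @param post_models Named list (by template_id) of `lr_model` or
#'   `pints_model` objects, required for lr/pints.
#' @param rmsd_cutoff LSS filter in Angstrom.
#' @return A `ranked_prediction` data.frame with confidence values.
#' @export
run_multiple_template <- function(protein, templates,
                                  measurement = c("umd", "wmd", "mds", "dsds"),
                                  models = list(),
                                  post = c("direct", "lr", "pints"),
                                  post_models = list(),
                                  rmsd_cutoff = 4.0) {
  measurement <- match.arg(measurement)
  post <- match.arg(post)
  if (post == "pints" && !measurement %in% c("umd", "wmd")) {
    stop("configuration error: PINTS applies only to the RMSD-type ",
         "deviations (umd, wmd), not to ", measurement, call. = FALSE)
  }
  if (is.character(protein)) protein <- read_pdb(protein)
  rows <- list()
  for (template in templates) {
    tid <- template$template_id
    model <- models[[tid]]
    sites <- lss_search(protein, template, rmsd_cutoff = rmsd_cutoff)
    for (site in sites) {
      sc <- .score_site(site, template, measurement, model)
      conf <- switch(post,
        direct = sc,
        lr = {
          pm <- post_models[[tid]]
          if (is.null(pm)) {
            stop("configuration error: no lr_model for template ", tid,
                 call. = FALSE)
          }
          lr_posterior(pm, sc)
        },
        pints = {
          pm <- post_models[[tid]]
          if (is.null(pm)) {
            stop("configuration error: no pints_model for template ", tid,
                 call. = FALSE)
          }
          pints_logF(pm, sqrt(sc))
        }
      )
      rows[[length(rows) + 1L]] <- data.frame(
        structure_id = protein$structure_id,
        residue_key = site_residue_key(site),
        template_id = tid,
        score = sc,
        confidence = conf,
        rmsd = site$rmsd,
        orientation = .orientation_of[[measurement]],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(rank = integer(), structure_id = character(),
                      residue_key = character(), template_id = character(),
                      score = numeric(), confidence = numeric(),
                      rmsd = numeric(), orientation = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("ranked_prediction", "data.frame")
    return(out)
  }
  merge_rankings(do.call(rbind, rows), method = post)
}

#' Repeated-split training and evaluation experiment
#'
#' Runs the full protocol on a labeled site collection: repeated 50/50
#' structure-level splits with the per-template positive-coverage
#' constraint, per-template model training on the training half only, and
#' evaluation of every measurement (and optional post-processing) on the
#' held-out half. Test structures never contribute to any model fit; the
#' structure ids used in training are recorded per repeat in the
#' `trained_on` attribute of the result for auditing.
#'
#' @param sites List of labeled `local_site` objects (their `template_id`
#'   must name an entry of `templates`).
#' @param templates Named list of `site_template` objects (names =
#'   template ids).
#' @param n_repeats Number of splits (default 2).
#' @param seed Integer seed.
#' @param measurements Subset of `c("umd","wmd","mds","dsds")`.
#' @param postprocessings Subset of `c("direct","lr","pints")`; per-protein
#'   metrics are reported for each.
#' @param epsilon_wmd Margin for WMD training (Angstrom^2).
#' @param iterations_wmd WMD training iterations.
#' @return data.frame with one row per measurement x postprocessing x
#'   grouping: mean ROC, ROC5 and Sensitivity over repeats. Attribute
#'   `trained_on` lists the training structure ids per repeat.
#' @export
run_experiment <- function(sites, templates, n_repeats = 2L, seed = 1L,
                           measurements = c("umd", "wmd", "mds", "dsds"),
                           postprocessings = c("direct", "lr"),
                           epsilon_wmd = 0.01, iterations_wmd = 2L) {
  stopifnot(length(sites) > 0L, length(templates) > 0L)
  measurements <- match.arg(measurements, several.ok = TRUE)
  postprocessings <- match.arg(postprocessings,
                               c("direct", "lr", "pints"), several.ok = TRUE)
  if (is.null(names(templates))) {
    names(templates) <- vapply(templates, `[[`, "", "template_id")
  }
  site_table <- data.frame(
    structure_id = vapply(sites, `[[`, "", "structure_id"),
    template_id = vapply(sites, `[[`, "", "template_id"),
    label = vapply(sites, function(s) as.numeric(s$label), 1),
    stringsAsFactors = FALSE
  )
  plans <- make_splits(site_table, n_repeats = n_repeats, seed = seed)
  acc <- list()
  trained_on <- list()
  record <- function(meas, post, grouping, rep_i, roc, roc5, sens) {
    acc[[length(acc) + 1L]] <<- data.frame(
      measurement = meas, postprocessing = post, grouping = grouping,
      repeat_index = rep_i, roc = roc, roc5 = roc5, sensitivity = sens,
      stringsAsFactors = FALSE
    )
  }
  for (rep_i in seq_along(plans)) {
    plan <- plans[[rep_i]]
    trained_on[[rep_i]] <- plan$train_ids
    in_train <- site_table$structure_id %in% plan$train_ids
    for (tid in names(templates)) {
      template <- templates[[tid]]
      sel <- site_table$template_id == tid
      tr_sites <- sites[sel & in_train]
      te_sites <- sites[sel & !in_train]
      y_te <- vapply(te_sites, function(s) as.numeric(s$label), 1)
      if (!any(y_te > 0) || !any(y_te < 0)) next
      y_tr <- vapply(tr_sites, function(s) as.numeric(s$label), 1)
      models <- list()
      if ("wmd" %in% measurements) {
        models$wmd <- train_wmd(tr_sites, template,
                                iterations = iterations_wmd,
                                epsilon = epsilon_wmd)
      }
      if ("dsds" %in% measurements) {
        models$dsds <- train_dsds_sites(tr_sites, template)
      }
      score_all <- function(ss, meas) {
        vapply(ss, function(s) .score_site(s, template, meas,
                                           models[[meas]]), 1)
      }
      for (meas in measurements) {
        sc_te <- score_all(te_sites, meas)
        ranking <- if (.orientation_of[[meas]] == "deviation") -sc_te else sc_te
        record(meas, "none", "per_template", rep_i,
               roc_score(ranking, y_te),
               roc5_score(ranking, y_te),
               sensitivity_at_specificity(ranking, y_te))
        # per-protein confidences for post-processed rankings
        for (post in postprocessings) {
          if (post == "pints" && !meas %in% c("umd", "wmd")) next
          sc_tr <- score_all(tr_sites, meas)
          conf <- switch(post,
            direct = ranking,
            lr = {
              pm <- fit_lr(sc_tr, y_tr, template_id = tid,
                           orientation = .orientation_of[[meas]])
              lr_posterior(pm, sc_te)
            },
            pints = {
              pm <- fit_pints_null(sqrt(sc_tr[y_tr < 0]), template)
              -pints_logF(pm, sqrt(sc_te))
            }
          )
          df <- data.frame(structure_id =
                             vapply(te_sites, `[[`, "", "structure_id"),
                           conf = conf, label = y_te,
                           stringsAsFactors = FALSE)
          per_prot <- split(df, df$structure_id)
          rocs <- roc5s <- senss <- numeric(0)
          for (pp in per_prot) {
            if (any(pp$label > 0) && any(pp$label < 0)) {
              rocs <- c(rocs, roc_score(pp$conf, pp$label))
              roc5s <- c(roc5s, roc5_score(pp$conf, pp$label))
              senss <- c(senss,
                         sensitivity_at_specificity(pp$conf, pp$label))
            }
          }
          if (length(rocs) > 0L) {
            record(meas, post, "per_protein", rep_i,
                   mean(rocs), mean(roc5s), mean(senss))
          }
        }
      }
    }
  }
  long <- do.call(rbind, acc)
  agg <- stats::aggregate(
    long[, c("roc", "roc5", "sensitivity")],
    by = long[, c("measurement", "postprocessing", "grouping")],
    FUN = mean
  )
  attr(agg, "trained_on") <- trained_on
  agg
}
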