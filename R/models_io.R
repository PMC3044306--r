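# Serialization of trained models as documented JSON text.

#' Write a trained model to a JSON file
#'
#' Supports `wmd_model`, `dsds_model`, `lr_model` and `pints_model`; the
#' file records the model class and all fitted parameters and round-trips
#' through [read_model()].
#'
#' @param model A trained model object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  kind <- class(model)[1L]
  payload <- switch(kind,
    wmd_model = list(kind = kind, template_id = model$weights$template_id,
                     beta = model$weights$beta, threshold = model$threshold,
                     epsilon = model$epsilon,
                     iterations_used = model$iterations_used),
    dsds_model = list(kind = kind, template_id = model$template_id,
                      coefficients = model$coefficients,
                      threshold = model$threshold),
    lr_model = list(kind = kind, template_id = model$template_id,
                    slope = model$slope, intercept = model$intercept,
                    orientation = model$orientation),
    pints_model = list(kind = kind, template_id = model$template_id,
                       null_location = model$null_location,
                       null_scale = model$null_scale,
                       matched_atom_count = model$matched_atom_count,
                       n_negatives = model$n_negatives),
    stop("unsupported model class: ", kind, call. = FALSE)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path Path to a model JSON file.
#' @return The reconstructed model object.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$kind)) stop("model format error: missing kind", call. = FALSE)
  switch(p$kind,
    wmd_model = structure(
      list(weights = importance_weights(p$beta, p$template_id),
           threshold = p$threshold, epsilon = p$epsilon,
           iterations_used = p$iterations_used,
           objective_trace = numeric(0)),
      class = "wmd_model"),
    dsds_model = dsds_model(p$coefficients, p$threshold, p$template_id),
    lr_model = structure(
      list(slope = p$slope, intercept = p$intercept,
           template_id = p$template_id, orientation = p$orientation),
      class = "lr_model"),
    pints_model = structure(
      list(null_location = p$null_location, null_scale = p$null_scale,
           matched_atom_count = p$matched_atom_count,
           n_negatives = p$n_negatives, template_id = p$template_id),
      class = "pints_model"),
    stop("model format error: unknown kind '", p$kind, "'", call. = FALSE)
  )
}
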