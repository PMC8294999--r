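# JSON serialization of the trained cascade: dictionary, AdaBoost trees,
# MIL stumps. Full double precision; round trips reproduce predictions
# exactly.

#' Save / load trained cascade models as JSON
#'
#' Serializes a `hotspot_models` object (dictionary atoms, CART tree
#' structures with thresholds and leaf votes, AdaBoost weights and `theta`,
#' MIL stumps and weights, configuration) to a single JSON file at full
#' double precision; a reloaded model reproduces margins, probability maps
#' and masks to numerical (1e-12) precision.
#'
#' @param models A `hotspot_models` from [train_pipeline()].
#' @param path JSON file path.
#' @return `save_models()` returns `path` invisibly; `load_models()` the
#'   reconstructed `hotspot_models`.
#' @export
save_models <- function(models, path) {
  if (!inherits(models, "hotspot_models")) {
    abort("`models` must come from train_pipeline().",
          class = "hotspotseg_input_error")
  }
  d <- models$dictionary
  obj <- list(
    format = "hotspotseg-models-1",
    dictionary = list(atoms = as.vector(d$atoms), d = nrow(d$atoms),
                      m = ncol(d$atoms), lambda = d$lambda, l = d$l,
                      center = isTRUE(d$center), seed = d$seed),
    adaboost = list(learners = models$adaboost$learners,
                    alphas = models$adaboost$alphas,
                    eps = models$adaboost$eps,
                    theta = models$adaboost$theta,
                    n_features = models$adaboost$n_features),
    mil = list(stumps = models$mil$stumps, weights = models$mil$weights,
               rule = models$mil$rule, n_features = models$mil$n_features),
    config = unclass(models$config)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_models
#' @export
load_models <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("model file not found: %s", path),
          class = "hotspotseg_config_error")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$format, "hotspotseg-models-1")) {
    abort(sprintf("%s is not a hotspotseg model file.", path),
          class = "hotspotseg_config_error")
  }
  dict <- structure(
    list(atoms = matrix(obj$dictionary$atoms, obj$dictionary$d,
                        obj$dictionary$m),
         lambda = obj$dictionary$lambda, l = obj$dictionary$l,
         codes = NULL, objective_trace = NULL,
         center = isTRUE(obj$dictionary$center), seed = obj$dictionary$seed),
    class = "sc_dictionary"
  )
  rebuild_tree <- function(node) {
    if (isTRUE(node$leaf)) return(list(leaf = TRUE, pred = node$pred))
    list(leaf = FALSE, feature = node$feature, threshold = node$threshold,
         left = rebuild_tree(node$left), right = rebuild_tree(node$right))
  }
  ada <- structure(
    list(learners = lapply(obj$adaboost$learners, rebuild_tree),
         alphas = as.numeric(obj$adaboost$alphas),
         eps = as.numeric(obj$adaboost$eps),
         theta = obj$adaboost$theta,
         train_error_trace = NULL,
         n_features = obj$adaboost$n_features, seed = NA_integer_),
    class = "adaboost_model"
  )
  mil <- structure(
    list(stumps = lapply(obj$mil$stumps, function(s) {
      list(score = s$score, feature = s$feature, threshold = s$threshold,
           polarity = s$polarity)
    }),
         weights = as.numeric(obj$mil$weights), rule = obj$mil$rule,
         n_features = obj$mil$n_features, seed = NA_integer_),
    class = "mil_model"
  )
  cfg <- do.call(pipeline_config,
                 obj$config[!vapply(obj$config, is.null, logical(1))])
  structure(list(dictionary = dict, adaboost = ada, mil = mil,
                 mil_loss_trace = NULL, config = cfg),
            class = "hotspot_models")
}
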