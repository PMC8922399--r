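#' @title Model checkpoints
#' @description JSON serialization of a trained model: configuration,
#'   feature-schema identity, and every parameter tensor. Loading refuses a
#'   checkpoint whose schema does not match the schema it is asked to run
#'   under, preventing silent feature misalignment.
#' @name checkpoint
NULL

pack_numeric <- function(x) {
  if (is.list(x)) return(lapply(x, pack_numeric))
  if (is.matrix(x)) return(list(.dim = dim(x), .data = as.numeric(x)))
  if (is.numeric(x)) return(list(.dim = NULL, .data = as.numeric(x)))
  x
}

unpack_numeric <- function(x) {
  if (is.list(x) && !is.null(names(x)) && identical(sort(names(x)), c(".data", ".dim"))) {
    v <- as.numeric(unlist(x$.data))
    if (length(x$.dim)) return(matrix(v, unlist(x$.dim)[1], unlist(x$.dim)[2]))
    return(v)
  }
  if (is.list(x)) return(lapply(x, unpack_numeric))
  x
}

#' Save a model to a JSON checkpoint
#' @param model `mt_model`.
#' @param path Output file.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mt_model"))
  params <- unclass(model$params)
  sid <- params$schema_id
  params$schema_id <- NULL
  obj <- list(config = unclass(model$config), schema = unclass(model$schema),
              schema_id = sid, params = pack_numeric(params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model from a JSON checkpoint
#' @param path Checkpoint file.
#' @param schema Schema to validate against (default: rebuilt from the
#'   checkpoint itself).
#' @return `mt_model`.
#' @export
load_checkpoint <- function(path, schema = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  cfg <- do.call(mt_model_config, obj$config[c("targets", "graph_feat_size",
                                               "n_attentive_layers",
                                               "n_readout_timesteps", "dropout",
                                               "leakyrelu_slope", "seed")])
  sch <- obj$schema
  sch$atom_dim <- as.integer(sch$atom_dim)
  sch$bond_dim <- as.integer(sch$bond_dim)
  class(sch) <- "feature_schema"
  if (!is.null(schema) && !identical(schema_id(schema), obj$schema_id)) {
    stop("checkpoint was trained under a different feature schema")
  }
  params <- unpack_numeric(obj$params)
  params$schema_id <- obj$schema_id
  class(params) <- "mt_model_state"
  mt_model(cfg, sch, params)
}
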