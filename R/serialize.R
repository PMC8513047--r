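#' Serialize a fitted network to JSON
#'
#' Writes weights, biases, input-scaling constants, hyperparameters and the
#' class-id map; [read_grain_net()] restores a model that predicts
#' identically.
#'
#' @param model A `grain_net`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_grain_net <- function(model, path) {
  payload <- list(
    format = "grainclass-net-1",
    n_hidden = model$n_hidden, algorithm = model$algorithm,
    feature_names = model$feature_names,
    classes = model$classes,
    input_center = as.list(model$input_center),
    input_scale = as.list(model$input_scale),
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    alpha = model$alpha, beta = model$beta, gamma = model$gamma,
    seed = model$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' Restore a network written by [write_grain_net()]
#'
#' @param path JSON path.
#' @return A `grain_net` (without the training trace).
#' @export
read_grain_net <- function(path) {
  p <- jsonlite::fromJSON(path)
  if (!identical(p$format, "grainclass-net-1"))
    stop("not a grainclass network file: ", path)
  structure(list(
    W1 = matrix(p$W1, nrow = p$n_hidden, byrow = FALSE),
    b1 = as.numeric(p$b1),
    W2 = matrix(p$W2, nrow = length(p$classes), byrow = FALSE),
    b2 = as.numeric(p$b2),
    input_center = unlist(p$input_center),
    input_scale = unlist(p$input_scale),
    feature_names = p$feature_names, classes = p$classes,
    n_hidden = p$n_hidden, algorithm = p$algorithm,
    alpha = p$alpha %||% NA_real_, beta = p$beta %||% NA_real_,
    gamma = p$gamma %||% NA_real_,
    n_weights = length(p$W1) + length(p$b1) + length(p$W2) + length(p$b2),
    trace = NULL, stop_reason = "loaded", seed = p$seed),
    class = "grain_net")
}
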