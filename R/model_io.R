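# Model serialization: fitted models round-trip through a JSON document
# holding names, centering/scaling constants, latent vectors, coefficients
# and the selected component count, at full floating-point precision.

#' Write a fitted model to a JSON document
#'
#' @param model A `pls_model` or `linear_model`.
#' @param path Output file path.
#' @param press Optional [press_curve()] stored alongside the model.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path, press = NULL) {
  doc <- unclass(model)
  doc$model_class <- class(model)[1]
  if (!is.null(press)) doc$press <- unclass(press)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "columnmajor")
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path JSON file path.
#' @return The model object; predictions reproduce the original model's to
#'   numerical precision. A stored PRESS curve is attached as attribute
#'   `press`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- doc$model_class
  press <- doc$press
  doc$model_class <- NULL
  doc$press <- NULL
  for (nm in c("coefficients", "x_means", "x_scales")) {
    if (!is.null(doc[[nm]])) {
      doc[[nm]] <- stats::setNames(as.numeric(doc[[nm]]),
                                   doc$predictor_names)
    }
  }
  for (nm in c("weights", "loadings")) {
    if (!is.null(doc[[nm]]) && !is.matrix(doc[[nm]])) {
      doc[[nm]] <- matrix(doc[[nm]], ncol = doc$n_components)
    }
  }
  model <- structure(doc, class = cls)
  if (!is.null(press)) {
    attr(model, "press") <- structure(press, class = "press_curve")
  }
  model
}
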