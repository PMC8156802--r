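# JSON serialization for fitted models: a readable header (parameters,
# class list, feature names) plus array payloads for the stored training
# features and output weights. Full double precision.

#' Save or load a fitted KELM model as JSON
#'
#' @param model A `kelm_model` from [train_kelm()].
#' @param path File path.
#' @return `write_kelm_model()` returns `path` invisibly;
#'   `read_kelm_model()` returns the restored `kelm_model`.
#' @export
write_kelm_model <- function(model, path) {
  if (!inherits(model, "kelm_model"))
    stop("`model` must come from train_kelm()", call. = FALSE)
  obj <- list(
    type = "kelm_model",
    h = model$h, lambda = model$lambda,
    class_list = model$class_list,
    feature_names = model$feature_names,
    Z = model$Z, C = model$C, beta = model$beta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_kelm_model
#' @export
read_kelm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "kelm_model"))
    stop("not a serialized kelm_model: ", path, call. = FALSE)
  Z <- as.matrix(obj$Z)
  colnames(Z) <- obj$feature_names
  C <- as.matrix(obj$C); colnames(C) <- obj$class_list
  beta <- as.matrix(obj$beta); colnames(beta) <- NULL
  structure(list(Z = Z, h = obj$h, lambda = obj$lambda, C = C, beta = beta,
                 class_list = obj$class_list,
                 feature_names = obj$feature_names),
            class = "kelm_model")
}

#' Save or load a fitted gait classifier as JSON
#'
#' Bundles the calibration bounds, normalization statistics and the KELM
#' model so a trained pipeline can be reused from disk.
#'
#' @param clf A `gait_classifier` from [train_gait_classifier()].
#' @param path File path.
#' @return `write_gait_classifier()` returns `path` invisibly;
#'   `read_gait_classifier()` returns the restored `gait_classifier`.
#' @export
write_gait_classifier <- function(clf, path) {
  if (!inherits(clf, "gait_classifier"))
    stop("`clf` must come from train_gait_classifier()", call. = FALSE)
  fin <- function(v) ifelse(is.finite(v), v, NA)
  obj <- list(
    type = "gait_classifier",
    calibration = clf$calibration, gamma = clf$gamma,
    bounds = if (is.null(clf$bounds)) NULL else list(
      p_th = attr(clf$bounds, "p_th"),
      feature = clf$bounds$feature,
      z_lb = fin(clf$bounds$z_lb), z_ub = fin(clf$bounds$z_ub),
      rho = fin(clf$bounds$rho), center = clf$bounds$center),
    normalizer = list(center = clf$normalizer$center,
                      scale = clf$normalizer$scale),
    kelm = list(h = clf$kelm$h, lambda = clf$kelm$lambda,
                class_list = clf$kelm$class_list,
                feature_names = clf$kelm$feature_names,
                Z = clf$kelm$Z, C = clf$kelm$C, beta = clf$kelm$beta)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' @rdname write_gait_classifier
#' @export
read_gait_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "gait_classifier"))
    stop("not a serialized gait_classifier: ", path, call. = FALSE)
  bounds <- NULL
  if (!is.null(obj$bounds)) {
    b <- obj$bounds
    unnull <- function(v, d) ifelse(is.na(v), d, v)
    bounds <- structure(
      data.frame(feature = b$feature, z_lb = unnull(b$z_lb, -Inf),
                 z_ub = unnull(b$z_ub, Inf), rho = b$rho,
                 center = b$center),
      p_th = b$p_th, class = c("feature_bounds", "data.frame"))
  }
  k <- obj$kelm
  Z <- as.matrix(k$Z); colnames(Z) <- k$feature_names
  C <- as.matrix(k$C); colnames(C) <- k$class_list
  beta <- as.matrix(k$beta); colnames(beta) <- NULL
  kelm <- structure(list(Z = Z, h = k$h, lambda = k$lambda, C = C,
                         beta = beta, class_list = k$class_list,
                         feature_names = k$feature_names),
                    class = "kelm_model")
  normalizer <- structure(
    list(center = stats::setNames(obj$normalizer$center, k$feature_names),
         scale = stats::setNames(obj$normalizer$scale, k$feature_names)),
    class = "feature_normalizer")
  structure(list(kelm = kelm, bounds = bounds, normalizer = normalizer,
                 calibration = obj$calibration, gamma = obj$gamma,
                 class_list = kelm$class_list),
            class = "gait_classifier")
}
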