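#' Radial-basis-function Gram matrix
#'
#' Computes `K[i, j] = exp(-||a_i - b_j||^2 / h)` between the rows of two
#' feature matrices. With `A == B` the result is symmetric with unit
#' diagonal; all entries lie in `(0, 1]`.
#'
#' @param A,B Numeric matrices with matching column counts (rows = samples).
#' @param h Positive kernel bandwidth. Typical grid: `2^(-9:9)`.
#' @return `nrow(A) x nrow(B)` kernel matrix.
#' @export
rbf_gram <- function(A, B = A, h) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B))
    stop("`A` and `B` must have the same number of columns", call. = FALSE)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("kernel bandwidth `h` must be a single positive number",
         call. = FALSE)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0  # guard against negative round-off
  exp(-d2 / h)
}

#' Train a kernel extreme learning machine
#'
#' A kernel extreme learning machine (KELM) is a kernel ridge classifier
#' trained in one closed-form solve. Class labels are one-vs-rest coded in a
#' target matrix `C` with `+1` in the true-class column and `-1` elsewhere,
#' and the output weights solve the regularized linear system
#' `beta = (K + I / lambda)^{-1} C` with `K` the RBF Gram matrix of the
#' training features. The solve uses a Cholesky factorization of the
#' symmetric positive-definite system; no iteration is involved.
#'
#' @param Z Training feature matrix (rows = frames), already calibrated and
#'   normalized.
#' @param labels Class label per row (factor or character); at least 2
#'   distinct classes, and at least as many rows as classes.
#' @param h RBF bandwidth, `> 0`. Default `2^3`. Typical grid `2^(-9:9)`.
#' @param lambda Ridge regularization, `> 0`. Default `1e4`. Typical grid
#'   `10^(-9:9)`. Larger `lambda` means weaker regularization; as
#'   `lambda -> Inf` the training outputs interpolate the coding matrix.
#' @return An object of class `kelm_model` storing `Z`, `h`, `lambda`, the
#'   coding matrix `C`, the output weights `beta` and the ordered
#'   `class_list`.
#' @seealso [predict_outputs()], [hard_decision()]
#' @export
train_kelm <- function(Z, labels, h = 2^3, lambda = 1e4) {
  Z <- as.matrix(Z)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0)
    stop("`lambda` must be a single positive number", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(Z))
    stop("one label per training row is required", call. = FALSE)
  class_list <- unique(labels)
  if (length(class_list) < 2L)
    stop("at least 2 classes are required for training", call. = FALSE)
  if (nrow(Z) < length(class_list))
    stop("need at least as many training rows as classes", call. = FALSE)
  dup <- duplicated(Z) | duplicated(Z, fromLast = TRUE)
  if (any(dup)) {
    key <- apply(Z[dup, , drop = FALSE], 1, paste, collapse = "\r")
    if (any(tapply(labels[dup], key, function(l) length(unique(l))) > 1L))
      warning("duplicate feature rows with conflicting labels; the fitted ",
              "outputs will average their codings")
  }
  C <- matrix(-1, nrow(Z), length(class_list),
              dimnames = list(NULL, class_list))
  C[cbind(seq_len(nrow(Z)), match(labels, class_list))] <- 1
  K <- rbf_gram(Z, Z, h)
  R <- chol(K + diag(1 / lambda, nrow(Z)))
  beta <- backsolve(R, backsolve(R, C, transpose = TRUE))
  structure(list(Z = Z, h = h, lambda = lambda, C = C, beta = beta,
                 class_list = class_list,
                 feature_names = colnames(Z)),
            class = "kelm_model")
}

#' @export
print.kelm_model <- function(x, ...) {
  cat(sprintf(
    "kelm_model: %d training frames, %d features, %d classes, h = %g, lambda = %g\n",
    nrow(x$Z), ncol(x$Z), length(x$class_list), x$h, x$lambda))
  invisible(x)
}

#' Continuous KELM outputs for new frames
#'
#' Evaluates `o = K(z, Z) beta` for each input row: one real-valued score
#' per class, higher meaning more plausible membership. Deterministic.
#'
#' @param model A `kelm_model`.
#' @param features Feature matrix preprocessed exactly like the training
#'   data (same calibration and normalization).
#' @return Numeric matrix, one row per input frame, one column per class.
#' @export
predict_outputs <- function(model, features) {
  if (!inherits(model, "kelm_model"))
    stop("`model` must come from train_kelm()", call. = FALSE)
  X <- as.matrix(features)
  if (is.null(dim(features)) && length(features) == ncol(model$Z))
    X <- matrix(features, nrow = 1)
  if (ncol(X) != ncol(model$Z))
    stop("feature column count (", ncol(X), ") does not match the model (",
         ncol(model$Z), ")", call. = FALSE)
  out <- rbf_gram(X, model$Z, model$h) %*% model$beta
  colnames(out) <- model$class_list
  out
}

#' Hard decision from continuous outputs
#'
#' Picks the class with maximal output score; ties are broken
#' deterministically in favor of the lowest class index.
#'
#' @param o Output vector (length = number of classes) or matrix (one row
#'   per frame).
#' @param class_list Ordered class labels; defaults to the names/colnames of
#'   `o`.
#' @return Class label (or vector of labels for matrix input).
#' @export
hard_decision <- function(o, class_list = NULL) {
  if (is.matrix(o)) {
    if (is.null(class_list)) class_list <- colnames(o)
    if (is.null(class_list)) class_list <- seq_len(ncol(o))
    return(class_list[apply(o, 1, which.max)])
  }
  if (length(o) == 0L) stop("empty output vector", call. = FALSE)
  if (is.null(class_list)) class_list <- names(o)
  if (is.null(class_list)) class_list <- seq_along(o)
  class_list[which.max(o)]
}

#' @export
predict.kelm_model <- function(object, newdata,
                               type = c("class", "outputs", "membership"),
                               gamma = 0.5, ...) {
  type <- match.arg(type)
  o <- predict_outputs(object, newdata)
  switch(type,
         outputs = o,
         class = hard_decision(o, object$class_list),
         membership = fuzzy_membership(o, gamma = gamma))
}
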