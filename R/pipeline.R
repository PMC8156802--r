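# End-to-end classifier: feature extraction -> unreliable-feature
# calibration -> z-score normalization -> KELM, with per-trajectory decision
# fusion on top.

#' Per-frame features and labels of a whole dataset
#'
#' Runs [extract_feature_sequence()] on every trajectory and stacks the
#' rows, keeping the subject label and trajectory index per row.
#'
#' @param dataset A [gait_dataset].
#' @return List with `X` (feature matrix), `y` (character label per row) and
#'   `trajectory` (integer trajectory index per row).
#' @export
dataset_features <- function(dataset) {
  stopifnot(inherits(dataset, "gait_dataset"))
  mats <- lapply(dataset$trajectories, extract_feature_sequence)
  nrows <- vapply(mats, nrow, integer(1))
  list(X = do.call(rbind, mats),
       y = rep(dataset_subjects(dataset), nrows),
       trajectory = rep(seq_along(mats), nrows))
}

#' Train the full gait classification pipeline
#'
#' Fits, in order: per-feature KDE calibration bounds on the pooled raw
#' training features (unless `calibration = "off"`), z-score normalization
#' statistics on the calibrated features, and the KELM classifier on the
#' normalized features. Test data later pass through the identical
#' transformations with the training-fitted bounds and statistics.
#'
#' @param train A [gait_dataset] with at least 2 classes.
#' @param h,lambda KELM kernel bandwidth and regularization
#'   ([train_kelm()]).
#' @param p_th Calibration tail threshold (default 0.999).
#' @param calibration `"clamp"` (default), `"mean"` or `"off"`.
#' @param gamma Membership spread parameter used at prediction time.
#' @return An object of class `gait_classifier` bundling the fitted
#'   `bounds`, `normalizer` and `kelm` model.
#' @export
train_gait_classifier <- function(train, h = 2^3, lambda = 1e4,
                                  p_th = 0.999,
                                  calibration = c("clamp", "mean", "off"),
                                  gamma = 0.5) {
  calibration <- match.arg(calibration)
  stopifnot(inherits(train, "gait_dataset"))
  if (length(train$class_list) < 2L)
    stop("training needs at least 2 classes", call. = FALSE)
  feats <- dataset_features(train)
  bounds <- NULL
  X <- feats$X
  if (calibration != "off") {
    bounds <- suppressWarnings(fit_feature_bounds(X, p_th = p_th))
    X <- calibrate_features(X, bounds, strategy = calibration)
  }
  normalizer <- fit_normalizer(X)
  model <- train_kelm(apply_normalizer(normalizer, X), feats$y,
                      h = h, lambda = lambda)
  structure(list(kelm = model, bounds = bounds, normalizer = normalizer,
                 calibration = calibration, gamma = gamma,
                 class_list = model$class_list),
            class = "gait_classifier")
}

#' @export
print.gait_classifier <- function(x, ...) {
  cat(sprintf(
    "gait_classifier: %d classes, calibration '%s', h = %g, lambda = %g\n",
    length(x$class_list), x$calibration, x$kelm$h, x$kelm$lambda))
  invisible(x)
}

prepare_features <- function(clf, X) {
  if (clf$calibration != "off")
    X <- calibrate_features(X, clf$bounds, strategy = clf$calibration)
  apply_normalizer(clf$normalizer, X)
}

#' Per-frame predictions for a trajectory or feature matrix
#'
#' @param clf A `gait_classifier`.
#' @param newdata A [gait_trajectory], [gait_dataset] or raw feature matrix.
#' @param type `"class"`, `"outputs"` or `"membership"`.
#' @return Labels, output matrix, or membership matrix (one row per frame).
#' @export
classify_frames <- function(clf, newdata,
                            type = c("class", "outputs", "membership")) {
  type <- match.arg(type)
  stopifnot(inherits(clf, "gait_classifier"))
  X <- if (inherits(newdata, "gait_trajectory"))
    extract_feature_sequence(newdata)
  else if (inherits(newdata, "gait_dataset"))
    dataset_features(newdata)$X
  else as.matrix(newdata)
  predict(clf$kelm, prepare_features(clf, X), type = type,
          gamma = clf$gamma)
}

#' Fused subject decision for one trajectory
#'
#' Computes per-frame fuzzy decisions for the leading fraction `ratio` of
#' the trajectory's feature frames and fuses them with the chosen rule.
#'
#' @param clf A `gait_classifier`.
#' @param traj A [gait_trajectory].
#' @param rule Fusion rule (see [fuse_decisions()]); default `"rws"`.
#' @param ratio Fraction of feature frames to fuse, in `(0, 1]`; the leading
#'   `ceiling(ratio * T)` frames are used (`subset_mode = "leading"`), or a
#'   random subset of that size (`subset_mode = "random"`).
#' @param subset_mode `"leading"` (default) or `"random"`.
#' @param seed Seed for `subset_mode = "random"`.
#' @param ... Passed to the fusion rule (`a`, `b`, `delta`, ...).
#' @return A `global_decision`; `$winner` is the predicted subject label.
#' @export
classify_trajectory <- function(clf, traj, rule = "rws", ratio = 1,
                                subset_mode = c("leading", "random"),
                                seed = NULL, ...) {
  subset_mode <- match.arg(subset_mode)
  if (!is.numeric(ratio) || ratio <= 0 || ratio > 1)
    stop("`ratio` must lie in (0, 1]", call. = FALSE)
  mu <- classify_frames(clf, traj, type = "membership")
  k <- max(1L, ceiling(ratio * nrow(mu)))
  keep <- if (subset_mode == "leading") seq_len(k) else
    with_seed(seed, sort(sample.int(nrow(mu), k)))
  fuse_decisions(mu[keep, , drop = FALSE], rule = rule,
                 class_list = clf$class_list, ...)
}

#' Fraction of exactly matching predictions
#'
#' @param predictions,truth Equal-length label vectors (length >= 1).
#' @return Accuracy in `[0, 1]`.
#' @export
frame_accuracy <- function(predictions, truth) {
  if (length(predictions) != length(truth) || length(truth) < 1L)
    stop("`predictions` and `truth` must have equal positive length",
         call. = FALSE)
  mean(as.character(predictions) == as.character(truth))
}

#' Select KELM parameters by validation trials
#'
#' Grid search over the kernel bandwidth and regularization, scored on a
#' held-out tail of every training recording. Each trajectory's leading
#' `1 - val_fraction` feature rows train the classifier and the trailing
#' rows are scored. The score is the per-frame accuracy of the arg-max of
#' the fuzzy memberships — the frame-level decision that the fusion rules
#' actually consume — so the selected parameters keep the classifier
#' outputs on a scale where the membership transformation is
#' discriminative. Ties go to the first grid point.
#'
#' @param train A [gait_dataset].
#' @param h_grid,lambda_grid Candidate grids (subsets of the conventional
#'   `2^(-9:9)` and `10^(-9:9)` grids).
#' @param val_fraction Fraction of each recording's frames held out for
#'   scoring (default 0.25).
#' @param p_th,calibration Calibration settings (fitted on the training
#'   part only).
#' @param gamma Membership spread parameter.
#' @return List with the selected `h` and `lambda` and the full `table` of
#'   validation accuracies.
#' @export
select_kelm_params <- function(train,
                               h_grid = 2^seq(-2, 8, by = 2),
                               lambda_grid = 10^seq(-3, 1, by = 1),
                               val_fraction = 0.25, p_th = 0.999,
                               calibration = c("clamp", "mean", "off"),
                               gamma = 0.5) {
  calibration <- match.arg(calibration)
  stopifnot(inherits(train, "gait_dataset"))
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("`val_fraction` must lie in (0, 1)", call. = FALSE)
  mats <- lapply(train$trajectories, extract_feature_sequence)
  subjects <- dataset_subjects(train)
  split <- lapply(mats, function(m) {
    k <- max(1L, floor((1 - val_fraction) * nrow(m)))
    k <- min(k, nrow(m) - 1L)
    list(fit = m[seq_len(k), , drop = FALSE],
         val = m[(k + 1L):nrow(m), , drop = FALSE])
  })
  Xfit <- do.call(rbind, lapply(split, `[[`, "fit"))
  yfit <- rep(subjects, vapply(split, function(s) nrow(s$fit), integer(1)))
  Xval <- do.call(rbind, lapply(split, `[[`, "val"))
  yval <- rep(subjects, vapply(split, function(s) nrow(s$val), integer(1)))
  if (calibration != "off") {
    bounds <- suppressWarnings(fit_feature_bounds(Xfit, p_th = p_th))
    Xfit <- calibrate_features(Xfit, bounds, strategy = calibration)
    Xval <- calibrate_features(Xval, bounds, strategy = calibration)
  }
  nrm <- fit_normalizer(Xfit)
  Xfit <- apply_normalizer(nrm, Xfit)
  Xval <- apply_normalizer(nrm, Xval)
  tab <- expand.grid(h = h_grid, lambda = lambda_grid)
  tab$accuracy <- mapply(function(h, lambda) {
    model <- train_kelm(Xfit, yfit, h = h, lambda = lambda)
    # remote grid corners can underflow every output to 0; the degenerate
    # equal-membership fallback simply scores badly, so keep quiet here
    mu <- suppressWarnings(
      predict(model, Xval, type = "membership", gamma = gamma))
    frame_accuracy(model$class_list[apply(mu, 1, which.max)], yval)
  }, tab$h, tab$lambda)
  best <- which.max(tab$accuracy)
  list(h = tab$h[best], lambda = tab$lambda[best], table = tab)
}

#' Fused accuracy versus fraction of test frames
#'
#' For every rule and every ratio in the grid, fuses the leading
#' `ceiling(ratio * T)` per-frame decisions of each test trajectory and
#' scores subject-level accuracy. Also reports single-frame accuracy (the
#' hard arg-max of the classifier outputs) over all test frames and the
#' subject-level confusion counts at ratio 1 for the first rule.
#'
#' @param clf A `gait_classifier`.
#' @param test A [gait_dataset].
#' @param rules Character vector of fusion rules (default all six).
#' @param ratios Strictly increasing ratio grid in `(0, 1]` (default
#'   `seq(0.1, 1, by = 0.1)`).
#' @param ... Passed to the fusion rules (`a`, `b`, `delta`, ...).
#' @return An object of class `eval_result`: list with `curve` (data frame
#'   `rule`, `ratio`, `accuracy`), `single_frame_accuracy`, and `confusion`.
#' @export
fusion_accuracy_curve <- function(clf, test,
                                  rules = c("rws", "sum", "product",
                                            "majority", "belief", "wbelief"),
                                  ratios = seq(0.1, 1, by = 0.1), ...) {
  stopifnot(inherits(clf, "gait_classifier"), inherits(test, "gait_dataset"))
  if (any(ratios <= 0 | ratios > 1))
    stop("ratios must lie in (0, 1]", call. = FALSE)
  if (any(diff(ratios) <= 0))
    stop("`ratios` must be strictly increasing", call. = FALSE)
  truth <- dataset_subjects(test)
  outputs <- lapply(test$trajectories, classify_frames, clf = clf,
                    type = "outputs")
  memberships <- lapply(outputs, fuzzy_membership, gamma = clf$gamma)
  # single-frame accuracy: hard decision = arg-max classifier output
  frame_pred <- unlist(lapply(outputs, function(o)
    clf$class_list[apply(o, 1, which.max)]))
  frame_truth <- rep(truth, vapply(outputs, nrow, integer(1)))
  sf_acc <- frame_accuracy(frame_pred, frame_truth)
  grid <- expand.grid(rule = rules, ratio = ratios,
                      stringsAsFactors = FALSE)
  grid$accuracy <- mapply(function(rule, ratio) {
    pred <- vapply(memberships, function(mu) {
      k <- max(1L, ceiling(ratio * nrow(mu)))
      fuse_decisions(mu[seq_len(k), , drop = FALSE], rule = rule,
                     class_list = clf$class_list, ...)$winner
    }, character(1))
    frame_accuracy(pred, truth)
  }, grid$rule, grid$ratio)
  pred_full <- vapply(memberships, function(mu)
    fuse_decisions(mu, rule = rules[1], class_list = clf$class_list,
                   ...)$winner, character(1))
  confusion <- table(truth = factor(truth, clf$class_list),
                     predicted = factor(pred_full, clf$class_list))
  structure(list(curve = grid, single_frame_accuracy = sf_acc,
                 confusion = confusion, rules = rules),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: single-frame accuracy %.3f\n",
              x$single_frame_accuracy))
  wide <- stats::reshape(x$curve, idvar = "ratio", timevar = "rule",
                         direction = "wide")
  names(wide) <- sub("^accuracy\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}
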