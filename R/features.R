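#' Pairwise marker-distance features of one frame
#'
#' Computes the Euclidean distance between every pair of markers in a single
#' motion frame and returns the strictly-upper-triangle entries of the
#' symmetric distance matrix in row-major order
#' (`d_{1,2}, d_{1,3}, ..., d_{m-1,m}`). With the standard 10-marker set this
#' is a vector of length `10 * 9 / 2 = 45`. Relative distances capture both
#' body shape and the momentary pose, and are invariant to rigid motion of
#' the whole marker set.
#'
#' @param frame An `M x 3` numeric matrix of marker positions (meters), e.g.
#'   from [marker_frame()].
#' @return Numeric vector of length `M(M-1)/2`, named `d_01_02`, ...
#' @examples
#' f <- matrix(0, 10, 3); f[2, ] <- c(3, 4, 0)
#' pairwise_distance_features(f)[["d_01_02"]]  # 5
#' @export
pairwise_distance_features <- function(frame) {
  frame <- as.matrix(frame)
  if (ncol(frame) != 3L || nrow(frame) < 2L)
    stop("`frame` must be an M x 3 matrix with M >= 2", call. = FALSE)
  if (!all(is.finite(frame)))
    stop("marker coordinates must be finite", call. = FALSE)
  d <- as.vector(stats::dist(frame))  # dist order == row-major upper triangle
  m <- nrow(frame)
  idx <- which(upper.tri(diag(m)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  names(d) <- sprintf("d_%02d_%02d", idx[, 1], idx[, 2])
  d
}

#' Forward-difference x-axis velocity features
#'
#' Estimates the walking-direction (x-axis) velocity of each marker from two
#' consecutive frames: `v_i = (x_i^{t+1} - x_i^t) / tau`. Values are signed;
#' direction is preserved.
#'
#' @param frame_t,frame_next `M x 3` marker-position matrices of consecutive
#'   frames.
#' @param tau Sampling interval in seconds, `> 0`.
#' @return Numeric vector of length `M`, named `v_01`, ...
#' @export
velocity_features <- function(frame_t, frame_next, tau) {
  frame_t <- as.matrix(frame_t); frame_next <- as.matrix(frame_next)
  if (!identical(dim(frame_t), dim(frame_next)))
    stop("frames must have identical dimensions", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("`tau` must be a single positive number", call. = FALSE)
  v <- (frame_next[, 1] - frame_t[, 1]) / tau
  names(v) <- sprintf("v_%02d", seq_along(v))
  v
}

#' Per-frame feature matrix of a trajectory
#'
#' Concatenates, for every frame `t = 1, ..., T-1`, the pairwise distance
#' features of frame `t` with the forward-difference x-velocities between
#' frames `t` and `t+1`. The last frame has no forward difference and
#' contributes no row, so a `T`-frame trajectory yields `T - 1` feature rows.
#' With 10 markers each row has `45 + 10 = 55` entries.
#'
#' @param traj A [gait_trajectory].
#' @return Numeric matrix of dimension `(T-1) x (M(M-1)/2 + M)` with feature
#'   column names (`d_01_02, ..., v_01, ...`).
#' @export
extract_feature_sequence <- function(traj) {
  if (!inherits(traj, "gait_trajectory"))
    stop("`traj` must be a gait_trajectory", call. = FALSE)
  nt <- n_frames(traj)
  if (nt < 2L)
    stop("insufficient data: at least 2 frames are required", call. = FALSE)
  nm <- n_markers(traj)
  kd <- nm * (nm - 1L) / 2L
  out <- matrix(NA_real_, nt - 1L, kd + nm)
  for (t in seq_len(nt - 1L)) {
    ft <- traj$coords[t, , , drop = TRUE]
    fn <- traj$coords[t + 1L, , , drop = TRUE]
    out[t, ] <- c(pairwise_distance_features(ft),
                  velocity_features(ft, fn, traj$tau))
  }
  colnames(out) <- c(names(pairwise_distance_features(
                       traj$coords[1, , , drop = TRUE])),
                     sprintf("v_%02d", seq_len(nm)))
  out
}

#' Fit per-feature z-score normalization statistics
#'
#' Feature magnitudes differ strongly between distances (meters) and
#' velocities (meters/second), so features are z-scored before
#' classification. Statistics are fitted on the training split only and then
#' applied unchanged to test data. Zero-variance columns get scale 1 (with a
#' warning) so normalization maps them to 0.
#'
#' @param train_features Non-empty numeric feature matrix (rows = frames).
#' @return An object of class `feature_normalizer` with `center` and `scale`
#'   vectors.
#' @export
fit_normalizer <- function(train_features) {
  x <- as.matrix(train_features)
  if (nrow(x) == 0L || ncol(x) == 0L)
    stop("training feature matrix must be non-empty", call. = FALSE)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)  # sample (n-1) standard deviation
  if (nrow(x) == 1L) scale[] <- NA_real_
  degenerate <- !is.finite(scale) | scale == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance feature column(s); using scale 1")
    scale[degenerate] <- 1
  }
  structure(list(center = center, scale = scale),
            class = "feature_normalizer")
}

#' Apply fitted normalization statistics
#'
#' @param stats A `feature_normalizer` from [fit_normalizer()].
#' @param features Feature matrix with the same column count (and order) as
#'   the training matrix.
#' @return Matrix of z-scored features.
#' @export
apply_normalizer <- function(stats, features) {
  if (!inherits(stats, "feature_normalizer"))
    stop("`stats` must come from fit_normalizer()", call. = FALSE)
  x <- as.matrix(features)
  if (ncol(x) != length(stats$center))
    stop("feature column count does not match the fitted normalizer",
         call. = FALSE)
  out <- sweep(sweep(x, 2, stats$center, "-"), 2, stats$scale, "/")
  dimnames(out) <- dimnames(x)
  out
}
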