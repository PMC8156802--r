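#' Standard lower-body marker set
#'
#' Marker naming convention used throughout the package: five markers per
#' body side, ordered left side first. On each side the markers sit at the
#' thigh, the shank (below the knee), the ankle on the shin side, the ankle
#' on the foot side, and the tiptoe.
#'
#' @format Character vector of length 10.
#' @export
gait_marker_names <- c(
  "L_thigh", "L_shank", "L_ankle_shin", "L_ankle_foot", "L_tiptoe",
  "R_thigh", "R_shank", "R_ankle_shin", "R_ankle_foot", "R_tiptoe"
)

#' Construct a gait trajectory
#'
#' A gait trajectory is an ordered sequence of motion-capture frames, each
#' holding the 3-D positions (meters) of a fixed set of body markers, together
#' with the subject label and the sampling interval `tau` (seconds; default
#' 0.2 s, i.e. 5 Hz).
#'
#' @param coords Numeric array of dimension `T x M x 3` (frames, markers,
#'   x/y/z), all values finite, in meters. `M` is 10 for the standard marker
#'   set; marker subsets with `M >= 2` are allowed for in-memory analysis.
#' @param subject Subject label (coerced to character, length 1).
#' @param tau Sampling interval in seconds, `> 0`.
#' @param frame_index Optional integer vector of strictly increasing,
#'   non-negative frame indices (default `1:T`).
#' @param marker_names Optional character vector of marker names; defaults to
#'   [gait_marker_names] when `M == 10`.
#'
#' @return An object of class `gait_trajectory` with elements `coords`,
#'   `subject`, `tau` and `frame_index`.
#' @examples
#' coords <- array(rnorm(2 * 10 * 3), dim = c(2, 10, 3))
#' traj <- gait_trajectory(coords, subject = "S01")
#' n_frames(traj)
#' @export
gait_trajectory <- function(coords, subject, tau = 0.2, frame_index = NULL,
                            marker_names = NULL) {
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("`coords` must be a T x M x 3 numeric array", call. = FALSE)
  storage.mode(coords) <- "double"
  nt <- dim(coords)[1]
  nm <- dim(coords)[2]
  if (nt < 2L)
    stop("a gait trajectory needs at least 2 frames (velocities use ",
         "consecutive frame pairs)", call. = FALSE)
  if (nm < 2L)
    stop("at least 2 markers are required", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("all marker coordinates must be finite", call. = FALSE)
  if (length(subject) != 1L || is.na(subject))
    stop("`subject` must be a single non-missing label", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("`tau` must be a single positive number (seconds)", call. = FALSE)
  if (is.null(frame_index)) frame_index <- seq_len(nt)
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != nt || anyNA(frame_index) ||
      any(frame_index < 0L) || any(diff(frame_index) <= 0L))
    stop("`frame_index` must be non-negative and strictly increasing, one ",
         "entry per frame", call. = FALSE)
  if (is.null(marker_names))
    marker_names <- if (nm == 10L) gait_marker_names else
      sprintf("m%02d", seq_len(nm))
  if (length(marker_names) != nm)
    stop("`marker_names` length must equal the number of markers",
         call. = FALSE)
  dimnames(coords) <- list(NULL, marker_names, c("x", "y", "z"))
  structure(
    list(coords = coords, subject = as.character(subject), tau = tau,
         frame_index = frame_index),
    class = "gait_trajectory"
  )
}

#' Number of frames in a trajectory
#' @param x A `gait_trajectory`.
#' @return Integer count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "gait_trajectory"))
  dim(x$coords)[1]
}

#' Number of markers in a trajectory
#' @param x A `gait_trajectory`.
#' @return Integer count.
#' @export
n_markers <- function(x) {
  stopifnot(inherits(x, "gait_trajectory"))
  dim(x$coords)[2]
}

#' Extract one marker frame
#'
#' @param x A `gait_trajectory`.
#' @param t Frame position (1-based row in the trajectory).
#' @return An `M x 3` numeric matrix of marker positions (meters).
#' @export
marker_frame <- function(x, t) {
  stopifnot(inherits(x, "gait_trajectory"))
  t <- as.integer(t)
  if (t < 1L || t > n_frames(x)) stop("frame position out of range", call. = FALSE)
  x$coords[t, , , drop = TRUE]
}

#' @export
print.gait_trajectory <- function(x, ...) {
  cat(sprintf(
    "gait_trajectory: subject '%s', %d frames x %d markers, tau = %g s (%g Hz)\n",
    x$subject, n_frames(x), n_markers(x), x$tau, 1 / x$tau))
  invisible(x)
}

#' Construct a gait dataset
#'
#' Bundles trajectories from several subjects with the ordered list of
#' distinct subject labels (the class list used for classifier training).
#'
#' @param trajectories List of [gait_trajectory] objects.
#' @param class_list Optional character vector of class labels; defaults to
#'   the distinct subject labels in order of first appearance. Every
#'   trajectory subject must appear in it.
#'
#' @return An object of class `gait_dataset` with elements `trajectories` and
#'   `class_list`.
#' @export
gait_dataset <- function(trajectories, class_list = NULL) {
  if (!is.list(trajectories) || length(trajectories) == 0L ||
      !all(vapply(trajectories, inherits, logical(1), "gait_trajectory")))
    stop("`trajectories` must be a non-empty list of gait_trajectory objects",
         call. = FALSE)
  subjects <- vapply(trajectories, function(tr) tr$subject, character(1))
  if (is.null(class_list)) class_list <- unique(subjects)
  class_list <- as.character(class_list)
  if (anyDuplicated(class_list))
    stop("`class_list` must not contain duplicates", call. = FALSE)
  if (!all(subjects %in% class_list))
    stop("every trajectory subject must appear in `class_list`",
         call. = FALSE)
  nm <- unique(vapply(trajectories, n_markers, integer(1)))
  if (length(nm) != 1L)
    stop("all trajectories must share the same marker count", call. = FALSE)
  structure(list(trajectories = trajectories, class_list = class_list),
            class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  nf <- vapply(x$trajectories, n_frames, integer(1))
  cat(sprintf(
    "gait_dataset: %d trajectories, %d classes, %d markers, %d total frames\n",
    length(x$trajectories), length(x$class_list),
    n_markers(x$trajectories[[1]]), sum(nf)))
  invisible(x)
}

#' Subject labels of a dataset
#' @param x A `gait_dataset`.
#' @return Character vector, one label per trajectory.
#' @export
dataset_subjects <- function(x) {
  stopifnot(inherits(x, "gait_dataset"))
  vapply(x$trajectories, function(tr) tr$subject, character(1))
}

#' Restrict a trajectory or dataset to a marker subset
#'
#' Keeps only the listed markers, e.g. the six-tracker configuration with one
#' marker at the thigh, shank and ankle of each side. The downstream feature
#' dimension becomes `m(m-1)/2 + m` for `m` retained markers.
#'
#' @param x A `gait_trajectory` or `gait_dataset`.
#' @param markers Integer indices or marker names to keep; at least 2.
#' @return Object of the same class restricted to the chosen markers.
#' @examples
#' # one tracker at thigh, shank and ankle per side:
#' # tracker_subset(ds, c(1, 2, 4, 6, 7, 9))
#' @export
tracker_subset <- function(x, markers) UseMethod("tracker_subset")

#' @export
tracker_subset.gait_trajectory <- function(x, markers) {
  nm <- n_markers(x)
  if (is.character(markers))
    markers <- match(markers, dimnames(x$coords)[[2]])
  markers <- as.integer(markers)
  if (anyNA(markers) || any(markers < 1L) || any(markers > nm))
    stop("invalid marker index", call. = FALSE)
  if (anyDuplicated(markers)) stop("duplicate marker index", call. = FALSE)
  if (length(markers) < 2L)
    stop("at least 2 markers must be retained (pairwise distances need ",
         "marker pairs)", call. = FALSE)
  gait_trajectory(x$coords[, markers, , drop = FALSE], x$subject, x$tau,
                  x$frame_index,
                  marker_names = dimnames(x$coords)[[2]][markers])
}

#' @export
tracker_subset.gait_dataset <- function(x, markers) {
  gait_dataset(lapply(x$trajectories, tracker_subset, markers = markers),
               class_list = x$class_list)
}
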