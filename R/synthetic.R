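# Synthetic gait-trajectory generator. A planar two-link (thigh-shank)
# kinematic model with antiphase legs gives each subject a distinguishable
# distance/velocity signature: hips advance at the subject's walking speed
# along x, thigh and knee angles follow sinusoids at the subject's gait
# frequency, and the ten markers are placed along the segments with fixed
# lateral (y) offsets per side. Gaussian sensor noise and sporadic outlier
# displacements emulate optical-capture artifacts.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(seed)
    return(expr)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Draw a synthetic subject population
#'
#' Samples per-subject anthropometric and gait parameters. Body height is
#' uniform on 1.44-1.78 m; segment lengths scale with height (thigh 24.5%,
#' shank 24.6%, foot 15.2%, hip height 53%); gait frequency is uniform on
#' 0.8-1.2 Hz (within the plausible 0.5-1.5 Hz band); stride length scales
#' with height so walking speed is `stride * frequency`; thigh-swing and
#' knee-flexion amplitudes, the gait phase offset and the lateral hip
#' half-width are drawn independently. All draws are deterministic given
#' `seed`.
#'
#' @param n_subjects Number of subjects, `>= 2`.
#' @param seed Optional integer seed.
#' @return A data frame of class `gait_population`, one row per subject,
#'   with columns `subject`, `height`, `thigh`, `shank`, `foot`,
#'   `hip_height`, `hip_halfwidth`, `frequency`, `stride`, `speed`,
#'   `swing_amp`, `knee_amp`, `phase`.
#' @export
sample_population <- function(n_subjects, seed = NULL) {
  if (!is.numeric(n_subjects) || n_subjects < 2L)
    stop("`n_subjects` must be at least 2", call. = FALSE)
  n <- as.integer(n_subjects)
  with_seed(seed, {
    height <- stats::runif(n, 1.44, 1.78)
    pop <- data.frame(
      subject = sprintf("S%02d", seq_len(n)),
      height = height,
      thigh = 0.245 * height * stats::runif(n, 0.96, 1.04),
      shank = 0.246 * height * stats::runif(n, 0.96, 1.04),
      foot = 0.152 * height * stats::runif(n, 0.95, 1.05),
      hip_height = 0.53 * height,
      hip_halfwidth = stats::runif(n, 0.08, 0.12),
      frequency = stats::runif(n, 0.8, 1.2),
      stride = 0.62 * height * stats::runif(n, 0.9, 1.1),
      swing_amp = stats::runif(n, 0.25, 0.40),
      knee_amp = stats::runif(n, 0.35, 0.60),
      phase = stats::runif(n, 0, 2 * pi),
      stringsAsFactors = FALSE
    )
    pop$speed <- pop$stride * pop$frequency
    if (any(pop$frequency < 0.5 | pop$frequency > 1.5))
      stop("gait frequency outside the plausible 0.5-1.5 Hz band")
    class(pop) <- c("gait_population", "data.frame")
    pop
  })
}

#' Simulate one marker trajectory for a subject
#'
#' Forward kinematics of the planar two-link leg model: per side, the thigh
#' angle is `swing_amp * sin(theta)` about the vertical with
#' `theta = 2 pi f t + phase` (right leg in antiphase), the knee flexes by
#' `knee_amp * (1 + cos(theta - pi/2)) / 2`, and the five side markers sit
#' at mid-thigh, mid-shank, two ankle positions and the tiptoe. Hips
#' translate along x at the walking speed. I.i.d. Gaussian noise of standard
#' deviation `noise_sd` is added to every coordinate. Deterministic given
#' `seed`.
#'
#' @param subject One row of a `gait_population` (or a list with the same
#'   fields).
#' @param n_frames Number of frames, `>= 2`.
#' @param tau Sampling interval in seconds (default 0.2, i.e. 5 Hz).
#' @param noise_sd Sensor noise standard deviation in meters (default
#'   0.002).
#' @param phase_offset Additional gait-phase offset in radians for this
#'   recording (default 0); recordings of the same subject start at
#'   arbitrary points of the gait cycle.
#' @param seed Optional integer seed.
#' @return A [gait_trajectory] with 10 markers.
#' @export
simulate_trajectory <- function(subject, n_frames, tau = 0.2,
                                noise_sd = 0.002, phase_offset = 0,
                                seed = NULL) {
  s <- as.list(subject)
  needed <- c("subject", "thigh", "shank", "foot", "hip_height",
              "hip_halfwidth", "frequency", "speed", "swing_amp", "knee_amp",
              "phase")
  if (!all(needed %in% names(s)))
    stop("`subject` must provide fields: ",
         paste(setdiff(needed, names(s)), collapse = ", "), call. = FALSE)
  if (any(vapply(s[c("thigh", "shank", "foot", "hip_height")],
                 function(v) !is.finite(v) || v <= 0, logical(1))))
    stop("segment lengths and hip height must be positive", call. = FALSE)
  if (n_frames < 2L) stop("`n_frames` must be at least 2", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be nonnegative", call. = FALSE)
  n_frames <- as.integer(n_frames)
  tt <- (seq_len(n_frames) - 1L) * tau
  coords <- array(NA_real_, dim = c(n_frames, 10L, 3L))
  for (side in 1:2) {                       # 1 = left, 2 = right
    ysign <- if (side == 1L) 1 else -1
    theta <- 2 * pi * s$frequency * tt + s$phase + phase_offset +
      (side - 1L) * pi
    thigh_ang <- s$swing_amp * sin(theta)
    knee_flex <- s$knee_amp * (1 + cos(theta - pi / 2)) / 2
    shank_ang <- thigh_ang - knee_flex
    hip <- cbind(s$speed * tt, ysign * s$hip_halfwidth, s$hip_height)
    thigh_dir <- cbind(sin(thigh_ang), 0, -cos(thigh_ang))
    shank_dir <- cbind(sin(shank_ang), 0, -cos(shank_ang))
    knee <- hip + s$thigh * thigh_dir
    ankle <- knee + s$shank * shank_dir
    off <- (side - 1L) * 5L
    coords[, off + 1L, ] <- hip + 0.55 * s$thigh * thigh_dir   # thigh
    coords[, off + 2L, ] <- knee + 0.50 * s$shank * shank_dir  # shank
    coords[, off + 3L, ] <- knee + 0.95 * s$shank * shank_dir  # ankle, shin side
    coords[, off + 4L, ] <- ankle + rep(c(0.03, 0, -0.02), each = n_frames)
    coords[, off + 5L, ] <- ankle + rep(c(s$foot, 0, -0.04), each = n_frames)
  }
  with_seed(seed, {
    if (noise_sd > 0)
      coords <- coords + stats::rnorm(length(coords), sd = noise_sd)
    gait_trajectory(coords, subject = s$subject, tau = tau)
  })
}

#' Inject sporadic outlier displacements into a trajectory
#'
#' Emulates sensing failures: each marker-frame is independently displaced
#' with probability `p` by `magnitude` meters along one random coordinate
#' axis with a random sign. Deterministic given `seed`.
#'
#' @param traj A [gait_trajectory].
#' @param p Outlier probability per marker-frame, in `[0, 1]`.
#' @param magnitude Displacement magnitude in meters.
#' @param seed Optional integer seed.
#' @return The corrupted trajectory; the attribute `"n_outliers"` records
#'   how many marker-frames were displaced.
#' @export
inject_outliers <- function(traj, p, magnitude, seed = NULL) {
  if (!inherits(traj, "gait_trajectory"))
    stop("`traj` must be a gait_trajectory", call. = FALSE)
  if (!is.numeric(p) || p < 0 || p > 1)
    stop("`p` must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    nt <- n_frames(traj); nm <- n_markers(traj)
    hit <- matrix(stats::runif(nt * nm) < p, nt, nm)
    k <- sum(hit)
    if (k > 0 && magnitude != 0) {
      axis <- sample.int(3L, k, replace = TRUE)
      sgn <- sample(c(-1, 1), k, replace = TRUE)
      idx <- which(hit, arr.ind = TRUE)
      traj$coords[cbind(idx, axis)] <-
        traj$coords[cbind(idx, axis)] + sgn * magnitude
    }
    attr(traj, "n_outliers") <- k
    traj
  })
}

#' Simulate a multi-subject gait dataset
#'
#' Draws (or reuses) a subject population and simulates one recording per
#' subject, optionally corrupted by outliers. Recording lengths follow the
#' capture protocol the package targets: consecutive frames at 5 Hz,
#' typically 45-180 frames per recording.
#'
#' @param n_subjects Number of subjects (ignored when `population` is
#'   given).
#' @param n_frames Frames per recording (single value or one per subject).
#' @param tau Sampling interval (seconds).
#' @param noise_sd Sensor noise standard deviation (meters).
#' @param outlier_p Outlier probability per marker-frame (default 0).
#' @param outlier_mag Outlier displacement (meters, default 0.3).
#' @param random_start Draw a random gait-phase offset per recording
#'   (default `TRUE`).
#' @param seed Optional integer seed fixing population and noise.
#' @param population Optional `gait_population` to reuse (so train and test
#'   sets share subjects).
#' @return A [gait_dataset].
#' @export
simulate_gait_dataset <- function(n_subjects = 10, n_frames = 120,
                                  tau = 0.2, noise_sd = 0.002,
                                  outlier_p = 0, outlier_mag = 0.3,
                                  random_start = TRUE,
                                  seed = NULL, population = NULL) {
  with_seed(seed, {
    if (is.null(population)) population <- sample_population(n_subjects)
    n <- nrow(population)
    n_frames <- rep_len(as.integer(n_frames), n)
    offsets <- if (random_start) stats::runif(n, 0, 2 * pi) else rep(0, n)
    trajs <- lapply(seq_len(n), function(i) {
      tr <- simulate_trajectory(population[i, ], n_frames[i], tau = tau,
                                noise_sd = noise_sd,
                                phase_offset = offsets[i])
      if (outlier_p > 0)
        tr <- inject_outliers(tr, outlier_p, outlier_mag)
      tr
    })
    gait_dataset(trajs, class_list = population$subject)
  })
}
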