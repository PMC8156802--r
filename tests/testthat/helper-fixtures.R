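# Shared fixtures: all synthetic, built in code.

# A small random trajectory with finite coordinates.
random_trajectory <- function(n_frames = 5, n_markers = 10, subject = "S01",
                              tau = 0.2, seed = 1) {
  set.seed(seed)
  coords <- array(rnorm(n_frames * n_markers * 3), c(n_frames, n_markers, 3))
  gait_trajectory(coords, subject = subject, tau = tau)
}

# A subject parameter list for degenerate kinematic cases.
manual_subject <- function(speed = 1, frequency = 1, phase = 0) {
  list(subject = "S01", height = 1.7, thigh = 0.42, shank = 0.42,
       foot = 0.26, hip_height = 0.9, hip_halfwidth = 0.1,
       frequency = frequency, stride = if (frequency > 0)
         speed / frequency else 0,
       speed = speed, swing_amp = 0.3, knee_amp = 0.5, phase = phase)
}

# Fixed-seed train/test benchmark shared by evaluation tests.
make_benchmark <- function(n_subjects = 10, train_frames = 121,
                           test_frames = 61, noise_sd = 0.002,
                           outlier_p = 0, outlier_mag = 0.3, seed = 11) {
  pop <- sample_population(n_subjects, seed = seed)
  list(
    population = pop,
    train = simulate_gait_dataset(population = pop, n_frames = train_frames,
                                  noise_sd = noise_sd, outlier_p = outlier_p,
                                  outlier_mag = outlier_mag, seed = seed + 1),
    test = simulate_gait_dataset(population = pop, n_frames = test_frames,
                                 noise_sd = noise_sd, outlier_p = outlier_p,
                                 outlier_mag = outlier_mag, seed = seed + 2)
  )
}
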