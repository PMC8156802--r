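test_that("frame accuracy counts exact matches", {
  expect_equal(frame_accuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(frame_accuracy(c("a", "b"), c("b", "a")), 0)
  expect_equal(frame_accuracy(c("a", "a", "b", "b"), c("a", "a", "b", "c")),
               0.75)
  expect_error(frame_accuracy("a", c("a", "b")), "equal")
})

test_that("tracker subsets shrink the feature dimension as m(m-1)/2 + m", {
  tr <- random_trajectory(n_frames = 6, seed = 1)
  six <- tracker_subset(tr, c(1, 2, 4, 6, 7, 9))
  expect_equal(n_markers(six), 6)
  expect_equal(ncol(extract_feature_sequence(six)), 21)  # 15 + 6
  expect_equal(dimnames(six$coords)[[2]][1:2], c("L_thigh", "L_shank"))
  # coordinates are those of the retained markers, order preserved
  expect_equal(six$coords[, 3, ], tr$coords[, 4, ])
  full <- tracker_subset(tr, 1:10)
  expect_identical(full$coords, tr$coords)
  expect_error(tracker_subset(tr, 5), "at least 2")
  expect_error(tracker_subset(tr, c(0, 3)), "invalid")
  expect_error(tracker_subset(tr, c(3, 3)), "duplicate")
  ds <- gait_dataset(list(tr))
  expect_equal(n_markers(tracker_subset(ds, 1:6)$trajectories[[1]]), 6)
})

test_that("the trained pipeline classifies an easy benchmark end to end", {
  bm <- make_benchmark(n_subjects = 4, train_frames = 61, test_frames = 31,
                       seed = 31)
  sel <- select_kelm_params(bm$train, h_grid = c(4, 64),
                            lambda_grid = c(1e-2, 1e-1, 1))
  clf <- train_gait_classifier(bm$train, h = sel$h, lambda = sel$lambda)
  pred <- classify_frames(clf, bm$test, type = "class")
  truth <- dataset_features(bm$test)$y
  expect_gt(frame_accuracy(pred, truth), 0.9)
  dec <- classify_trajectory(clf, bm$test$trajectories[[2]])
  expect_s3_class(dec, "global_decision")
  expect_identical(dec$winner, bm$test$trajectories[[2]]$subject)
  # leading-frames versus random subsets, both reproducible
  d1 <- classify_trajectory(clf, bm$test$trajectories[[1]], ratio = 0.3,
                            subset_mode = "random", seed = 2)
  d2 <- classify_trajectory(clf, bm$test$trajectories[[1]], ratio = 0.3,
                            subset_mode = "random", seed = 2)
  expect_identical(d1$membership, d2$membership)
  expect_error(classify_trajectory(clf, bm$test$trajectories[[1]],
                                   ratio = 1.2), "ratio")
})

test_that("accuracy curves cover the ratio grid for every rule", {
  bm <- make_benchmark(n_subjects = 4, train_frames = 61, test_frames = 31,
                       seed = 41)
  sel <- select_kelm_params(bm$train, h_grid = c(4, 64),
                            lambda_grid = c(1e-2, 1e-1, 1))
  clf <- train_gait_classifier(bm$train, h = sel$h, lambda = sel$lambda)
  ev <- fusion_accuracy_curve(clf, bm$test)
  expect_s3_class(ev, "eval_result")
  expect_equal(nrow(ev$curve), 6 * 10)           # 6 rules x 10 ratios
  expect_true(all(ev$curve$accuracy >= 0 & ev$curve$accuracy <= 1))
  expect_true(ev$single_frame_accuracy > 0.9)
  expect_equal(sum(ev$confusion), 4)
  # rerun is identical: the harness is deterministic
  ev2 <- fusion_accuracy_curve(clf, bm$test)
  expect_identical(ev$curve, ev2$curve)
  expect_error(fusion_accuracy_curve(clf, bm$test, ratios = c(0.5, 0.2)),
               "increasing")
  expect_error(fusion_accuracy_curve(clf, bm$test, ratios = c(0, 1)),
               "\\(0, 1\\]")
})

test_that("parameter selection returns a grid point with its score table", {
  bm <- make_benchmark(n_subjects = 3, train_frames = 41, test_frames = 21,
                       seed = 51)
  sel <- select_kelm_params(bm$train, h_grid = c(4, 64),
                            lambda_grid = c(1e-3, 1e-1))
  expect_true(sel$h %in% c(4, 64))
  expect_true(sel$lambda %in% c(1e-3, 1e-1))
  expect_equal(nrow(sel$table), 4)
  expect_equal(max(sel$table$accuracy),
               sel$table$accuracy[sel$table$h == sel$h &
                                  sel$table$lambda == sel$lambda])
})
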