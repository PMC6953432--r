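test_that("separable cohorts reach near-perfect accuracy", {
  fc <- gen_feature_cohort(cohort_spec(n_per_group = 15, seed = 36),
                           effect_scale = 5)
  cv <- tune_and_score(fc, n_iter = 20, seed = 1)
  expect_gte(cv$median_accuracy, 0.95)
  expect_length(cv$accuracies, 20)
  expect_true(all(cv$accuracies >= 0 & cv$accuracies <= 1))
  # held-out animals identical to training are classified perfectly
  ph <- predict_heldout(cv, fc[1:6, ])
  expect_equal(ph$animals$majority_class, fc$group[1:6])
})

test_that("repeated CV is deterministic under a fixed master seed", {
  fc <- gen_feature_cohort(cohort_spec(n_per_group = 8, seed = 37),
                           effect_scale = 1)
  cv1 <- tune_and_score(fc, n_iter = 8, seed = 99)
  cv2 <- tune_and_score(fc, n_iter = 8, seed = 99)
  expect_identical(cv1$accuracies, cv2$accuracies)
  expect_identical(cv1$params, cv2$params)
})

test_that("duplicating a feature column barely moves the median accuracy", {
  fc <- gen_feature_cohort(cohort_spec(n_per_group = 12, seed = 38),
                           effect_scale = 1.5)
  cv <- tune_and_score(fc, n_iter = 30, seed = 2)
  fc2 <- dplyr::mutate(fc, beta_power_copy = .data$beta_power)
  cv2 <- tune_and_score(fc2, n_iter = 30, seed = 2)
  expect_lt(abs(cv2$median_accuracy - cv$median_accuracy), 0.05 + 1e-9)
})

test_that("held-out cohorts from the training distribution vote correctly", {
  sp <- cohort_spec(n_per_group = 15, seed = 39)
  cv <- tune_and_score(gen_feature_cohort(sp, effect_scale = 5),
                       n_iter = 30, seed = 3)
  # a third group drawn from the control distribution
  new <- gen_feature_cohort(cohort_spec(n_per_group = 12, seed = 40),
                            effect_scale = 5, seed = 40)
  ctrl <- new[new$group == "control", ]
  ph <- predict_heldout(cv, ctrl)
  expect_gte(ph$groups$fraction[ph$groups$class == "control"], 0.75)
  # single-animal table degenerates gracefully
  one <- predict_heldout(cv, ctrl[1, ])
  expect_equal(nrow(one$animals), 1)
  expect_true(one$animals$majority_class %in% cv$label_levels)
  expect_error(predict_heldout(cv, ctrl[, -3]), "lacks")
})

test_that("input validation rejects unusable cohorts", {
  fc <- gen_feature_cohort(cohort_spec(n_per_group = 5, seed = 41))
  expect_error(tune_and_score(fc[c(1, 2, 6, 7, 8, 9), ], n_iter = 2, seed = 1),
               "at least 3")
  fc_na <- fc
  fc_na$beta_power[2] <- NA
  expect_error(tune_and_score(fc_na, n_iter = 2, seed = 1), "missing")
})

test_that("label-shuffled data scores at chance on average", {
  fc <- gen_feature_cohort(cohort_spec(n_per_group = 15, seed = 42),
                           effect_scale = 3)
  set.seed(43)
  fc$group <- sample(fc$group)
  cv <- tune_and_score(fc, n_iter = 30, seed = 4)
  expect_gte(cv$median_accuracy, 0.25)
  expect_lte(cv$median_accuracy, 0.75)
})

test_that("the decision map covers the embedded cohort", {
  fc <- gen_feature_cohort(cohort_spec(n_per_group = 10, seed = 44),
                           effect_scale = 5)
  cv <- tune_and_score(fc, n_iter = 10, seed = 5)
  dm <- decision_map(cv, fc, grid_n = 25, seed = 6)
  expect_equal(nrow(dm$points), nrow(fc))
  expect_equal(nrow(dm$grid), 625)
  # grid covers the embedded bounding box
  expect_lte(min(dm$grid$dim1), min(dm$points$dim1))
  expect_gte(max(dm$grid$dim1), max(dm$points$dim1))
  expect_true(all(dm$grid$class %in% cv$label_levels))
  # strongly separated classes separate in the embedding: majority votes agree
  expect_gt(mean(dm$points$predicted == dm$points$label), 0.9)
  expect_error(decision_map(cv, fc[1:3, ]), "at least 5")
  p <- autoplot(dm)
  expect_s3_class(p, "ggplot")
})

test_that("tidiers expose per-iteration results", {
  fc <- gen_feature_cohort(cohort_spec(n_per_group = 8, seed = 45),
                           effect_scale = 2)
  cv <- tune_and_score(fc, n_iter = 5, seed = 7)
  td <- tidy(cv)
  expect_equal(nrow(td), 5)
  expect_true(all(c("accuracy", "n_quantiles", "percentile", "k", "weights")
                  %in% names(td)))
  expect_equal(glance(cv)$median.accuracy, cv$median_accuracy)
})
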