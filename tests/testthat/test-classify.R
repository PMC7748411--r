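test_that("classifiers are deterministic and live on the probability simplex", {
  tax <- test_taxonomy()
  model <- test_small_model()
  te <- build_training_set(tax, regimes = 4, instances_per_profile = 2,
                           seed = 7100)
  f <- features_from_instances(te)
  P <- predict_proba(model, f)
  expect_equal(dim(P), c(nrow(f), 123L))
  expect_true(all(P >= 0))
  expect_equal(unname(rowSums(P)), rep(1, nrow(f)), tolerance = 1e-9)

  tr <- build_training_set(tax, regimes = 4, instances_per_profile = 3,
                           seed = 7101)
  ftr <- features_from_instances(tr)
  m1 <- train_classifier(ftr, ftr$profile_id, tax, "random_forest",
                         hyperparams = list(num_trees = 100), seed = 3)
  m2 <- train_classifier(ftr, ftr$profile_id, tax, "random_forest",
                         hyperparams = list(num_trees = 100), seed = 3)
  expect_identical(predict(m1, f), predict(m2, f))
})

test_that("an unregularised forest memorises clean training data", {
  tax <- test_taxonomy()
  tr <- build_training_set(tax, regimes = 1e4, instances_per_profile = 4,
                           seed = 7200)
  f <- features_from_instances(tr)
  model <- train_classifier(
    f, f$profile_id, tax, "random_forest",
    hyperparams = list(num_trees = 200, sample_fraction = 1,
                       min_node_size = 1),
    seed = 4
  )
  pred <- predict(model, f)
  expect_equal(mean(pred$profile_id == f$profile_id), 1)
})

test_that("label validation rejects unknown and missing classes", {
  tax <- test_taxonomy()
  tr <- build_training_set(tax, regimes = 4, instances_per_profile = 2,
                           seed = 7300)
  f <- features_from_instances(tr)
  bad <- f$profile_id
  bad[1] <- 999L
  expect_error(train_classifier(f, bad, tax, "random_forest", seed = 1),
               "unknown profile id.*999")
  sub <- f[f$profile_id != 1L, ]
  expect_error(
    train_classifier(sub, sub$profile_id, tax, "random_forest", seed = 1),
    "no training instances.*1"
  )
})

test_that("the deterministic model emits one-hot probabilities", {
  tax <- test_taxonomy()
  det <- train_classifier(NULL, NULL, tax, "deterministic",
                          hyperparams = list(tolerance = 0.25))
  ts <- build_training_set(tax, regimes = 4, instances_per_profile = 2,
                           seed = 7400, profile_ids = c(2, 30, 60))
  # feed the noiseless means through the feature schema
  f <- features_from_instances(ts)
  f$m_e0 <- ts$m_e0; f$m_eX <- ts$m_eX
  f$m_eY <- ts$m_eY; f$m_eXY <- ts$m_eXY
  P <- predict_proba(det, f)
  expect_true(all(P %in% c(0, 1)))
  expect_equal(unname(rowSums(P)), rep(1, nrow(f)))
  pred <- predict(det, f)
  expect_equal(pred$profile_id, ts$profile_id)
  expect_equal(pred$p, rep(1, nrow(f)))
})

test_that("evaluation metrics match their definitions on exact predictions", {
  tax <- test_taxonomy()
  det <- train_classifier(NULL, NULL, tax, "deterministic")
  ts <- build_training_set(tax, regimes = 4, instances_per_profile = 3,
                           seed = 7500, profile_ids = c(2, 11, 30))
  f <- features_from_instances(ts)
  f$m_e0 <- ts$m_e0; f$m_eX <- ts$m_eX
  f$m_eY <- ts$m_eY; f$m_eXY <- ts$m_eXY
  # perfect one-hot predictions: log gain 0, accuracy 1
  ev <- evaluate_classifier(det, f, ts$profile_id)
  expect_equal(ev$overall_accuracy, 1)
  expect_equal(ev$log_gain, 0)
  pc <- ev$per_class[ev$per_class$n > 0, ]
  expect_true(all(pc$precision == 1 & pc$recall == 1))

  # all-wrong one-hot predictions hit the probability floor
  wrong <- rep(c(11L, 30L, 2L), each = 3)
  ev2 <- evaluate_classifier(det, f, wrong)
  expect_equal(ev2$overall_accuracy, 0)
  expect_equal(ev2$log_gain, -log(1e-15))

  g <- glance(ev)
  expect_equal(g$accuracy, 1)
  expect_equal(nrow(tidy(ev)), 123L)
  expect_s3_class(ggplot2::autoplot(ev), "ggplot")
  expect_error(evaluate_classifier(det, f, rep(999L, nrow(f))),
               "unknown profile id")
})

test_that("matching random labels scores at the 1/123 guess rate", {
  tax <- test_taxonomy()
  set.seed(7600)
  V <- matrix(stats::runif(8000 * 4, -14, 14), ncol = 4)
  ids <- match_deterministic(V, tax)
  shuffled <- sample(tax$profiles$id, 8000, replace = TRUE)
  acc <- mean(ids == shuffled)
  expect_lt(abs(acc - 1 / 123), 4 * sqrt((1 / 123) * (122 / 123) / 8000))
})

test_that("compare_models tabulates identical models identically", {
  tax <- test_taxonomy()
  model <- test_small_model()
  te <- build_training_set(tax, regimes = 4, instances_per_profile = 2,
                           seed = 7700)
  f <- features_from_instances(te)
  sets <- list(low = list(features = f, labels = f$profile_id))
  cmp <- compare_models(list(a = model, b = model), sets)
  expect_equal(nrow(cmp), 2L)
  expect_equal(cmp$accuracy[1], cmp$accuracy[2])
  expect_equal(cmp$log_gain[1], cmp$log_gain[2])
})

test_that("classifier artifacts survive serialisation", {
  model <- test_small_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(model, path)
  back <- load_classifier(path)
  tax <- test_taxonomy()
  te <- build_training_set(tax, regimes = 4, instances_per_profile = 1,
                           seed = 7800, profile_ids = c(2, 50))
  f <- features_from_instances(te)
  expect_identical(predict(model, f), predict(back, f))
  notmodel <- withr::local_tempfile(fileext = ".rds")
  saveRDS(1:3, notmodel)
  expect_error(load_classifier(notmodel), "not a classifier artifact")
})
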