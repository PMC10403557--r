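make_spec32 <- function() phantom_spec(height = 32, width = 32)

test_that("the ensemble has the configured number of members on disjoint folds", {
  d <- sharp_detective()
  expect_s3_class(d, "shortcut_detective")
  expect_length(d$members, 5)
  expect_equal(d$ada$attribute, "sharpness")
  vaucs <- vapply(d$members, function(m) m$val_auc, numeric(1))
  expect_true(all(is.finite(vaucs)))
})

test_that("ensemble scores are the arithmetic mean of member probabilities", {
  p <- length(adadetect:::feature_names())
  member_with_prob <- function(prob) {
    list(backend = "feature_linear",
         fit = list(type = "feature_linear", beta = c(qlogis(prob), rep(0, p)),
                    features = adadetect:::feature_names()),
         val_auc = NA_real_, fold = 1L)
  }
  probs <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  d <- constant_detective(c(16L, 16L))
  d$members <- lapply(probs, member_with_prob)
  img <- generate_phantom(phantom_spec(height = 16, width = 16), 1)
  s <- predict(d, list(img))
  expect_equal(s, mean(probs))
  ## all members at 1.0 combine to 1.0
  d$members <- lapply(rep(1, 3), member_with_prob)
  expect_equal(predict(d, list(img)), 1)
  ## inference is pure
  d2 <- sharp_detective()
  img64 <- generate_phantom(phantom_spec(), 2)
  expect_identical(predict(d2, list(img64)), predict(d2, list(img64)))
  expect_true(all(predict(d2, list(img64)) >= 0 & predict(d2, list(img64)) <= 1))
})

test_that("scoring refuses images that do not match the training size", {
  d <- sharp_detective()
  expect_error(predict(d, list(matrix(0L, 32, 32))), "does not match")
})

test_that("training refuses single-class data and flags unknown provenance", {
  spec <- make_spec32()
  pool <- generate_phantom_pool(40, spec, 51)
  ts <- build_detective_trainset(pool, ada_spec("contrast", gamma = 1.3), seed = 1)
  one_class <- labeled_dataset(ts$images[ts$labels == 1L],
                               ts$labels[ts$labels == 1L])
  expect_error(shortcut_detective(one_class, detective_config(ensemble_size = 2)),
               "both classes")
  noprov <- labeled_dataset(ts$images, ts$labels)
  expect_error(shortcut_detective(noprov, detective_config(ensemble_size = 2)),
               "provenance")
  expect_warning(
    d <- shortcut_detective(noprov, detective_config(ensemble_size = 2, seed = 2),
                            ada = ada_spec("contrast", gamma = 1.3)),
    "provenance")
  expect_true(d$unknown_provenance)
})

test_that("a detective trained on identity-spec data performs at chance", {
  pool <- pool600()[1:300]
  ts <- build_detective_trainset(pool, ada_spec("contrast", gamma = 1), seed = 7)
  d <- shortcut_detective(ts, detective_config(seed = 5))
  holdout <- generate_labeled_dataset(300, phantom_spec(), seed = 71)
  auc <- compute_auc(predict(d, holdout), holdout$labels)
  expect_gte(auc, 0.4)
  expect_lte(auc, 0.6)
})

test_that("training is deterministic given the config seed", {
  spec <- make_spec32()
  pool <- generate_phantom_pool(60, spec, 61)
  ts <- build_detective_trainset(pool, ada_spec("sharpness", blur_sigma = 1), seed = 2)
  d1 <- shortcut_detective(ts, detective_config(ensemble_size = 2, seed = 9))
  d2 <- shortcut_detective(ts, detective_config(ensemble_size = 2, seed = 9))
  ev <- generate_phantom_pool(10, spec, 62)
  expect_identical(predict(d1, ev), predict(d2, ev))
})

test_that("patient-grouped folds never split a patient across train and validation", {
  pids <- rep(sprintf("P%02d", 1:10), each = 4)
  folds <- adadetect:::make_folds(40, 5, pids, seed = 3)
  for (p in unique(pids)) {
    expect_length(unique(folds[pids == p]), 1)
  }
  expect_setequal(unique(folds), 1:5)
})

test_that("the reference convnet passes the certification suite at default magnitudes", {
  spec <- make_spec32()
  pool <- generate_phantom_pool(240, spec, 81)
  ts <- build_detective_trainset(pool, ada_spec("sharpness", blur_sigma = 1.0),
                                 seed = 82)
  cfg <- detective_config(backend = "reference_convnet", ensemble_size = 2,
                          seed = 83, max_epochs = 6, patience = 2)
  d <- shortcut_detective(ts, cfg)
  free <- generate_labeled_dataset(240, spec, 84)
  d <- certify(d, free, replicates = 500, seed = 85)
  expect_true(d$certification$passed)
  expect_s3_class(d$certification, "certification_report")
})

test_that("held-out AUC is non-decreasing in contrast injection magnitude", {
  pool <- pool600()[1:300]
  aucs <- vapply(c(1.0, 1.15, 1.3), function(g) {
    ada <- ada_spec("contrast", gamma = g)
    ts <- build_detective_trainset(pool, ada, seed = 91)
    d <- shortcut_detective(ts, detective_config(seed = 92))
    ev <- inject_into_class(generate_labeled_dataset(200, phantom_spec(), 93),
                            ada, 1)
    compute_auc(predict(d, ev), ev$labels)
  }, numeric(1))
  expect_true(all(diff(aucs) >= 0))
  expect_lt(aucs[1], 0.65) # no injected signal at gamma 1
  expect_gt(aucs[3], 0.99)
})
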