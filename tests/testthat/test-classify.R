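test_that("ordinal decomposition arithmetic is exact", {
  # consistent thresholds
  p <- ordinal_recombine(c(0.9, 0.2))
  expect_equal(as.numeric(p), c(0.1, 0.7, 0.2), tolerance = 1e-12)
  expect_identical(which.max(p), 2L)
  # inconsistent thresholds: clip the negative mass, renormalise
  p2 <- ordinal_recombine(c(0.2, 0.9))
  expect_equal(as.numeric(p2), c(0.8, 0, 0.9) / 1.7, tolerance = 1e-12)
  expect_identical(which.max(p2), 3L)
  # probabilities always sum to one
  set.seed(1)
  for (i in 1:200) {
    p <- ordinal_recombine(runif(2))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  expect_error(ordinal_wrap(classifier_spec("naive-bayes"), 1), "at least 2")
})

test_that("with two classes the wrapper equals the base classifier", {
  set.seed(4)
  d <- data.frame(x = c(rnorm(25, 0), rnorm(25, 2)),
                  label = rep(1:2, each = 25))
  for (method in c("naive-bayes", "decision-tree-pruned")) {
    wrapped <- train_classifier(d, ordinal_wrap(classifier_spec(method), 2))
    base <- train_classifier(d, classifier_spec(method, ordinal = FALSE))
    base$classes <- 1:2
    grid <- data.frame(x = seq(-2, 4, by = 0.25))
    expect_identical(predict(wrapped, grid), predict(base, grid))
  }
})

test_that("separable training data is learned perfectly", {
  d <- separable_features(12)
  for (method in c("naive-bayes", "decision-tree-pruned",
                   "best-first-tree", "reduced-error-pruning-tree",
                   "random-forest")) {
    m <- train_classifier(d, ordinal_wrap(classifier_spec(method), 3))
    expect_identical(mean(predict(m, d) == d$label), 1,
                     label = method)
  }
})

test_that("complement naive Bayes learns count-style class signatures", {
  # CNB is a one-sided evidence model: it excels on count vectors with
  # class-specific signatures, not on low-dimensional magnitude features
  set.seed(2)
  n <- 30
  d <- data.frame(f1 = c(rpois(n, 6), rpois(n, 1), rpois(n, 1)),
                  f2 = c(rpois(n, 1), rpois(n, 6), rpois(n, 1)),
                  f3 = c(rpois(n, 1), rpois(n, 1), rpois(n, 6)),
                  label = rep(1:3, each = n))
  m <- train_classifier(d, ordinal_wrap(
    classifier_spec("complement-naive-bayes"), 3))
  expect_gte(mean(predict(m, d) == d$label), 0.9)
  # and it trains without error on any labelled numeric features
  m2 <- train_classifier(separable_features(8),
                         classifier_spec("complement-naive-bayes"))
  expect_s3_class(m2, "likertext_model")
})

test_that("contradictory duplicate vectors still train", {
  d <- data.frame(x = c(1, 1, 2, 2), label = c(1, 2, 1, 2))
  m <- train_classifier(d, ordinal_wrap(classifier_spec("naive-bayes"), 3))
  expect_true(predict(m, d[1, ]) %in% c(1L, 2L))
})

test_that("training is deterministic under a fixed seed", {
  d <- monotone_features(20, sd = 1, seed = 2)
  spec <- ordinal_wrap(classifier_spec("random-forest", seed = 42L), 3)
  m1 <- train_classifier(d, spec)
  m2 <- train_classifier(d, spec)
  expect_identical(predict(m1, d), predict(m2, d))
  expect_identical(serialize(m1$fit$thresholds[[1]]$fit$forest, NULL),
                   serialize(m2$fit$thresholds[[1]]$fit$forest, NULL))
})

test_that("single-class data and schema mismatches are hard errors", {
  d <- data.frame(x = 1:5, label = rep(2L, 5))
  expect_error(train_classifier(d, classifier_spec("naive-bayes")),
               "single class")
  d2 <- separable_features(5)
  m <- train_classifier(d2, classifier_spec("naive-bayes"))
  wrong <- d2; names(wrong)[1] <- "renamed"
  expect_error(predict(m, wrong), "fingerprint mismatch")
})

test_that("our naive Bayes agrees with an independent implementation", {
  # e1071's Gaussian treatment is the cross-check on a fixture where every
  # class-conditional variance is comfortably positive
  set.seed(7)
  d <- data.frame(x1 = c(rnorm(30, 0), rnorm(30, 2), rnorm(30, 4)),
                  x2 = rnorm(90), label = rep(1:3, each = 30))
  ours <- train_classifier(
    d, classifier_spec("naive-bayes", hyper = list(density = "gaussian"),
                       ordinal = FALSE))
  ref <- e1071::naiveBayes(d[, 1:2], factor(d$label))
  grid <- data.frame(x1 = seq(-1, 5, by = 0.5), x2 = 0)
  expect_identical(as.integer(predict(ours, grid)),
                   as.integer(as.character(predict(ref, grid))))
})

test_that("cross-validation folds partition and stratify", {
  y <- rep(1:3, each = 20)
  f <- cv_folds(y, k = 10, stratified = TRUE, seed = 1)
  expect_identical(sort(unique(f)), 1:10)
  expect_identical(length(f), length(y))
  for (cl in 1:3)                       # stratified: 2 per class per fold
    expect_true(all(table(f[y == cl]) == 2))
  expect_identical(cv_folds(y, 10, TRUE, 5), cv_folds(y, 10, TRUE, 5))
  expect_error(cv_folds(1:5, k = 10), "fewer folds")
  expect_warning(cv_folds(c(rep(1, 30), 2), k = 10), "plain random")
})

test_that("cross-validating a perfect rule fills the diagonal", {
  d <- separable_features(10, seed = 3)
  cm <- cross_validate(d, ordinal_wrap(classifier_spec("naive-bayes"), 3),
                       k = 10, seed = 42)
  expect_identical(sum(cm), 30L)
  expect_identical(sum(diag(cm)), 30L)
})

test_that("the ordinal wrapper never trails the base learner by much", {
  # monotone signal, 20 seeded replicates
  diffs <- vapply(1:20, function(s) {
    d <- monotone_features(15, sd = 0.9, seed = s)
    acc <- function(spec) {
      cm <- cross_validate(d, spec, k = 5, seed = s)
      sum(diag(cm)) / sum(cm)
    }
    acc(ordinal_wrap(classifier_spec("naive-bayes"), 3)) -
      acc(classifier_spec("naive-bayes", ordinal = FALSE))
  }, numeric(1))
  expect_gte(mean(diffs), -0.02)
})

test_that("models persist with an auditable sidecar", {
  d <- separable_features(5)
  m <- train_classifier(d, classifier_spec("naive-bayes"))
  p <- tempfile(fileext = ".rds")
  write_model(m, p)
  side <- jsonlite::read_json(paste0(p, ".json"))
  expect_identical(side$method, "naive-bayes")
  expect_identical(side$seed, 42L)
  m2 <- read_model(p)
  expect_identical(predict(m2, d), predict(m, d))
})
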