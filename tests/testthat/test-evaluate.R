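test_that("per-class metrics follow the P/R/F definitions", {
  cm <- confusion_matrix(c("a", "a", "a", "a", "b"),
                         c("a", "a", "a", "b", "a"))
  m <- class_metrics(cm)
  a <- m[m$class == "a", ]
  expect_identical(c(a$tp, a$fp, a$fn), c(3, 1, 1))
  expect_equal(c(a$precision, a$recall, a$f), rep(0.75, 3))

  diagonal <- confusion_matrix(rep(1:3, 5), rep(1:3, 5))
  md <- class_metrics(diagonal)
  expect_true(all(md$precision == 1 & md$recall == 1 & md$f == 1))

  # class never predicted: 0/0 reported as 0 and flagged
  never <- matrix(c(5L, 3L, 0L, 0L), 2, 2,
                  dimnames = list(actual = c("x", "y"),
                                  predicted = c("x", "y")))
  class(never) <- "confusion_matrix"
  mn <- class_metrics(never)
  y <- mn[mn$class == "y", ]
  expect_identical(c(y$precision, y$recall), c(0, 0))
  expect_true(y$degenerate)
  expect_error(class_metrics(matrix(0, 2, 2)), "no observations")
})

test_that("weighted metrics are support-weighted means", {
  cm <- random_confusion(3)
  m <- class_metrics(cm)
  w <- m$support / sum(m$support)
  wm <- weighted_metrics(cm)
  expect_equal(wm[["precision"]], sum(w * m$precision), tolerance = 1e-12)
  expect_equal(wm[["f"]], sum(w * m$f), tolerance = 1e-12)
  # direct weighted-mean arithmetic: precisions .8/.6 at supports 10/30
  expect_equal(sum(c(10, 30) / 40 * c(0.8, 0.6)), 0.65)
  # perfect prediction and uniform-support symmetry
  expect_equal(unname(weighted_metrics(confusion_matrix(1:3, 1:3))),
               c(1, 1, 1))
  uni <- confusion_matrix(rep(1:2, each = 10),
                          c(rep(1, 8), rep(2, 2), rep(1, 3), rep(2, 7)))
  mu <- class_metrics(uni)
  expect_equal(weighted_metrics(uni)[["precision"]], mean(mu$precision))
})

test_that("F-measure is the harmonic mean with a 0/0 convention", {
  expect_identical(f_measure(0.5, 0.5), 0.5)
  expect_identical(f_measure(1, 0), 0)
  expect_identical(f_measure(0.75, 0.75), 0.75)
  expect_identical(f_measure(0, 0), 0)
})

test_that("Cohen's kappa matches hand computations", {
  perfect <- confusion_matrix(rep(1:3, 7), rep(1:3, 7))
  expect_equal(cohen_kappa(perfect), 1)
  at <- matrix(c(20L, 10L, 5L, 15L), 2, 2)   # [[20,5],[10,15]] by rows
  expect_equal(cohen_kappa(at), 0.4, tolerance = 1e-12)
  # one rater constant, the other uniform: chance-level agreement
  const <- matrix(c(25L, 0L, 25L, 0L), 2, 2)
  expect_equal(cohen_kappa(const), 0, tolerance = 1e-12)
  both_const <- matrix(c(10L, 0L, 0L, 0L), 2, 2)
  expect_warning(k <- cohen_kappa(both_const), "undefined")
  expect_true(is.na(k))
})

test_that("weighted kappa reduces to Cohen's under identity weights", {
  set.seed(11)
  for (i in 1:100) {
    at <- matrix(sample(0:30, 9, replace = TRUE), 3, 3)
    if (sum(at) == 0) at[1, 1] <- 1
    pe <- sum(rowSums(at) * colSums(at)) / sum(at)^2
    if (abs(1 - pe) < 1e-9) next
    expect_equal(weighted_kappa(at, "identity"), cohen_kappa(at),
                 tolerance = 1e-12)
  }
  perfect <- diag(c(5L, 6L, 7L))
  expect_equal(weighted_kappa(perfect, "linear"), 1)
  expect_equal(weighted_kappa(perfect, "quadratic"), 1)
})

test_that("weighted kappa rewards near-miss disagreements", {
  adjacent <- matrix(c(10L, 0L, 0L, 5L, 10L, 5L, 0L, 0L, 10L), 3, 3)
  extreme <- matrix(c(10L, 0L, 5L, 0L, 10L, 0L, 5L, 0L, 10L), 3, 3)
  expect_gt(weighted_kappa(adjacent, "linear"),
            weighted_kappa(extreme, "linear"))
  expect_gt(weighted_kappa(adjacent, "quadratic"),
            weighted_kappa(extreme, "quadratic"))
})

test_that("metrics stay in range on random matrices", {
  set.seed(23)
  for (i in 1:1000) {
    cm <- random_confusion(sample(2:4, 1))
    wm <- weighted_metrics(cm)
    expect_true(all(wm >= 0 & wm <= 1))
    k <- suppressWarnings(cohen_kappa(cm))
    if (!is.na(k)) expect_true(k >= -1 && k <= 1)
    kw <- suppressWarnings(weighted_kappa(cm, "linear"))
    if (!is.na(kw)) expect_true(kw >= -1 && kw <= 1 + 1e-12)
  }
})

test_that("summary statistics reproduce and are permutation-invariant", {
  f <- c(91.3, 71.4, 81.0, 66.9, 75.6, 59.0, 81.0, 73.2, 70.6, 73.8)
  vals <- data.frame(question = paste0("Q", 1:10), precision = f,
                     recall = f, f = f)
  s <- summarize_questions(vals)
  expect_identical(round_half_up(s$stats["f", "mean"], 1), 74.4)
  expect_identical(round_half_up(s$stats["f", "sd"], 1), 8.8)
  expect_identical(s$stats["f", "min"], 59.0)
  expect_identical(s$stats["f", "max"], 91.3)
  perm <- vals[sample(nrow(vals)), ]
  expect_equal(summarize_questions(perm)$stats, s$stats)

  one <- summarize_questions(vals[1, ])
  expect_true(is.na(one$stats["f", "sd"]))
  expect_identical(one$stats["f", "min"], one$stats["f", "max"])
  same <- vals; same$f <- 50
  expect_identical(summarize_questions(same)$stats["f", "sd"], 0)
  expect_error(summarize_questions(vals[0, ]), "nrow")
})

test_that("half-up rounding matches the reporting convention", {
  expect_identical(round_half_up(74.35, 1), 74.4)
  expect_identical(round_half_up(74.44999, 1), 74.4)
  expect_identical(round_half_up(-0.25, 1), -0.3)
})
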