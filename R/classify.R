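# ---------------------------------------------------------------------------
# Per-question ordinal classifiers.
#
# Base learners follow the published roster (naive Bayes, complement naive
# Bayes, three pruned-decision-tree variants, random forest). The ordinal
# decomposition wrapper -- the ordering-aware computation -- is implemented
# here: a k-class ordinal problem becomes k-1 binary threshold problems
# Pr(y > t), recombined into class probabilities. Naive Bayes and the tree
# family are backed by e1071, rpart and randomForest; complement naive
# Bayes is implemented in-package. The tree variants share one pruned-CART
# implementation distinguished by pruning-strategy flags (their original
# splitting subtleties are not part of this system's contribution); method
# names are preserved for fidelity of reporting.
# ---------------------------------------------------------------------------

.classifier_methods <- c("naive-bayes", "complement-naive-bayes",
                         "decision-tree-pruned", "best-first-tree",
                         "reduced-error-pruning-tree", "random-forest")

#' Describe a classifier configuration
#'
#' @param method one of `"naive-bayes"`, `"complement-naive-bayes"`,
#'   `"decision-tree-pruned"`, `"best-first-tree"`,
#'   `"reduced-error-pruning-tree"`, `"random-forest"`.
#' @param hyper named list of hyperparameters (passed to the backend).
#' @param ordinal wrap the learner in the ordinal binary decomposition?
#' @param seed random seed recorded in every artifact.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(method, hyper = list(), ordinal = TRUE,
                            seed = 42L) {
  method <- match.arg(method, .classifier_methods)
  structure(list(method = method, hyper = hyper, ordinal = isTRUE(ordinal),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Wrap a base classifier specification for ordinal decomposition
#'
#' The wrapper trains `k - 1` binary models for the threshold probabilities
#' `Pr(y > 1), ..., Pr(y > k-1)` and recombines them as `P(1) = 1 - Pr(y>1)`,
#' `P(j) = Pr(y>j-1) - Pr(y>j)`, `P(k) = Pr(y>k-1)`. Negative intermediate
#' masses (inconsistent thresholds) are clipped to 0 and the vector is
#' renormalised; prediction is the arg-max with ties resolved toward the
#' lower class. With `k = 2` the wrapper is identical to the base binary
#' classifier.
#'
#' @param spec a `classifier_spec`.
#' @param k number of ordered classes (>= 2).
#' @return the spec with the ordinal flag set.
#' @export
ordinal_wrap <- function(spec, k = 3L) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (k < 2) stop("ordinal decomposition needs at least 2 classes",
                  call. = FALSE)
  spec$ordinal <- TRUE
  spec$k <- as.integer(k)
  spec
}

.schema_fingerprint <- function(x) paste(colnames(x), collapse = "")

# -- base learners ----------------------------------------------------------

.fit_base <- function(x, y, spec) {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2)
    return(list(kind = "constant", level = as.character(y[1]),
                levels = levels(y)))
  set.seed(spec$seed)
  h <- spec$hyper
  switch(spec$method,
    "naive-bayes" = .fit_gnb(x, y,
                             var_smooth = h$var_smooth %||% 1e-9,
                             density = h$density %||% "kernel"),
    "complement-naive-bayes" = .fit_cnb(x, y, alpha = h$alpha %||% 1),
    "random-forest" = list(
      kind = "rf", levels = levels(y),
      fit = randomForest::randomForest(x, y,
                                       ntree = h$ntree %||% 200)),
    { # pruned-CART family
      cp <- switch(spec$method,
                   "decision-tree-pruned" = h$cp %||% 0.01,
                   "best-first-tree" = h$cp %||% 0.005,
                   "reduced-error-pruning-tree" = h$cp %||% 0.02)
      df <- cbind(x, .y = y)
      list(kind = "rpart", levels = levels(y),
           fit = rpart::rpart(.y ~ ., data = df, method = "class",
                              control = rpart::rpart.control(
                                cp = cp, minsplit = h$minsplit %||% 5,
                                xval = 0)))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Naive Bayes over real-valued features. density = "kernel" (default)
# estimates each class-conditional feature density with a Gaussian kernel
# over the training values (Silverman-style bandwidth, floored so constant
# features stay well-behaved); this keeps the binary threshold problems of
# the ordinal wrapper honest when a pooled class is multi-modal. density =
# "gaussian" fits a single Gaussian per class/feature with variance
# smoothing (floored at var_smooth * max overall feature variance).
.fit_gnb <- function(x, y, var_smooth = 1e-9, density = "kernel") {
  x <- as.matrix(x)
  lv <- levels(y)
  prior <- table(y) / length(y)
  if (density == "kernel") {
    glob_sd <- sqrt(max(apply(x, 2, stats::var), 1e-12))
    values <- lapply(lv, function(c) x[y == c, , drop = FALSE])
    bw <- t(vapply(values, function(xc) {
      s <- apply(xc, 2, stats::sd)
      s[is.na(s)] <- 0
      pmax(1.06 * s * nrow(xc)^(-1 / 5), 0.05 * glob_sd, 1e-3)
    }, numeric(ncol(x))))
    if (ncol(x) == 1) bw <- matrix(bw, ncol = 1)
    dimnames(bw) <- list(lv, colnames(x))
    return(list(kind = "knb", levels = lv, values = values, bw = bw,
                log_prior = log(as.numeric(prior) + 1e-12)))
  }
  mu <- s2 <- matrix(0, length(lv), ncol(x),
                     dimnames = list(lv, colnames(x)))
  for (c in lv) {
    xc <- x[y == c, , drop = FALSE]
    mu[c, ] <- colMeans(xc)
    s2[c, ] <- apply(xc, 2, stats::var)
  }
  s2[is.na(s2)] <- 0
  eps <- var_smooth * max(apply(x, 2, stats::var), 1e-12)
  s2 <- s2 + max(eps, 1e-12)
  list(kind = "gnb", levels = lv, mu = mu, s2 = s2,
       log_prior = log(as.numeric(prior) + 1e-12))
}

# Complement naive Bayes with add-one smoothing over complement frequency
# estimates and the class-prior term of the standard formulation
# (score = log p(c) - x . w_c, weights normalised per class). Real-valued
# features are shifted to be non-negative using the per-feature training
# minimum (stored on the model).
.fit_cnb <- function(x, y, alpha = 1) {
  x <- as.matrix(x)
  shift <- apply(x, 2, min)
  x <- sweep(x, 2, shift)
  lv <- levels(y)
  w <- matrix(0, length(lv), ncol(x), dimnames = list(lv, colnames(x)))
  for (c in lv) {
    comp <- x[y != c, , drop = FALSE]
    num <- colSums(comp) + alpha
    theta <- num / sum(num)
    wc <- log(theta)
    w[c, ] <- wc / sum(abs(wc))
  }
  prior <- table(y) / length(y)
  list(kind = "cnb", levels = lv, weights = w, shift = shift,
       log_prior = log(as.numeric(prior) + 1e-12))
}

.predict_base_prob <- function(model, x) {
  lv <- model$levels
  n <- nrow(x)
  switch(model$kind,
    mixnb = {
      post <- .predict_base_prob(model$components, x)
      cls <- as.integer(colnames(post))
      gt <- rowSums(post[, cls > model$t, drop = FALSE])
      cbind("0" = 1 - gt, "1" = gt)
    },
    constant = {
      p <- matrix(0, n, length(lv), dimnames = list(NULL, lv))
      p[, model$level] <- 1
      p
    },
    knb = {
      xm <- as.matrix(x)
      ll <- vapply(seq_along(model$levels), function(ci) {
        tr <- model$values[[ci]]
        h <- model$bw[ci, ]
        fl <- vapply(seq_len(ncol(xm)), function(f) {
          d <- outer(xm[, f], tr[, f], "-") / h[f]
          log(pmax(rowMeans(stats::dnorm(d)) / h[f], 1e-300))
        }, numeric(nrow(xm)))
        if (nrow(xm) == 1) fl <- matrix(fl, nrow = 1)
        model$log_prior[ci] + rowSums(fl)
      }, numeric(nrow(xm)))
      if (is.null(dim(ll))) ll <- matrix(ll, nrow = nrow(xm))
      p <- exp(ll - apply(ll, 1, max))
      p <- p / rowSums(p)
      colnames(p) <- model$levels
      p
    },
    gnb = {
      xm <- as.matrix(x)
      ll <- vapply(seq_along(model$levels), function(ci) {
        ld <- stats::dnorm(xm, rep(model$mu[ci, ], each = nrow(xm)),
                           rep(sqrt(model$s2[ci, ]), each = nrow(xm)),
                           log = TRUE)
        if (nrow(xm) == 1) ld <- matrix(ld, nrow = 1)
        model$log_prior[ci] + rowSums(ld)
      }, numeric(nrow(xm)))
      if (is.null(dim(ll))) ll <- matrix(ll, nrow = nrow(xm))
      p <- exp(ll - apply(ll, 1, max))
      p <- p / rowSums(p)
      colnames(p) <- model$levels
      p
    },
    rf = stats::predict(model$fit, x, type = "prob"),
    rpart = stats::predict(model$fit, as.data.frame(x), type = "prob"),
    cnb = {
      xm <- sweep(as.matrix(x), 2, model$shift)
      xm[xm < 0] <- 0
      score <- -xm %*% t(model$weights)       # higher = more likely
      score <- sweep(score, 2, model$log_prior, "+")
      p <- exp(score - apply(score, 1, max))
      p / rowSums(p)
    },
    stop("unknown model kind"))
}

# -- training ---------------------------------------------------------------

#' Train a (possibly ordinal) classifier on labelled feature vectors
#'
#' @param data data frame of numeric features plus an integer `label`
#'   column with at least two distinct values in 1..3 (or 1..k).
#' @param spec a `classifier_spec`.
#' @param scheme optional `question_scheme()` recorded on the model.
#' @return object of class `likertext_model`. Prediction refuses feature
#'   frames whose column fingerprint differs from the training schema.
#' @export
train_classifier <- function(data, spec, scheme = NULL) {
  stopifnot(inherits(spec, "classifier_spec"), "label" %in% names(data))
  y <- as.integer(data$label)
  x <- data[, setdiff(names(data), "label"), drop = FALSE]
  if (length(unique(y)) < 2)
    stop("training data contains a single class", call. = FALSE)
  k <- spec$k %||% max(y, 3L)
  classes <- seq_len(k)
  fingerprint <- .schema_fingerprint(x)
  if (spec$ordinal && k > 2) {
    if (spec$method == "naive-bayes") {
      # Generative base learner: each binary threshold model is a mixture
      # of the per-class components, P(y > t | x) = sum_{c > t} P(c | x).
      # Fitting a naive product directly to the pooled "y <= t" class would
      # multiply the pool-proportion dilution once per feature and bias the
      # thresholds (see the methods vignette).
      comp <- .fit_base(x, factor(y, levels = classes), spec)
      thresholds <- lapply(seq_len(k - 1L), function(t)
        list(kind = "mixnb", components = comp, t = t,
             levels = c("0", "1")))
    } else {
      thresholds <- lapply(seq_len(k - 1L), function(t)
        .fit_base(x, factor(as.integer(y > t), levels = 0:1), spec))
    }
    fit <- list(type = "ordinal", thresholds = thresholds)
  } else if (spec$ordinal && k == 2) {
    fit <- list(type = "ordinal",
                thresholds = list(.fit_base(
                  x, factor(as.integer(y > 1), levels = 0:1), spec)))
  } else {
    fit <- list(type = "multiclass",
                base = .fit_base(x, factor(y, levels = classes), spec))
  }
  structure(list(spec = spec, fit = fit, classes = classes,
                 fingerprint = fingerprint, scheme = scheme),
            class = "likertext_model")
}

#' @export
print.likertext_model <- function(x, ...) {
  cat("<likertext_model> method=", x$spec$method,
      if (x$fit$type == "ordinal") " (ordinal decomposition)",
      ", classes=", paste(x$classes, collapse = "/"),
      ", seed=", x$spec$seed, "\n", sep = "")
  invisible(x)
}

#' Recombine threshold probabilities into ordinal class probabilities
#'
#' Exposed for direct use/testing of the decomposition arithmetic:
#' given `Pr(y > t)` for t = 1..k-1, returns `(P(1), ..., P(k))` with
#' negative intermediate masses clipped to 0 and the vector renormalised.
#'
#' @param p_gt numeric vector (or matrix, rows = instances) of threshold
#'   probabilities.
#' @return probability vector/matrix over the k classes.
#' @export
ordinal_recombine <- function(p_gt) {
  if (is.null(dim(p_gt))) p_gt <- matrix(p_gt, nrow = 1)
  k <- ncol(p_gt) + 1L
  p <- cbind(1 - p_gt[, 1], if (k > 2)
    p_gt[, -ncol(p_gt), drop = FALSE] - p_gt[, -1, drop = FALSE],
    p_gt[, ncol(p_gt)])
  p[p < 0] <- 0
  rs <- rowSums(p)
  rs[rs == 0] <- 1
  p <- p / rs
  colnames(p) <- as.character(seq_len(k))
  p
}

#' Predict ordinal labels or class probabilities
#'
#' @param object a `likertext_model`.
#' @param newdata feature data frame with the training columns.
#' @param type `"class"` (integer labels; ties go to the lower class) or
#'   `"prob"` (probability matrix).
#' @param ... unused.
#' @export
predict.likertext_model <- function(object, newdata, type = c("class", "prob"),
                                    ...) {
  type <- match.arg(type)
  newdata <- newdata[, setdiff(names(newdata), "label"), drop = FALSE]
  if (!identical(.schema_fingerprint(newdata), object$fingerprint))
    stop("feature schema fingerprint mismatch", call. = FALSE)
  if (object$fit$type == "ordinal") {
    p_gt <- vapply(object$fit$thresholds, function(m)
      .predict_base_prob(m, newdata)[, "1"], numeric(nrow(newdata)))
    if (is.null(dim(p_gt))) p_gt <- matrix(p_gt, nrow = nrow(newdata))
    p <- ordinal_recombine(p_gt)
  } else {
    p <- .predict_base_prob(object$fit$base, newdata)
    colnames(p) <- as.character(object$classes)
  }
  if (type == "prob") return(p)
  apply(p, 1, function(r) which.max(r))  # which.max: first max = lower class
}

# -- cross-validation -------------------------------------------------------

#' Assign cross-validation folds
#'
#' Stratified when every class has at least `k` members, otherwise plain
#' random folds with a warning. Deterministic given the seed.
#'
#' @param y integer labels.
#' @param k number of folds.
#' @param stratified attempt stratification?
#' @param seed RNG seed.
#' @return integer fold id (1..k) per instance.
#' @export
cv_folds <- function(y, k = 10L, stratified = TRUE, seed = 42L) {
  n <- length(y)
  if (n < k) stop("n < k; use fewer folds (k <= ", n, ")", call. = FALSE)
  set.seed(seed)
  fold <- integer(n)
  if (stratified && all(table(y) >= k)) {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    if (stratified)
      warning("some class has fewer than k members; plain random folds used")
    fold <- rep_len(seq_len(k), n)[sample(n)]
  }
  fold
}

#' k-fold cross-validation pooled into one confusion matrix
#'
#' Every instance is tested exactly once; test-fold predictions are pooled
#' into a single confusion matrix over the ordinal classes.
#'
#' @param data feature data frame with `label` column.
#' @param spec a `classifier_spec`.
#' @param k folds (default 10).
#' @param stratified stratify folds by class when possible.
#' @param seed fold-assignment seed (training uses `spec$seed`).
#' @return a `confusion_matrix` (actual x predicted).
#' @export
cross_validate <- function(data, spec, k = 10L, stratified = TRUE,
                           seed = 42L) {
  y <- as.integer(data$label)
  fold <- cv_folds(y, k = k, stratified = stratified, seed = seed)
  classes <- as.character(seq_len(spec$k %||% max(y, 3L)))
  pred <- integer(length(y))
  for (f in seq_len(k)) {
    test <- fold == f
    model <- train_classifier(data[!test, , drop = FALSE], spec)
    pred[test] <- predict(model, data[test, , drop = FALSE])
  }
  confusion_matrix(y, pred, classes = classes)
}

# -- model persistence ------------------------------------------------------

#' Save / load a trained model with a JSON sidecar
#'
#' The model is serialised with `saveRDS()`; a human-readable JSON sidecar
#' (`<path>.json`) records the spec, seed and schema fingerprint so a run
#' can be audited without deserialising the model.
#'
#' @param model a `likertext_model`.
#' @param path file path for the model artifact.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(
    list(method = model$spec$method, seed = model$spec$seed,
         ordinal = model$spec$ordinal, classes = model$classes,
         fingerprint = model$fingerprint),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) readRDS(path)
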