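# Shared fixtures, built in code.

# first sentence of a parsed response
sent1 <- function(text) parse_response(text)$sentences[[1]]

# tiny synonym lexicon used by loader / normalisation tests
swelling_lexicon_df <- function() {
  data.frame(
    concept_id = c("C1", "C1", "C1"),
    name = c("swelling", "edema", "oedema"),
    semantic_type = rep("sosy", 3),
    stringsAsFactors = FALSE)
}

write_lexicon_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent greedy leftmost-longest matcher used as a brute-force oracle:
# enumerates every dictionary match on a lemma sequence, then replays the
# greedy selection by explicit enumeration rather than an index walk.
oracle_matches <- function(lemmas, keys) {
  all <- list()
  for (i in seq_along(lemmas)) {
    for (k in seq_along(keys)) {
      kl <- strsplit(keys[k], " ")[[1]]
      j <- i + length(kl) - 1L
      if (j <= length(lemmas) && all(lemmas[i:j] == kl))
        all[[length(all) + 1L]] <- c(start = i, end = j, key = k)
    }
  }
  if (!length(all)) return(NULL)
  all <- do.call(rbind, lapply(all, function(v)
    data.frame(start = as.integer(v["start"]), end = as.integer(v["end"]),
               key = as.integer(v["key"]))))
  picked <- list()
  covered <- rep(FALSE, length(lemmas))
  repeat {
    cand <- all[!vapply(seq_len(nrow(all)), function(r)
      any(covered[all$start[r]:all$end[r]]), logical(1)), , drop = FALSE]
    if (!nrow(cand)) break
    cand <- cand[order(cand$start, -(cand$end - cand$start), cand$key), ,
                 drop = FALSE]
    # leftmost, then longest, then file order
    best <- cand[1, ]
    left <- cand[cand$start == best$start, , drop = FALSE]
    best <- left[order(-(left$end - left$start), left$key)[1], ]
    picked[[length(picked) + 1L]] <- best
    covered[best$start:best$end] <- TRUE
  }
  do.call(rbind, picked)
}

# brute-force O(n^2) windowed pair counter (sentence-bounded)
oracle_pair_count <- function(tk, target, window) {
  n <- nrow(tk)
  count <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    if (tk$lemma[i] != target) next
    for (j in seq_len(n)) {
      if (j == i) next
      if (tk$doc[j] != tk$doc[i] || tk$sentence[j] != tk$sentence[i]) next
      if (abs(j - i) > window) next
      l <- tk$lemma[j]
      count[[l]] <- (if (is.null(count[[l]])) 0 else count[[l]]) + 1
    }
  }
  out <- vapply(ls(count), function(k) count[[k]], numeric(1))
  out[order(names(out))]
}

# random token table for collocation property tests
random_corpus <- function(n_tokens, vocab, n_sent = 5, seed = 1) {
  set.seed(seed)
  data.frame(doc = 1L,
             sentence = sort(sample(n_sent, n_tokens, replace = TRUE)),
             lemma = sample(vocab, n_tokens, replace = TRUE),
             pos = "NOUN", stringsAsFactors = FALSE)
}

# linearly separable toy features: grade equals the label
separable_features <- function(n_per_class = 10, seed = 1) {
  set.seed(seed)
  lab <- rep(1:3, each = n_per_class)
  data.frame(grade = lab, extra = round(stats::runif(length(lab)), 3),
             label = lab)
}

# monotone-signal features with Gaussian noise
monotone_features <- function(n_per_class = 30, sd = 0.8, seed = 1) {
  set.seed(seed)
  lab <- rep(1:3, each = n_per_class)
  data.frame(x1 = lab + stats::rnorm(length(lab), 0, sd),
             x2 = lab + stats::rnorm(length(lab), 0, sd),
             label = lab)
}

random_confusion <- function(k = 3, max_n = 20) {
  m <- matrix(sample(0:max_n, k * k, replace = TRUE), k, k)
  if (sum(m) == 0) m[1, 1] <- 1
  dimnames(m) <- list(actual = as.character(seq_len(k)),
                      predicted = as.character(seq_len(k)))
  class(m) <- "confusion_matrix"
  m
}

# per-instance brute force for weighted P/R/F: expand the matrix into
# (actual, predicted) instances and tally from scratch
oracle_weighted_metrics <- function(cm) {
  classes <- rownames(cm)
  actual <- rep(rep(classes, ncol(cm)), as.vector(cm))
  predicted <- rep(rep(classes, each = nrow(cm)), as.vector(cm))
  # rebuild per class
  p <- r <- f <- w <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    c <- classes[ci]
    tp <- sum(actual == c & predicted == c)
    fp <- sum(actual != c & predicted == c)
    fn <- sum(actual == c & predicted != c)
    p[ci] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r[ci] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f[ci] <- if (p[ci] + r[ci] == 0) 0 else
      2 * p[ci] * r[ci] / (p[ci] + r[ci])
    w[ci] <- sum(actual == c)
  }
  w <- w / sum(w)
  c(precision = sum(w * p), recall = sum(w * r), f = sum(w * f))
}
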