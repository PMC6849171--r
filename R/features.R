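# ---------------------------------------------------------------------------
# Per-question feature vectors. Each question Q3-Q10 is classified on its
# own 3-point ordinal scheme; features are assembled from the NER, negation,
# graded-lexicon and sentiment outputs according to a per-question schema.
#
# The shipped default schemas are this package's construction: only their
# dimensionalities (Q3:8 Q4:8 Q5:8 Q6:10 Q7:5 Q8:14 Q9:14) are fixed by the
# published system description, not the identity of each feature. They are
# therefore configurable (YAML) and documented as non-canonical.
# ---------------------------------------------------------------------------

#' Ordinal class schemes per question
#'
#' Q3: worse/same/better; Q4: no/reasonably/fully; Q5-Q7: none/some/severe;
#' Q8-Q9: not at all/somewhat/a lot; Q10: negative/neutral/positive.
#' Labels are always 1 < 2 < 3 under the question's scheme.
#'
#' @param question `"Q3"` ... `"Q10"`.
#' @return list with `question` and `classes` (names for labels 1..3).
#' @export
question_scheme <- function(question) {
  schemes <- list(
    Q3 = c("worse", "same", "better"),
    Q4 = c("no", "reasonably", "fully"),
    Q5 = c("none", "some", "severe"),
    Q6 = c("none", "some", "severe"),
    Q7 = c("none", "some", "severe"),
    Q8 = c("not at all", "somewhat", "a lot"),
    Q9 = c("not at all", "somewhat", "a lot"),
    Q10 = c("negative", "neutral", "positive"))
  if (!question %in% names(schemes))
    stop("no ordinal scheme for question: ", question, call. = FALSE)
  list(question = question, classes = schemes[[question]])
}

.descriptor <- function(name, source, ...) {
  list(name = name, source = source, params = list(...))
}

.descriptor_dim <- function(d) if (d$source == "sentiment-label") 3L else 1L

#' Length (dimensionality) of a feature schema
#' @param schema a schema from [default_schemas()].
#' @return integer; one-hot descriptors count once per level.
#' @export
schema_length <- function(schema) {
  sum(vapply(schema$descriptors, .descriptor_dim, integer(1)))
}

.sosy_types <- "sosy"
.activity_types <- c("dora", "ocdi", "ocac", "prog")

#' Default per-question feature schemas
#'
#' One schema per question Q3-Q9, each an ordered list of feature
#' descriptors drawing on the extraction modules: `ner-count` /
#' `ner-negated-count` (concept mentions of given semantic types, negated
#' or not), `grade-max` (maximum graded-modifier severity for an aspect),
#' `negation-count`, `sentiment-score`, `sentiment-label` (one-hot over
#' negative/neutral/positive) and `keyword-flag`. Q10 has no feature
#' schema: its prediction is the majority sentence-polarity label (see
#' [predict_sentiment_label()]).
#'
#' @return named list of schemas; `schema_length()` of each matches the
#'   published per-question feature counts (8, 8, 8, 10, 5, 14, 14).
#' @export
default_schemas <- function() {
  d <- .descriptor
  list(
    Q3 = list(question = "Q3", descriptors = list(
      d("kw_worse", "keyword-flag",
        words = c("worse", "worsened", "worsen", "deteriorated", "deteriorate")),
      d("kw_same", "keyword-flag",
        words = c("same", "unchanged", "similar", "stable", "change")),
      d("kw_better", "keyword-flag",
        words = c("better", "improved", "improve", "improving", "improvement",
                  "progress")),
      d("negation_count", "negation-count"),
      d("sentiment_score", "sentiment-score"),
      d("sentiment_label", "sentiment-label"))),
    Q4 = list(question = "Q4", descriptors = list(
      d("kw_low", "keyword-flag",
        words = c("unsure", "nervous", "worried", "anxious", "unconfident")),
      d("kw_mid", "keyword-flag",
        words = c("reasonably", "fairly", "somewhat", "moderately", "quite")),
      d("kw_high", "keyword-flag",
        words = c("fully", "very", "completely", "totally", "extremely")),
      d("negation_count", "negation-count"),
      d("sentiment_score", "sentiment-score"),
      d("sentiment_label", "sentiment-label"))),
    Q5 = list(question = "Q5", descriptors = list(
      d("ner_count", "ner-count", types = .sosy_types),
      d("ner_negated_count", "ner-negated-count", types = .sosy_types),
      d("grade_max", "grade-max", aspect = "stiffness",
        headwords = "stiffness"),
      d("negation_count", "negation-count"),
      d("sentiment_score", "sentiment-score"),
      d("sentiment_label", "sentiment-label"))),
    Q6 = list(question = "Q6", descriptors = list(
      d("ner_count", "ner-count", types = .sosy_types),
      d("ner_negated_count", "ner-negated-count", types = .sosy_types),
      d("grade_max", "grade-max", aspect = "pain",
        headwords = c("pain", "ache")),
      d("negation_count", "negation-count"),
      d("sentiment_score", "sentiment-score"),
      d("sentiment_label", "sentiment-label"),
      d("kw_constant", "keyword-flag", words = c("constant", "constantly")),
      d("kw_occasional", "keyword-flag",
        words = c("occasional", "occasionally", "intermittent")))),
    Q7 = list(question = "Q7", descriptors = list(
      d("ner_count", "ner-count", types = .sosy_types),
      d("ner_negated_count", "ner-negated-count", types = .sosy_types),
      d("grade_max", "grade-max", aspect = "symptoms",
        headwords = c("swelling", "clicking", "locking", "bruising",
                      "instability", "grinding", "popping", "numbness",
                      "tingling", "weakness", "symptom")),
      d("negation_count", "negation-count"),
      d("sentiment_score", "sentiment-score"))),
    Q8 = list(question = "Q8", descriptors = list(
      d("ner_count", "ner-count", types = .activity_types),
      d("ner_negated_count", "ner-negated-count", types = .activity_types),
      d("grade_max", "grade-max", aspect = "limitation",
        headwords = c("limited", "limit", "restricted", "restrict",
                      "unable", "struggle")),
      d("negation_count", "negation-count"),
      d("sentiment_score", "sentiment-score"),
      d("sentiment_label", "sentiment-label"),
      d("kw_not_limited", "keyword-flag",
        words = c("fine", "normal", "usual", "manage")),
      d("kw_somewhat", "keyword-flag",
        words = c("somewhat", "slightly", "harder", "partly")),
      d("kw_a_lot", "keyword-flag",
        words = c("unable", "struggle", "lot", "severely")),
      d("kw_avoid", "keyword-flag", words = c("avoid", "stop", "cut")),
      d("kw_help", "keyword-flag", words = c("help", "support")),
      d("kw_task", "keyword-flag",
        words = c("task", "housework", "shopping", "stairs", "driving")))),
    Q9 = list(question = "Q9", descriptors = list(
      d("ner_count", "ner-count", types = .activity_types),
      d("ner_negated_count", "ner-negated-count", types = .activity_types),
      d("grade_max", "grade-max", aspect = "limitation",
        headwords = c("limited", "limit", "restricted", "restrict",
                      "unable", "struggle")),
      d("negation_count", "negation-count"),
      d("sentiment_score", "sentiment-score"),
      d("sentiment_label", "sentiment-label"),
      d("kw_not_limited", "keyword-flag",
        words = c("fine", "normal", "usual", "manage")),
      d("kw_somewhat", "keyword-flag",
        words = c("somewhat", "slightly", "harder", "partly")),
      d("kw_a_lot", "keyword-flag",
        words = c("unable", "struggle", "lot", "severely")),
      d("kw_avoid", "keyword-flag", words = c("avoid", "stop", "cut")),
      d("kw_work", "keyword-flag", words = c("work", "job")),
      d("kw_play", "keyword-flag",
        words = c("play", "exercise", "hobby", "sport")))))
}

#' Default feature-extraction resources
#'
#' @return list with `minilex`, `graded` (list of graded lexicons) and
#'   `polarity`.
#' @export
default_resources <- function() {
  list(minilex = default_mini_lexicon(),
       graded = default_graded_lexicons(),
       polarity = default_polarity_lexicon())
}

#' Majority sentence-polarity label for a response
#'
#' The Q10 prediction path: every sentence is scored for polarity and the
#' majority label over the polar (non-neutral) sentences wins; responses
#' with no polar sentence, and positive/negative ties, fall back to
#' neutral. Restricting the vote to polar sentences keeps incidental
#' neutral sentences ("I will mention it at my next appointment.") from
#' washing out an expressed opinion.
#'
#' @param doc a `parsed_document` (or raw text, parsed on the fly).
#' @param polarity polarity lexicon.
#' @param neutral_band neutral band for per-sentence labels.
#' @return ordinal label 1 (negative), 2 (neutral) or 3 (positive).
#' @export
predict_sentiment_label <- function(doc,
                                    polarity = default_polarity_lexicon(),
                                    neutral_band = 0.1) {
  if (is.character(doc)) doc <- parse_response(doc)
  sp <- score_sentiment(doc, lexicon = polarity,
                        neutral_band = neutral_band)
  polar <- sp[sp$label != "neutral", , drop = FALSE]
  if (!nrow(polar)) return(2L)
  n_neg <- sum(polar$label == "negative")
  n_pos <- sum(polar$label == "positive")
  if (n_neg == n_pos) 2L else if (n_neg > n_pos) 1L else 3L
}

#' Extract a feature vector for one response
#'
#' Runs pre-processing, NER, negation, graded-lexicon lookup and sentiment
#' over a raw response and fills the question's schema in order.
#' Multi-sentence responses sum counts over sentences, take the maximum
#' severity grade and average the sentiment score; the sentiment label is a
#' majority vote (ties neutral). A grade-max with no graded modifier is
#' encoded as 0. Deterministic for fixed resources.
#'
#' @param text raw response text (or an already parsed document).
#' @param question `"Q3"` ... `"Q9"`.
#' @param schema schema for the question; default from [default_schemas()].
#' @param resources resource bundle from [default_resources()].
#' @return named numeric vector of length `schema_length(schema)`.
#' @export
extract_features <- function(text, question, schema = NULL,
                             resources = default_resources()) {
  if (is.null(schema)) {
    schemas <- default_schemas()
    if (!question %in% names(schemas))
      stop("no feature schema for question: ", question, call. = FALSE)
    schema <- schemas[[question]]
  }
  doc <- if (inherits(text, "parsed_document")) text else parse_response(text)
  marks <- detect_negation(doc)
  mentions <- recognize(doc, resources$minilex)
  sent <- score_sentiment(doc, lexicon = resources$polarity)
  neg_by_sent <- split(marks$token, marks$sentence)

  mention_negated <- function(m) {
    vapply(seq_len(nrow(m)), function(i) {
      negs <- neg_by_sent[[as.character(m$sentence[i])]]
      if (is.null(negs)) return(FALSE)
      any(seq(m$start[i], m$end[i] - 1L) %in% negs)
    }, logical(1))
  }

  lemmas <- unlist(lapply(doc$sentences, function(s) s$tokens$lemma))
  surfaces <- tolower(unlist(lapply(doc$sentences,
                                    function(s) s$tokens$surface)))

  out <- numeric(0)
  for (d in schema$descriptors) {
    v <- switch(d$source,
      "ner-count" = {
        sum(mentions$semantic_type %in% d$params$types)
      },
      "ner-negated-count" = {
        m <- mentions[mentions$semantic_type %in% d$params$types, ,
                      drop = FALSE]
        if (nrow(m)) sum(mention_negated(m)) else 0
      },
      "grade-max" = {
        lx <- resources$graded[[d$params$aspect]]
        if (is.null(lx))
          stop("missing graded lexicon for aspect: ", d$params$aspect,
               call. = FALSE)
        gs <- vapply(seq_along(doc$sentences), function(i)
          lookup_grade(doc$sentences[[i]], lx,
                       headwords = d$params$headwords,
                       marks = marks[marks$sentence == i - 1L, ,
                                     drop = FALSE]),
          integer(1))
        if (all(is.na(gs))) 0 else max(gs, na.rm = TRUE)
      },
      "negation-count" = nrow(marks),
      "sentiment-score" = if (nrow(sent)) mean(sent$score) else 0,
      "sentiment-label" = {
        counts <- table(factor(sent$label,
                               levels = c("negative", "neutral", "positive")))
        top <- if (!nrow(sent) || sum(counts == max(counts)) > 1) "neutral"
               else names(counts)[which.max(counts)]
        stats::setNames(as.numeric(c("negative", "neutral", "positive") == top),
                        paste0(d$name, "_", c("neg", "neu", "pos")))
      },
      "keyword-flag" = {
        kws <- tolower(d$params$words)
        as.numeric(any(lemmas %in% kws | surfaces %in% kws))
      },
      stop("unknown feature source: ", d$source, call. = FALSE))
    if (is.null(names(v))) names(v) <- d$name
    out <- c(out, v)
  }
  stopifnot(all(is.finite(out)), length(out) == schema_length(schema))
  out
}

#' Build a feature matrix for a set of responses to one question
#'
#' @param texts character vector of raw responses.
#' @param question question id.
#' @param labels optional gold ordinal labels (1..3), attached as a `label`
#'   column.
#' @param schema,resources as in [extract_features()].
#' @return data frame, one row per response, feature columns in schema
#'   order (plus `label` if provided).
#' @export
feature_matrix <- function(texts, question, labels = NULL, schema = NULL,
                           resources = default_resources()) {
  rows <- lapply(texts, extract_features, question = question,
                 schema = schema, resources = resources)
  out <- as.data.frame(do.call(rbind, rows))
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(texts), all(labels %in% 1:3))
    out$label <- as.integer(labels)
  }
  out
}
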