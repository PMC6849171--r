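test_that("default schemas carry the published dimensionalities", {
  sch <- default_schemas()
  want <- c(Q3 = 8L, Q4 = 8L, Q5 = 8L, Q6 = 10L, Q7 = 5L, Q8 = 14L,
            Q9 = 14L)
  got <- vapply(sch, schema_length, integer(1))
  expect_identical(got[names(want)], want)
  expect_true(all(got > 0))
})

test_that("ordinal class schemes follow the questionnaire design", {
  expect_identical(question_scheme("Q3")$classes, c("worse", "same", "better"))
  expect_identical(question_scheme("Q6")$classes, c("none", "some", "severe"))
  expect_identical(question_scheme("Q9")$classes,
                   c("not at all", "somewhat", "a lot"))
  expect_identical(question_scheme("Q10")$classes,
                   c("negative", "neutral", "positive"))
  expect_error(question_scheme("Q1"), "no ordinal scheme")
})

test_that("the work/hobbies answer produces a rich activity count", {
  fv <- extract_features(paste(
    "Not been able to carry out my normal job at work due to my injury",
    "as I am a commercial vehicle mechanic. Limited exercise and hobbies",
    "I haven't been able to play squash due to the injury and golf as I",
    "can't twist my knee fully yet."), "Q9")
  expect_gte(fv[["ner_count"]], 7)
})

test_that("severity features reflect grading and negation", {
  fv <- extract_features("Constant pain whether sitting or standing.", "Q6")
  expect_identical(fv[["grade_max"]], 3)
  expect_identical(fv[["negation_count"]], 0)
  expect_identical(fv[["kw_constant"]], 1)

  # every pain mention negated: negated count equals the count, grade 0
  fv0 <- extract_features(
    "No pain when sitting and no pain when standing.", "Q6")
  expect_gte(fv0[["ner_count"]], 2)
  expect_identical(fv0[["ner_negated_count"]], fv0[["ner_count"]])
  expect_identical(fv0[["grade_max"]], 0)
})

test_that("feature extraction is deterministic and schema-aligned", {
  corp <- generate_responses(synth_config(n = 4, seed = 13, noise = 0.1))
  sch <- default_schemas()
  for (q in names(sch)) {
    sub <- corp$responses[corp$responses$question_id == q, ]
    a <- feature_matrix(sub$text, q, labels = sub$label)
    b <- feature_matrix(sub$text, q, labels = sub$label)
    expect_identical(a, b)
    expect_identical(ncol(a), schema_length(sch[[q]]) + 1L)
    expect_true(all(is.finite(as.matrix(a))))
    # byte-identical CSV across runs
    fa <- tempfile(); fb <- tempfile()
    utils::write.csv(a, fa, row.names = FALSE)
    utils::write.csv(b, fb, row.names = FALSE)
    expect_identical(readLines(fa), readLines(fb))
  }
})

test_that("merging synonym concepts never increases the mention count", {
  split_lex <- mini_lexicon(data.frame(
    concept_id = c("C1", "C2"), name = c("swelling", "edema"),
    semantic_type = "sosy"))
  merged_lex <- mini_lexicon(data.frame(
    concept_id = c("C1", "C1"), name = c("swelling", "edema"),
    semantic_type = "sosy"))
  res_split <- default_resources(); res_split$minilex <- split_lex
  res_merged <- default_resources(); res_merged$minilex <- merged_lex
  tx <- "Some swelling and edema around the knee."
  a <- extract_features(tx, "Q7", resources = res_split)
  b <- extract_features(tx, "Q7", resources = res_merged)
  expect_lte(b[["ner_count"]], a[["ner_count"]])
})

test_that("unknown questions and missing aspect lexicons are hard errors", {
  expect_error(extract_features("text", "Q99"), "no feature schema")
  res <- default_resources()
  res$graded$pain <- NULL
  expect_error(extract_features("Mild pain.", "Q6", resources = res),
               "missing graded lexicon")
})

test_that("the sentiment-only path maps polarity onto the Q10 scheme", {
  expect_identical(predict_sentiment_label(
    "The treatment is not helping and I feel terrible."), 1L)
  expect_identical(predict_sentiment_label("No other comments this week."),
                   2L)
  expect_identical(predict_sentiment_label(
    "The physiotherapy is helping and I feel great."), 3L)
  expect_identical(predict_sentiment_label(""), 2L)
  # a neutral filler sentence does not wash out an expressed opinion
  expect_identical(predict_sentiment_label(paste(
    "The physiotherapy is helping and I feel great.",
    "I will mention it at my next appointment.")), 3L)
})
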