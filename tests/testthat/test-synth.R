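test_that("generation is byte-identical under a fixed seed", {
  a <- generate_responses(synth_config(n = 10, seed = 7))
  b <- generate_responses(synth_config(n = 10, seed = 7))
  expect_identical(a$responses, b$responses)
  expect_identical(a$slots, b$slots)
  c <- generate_responses(synth_config(n = 10, seed = 8))
  expect_false(identical(a$responses$text, c$responses$text))
})

test_that("full negation rate yields a mark in every class-1 response", {
  corp <- generate_responses(synth_config(
    n = 6, seed = 3, negation_rate = 1, class_dist = c(1, 0, 0),
    noise = 0, questions = paste0("Q", 3:10)))
  for (tx in corp$responses$text)
    expect_gt(nrow(detect_negation(parse_response(tx))), 0)
})

test_that("balanced class draws stay inside exact multinomial bounds", {
  corp <- generate_responses(synth_config(n = 300, seed = 2,
                                          questions = c("Q5", "Q8")))
  for (q in c("Q5", "Q8")) {
    counts <- table(factor(
      corp$responses$label[corp$responses$question_id == q], levels = 1:3))
    lo <- qbinom(0.005, 300, 1 / 3)
    hi <- qbinom(0.995, 300, 1 / 3)
    expect_true(all(counts >= lo & counts <= hi))
  }
})

test_that("gold labels are consistent with the graded signal", {
  corp <- generate_responses(synth_config(n = 30, seed = 5, noise = 0,
                                          questions = "Q6"))
  g <- default_graded_lexicons()$pain
  for (i in seq_len(nrow(corp$responses))) {
    r <- corp$responses[i, ]
    doc <- parse_response(r$text)
    grades <- vapply(doc$sentences, lookup_grade, integer(1), lex = g,
                     headwords = c("pain", "ache"))
    gmax <- if (all(is.na(grades))) 0L else max(grades, na.rm = TRUE)
    if (r$label == 3) expect_identical(gmax, 3L)
    if (r$label == 1) expect_lte(gmax, 1L)
  }
})

test_that("gold annotations tag each slot once and round-trip", {
  corp <- generate_responses(synth_config(n = 5, seed = 4, noise = 0,
                                          questions = c("Q1", "Q2", "Q9")))
  tagged <- generate_gold_annotations(corp)
  expect_identical(sort(names(tagged)), sort(unique(corp$slots$response_id)))
  for (id in names(tagged)) {
    back <- read_gold_annotations(tagged[[id]])
    sp <- corp$slots[corp$slots$response_id == id, ]
    expect_identical(back$text,
                     corp$responses$text[corp$responses$response_id == id])
    expect_identical(nrow(back$spans), nrow(sp))
    expect_identical(back$spans$start, sp$start)
    expect_identical(back$spans$end, sp$end)
    # anatomy slots carry the ne3 tag
    expect_identical(back$spans$tag[sp$type == "anat"],
                     rep("ne3", sum(sp$type == "anat")))
  }
})

test_that("NER recall on generated gold is perfect at zero noise", {
  corp <- generate_responses(synth_config(n = 10, seed = 6, noise = 0,
                                          questions = c("Q1", "Q2", "Q9")))
  lex <- default_mini_lexicon()
  found <- 0L
  for (i in seq_len(nrow(corp$slots))) {
    sl <- corp$slots[i, ]
    r <- corp$responses[corp$responses$response_id == sl$response_id, ]
    doc <- parse_response(r$text, id = r$response_id)
    m <- recognize(doc, lex)
    hit <- FALSE
    for (j in seq_len(nrow(m))) {
      cs <- mention_char_span(doc, m$sentence[j], m$start[j], m$end[j])
      if (cs[1] == sl$start && cs[2] == sl$end &&
          m$concept_id[j] == sl$concept_id) hit <- TRUE
    }
    found <- found + hit
  }
  expect_identical(found, nrow(corp$slots))
})

test_that("lexical noise perturbs text without breaking slot offsets", {
  corp <- generate_responses(synth_config(n = 40, seed = 9, noise = 0.5,
                                          questions = c("Q2", "Q9")))
  for (i in seq_len(nrow(corp$slots))) {
    sl <- corp$slots[i, ]
    tx <- corp$responses$text[corp$responses$response_id == sl$response_id]
    expect_identical(substr(tx, sl$start + 1, sl$end), sl$text)
  }
})

test_that("responses survive a JSON-lines round trip", {
  corp <- generate_responses(synth_config(n = 3, seed = 1))
  p <- tempfile(fileext = ".jsonl")
  write_responses_jsonl(corp$responses, p)
  back <- read_responses_jsonl(p)
  expect_identical(nrow(back), nrow(corp$responses))
  expect_identical(back$text, corp$responses$text)
  expect_identical(attr(back, "skipped"), 0L)
  # malformed lines are skipped and counted
  writeLines(c(readLines(p), "{not json"), p)
  back2 <- read_responses_jsonl(p)
  expect_identical(nrow(back2), nrow(corp$responses))
  expect_identical(attr(back2, "skipped"), 1L)
  expect_error(read_responses_jsonl(p, strict = TRUE), "malformed")
})
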