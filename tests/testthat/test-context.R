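test_that("negative determiner negates only its own mention", {
  doc <- parse_response(paste(
    "No pain when sitting, some pain when walking upstairs",
    "and walking long distances."))
  marks <- detect_negation(doc)
  toks <- doc$sentences[[1]]$tokens
  pains <- toks$index[toks$lemma == "pain"]
  expect_true(pains[1] %in% marks$token)
  expect_false(pains[2] %in% marks$token)
  expect_identical(marks$rule[marks$token == pains[1]], "R2")
})

test_that("copular negation propagates to subject and predicate", {
  doc <- parse_response("The pain is not constant.")
  marks <- detect_negation(doc)
  toks <- doc$sentences[[1]]$tokens
  negated <- toks$surface[marks$token + 1L]
  expect_true(all(c("pain", "constant") %in% negated))
  expect_true("R3" %in% marks$rule)
})

test_that("negation propagates through the verbal chain to objects", {
  doc <- parse_response("I have not had any pain this week.")
  marks <- detect_negation(doc)
  toks <- doc$sentences[[1]]$tokens
  expect_true(toks$index[toks$lemma == "pain"] %in% marks$token)
})

test_that("a marked nominal cancels its adjectival modifiers", {
  doc <- parse_response("No constant pain this week.")
  marks <- detect_negation(doc)
  toks <- doc$sentences[[1]]$tokens
  expect_true(toks$index[toks$surface == "constant"] %in% marks$token)
  expect_true("R4" %in% marks$rule)
})

test_that("no cue yields no marks and detection is pure", {
  doc <- parse_response("Severe stiffness in the morning.")
  expect_identical(nrow(detect_negation(doc)), 0L)
  doc2 <- parse_response("The pain is not constant.")
  expect_identical(detect_negation(doc2), detect_negation(doc2))
})

test_that("removing all cue tokens removes all marks", {
  cues <- c("no", "not", "n't", "never", "neither", "none")
  texts <- generate_responses(synth_config(n = 5, seed = 9,
                                           negation_rate = 1,
                                           class_dist = c(1, 0, 0),
                                           noise = 0))$responses$text
  for (tx in texts) {
    words <- strsplit(tx, " ")[[1]]
    stripped <- paste(words[!tolower(gsub("[[:punct:]]", "", words)) %in%
                              cues & !grepl("n't", words)],
                      collapse = " ")
    expect_identical(nrow(detect_negation(parse_response(stripped))), 0L,
                     label = stripped)
  }
})

test_that("rule subsets can be disabled", {
  doc <- parse_response("No constant pain this week.")
  m12 <- detect_negation(doc, rules = c("R1", "R2"))
  expect_false("R4" %in% m12$rule)
  expect_identical(nrow(detect_negation(doc, rules = "R1")), 0L)
})

test_that("sentiment polarity matches the narrative examples", {
  neg <- score_sentiment(parse_response(paste(
    "My pain was unbearable and I was screaming, crying,",
    "and regretting how it happened.")))
  expect_identical(neg$label, "negative")
  expect_lt(neg$score, -0.1)

  pos <- score_sentiment(parse_response("no pain at all and feeling great"))
  expect_identical(pos$label, "positive")
  expect_gt(pos$score, 0.1)

  expect_identical(nrow(score_sentiment(parse_response(""))), 0L)
  neutral <- score_sentiment(parse_response("The clinic is in town."))
  expect_identical(neutral$label, "neutral")
  expect_identical(neutral$score, 0)
})

test_that("negating a polar sentence flips the score sign", {
  pairs <- list(c("I feel great.", "I do not feel great."),
                c("The pain is bad.", "The pain is not bad."),
                c("The treatment is helping.",
                  "The treatment is not helping."))
  for (p in pairs) {
    a <- score_sentiment(parse_response(p[1]))$score
    b <- score_sentiment(parse_response(p[2]))$score
    expect_true(sign(a) == -sign(b) && a != 0, label = p[2])
  }
})

test_that("polarity lexicon loading validates scores", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("term\tscore", "good\t0.5", "bad\t-0.5"), p)
  lx <- load_polarity_lexicon(p)
  expect_identical(unname(lx["good"]), 0.5)
  writeLines(c("term\tscore", "good\t1.5"), p)
  expect_error(load_polarity_lexicon(p), "\\[-1, 1\\]")
})

test_that("the sentiment scorer is pluggable", {
  sentiment_scorer("always_pos", function(sentence, marks, lexicon) 1)
  sp <- score_sentiment(parse_response("The pain is awful."),
                        scorer = "always_pos")
  expect_identical(sp$label, "positive")
  expect_error(score_sentiment(parse_response("x"), scorer = "absent"),
               "not available")
})
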