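test_that("synonym rows collapse onto one concept", {
  path <- write_lexicon_tsv(swelling_lexicon_df())
  lex <- load_lexicon(path)
  expect_identical(nrow(lex$entries), 3L)
  expect_length(unique(lex$entries$concept_id), 1L)
})

test_that("lexicon loader is tolerant and errors are informative", {
  # extra unknown column ignored
  df <- swelling_lexicon_df()
  df$comment <- "x"
  lex <- load_lexicon(write_lexicon_tsv(df))
  expect_identical(sort(names(lex$entries)[1:3]),
                   c("concept_id", "name", "semantic_type"))
  # header-only file: empty lexicon with warning
  p <- write_lexicon_tsv(swelling_lexicon_df()[0, ])
  expect_warning(lex0 <- load_lexicon(p), "no entries")
  expect_identical(nrow(lex0$entries), 0L)
  # missing required column named in the error
  bad <- data.frame(concept_id = "C1", name = "swelling")
  expect_error(load_lexicon(write_lexicon_tsv(bad)), "semantic_type")
  # duplicate (name, type) rows collapse with a warning
  dup <- rbind(swelling_lexicon_df(), swelling_lexicon_df()[1, ])
  expect_warning(lexd <- load_lexicon(write_lexicon_tsv(dup)), "duplicate")
  expect_identical(nrow(lexd$entries), 3L)
})

test_that("the ACL answer yields the five published mentions", {
  doc <- parse_response(paste(
    "I completely ruptured my ACL and had ACL reconstruction surgery",
    "using a hamstring graft."))
  m <- answer_open_question(doc, default_mini_lexicon(), "Q1")
  expect_identical(m$text,
                   c("completely ruptured", "ACL", "ACL",
                     "reconstruction surgery", "hamstring graft"))
  expect_identical(m$semantic_type, c("cond", "anat", "anat", "surg", "surg"))
  # both ACL mentions normalise to one concept
  expect_length(unique(m$concept_id[m$text == "ACL"]), 1L)
})

test_that("activity mentions in the work/hobbies answer are recognised", {
  doc <- parse_response(paste(
    "Not been able to carry out my normal job at work due to my injury",
    "as I am a commercial vehicle mechanic. Limited exercise and hobbies",
    "I haven't been able to play squash due to the injury and golf as I",
    "can't twist my knee fully yet."))
  m <- recognize(doc, default_mini_lexicon(),
                 c("dora", "ocdi", "ocac", "prog"))
  expect_identical(nrow(m), 7L)
  got <- setNames(m$semantic_type, m$text)
  expect_identical(got[["job"]], "ocdi")
  expect_identical(got[["work"]], "ocac")
  expect_identical(got[["vehicle mechanic"]], "prog")
  expect_true(all(got[c("exercise", "hobbies", "squash", "golf")] == "dora"))
})

test_that("normalisation is case-insensitive over synonyms", {
  lex <- default_mini_lexicon()
  ids <- vapply(c("swelling", "edema", "oedema", "OEDEMA", "Edema"),
                normalize_concept, character(1), lex = lex)
  expect_length(unique(ids), 1L)
  expect_false(is.na(ids[[1]]))
  # knee-rehabilitation-specific exercise deliberately absent
  expect_true(is.na(normalize_concept("hamstring curls", lex)))
})

test_that("layman treatment names answer Q2 normalised", {
  lex <- default_mini_lexicon()
  m <- answer_open_question(parse_response("physio"), lex, "Q2")
  expect_identical(nrow(m), 1L)
  expect_identical(m$concept_id, normalize_concept("physiotherapy", lex))
  expect_identical(nrow(answer_open_question(parse_response(""), lex, "Q2")),
                   0L)
  expect_error(answer_open_question(parse_response("x"), lex, "Q5"),
               "Q1, Q2")
})

test_that("matching is greedy leftmost-longest and never overlaps", {
  lexdf <- data.frame(
    concept_id = c("A", "B", "C", "D", "E"),
    name = c("pain", "knee pain", "knee", "sharp knee pain", "sharp"),
    semantic_type = "sosy", stringsAsFactors = FALSE)
  lex <- mini_lexicon(lexdf)
  keys <- lex$entries$lemma_key
  set.seed(42)
  vocab <- c("pain", "knee", "sharp", "joint", "the", "and")
  for (rep in 1:40) {
    lemmas <- sample(vocab, sample(3:15, 1), replace = TRUE)
    doc <- structure(list(id = "t", text = NA, sentences = list(list(
      tokens = data.frame(index = seq_along(lemmas) - 1L, surface = lemmas,
                          lemma = lemmas, pos = "NOUN",
                          start = 0L, end = 1L, stringsAsFactors = FALSE),
      edges = data.frame(dependent = seq_along(lemmas) - 1L, head = -1L,
                         relation = "root")))), class = "parsed_document")
    got <- recognize(doc, lex)
    want <- oracle_matches(lemmas, keys)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      want <- want[order(want$start), , drop = FALSE]
      expect_identical(got$start, want$start - 1L)
      expect_identical(got$end, want$end)
      expect_identical(got$concept_id, lex$entries$concept_id[want$key])
    }
    # non-overlap invariant
    if (nrow(got) > 1)
      expect_true(all(got$start[-1] >= got$end[-nrow(got)]))
  }
})

test_that("type filter is sound and synonyms recognise consistently", {
  lex <- default_mini_lexicon()
  types <- c("drug", "devi")
  m <- recognize(parse_response(
    "Taking ibuprofen and wearing a knee brace after physio."), lex, types)
  expect_true(all(m$semantic_type %in% types))
  # every name of a concept resolves to the same id through recognize()
  some <- lex$entries[lex$entries$concept_id %in%
                        c("LK0704", "LK0301", "LK0405"), ]
  for (i in seq_len(nrow(some))) {
    m <- recognize(parse_response(some$name[i]), lex,
                   some$semantic_type[i])
    expect_identical(unique(m$concept_id), some$concept_id[i])
  }
})

test_that("no lexicon names means no mentions", {
  m <- recognize(parse_response("Nothing relevant whatsoever here."),
                 mini_lexicon(swelling_lexicon_df()))
  expect_identical(nrow(m), 0L)
})

test_that("inline gold annotations round-trip", {
  text <- "I ruptured my ACL and had reconstruction surgery."
  spans <- data.frame(start = c(14L, 26L), end = c(17L, 48L),
                      tag = c("ne3", "ne2"))
  tagged <- write_gold_annotations(text, spans)
  expect_identical(tagged, paste0(
    "I ruptured my <ne3>ACL</ne3> and had ",
    "<ne2>reconstruction surgery</ne2>."))
  back <- read_gold_annotations(tagged)
  expect_identical(back$text, text)
  expect_identical(back$spans$start, spans$start)
  expect_identical(back$spans$end, spans$end)
  expect_identical(back$spans$tag, spans$tag)
  # overlapping spans refuse to serialise
  expect_error(write_gold_annotations(text, data.frame(
    start = c(0L, 3L), end = c(5L, 8L), tag = "ne1")), "overlap")
})
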