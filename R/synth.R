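# ---------------------------------------------------------------------------
# Seeded generator of labelled synthetic questionnaire responses.
#
# Clinical free-text answers to this kind of questionnaire are private, so
# the generator emulates their statistical structure: short (1-2 sentence)
# first-person symptom narratives whose ordinal class is controlled by
# construction. Class-3 responses draw grade-3 severity modifiers, class-1
# responses draw negated symptom mentions (with probability negation_rate)
# or absence phrasing, class-2 sits in between; named-entity slots are
# filled from the bundled mini-lexicon so NER recall on the generated gold
# is perfect at zero noise. Lexical noise (typos, synonym swaps, distractor
# clauses) degrades the signal at a controlled rate.
# ---------------------------------------------------------------------------

#' Generator configuration
#'
#' @param n responses per question.
#' @param seed RNG seed (all randomness flows through it).
#' @param class_dist probability over ordinal classes 1..3.
#' @param negation_rate probability that a class-1 response uses negated
#'   symptom phrasing rather than an absence phrase.
#' @param noise lexical-noise rate: per-response probability of each of a
#'   character typo, a synonym swap inside a concept, and a distractor
#'   clause.
#' @param sentences range (min, max) of sentences per response; extra
#'   sentences are neutral filler.
#' @param questions question ids to generate for.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n = 300L, seed = 1L, class_dist = rep(1 / 3, 3),
                         negation_rate = 0.5, noise = 0.05,
                         sentences = c(1L, 2L),
                         questions = paste0("Q", 1:10)) {
  stopifnot(n >= 1, length(class_dist) == 3, all(class_dist >= 0),
            abs(sum(class_dist) - 1) < 1e-8,
            negation_rate >= 0, negation_rate <= 1, noise >= 0, noise <= 1)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 class_dist = class_dist, negation_rate = negation_rate,
                 noise = noise, sentences = as.integer(sentences),
                 questions = questions),
            class = "synth_config")
}

# template pools: per question, per class, split into negated / plain
# phrasing for class 1. {type} slots are filled from the mini-lexicon;
# {g2}/{g3} draw a grade-2/grade-3 modifier from the question's aspect
# lexicon.
.synth_templates <- function() {
  list(
    Q1 = list(plain = c(
      "I am being treated for {cond}.",
      "I have {cond} and my {anat} is affected.",
      "I injured my {anat} and had {surg}.",
      "I completely ruptured my {anat} and had {surg} last year.",
      "Diagnosed with {cond} after an injury to my {anat}.")),
    Q2 = list(plain = c(
      "I am using {thpr} and taking {drug}.",
      "I have a {devi} and do {exac} every day.",
      "Currently having {thpr} for my knee.",
      "Weekly {thpr} plus {exac} at home.",
      "Taking {drug} and wearing a {devi} when walking.")),
    Q3 = list(
      `1` = list(
        neg = c("My knee is not improving and it feels worse.",
                "The knee has not settled and things have got worse."),
        plain = c("My knee has got worse this week.",
                  "The pain has worsened and my knee feels worse than before.",
                  "My knee condition has deteriorated over the past week.")),
      `2` = list(plain = c(
        "My knee feels much the same as last week.",
        "The condition is stable and similar to last week.",
        "No real change, my knee feels the same as before.")),
      `3` = list(plain = c(
        "My knee feels better and keeps improving.",
        "There has been good progress and the knee is much better.",
        "The knee has improved a lot this week."))),
    Q4 = list(
      `1` = list(
        neg = c("I do not feel confident about looking after my knee.",
                "I am not confident that I can manage my knee."),
        plain = c("I am worried and unsure about looking after my knee.",
                  "I feel nervous and anxious about managing my knee.")),
      `2` = list(plain = c(
        "I feel reasonably confident about looking after my knee.",
        "I am fairly confident about managing my knee.",
        "I feel somewhat confident looking after it.")),
      `3` = list(plain = c(
        "I feel fully confident about looking after my knee.",
        "I am completely confident that I can manage my knee.",
        "I feel very confident about looking after it."))),
    Q5 = list(
      `1` = list(
        neg = c("No stiffness at all this week.",
                "I have not had any stiffness in my knee.",
                "The knee is not stiff at the moment."),
        plain = c("The knee has been absolutely fine this week.")),
      `2` = list(plain = c(
        "{g2} stiffness in the morning.",
        "Some stiffness after sitting for a while.",
        "{g2} stiffness when I wake up.")),
      `3` = list(plain = c(
        "{g3} stiffness all day and it is hard to bend the knee.",
        "The stiffness is {g3} and constant.",
        "{g3} stiffness which makes walking difficult."))),
    Q6 = list(
      `1` = list(
        neg = c("No pain when sitting or standing.",
                "I have not had any pain this week.",
                "The pain is not constant and I have felt fine."),
        plain = c("My knee has been completely pain-free this week.")),
      `2` = list(plain = c(
        "{g2} pain around the joint.",
        "Some pain when walking upstairs and walking long distances.",
        "{g2} pain especially when going up steps.")),
      `3` = list(plain = c(
        "{g3} pain whether sitting or standing.",
        "My pain was {g3} and I was screaming and crying.",
        "{g3} pain at night and it is unbearable."))),
    Q7 = list(
      `1` = list(
        neg = c("No swelling or other symptoms this week.",
                "I have not noticed any swelling or clicking."),
        plain = c("The knee has felt completely normal this week.")),
      `2` = list(plain = c(
        "{g2} swelling around the knee.",
        "Occasional clicking when bending the knee.",
        "Some bruising and {g2} swelling.")),
      `3` = list(plain = c(
        "{g3} swelling and the knee keeps giving way.",
        "The swelling is {g3} and the knee keeps locking.",
        "{g3} swelling with constant grinding and instability."))),
    Q8 = list(
      `1` = list(
        neg = c("My knee has not limited my daily tasks at all.",
                "The knee has not stopped me doing my housework."),
        plain = c("I have managed all my daily tasks fine as usual.",
                  "Day to day tasks have been normal and easy this week.")),
      `2` = list(plain = c(
        "Somewhat limited, housework and shopping are harder than usual.",
        "My knee has slightly limited my day to day tasks.",
        "Some tasks like driving are harder but I manage.")),
      `3` = list(plain = c(
        "I have been unable to do my daily tasks and I struggle with stairs.",
        "My knee has severely limited everything, even housework.",
        "I struggle a lot with daily tasks and avoid stairs completely."))),
    Q9 = list(
      `1` = list(
        neg = c("My knee has not limited my {ocac} or my {dora} at all.",
                "The injury has not stopped me playing {dora} or doing my {ocdi}."),
        plain = c("I have carried out my {ocdi} and played {dora} as normal.",
                  "Managed {ocac} and {dora} fine this week.")),
      `2` = list(plain = c(
        "Somewhat limited at {ocac} and I had to cut down on {dora}.",
        "My knee slightly limited my {ocdi} and I played less {dora}.",
        "{dora} is harder than usual but I still manage my {ocac}.")),
      `3` = list(plain = c(
        "I have been unable to play {dora} and had to stop {ocac} because of my knee.",
        "My knee has severely limited my {ocdi} and I struggle at {ocac}.",
        "Not been able to carry out my {ocdi} at {ocac} and I can't play {dora} at all."))),
    Q10 = list(
      `1` = list(
        neg = c("The treatment is not helping and I feel terrible.",
                "I am not happy with how the knee is going."),
        plain = c("I feel miserable about my knee and the treatment.",
                  "The knee is awful and I am unhappy with progress.")),
      `2` = list(plain = c(
        "No other comments this week.",
        "Nothing else to add about the treatment.",
        "The clinic appointment is next week.")),
      `3` = list(plain = c(
        "The physiotherapy is helping and I feel great.",
        "I am really pleased with the progress of my knee.",
        "The treatment is working well and I am happy."))))
}

.filler_sentences <- c(
  "I have been keeping an eye on it.",
  "I will mention it at my next appointment.",
  "It has been a busy week otherwise.")

.question_aspect <- c(Q5 = "stiffness", Q6 = "pain", Q7 = "symptoms",
                      Q8 = "limitation", Q9 = "limitation")

# fill one template; returns list(text, slots = df(start, end, type, text))
.fill_template <- function(template, lex, graded, aspect) {
  slots <- data.frame(start = integer(0), end = integer(0),
                      type = character(0), text = character(0),
                      concept_id = character(0), stringsAsFactors = FALSE)
  out <- ""
  rest <- template
  repeat {
    m <- regexpr("\\{[a-z0-9]+\\}", rest)
    if (m == -1) { out <- paste0(out, rest); break }
    out <- paste0(out, substr(rest, 1, m - 1))
    key <- gsub("[{}]", "", regmatches(rest, m))
    rest <- substr(rest, m + attr(m, "match.length"), nchar(rest))
    if (key %in% c("g2", "g3")) {
      gl <- graded[[aspect]]
      grade <- as.integer(sub("g", "", key))
      pool <- names(gl$grades)[gl$grades == grade]
      fill <- sample(pool, 1)
      if (substr(out, nchar(out), nchar(out)) == "" || !nzchar(out) ||
          grepl("(^|[.!?] )$", out))
        fill <- paste0(toupper(substr(fill, 1, 1)), substr(fill, 2, nchar(fill)))
      out <- paste0(out, fill)
    } else {
      rows <- which(lex$entries$semantic_type == key)
      r <- if (length(rows) > 1) sample(rows, 1) else rows
      fill <- lex$entries$name[r]
      slots <- rbind(slots, data.frame(
        start = nchar(out), end = nchar(out) + nchar(fill), type = key,
        text = fill, concept_id = lex$entries$concept_id[r],
        stringsAsFactors = FALSE))
      out <- paste0(out, fill)
    }
  }
  list(text = out, slots = slots)
}

# noise operators; slot offsets are kept consistent
.apply_noise <- function(text, slots, lex, rate) {
  # typo: swap two adjacent characters of a word outside slot spans
  if (stats::runif(1) < rate) {
    m <- gregexpr("[A-Za-z]{4,}", text)[[1]]
    if (m[1] != -1) {
      cand <- which(vapply(seq_along(m), function(i) {
        s <- as.integer(m[i]) - 1L; e <- s + attr(m, "match.length")[i]
        !nrow(slots) || all(e <= slots$start | s >= slots$end)
      }, logical(1)))
      if (length(cand)) {
        i <- if (length(cand) > 1) sample(cand, 1) else cand
        s <- as.integer(m[i])
        w <- attr(m, "match.length")[i]
        p <- s + sample(w - 2L, 1)           # swap inside the word
        text <- paste0(substr(text, 1, p - 1), substr(text, p + 1, p + 1),
                       substr(text, p, p), substr(text, p + 2, nchar(text)))
      }
    }
  }
  # synonym swap: replace one slot fill with another name of its concept
  if (nrow(slots) && stats::runif(1) < rate) {
    i <- if (nrow(slots) > 1) sample(nrow(slots), 1) else 1L
    syn <- lex$entries[lex$entries$concept_id == slots$concept_id[i] &
                       lex$entries$name != slots$text[i], , drop = FALSE]
    if (nrow(syn)) {
      r <- if (nrow(syn) > 1) sample(nrow(syn), 1) else 1L
      new <- syn$name[r]
      delta <- nchar(new) - nchar(slots$text[i])
      text <- paste0(substr(text, 1, slots$start[i]), new,
                     substr(text, slots$end[i] + 1, nchar(text)))
      slots$text[i] <- new
      slots$end[i] <- slots$end[i] + delta
      later <- slots$start > slots$start[i]
      slots$start[later] <- slots$start[later] + delta
      slots$end[later] <- slots$end[later] + delta
    }
  }
  # distractor clause appended before the final period
  if (stats::runif(1) < rate) {
    distract <- c(" which I wanted to mention",
                  " as discussed at the clinic",
                  " much like the week before")
    d <- sample(distract, 1)
    if (grepl("\\.$", text))
      text <- paste0(substr(text, 1, nchar(text) - 1), d, ".")
    else text <- paste0(text, d)
  }
  list(text = text, slots = slots)
}

#' Generate a labelled synthetic response corpus
#'
#' Reproducible under a fixed seed. Open questions Q1-Q2 carry named-entity
#' slots and no ordinal label; Q3-Q10 carry a gold ordinal label consistent
#' with the filled template by construction.
#'
#' @param config a [synth_config()].
#' @param lex mini-lexicon used to fill NE slots (default bundled).
#' @param graded graded lexicons for severity slots (default bundled).
#' @return list of class `synth_corpus`: `responses` (data frame with
#'   `response_id`, `participant_id`, `timestamp`, `question_id`, `text`,
#'   `label`, `template`) and `slots` (gold NE spans: `response_id`,
#'   `start`, `end`, `type`, `text`, `concept_id`; offsets 0-based
#'   half-open).
#' @export
generate_responses <- function(config = synth_config(),
                               lex = default_mini_lexicon(),
                               graded = default_graded_lexicons()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  templates <- .synth_templates()
  res <- list(); slt <- list()
  rid <- 0L
  for (q in config$questions) {
    pool_q <- templates[[q]]
    if (is.null(pool_q)) stop("no templates for question ", q, call. = FALSE)
    aspect <- unname(.question_aspect[q])
    for (i in seq_len(config$n)) {
      rid <- rid + 1L
      if (q %in% c("Q1", "Q2")) {
        label <- NA_integer_
        tpl_pool <- pool_q$plain
      } else {
        label <- sample(3L, 1, prob = config$class_dist)
        cl <- pool_q[[as.character(label)]]
        tpl_pool <- if (label == 1L && !is.null(cl$neg) &&
                        stats::runif(1) < config$negation_rate)
          cl$neg else cl$plain
      }
      ti <- if (length(tpl_pool) > 1) sample(length(tpl_pool), 1) else 1L
      filled <- .fill_template(tpl_pool[ti], lex, graded,
                               if (is.na(aspect)) "pain" else aspect)
      text <- filled$text; slots <- filled$slots
      # optional neutral filler sentence
      n_extra <- sample(seq(config$sentences[1], config$sentences[2]), 1) - 1L
      if (n_extra > 0)
        text <- paste(text, paste(sample(.filler_sentences, n_extra),
                                  collapse = " "))
      noised <- .apply_noise(text, slots, lex, config$noise)
      text <- noised$text; slots <- noised$slots
      id <- sprintf("R%05d", rid)
      res[[rid]] <- data.frame(
        response_id = id,
        participant_id = sprintf("P%03d", ((i - 1L) %% 20L) + 1L),
        timestamp = sprintf("2026-01-%02dT09:00:00", ((i - 1L) %% 28L) + 1L),
        question_id = q, text = text, label = label,
        template = sprintf("%s-%s-%d", q,
                           if (is.na(label)) "na" else label, ti),
        stringsAsFactors = FALSE)
      if (nrow(slots)) {
        slots$response_id <- id
        slt[[length(slt) + 1L]] <- slots
      }
    }
  }
  structure(list(
    responses = do.call(rbind, res),
    slots = if (length(slt)) do.call(rbind, slt) else
      data.frame(start = integer(0), end = integer(0), type = character(0),
                 text = character(0), concept_id = character(0),
                 response_id = character(0), stringsAsFactors = FALSE),
    config = config), class = "synth_corpus")
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat("<synth_corpus> ", nrow(x$responses), " responses over ",
      length(unique(x$responses$question_id)), " questions (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}

.slot_tag <- c(cond = "ne1", surg = "ne2", anat = "ne3")

#' Emit inline-XML gold annotations for generated responses
#'
#' Conditions, surgical procedures and anatomy slots use the `ne1`/`ne2`/
#' `ne3` tags; other semantic types use their type code as the tag.
#' Spans are maximal-extent and non-nested by construction (the writer
#' asserts non-overlap).
#'
#' @param corpus a `synth_corpus`.
#' @return named character vector (one tagged string per response that has
#'   at least one slot).
#' @export
generate_gold_annotations <- function(corpus) {
  stopifnot(inherits(corpus, "synth_corpus"))
  ids <- unique(corpus$slots$response_id)
  out <- vapply(ids, function(id) {
    text <- corpus$responses$text[corpus$responses$response_id == id]
    sp <- corpus$slots[corpus$slots$response_id == id, , drop = FALSE]
    tag <- ifelse(sp$type %in% names(.slot_tag), .slot_tag[sp$type], sp$type)
    write_gold_annotations(text, data.frame(start = sp$start, end = sp$end,
                                            tag = tag))
  }, character(1))
  stats::setNames(out, ids)
}

#' Write / read responses as JSON-lines
#'
#' One JSON object per line with fields `participant_id`, `timestamp`,
#' `question_id`, `text` (and `response_id`/`label` when present) -- the
#' format the pipeline reader consumes.
#'
#' @param responses response data frame (e.g. `synth_corpus$responses`).
#' @param path output file.
#' @export
write_responses_jsonl <- function(responses, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(responses))) {
    row <- as.list(responses[i, , drop = FALSE])
    row <- row[!vapply(row, function(v) is.na(v) || is.null(v), logical(1))]
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_responses_jsonl
#' @param strict error on malformed lines instead of skipping them.
#' @return `read_responses_jsonl()` returns a data frame plus an attribute
#'   `skipped` with the number of unparseable lines.
#' @export
read_responses_jsonl <- function(path, strict = FALSE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- list(); skipped <- 0L
  for (ln in lines) {
    row <- tryCatch(jsonlite::fromJSON(ln), error = function(e) NULL)
    if (is.null(row) || is.null(row$question_id) || is.null(row$text)) {
      if (strict) stop("malformed response line: ", ln, call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, .pad_fields(rows)) else
    data.frame(question_id = character(0), text = character(0),
               stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

.pad_fields <- function(rows) {
  fields <- unique(unlist(lapply(rows, names)))
  lapply(rows, function(r) {
    for (f in setdiff(fields, names(r))) r[[f]] <- NA
    r[, fields, drop = FALSE]
  })
}
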