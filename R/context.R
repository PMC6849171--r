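# ---------------------------------------------------------------------------
# Contextual modifiers of concept mentions: explicit syntactic negation
# detected on dependency graphs, and sentence-level sentiment polarity.
#
# Only explicitly asserted negation (an overt cue such as "not" or "no",
# recoverable from grammatical relations) is handled; implicit, pragmatic
# negation (e.g. the verb "to ease" effectively negating "pain") is out of
# scope and is partially covered by the sentiment scorer instead.
# ---------------------------------------------------------------------------

.neg_adv_cues <- c("not", "n't")
.neg_det_cues <- c("no", "neither", "none")
.copular_lemmas <- c("be", "seem", "feel", "look", "remain", "stay")

#' Negation rule inventory
#'
#' Four deterministic rules applied in order over a sentence's dependency
#' tree:
#' \describe{
#'   \item{R1}{a negation adverb (*not*, *n't*) attached by a `neg` relation
#'     marks its head.}
#'   \item{R2}{a negative determiner (*no*, *neither*, *none*) attached by a
#'     `det` relation marks its nominal head.}
#'   \item{R3}{propagation along the verbal backbone: a marked auxiliary or
#'     copula passes the mark to the verb or predicate it supports; a marked
#'     copular/linking verb passes it to its nominal/adjectival subject and
#'     predicate; a marked verb passes it to its direct object mention (so
#'     in "no pain and do not feel pain" both mentions end up negated).}
#'   \item{R4}{a marked nominal propagates to its adjectival modifiers, so
#'     "no constant pain" also cancels *constant*.}
#' }
#' Individual rules can be disabled via the `rules` argument of
#' [detect_negation()] (mirrored by the pipeline configuration).
#' @return character vector of rule ids.
#' @export
negation_rules <- function() c("R1", "R2", "R3", "R4")

.empty_marks <- function() {
  data.frame(sentence = integer(0), token = integer(0), cue = integer(0),
             rule = character(0), stringsAsFactors = FALSE)
}

# sentence: list(tokens, edges); returns marks for one sentence (0-based)
.detect_negation_sentence <- function(sentence, sent_idx,
                                      rules = negation_rules()) {
  toks <- sentence$tokens
  edges <- sentence$edges
  n <- nrow(toks)
  if (!n) return(.empty_marks())
  marked <- rep(FALSE, n)            # 1-based over tokens
  out <- list()
  add <- function(tok0, cue0, rule) {
    if (tok0 < 0) return()
    if (marked[tok0 + 1L]) return()
    marked[tok0 + 1L] <<- TRUE
    out[[length(out) + 1L]] <<- data.frame(
      sentence = sent_idx, token = tok0, cue = cue0, rule = rule,
      stringsAsFactors = FALSE)
  }
  lem <- toks$lemma
  # R1 / R2: direct cue attachment
  for (i in seq_len(n)) {
    rel <- edges$relation[i]
    hd <- edges$head[i]
    if ("R1" %in% rules && rel == "neg" &&
        tolower(toks$surface[i]) %in% .neg_adv_cues)
      add(hd, i - 1L, "R1")
    if ("R2" %in% rules && rel == "det" && lem[i] %in% .neg_det_cues &&
        hd >= 0 && toks$pos[hd + 1L] %in% c("NOUN", "PRON"))
      add(hd, i - 1L, "R2")
  }
  # R3 / R4: propagate to fixpoint (a copular mark can expose a nominal
  # whose adjectival modifiers must then be cancelled too)
  repeat {
    grew <- FALSE
    if ("R3" %in% rules) {
      for (m in which(marked)) {
        cue <- .mark_cue(out, m - 1L)
        # negated auxiliary/copula applies to the verb or predicate it
        # supports ("is not helping", "was not constant")
        if (toks$pos[m] == "AUX" &&
            edges$relation[m] %in% c("aux", "cop") && edges$head[m] >= 0 &&
            !marked[edges$head[m] + 1L]) {
          add(edges$head[m], cue, "R3"); grew <- TRUE
        }
        if (toks$pos[m] %in% c("AUX", "VERB") &&
            lem[m] %in% .copular_lemmas) {
          kids <- which(edges$head == (m - 1L) &
                        edges$relation %in% c("nsubj", "attr"))
          for (k in kids) {
            if (!marked[k]) { add(k - 1L, cue, "R3"); grew <- TRUE }
          }
        }
        # a negated verb applies along its verbal chain and to its direct
        # object mention ("have not had any pain" negates "pain")
        if (toks$pos[m] %in% c("VERB", "AUX")) {
          kids <- which(edges$head == (m - 1L) &
                        edges$relation %in% c("obj", "aux"))
          for (k in kids) {
            if (!marked[k]) { add(k - 1L, cue, "R3"); grew <- TRUE }
          }
        }
      }
    }
    if ("R4" %in% rules) {
      for (m in which(marked)) {
        if (toks$pos[m] %in% c("NOUN", "PRON")) {
          kids <- which(edges$head == (m - 1L) & edges$relation == "amod")
          cue <- .mark_cue(out, m - 1L)
          for (k in kids) {
            if (!marked[k]) { add(k - 1L, cue, "R4"); grew <- TRUE }
          }
        }
      }
    }
    if (!grew) break
  }
  if (!length(out)) return(.empty_marks())
  do.call(rbind, out)
}

.mark_cue <- function(out, tok0) {
  for (m in out) if (m$token == tok0) return(m$cue)
  tok0
}

#' Detect explicitly negated tokens
#'
#' Applies the rule inventory of [negation_rules()] to every sentence of a
#' parsed document (or to a single sentence list). Pure and deterministic:
#' repeated calls on the same input yield identical marks.
#'
#' @param x a `parsed_document`, or a single sentence (list with `tokens`
#'   and `edges`).
#' @param rules subset of rule ids to apply.
#' @return data frame of negation marks: `sentence` (0-based), `token`
#'   (0-based index of the negated token), `cue` (0-based index of the cue
#'   token), `rule`.
#' @export
detect_negation <- function(x, rules = negation_rules()) {
  if (inherits(x, "parsed_document")) {
    if (!length(x$sentences)) return(.empty_marks())
    out <- lapply(seq_along(x$sentences), function(i)
      .detect_negation_sentence(x$sentences[[i]], i - 1L, rules))
    return(do.call(rbind, out))
  }
  stopifnot(is.list(x), !is.null(x$tokens), !is.null(x$edges))
  .detect_negation_sentence(x, 0L, rules)
}

# -- sentiment --------------------------------------------------------------

#' Load a polarity lexicon
#'
#' TSV with columns `term` and `score`; scores must lie in \[-1, 1\]. Terms
#' are lemmatised so lookup meets parsed text in lemma space.
#'
#' @param path TSV file path.
#' @return named numeric vector (names are lemmas).
#' @export
load_polarity_lexicon <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           fileEncoding = "UTF-8")
  if (!all(c("term", "score") %in% names(raw)))
    stop("polarity lexicon must have columns 'term' and 'score'",
         call. = FALSE)
  sc <- as.numeric(raw$score)
  if (any(is.na(sc)) || any(sc < -1 | sc > 1))
    stop("polarity scores must be numeric in [-1, 1]", call. = FALSE)
  stats::setNames(sc, lemmatize(tolower(raw$term)))
}

#' Sentiment scorer registry
#'
#' The sentiment stage is pluggable: a scorer is a function
#' `function(sentence, marks, lexicon)` returning a numeric score in
#' \[-1, 1\]. The shipped default sums a graded polarity lexicon over
#' tokens, sign-flipping tokens negated according to [detect_negation()],
#' and normalises by the number of polar tokens.
#'
#' @param name scorer name; `"lexicon"` is always available.
#' @param fun optional scorer function to register under `name`.
#' @export
sentiment_scorer <- local({
  scorers <- new.env(parent = emptyenv())
  function(name = "lexicon", fun = NULL) {
    if (!is.null(fun)) {
      assign(name, fun, envir = scorers)
      return(invisible(fun))
    }
    if (name == "lexicon") return(.score_lexicon)
    if (!exists(name, envir = scorers))
      stop("sentiment scorer not available: ", name, call. = FALSE)
    get(name, envir = scorers)
  }
})

.score_lexicon <- function(sentence, marks, lexicon) {
  toks <- sentence$tokens
  if (!nrow(toks)) return(0)
  hit <- toks$lemma %in% names(lexicon)
  if (!any(hit)) return(0)
  s <- lexicon[toks$lemma[hit]]
  negated <- toks$index[hit] %in% marks$token
  s[negated] <- -s[negated]
  max(-1, min(1, mean(s)))
}

#' Score sentence-level sentiment polarity
#'
#' @param sentence a single sentence (list with `tokens` and `edges`) or a
#'   `parsed_document` (scored per sentence).
#' @param lexicon named numeric polarity lexicon (see
#'   [load_polarity_lexicon()]); defaults to the bundled lexicon.
#' @param neutral_band sentences with |score| below this are neutral.
#' @param scorer scorer name (see [sentiment_scorer()]).
#' @param rules negation rules passed to [detect_negation()].
#' @return data frame with one row per sentence: `sentence` (0-based),
#'   `label` (negative/neutral/positive) and `score` in \[-1, 1\].
#' @export
score_sentiment <- function(sentence, lexicon = default_polarity_lexicon(),
                            neutral_band = 0.1, scorer = "lexicon",
                            rules = negation_rules()) {
  fn <- sentiment_scorer(scorer)
  one <- function(s, idx) {
    marks <- .detect_negation_sentence(s, idx, rules)
    sc <- fn(s, marks, lexicon)
    lab <- if (abs(sc) < neutral_band) "neutral"
           else if (sc > 0) "positive" else "negative"
    data.frame(sentence = idx, label = lab, score = sc,
               stringsAsFactors = FALSE)
  }
  if (inherits(sentence, "parsed_document")) {
    if (!length(sentence$sentences))
      return(data.frame(sentence = integer(0), label = character(0),
                        score = numeric(0), stringsAsFactors = FALSE))
    return(do.call(rbind, lapply(seq_along(sentence$sentences), function(i)
      one(sentence$sentences[[i]], i - 1L))))
  }
  one(sentence, 0L)
}
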