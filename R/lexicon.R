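# ---------------------------------------------------------------------------
# Graded (ordinal) modifier lexicons and collocation-based lexicon
# induction.
#
# A graded lexicon maps modifiers of one symptom aspect (pain, stiffness,
# ...) onto the 3-point severity scheme (1 none-level, 2 some, 3 severe):
# "mild pain" < "severe pain", "slight pain" < "bad pain", "sharp" is
# severe. Candidate modifiers for new aspects can be induced from any plain
# corpus with the PMI collocation extractor and then hand-graded; grading
# laymen's modifiers needs no medical expertise.
# ---------------------------------------------------------------------------

#' Load a graded modifier lexicon
#'
#' TSV with columns `modifier` and `grade`; grades must be 1, 2 or 3
#' (none/some/severe). Modifiers are lower-cased and lemmatised; duplicates
#' keep the last row with a warning.
#'
#' @param path TSV file path.
#' @param aspect aspect headword the lexicon grades (defaults to the file
#'   base name, e.g. `pain` for `pain.tsv`).
#' @return object of class `graded_lexicon`: list with `aspect` and
#'   `grades` (named integer vector keyed by modifier lemma).
#' @export
load_graded_lexicon <- function(path,
                                aspect = sub("\\.[^.]*$", "", basename(path))) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           fileEncoding = "UTF-8")
  if (!all(c("modifier", "grade") %in% names(raw)))
    stop("graded lexicon must have columns 'modifier' and 'grade'",
         call. = FALSE)
  g <- suppressWarnings(as.integer(raw$grade))
  if (any(is.na(g)) || any(!g %in% 1:3))
    stop("grades must be 1, 2 or 3 in ", path, call. = FALSE)
  key <- lemmatize(tolower(raw$modifier))
  if (anyDuplicated(key)) {
    warning("duplicate modifiers in ", path, "; last entry wins")
    keep <- !duplicated(key, fromLast = TRUE)
    key <- key[keep]; g <- g[keep]
  }
  graded_lexicon(stats::setNames(g, key), aspect)
}

#' Construct a graded lexicon from a named vector
#'
#' @param grades named integer vector (names = modifiers, values in 1..3).
#' @param aspect aspect headword.
#' @export
graded_lexicon <- function(grades, aspect) {
  stopifnot(all(grades %in% 1:3), !is.null(names(grades)))
  structure(list(aspect = aspect,
                 grades = stats::setNames(as.integer(grades),
                                          tolower(names(grades)))),
            class = "graded_lexicon")
}

#' @export
print.graded_lexicon <- function(x, ...) {
  cat("<graded_lexicon> aspect=", x$aspect, ", ", length(x$grades),
      " modifiers\n", sep = "")
  invisible(x)
}

#' Load a directory of graded lexicons
#'
#' Each `<aspect>.tsv` in the directory becomes one graded lexicon keyed by
#' aspect; the pipeline configuration maps questions to aspects.
#'
#' @param dir directory of TSV files.
#' @return named list of `graded_lexicon` objects.
#' @export
load_graded_lexicons <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  out <- lapply(files, load_graded_lexicon)
  stats::setNames(out, vapply(out, `[[`, character(1), "aspect"))
}

#' Severity grade of a symptom mention from its graded modifiers
#'
#' Returns the maximum grade over the modifiers of a headword that appear in
#' the lexicon: adjectival (`amod`) and adverbial (`advmod`) dependents,
#' predicative adjectives linked through a copula whose subject is the
#' headword, and the immediately preceding modifier token. Modifiers
#' cancelled by explicit negation are skipped, so "The pain is not
#' constant." yields no grade from *constant*. Returns `NA` when no graded
#' modifier is present.
#'
#' @param sentence a sentence (list with `tokens` and `edges`).
#' @param lex a `graded_lexicon`.
#' @param headwords lemmas of the aspect headword(s); defaults to the
#'   lexicon's aspect.
#' @param marks negation marks for this sentence (computed if omitted).
#' @return integer grade in 1..3, or `NA_integer_`.
#' @export
lookup_grade <- function(sentence, lex, headwords = lex$aspect,
                         marks = NULL) {
  stopifnot(inherits(lex, "graded_lexicon"))
  toks <- sentence$tokens
  if (!nrow(toks)) return(NA_integer_)
  if (is.null(marks)) marks <- .detect_negation_sentence(sentence, 0L)
  negated <- toks$index %in% marks$token
  edges <- sentence$edges
  hw <- unique(c(tolower(headwords), lemmatize(headwords)))
  heads1 <- which(toks$lemma %in% hw | tolower(toks$surface) %in% hw)
  best <- NA_integer_
  consider <- function(i1) {
    if (negated[i1]) return()
    g <- lex$grades[toks$lemma[i1]]
    if (!is.na(g)) best <<- max(best, g, na.rm = TRUE)
  }
  for (h in heads1) {
    h0 <- h - 1L
    # dependent modifiers, including graded determiners ("some pain")
    for (k in which(edges$head == h0 &
                    edges$relation %in% c("amod", "advmod", "det")))
      consider(k)
    # predicative adjective through a copular head: pain <-nsubj- is -attr-> X
    hd <- edges$head[h]
    if (edges$relation[h] == "nsubj" && hd >= 0 &&
        toks$pos[hd + 1L] %in% c("AUX", "VERB")) {
      for (k in which(edges$head == hd & edges$relation == "attr"))
        consider(k)
    }
    # immediately preceding modifier token
    if (h > 1L && toks$pos[h - 1L] %in% c("ADJ", "ADV")) consider(h - 1L)
  }
  if (is.na(best)) NA_integer_ else as.integer(best)
}

# -- collocation extraction -------------------------------------------------

#' Flatten a corpus into a token table
#'
#' Accepts raw text (character vector; each element is parsed), a single
#' `parsed_document`, a list of them, or an already-flattened token data
#' frame (columns `doc`, `sentence`, `lemma`, `pos`), which is returned
#' as-is. Returns one row per token with document/sentence ids, lemma and
#' POS.
#'
#' @param corpus character vector, `parsed_document`, list of documents, or
#'   token data frame.
#' @return data frame with columns `doc`, `sentence`, `lemma`, `pos`.
#' @export
corpus_tokens <- function(corpus) {
  if (is.data.frame(corpus)) {
    stopifnot(all(c("doc", "sentence", "lemma", "pos") %in% names(corpus)))
    return(corpus)
  }
  if (inherits(corpus, "parsed_document")) corpus <- list(corpus)
  if (is.character(corpus)) corpus <- lapply(corpus, parse_response)
  stopifnot(is.list(corpus))
  out <- list()
  for (d in seq_along(corpus)) {
    doc <- corpus[[d]]
    for (s in seq_along(doc$sentences)) {
      tk <- doc$sentences[[s]]$tokens
      if (!nrow(tk)) next
      out[[length(out) + 1L]] <- data.frame(
        doc = d, sentence = s, lemma = tk$lemma, pos = tk$pos,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(doc = integer(0), sentence = integer(0),
                      lemma = character(0), pos = character(0)))
  do.call(rbind, out)
}

#' Extract collocates of a target word by pointwise mutual information
#'
#' Counts co-occurrences of each candidate collocate within a symmetric
#' token window around every occurrence of the target, inside sentence
#' boundaries, and scores them with base-2 PMI:
#' `PMI(c, t) = log2(N * f(c, t) / (f(c) * f(t)))`, where `N` is the corpus
#' token count. Pairs never observed together are omitted. Defaults (window
#' 5, adjectives only) reflect standard corpus-linguistics practice for
#' inducing candidate graded modifiers.
#'
#' @param corpus anything accepted by [corpus_tokens()].
#' @param target target word (matched on lemma, case-insensitive).
#' @param window maximum token distance (>= 1).
#' @param pos_filter POS tags collocates must carry; NULL keeps all.
#' @return object of class `collocation_table`: a data frame with columns
#'   `collocate`, `joint`, `f_collocate`, `f_target`, `N`, `pmi`, sorted by
#'   PMI descending, plus attributes `target`, `window`, `pos_filter`.
#' @export
extract_collocates <- function(corpus, target, window = 5,
                               pos_filter = "ADJ") {
  stopifnot(window >= 1)
  tk <- corpus_tokens(corpus)
  target <- lemmatize(tolower(target))[1]
  N <- nrow(tk)
  empty <- structure(
    data.frame(collocate = character(0), joint = numeric(0),
               f_collocate = numeric(0), f_target = numeric(0),
               N = numeric(0), pmi = numeric(0), stringsAsFactors = FALSE),
    target = target, window = window, pos_filter = pos_filter,
    class = c("collocation_table", "data.frame"))
  if (!N) { warning("empty corpus"); return(empty) }
  f_t <- sum(tk$lemma == target)
  if (!f_t) { warning("target '", target, "' absent from corpus"); return(empty) }
  f_all <- table(tk$lemma)
  joint <- new.env(parent = emptyenv())
  sent_key <- paste(tk$doc, tk$sentence)
  tpos <- which(tk$lemma == target)
  for (i in tpos) {
    lo <- max(1L, i - as.integer(window))
    hi <- min(N, i + as.integer(window))
    for (j in lo:hi) {
      if (j == i || sent_key[j] != sent_key[i]) next
      c_lem <- tk$lemma[j]
      joint[[c_lem]] <- (if (is.null(joint[[c_lem]])) 0 else joint[[c_lem]]) + 1
    }
  }
  coll <- setdiff(ls(joint), target)   # a word is not its own collocate
  if (!is.null(pos_filter) && length(pos_filter)) {
    keep_pos <- unique(tk$lemma[tk$pos %in% pos_filter])
    coll <- intersect(coll, keep_pos)
  }
  if (!length(coll)) return(empty)
  jn <- vapply(coll, function(x) joint[[x]], numeric(1))
  fc <- as.numeric(f_all[coll])
  pmi <- log2(N * jn / (fc * f_t))
  out <- data.frame(collocate = coll, joint = jn, f_collocate = fc,
                    f_target = f_t, N = N, pmi = pmi,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$pmi, out$collocate), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, target = target, window = window, pos_filter = pos_filter,
            class = c("collocation_table", "data.frame"))
}
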