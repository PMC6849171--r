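# ---------------------------------------------------------------------------
# Dictionary-based named-entity recognition with concept normalisation.
#
# The terminology is a "mini-lexicon" with UMLS-like structure: every row is
# (concept_id, name, semantic_type); synonym names share one concept_id, so
# recognised surface variants (swelling / edema / oedema) normalise to the
# same identifier. Matching is greedy leftmost-longest over lemmas,
# case-insensitive, and never emits nested or overlapping mentions.
# ---------------------------------------------------------------------------

# Semantic-type codes used by the bundled lexicon:
#   cond  medical condition          surg  surgical procedure
#   anat  anatomical structure       thpr  therapeutic procedure
#   drug  drug / medication          devi  medical device
#   exac  exercise activity          sosy  sign or symptom
#   dora  daily or recreational activity
#   ocdi  occupation or discipline   ocac  occupational activity
#   prog  professional or occupational group

#' Semantic-type groups answering the two open-ended questions
#'
#' Q1 (current knee condition) is answered by mentions of medical
#' conditions, surgical procedures and anatomical structures; Q2 (current
#' treatment) by therapeutic procedures, drugs, devices and exercise
#' activities.
#' @return named list of character vectors of semantic-type codes.
#' @export
open_question_types <- function() {
  list(Q1 = c("cond", "surg", "anat"),
       Q2 = c("thpr", "drug", "devi", "exac"))
}

.build_lexicon <- function(entries) {
  stopifnot(all(c("concept_id", "name", "semantic_type") %in% names(entries)))
  entries <- entries[, c("concept_id", "name", "semantic_type")]
  entries$concept_id <- as.character(entries$concept_id)
  entries$name <- as.character(entries$name)
  entries$semantic_type <- as.character(entries$semantic_type)
  keep <- !duplicated(paste(tolower(entries$name), entries$semantic_type))
  if (any(!keep))
    warning(sum(!keep), " duplicate (name, semantic_type) row(s) collapsed")
  entries <- entries[keep, , drop = FALSE]
  rownames(entries) <- NULL
  lk <- lapply(strsplit(tolower(entries$name), " +"), lemmatize)
  entries$lemma_key <- vapply(lk, paste, character(1), collapse = " ")
  entries$n_tok <- lengths(lk)
  first <- vapply(lk, function(x) if (length(x)) x[[1]] else "", character(1))
  index <- split(seq_len(nrow(entries)), first)
  structure(list(entries = entries, index = index,
                 max_len = if (nrow(entries)) max(entries$n_tok) else 0L),
            class = "mini_lexicon")
}

#' Load a concept mini-lexicon from TSV
#'
#' The file must be tab-separated with a header naming at least the columns
#' `concept_id`, `name` and `semantic_type`; unknown extra columns are
#' ignored. Duplicate (name, semantic_type) rows are collapsed with a
#' warning; an empty file yields an empty lexicon with a warning. Names are
#' lemmatised at load time with [lemmatize()] so that lookup operates in the
#' same lemma space as parsed text.
#'
#' @param path path to a UTF-8 TSV file.
#' @return an object of class `mini_lexicon`.
#' @export
load_lexicon <- function(path) {
  raw <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                      comment.char = "", fileEncoding = "UTF-8"),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) {
    if (is.null(raw)) {
      warning("empty lexicon file: ", path)
      raw <- data.frame(concept_id = character(0), name = character(0),
                        semantic_type = character(0))
    } else {
      missing <- setdiff(c("concept_id", "name", "semantic_type"), names(raw))
      if (length(missing))
        stop("lexicon file ", path, " is missing required column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      warning("lexicon file has no entries: ", path)
    }
  }
  missing <- setdiff(c("concept_id", "name", "semantic_type"), names(raw))
  if (length(missing))
    stop("lexicon file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  .build_lexicon(raw)
}

#' Construct a mini-lexicon from a data frame
#'
#' @param entries data frame with columns `concept_id`, `name`,
#'   `semantic_type`.
#' @return a `mini_lexicon`.
#' @export
mini_lexicon <- function(entries) .build_lexicon(entries)

#' @export
print.mini_lexicon <- function(x, ...) {
  cat("<mini_lexicon> ", nrow(x$entries), " names, ",
      length(unique(x$entries$concept_id)), " concepts, ",
      length(unique(x$entries$semantic_type)), " semantic types\n", sep = "")
  invisible(x)
}

.empty_mentions <- function() {
  data.frame(response_id = character(0), sentence = integer(0),
             start = integer(0), end = integer(0), text = character(0),
             concept_id = character(0), semantic_type = character(0),
             stringsAsFactors = FALSE)
}

#' Recognise concept mentions in a parsed document
#'
#' Greedy leftmost-longest dictionary matching over lemmas,
#' case-insensitive. Matches never overlap and nested mentions are not
#' emitted; when two candidate matches at the same position have equal
#' length, lexicon file order breaks the tie. `types` restricts the
#' dictionary to the given semantic-type codes before matching (an empty or
#' NULL set means all types).
#'
#' @param doc a `parsed_document`.
#' @param lex a `mini_lexicon`.
#' @param types character vector of semantic-type codes, or NULL for all.
#' @return a data frame of concept mentions: `response_id`, `sentence`
#'   (0-based), token span `start`/`end` (0-based, half-open), matched
#'   `text`, `concept_id`, `semantic_type`.
#' @export
recognize <- function(doc, lex, types = NULL) {
  stopifnot(inherits(doc, "parsed_document"), inherits(lex, "mini_lexicon"))
  entries <- lex$entries
  if (!is.null(types) && length(types))
    entries <- entries[entries$semantic_type %in% types, , drop = FALSE]
  if (!nrow(entries) || !length(doc$sentences)) return(.empty_mentions())
  index <- split(seq_len(nrow(entries)),
                 vapply(strsplit(entries$lemma_key, " "), `[`, character(1), 1))
  out <- list()
  for (si in seq_along(doc$sentences)) {
    toks <- doc$sentences[[si]]$tokens
    lem <- toks$lemma
    i <- 1L
    while (i <= length(lem)) {
      rows <- index[[lem[i]]]
      best <- NA_integer_; best_len <- 0L
      if (!is.null(rows)) {
        for (r in rows) {
          k <- entries$n_tok[r]
          if (k < best_len || i + k - 1L > length(lem)) next
          if (identical(paste(lem[i:(i + k - 1L)], collapse = " "),
                        entries$lemma_key[r])) {
            if (k > best_len) { best <- r; best_len <- k }
            # equal length: keep earlier file row (rows scanned in order)
          }
        }
      }
      if (!is.na(best)) {
        span <- i:(i + best_len - 1L)
        out[[length(out) + 1L]] <- data.frame(
          response_id = doc$id, sentence = si - 1L,
          start = i - 1L, end = i + best_len - 1L,
          text = paste(toks$surface[span], collapse = " "),
          concept_id = entries$concept_id[best],
          semantic_type = entries$semantic_type[best],
          stringsAsFactors = FALSE)
        i <- i + best_len
      } else i <- i + 1L
    }
  }
  if (!length(out)) return(.empty_mentions())
  do.call(rbind, out)
}

#' Normalise a name to its concept identifier
#'
#' Case-insensitive synonym lookup in lemma space: all synonym names of a
#' concept return the same identifier. Unknown names return `NA` rather than
#' signalling an error.
#'
#' @param name a non-empty string.
#' @param lex a `mini_lexicon`.
#' @return the concept id, or `NA_character_` if the name is unknown.
#' @export
normalize_concept <- function(name, lex) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name),
            inherits(lex, "mini_lexicon"))
  key <- paste(lemmatize(strsplit(tolower(name), " +")[[1]]),
               collapse = " ")
  hit <- which(lex$entries$lemma_key == key)
  if (!length(hit)) hit <- which(tolower(lex$entries$name) == tolower(name))
  if (!length(hit)) return(NA_character_)
  lex$entries$concept_id[hit[1]]
}

#' Answer an open-ended question with normalised concept mentions
#'
#' Q1 (knee condition) returns mentions of conditions, surgical procedures
#' and anatomical structures; Q2 (treatment) returns mentions of therapeutic
#' procedures, drugs, devices and exercise activities. Mentions are ordered
#' by text position.
#'
#' @param doc a `parsed_document`.
#' @param lex a `mini_lexicon`.
#' @param question `"Q1"` or `"Q2"`.
#' @return a concept-mention data frame (see [recognize()]).
#' @export
answer_open_question <- function(doc, lex, question) {
  types <- open_question_types()
  if (!question %in% names(types))
    stop("question must be one of: ", paste(names(types), collapse = ", "),
         call. = FALSE)
  m <- recognize(doc, lex, types[[question]])
  m[order(m$sentence, m$start), , drop = FALSE]
}

# -- inline gold annotations ------------------------------------------------

#' Read inline-tagged gold annotations
#'
#' Parses text carrying inline span tags (`<ne1>...</ne1>`,
#' `<dora>...</dora>`, ...) into plain text plus a span table with 0-based
#' half-open character offsets into the untagged text. Tags must not nest.
#'
#' @param tagged a single string with inline tags.
#' @return list with `text` (untagged string) and `spans` (data frame
#'   `start`, `end`, `tag`, `text`).
#' @export
read_gold_annotations <- function(tagged) {
  stopifnot(is.character(tagged), length(tagged) == 1)
  pat <- "<([A-Za-z][A-Za-z0-9]*)>(.*?)</\\1>"
  out <- data.frame(start = integer(0), end = integer(0),
                    tag = character(0), text = character(0),
                    stringsAsFactors = FALSE)
  plain <- ""
  rest <- tagged
  repeat {
    m <- regexpr(pat, rest, perl = TRUE)
    if (m == -1) { plain <- paste0(plain, rest); break }
    pre <- substr(rest, 1, m - 1)
    whole <- regmatches(rest, m)
    tag <- sub(pat, "\\1", whole, perl = TRUE)
    inner <- sub(pat, "\\2", whole, perl = TRUE)
    start <- nchar(plain) + nchar(pre)
    out <- rbind(out, data.frame(start = start,
                                 end = start + nchar(inner),
                                 tag = tag, text = inner,
                                 stringsAsFactors = FALSE))
    plain <- paste0(plain, pre, inner)
    rest <- substr(rest, m + attr(m, "match.length"), nchar(rest))
  }
  list(text = plain, spans = out)
}

#' Write inline-tagged gold annotations
#'
#' Inserts inline span tags into plain text at the given 0-based half-open
#' character offsets. Spans must be non-overlapping (maximal-extent,
#' non-nested annotation convention); overlap is an error.
#'
#' @param text plain string.
#' @param spans data frame with `start`, `end`, `tag`.
#' @return the tagged string.
#' @export
write_gold_annotations <- function(text, spans) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nrow(spans)) return(text)
  spans <- spans[order(spans$start), , drop = FALSE]
  if (any(spans$start[-1] < spans$end[-nrow(spans)]))
    stop("overlapping annotation spans", call. = FALSE)
  if (any(spans$start < 0 | spans$end > nchar(text) | spans$end < spans$start))
    stop("annotation span outside text bounds", call. = FALSE)
  for (i in rev(seq_len(nrow(spans)))) {
    s <- spans$start[i]; e <- spans$end[i]; tag <- spans$tag[i]
    text <- paste0(substr(text, 1, s), "<", tag, ">",
                   substr(text, s + 1, e), "</", tag, ">",
                   substr(text, e + 1, nchar(text)))
  }
  text
}

#' Character span of a token-level mention
#'
#' @param doc the `parsed_document` the mention came from.
#' @param sentence 0-based sentence index.
#' @param start,end 0-based half-open token span.
#' @return integer vector `c(start, end)`: 0-based half-open character
#'   offsets into `doc$text`.
#' @export
mention_char_span <- function(doc, sentence, start, end) {
  toks <- doc$sentences[[sentence + 1L]]$tokens
  c(toks$start[start + 1L], toks$end[end])
}
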