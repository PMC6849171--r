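# ---------------------------------------------------------------------------
# Linguistic pre-processing: tokenisation, POS tagging, lemmatisation and
# dependency attachment for short first-person symptom narratives.
#
# The default backend is a compact deterministic rule-based parser. It is
# exposed through an adapter interface (see `parser_backend()`) so that a
# heavier statistical parser can be substituted without touching downstream
# modules: every later stage consumes only the ParsedDocument contract
# (tokens with POS tags and a dependency tree per sentence).
# ---------------------------------------------------------------------------

# Closed-class word lists. Coarse universal-style tagset:
# NOUN VERB AUX ADJ ADV ADP DET PRON CCONJ SCONJ PART NUM PUNCT
.lx_det <- c("the", "a", "an", "no", "some", "any", "this", "that", "these",
             "those", "my", "your", "his", "her", "its", "our", "their",
             "every", "each", "neither", "none", "all", "both", "another",
             "other", "such", "more", "most", "less", "much", "several")

.lx_pron <- c("i", "you", "he", "she", "it", "we", "they", "me", "him", "us",
              "them", "myself", "himself", "herself", "itself", "anything",
              "something", "nothing", "everything", "what", "which", "who",
              "mine", "yours")

.lx_aux <- c("am", "is", "are", "was", "were", "be", "been", "being", "have",
             "has", "had", "do", "does", "did", "will", "would", "can",
             "could", "shall", "should", "may", "might", "must", "ca", "wo",
             "seems", "seem", "seemed", "feels", "felt")

.lx_adp <- c("in", "on", "at", "of", "for", "with", "without", "around",
             "about", "during", "after", "before", "over", "under", "from",
             "up", "down", "by", "into", "onto", "near", "between", "through",
             "against", "to", "towards", "across", "behind", "off", "out",
             "than", "despite", "via", "per", "within")

.lx_sconj <- c("when", "while", "because", "if", "although", "though",
               "whether", "since", "unless", "until", "whenever", "as")

.lx_cconj <- c("and", "or", "but", "nor", "plus", "yet")

.lx_part <- c("to", "n't", "not")  # "to"/negators re-tagged below

.lx_adv <- c("not", "n't", "never", "very", "quite", "really", "especially",
             "occasionally", "sometimes", "often", "always", "also", "still",
             "too", "now", "then", "again", "fully", "completely", "slightly",
             "somewhat", "reasonably", "fairly", "moderately", "totally",
             "extremely", "away", "upstairs", "downstairs", "downhill",
             "uphill", "only", "just", "there", "here", "well", "much",
             "far", "mostly", "barely", "hardly", "rarely", "currently",
             "generally", "usually", "even", "already", "soon", "together",
             "back", "severely", "partly", "hugely", "massively")

# Open-class domain vocabulary (knee rehabilitation narratives).
.lx_adj <- c("mild", "severe", "sharp", "stabbing", "intermittent",
             "constant", "occasional", "slight", "bad", "dull", "chronic",
             "acute", "excruciating", "unbearable", "burning", "nagging",
             "throbbing", "shooting", "persistent", "frequent", "general",
             "sore", "stiff", "swollen", "tender", "painful", "pain-free",
             "confident", "able", "unable", "normal", "usual", "better",
             "worse", "same", "great", "good", "fine", "terrible", "awful",
             "horrible", "difficult", "hard", "easy", "easier", "harder",
             "limited", "moderate", "minimal", "extreme", "noticeable",
             "momentary", "sudden", "medial", "lateral", "nocturnal",
             "uneven", "long", "short", "full", "commercial", "further",
             "real", "similar", "stable", "new", "old", "significant",
             "light", "heavy", "gentle", "considerable", "agonising",
             "agonizing", "overwhelming", "niggling", "dreadful", "unsure",
             "nervous", "worried", "anxious", "positive", "negative",
             "neutral", "weekly", "daily", "stiff-free", "free", "main",
             "whole", "certain", "various", "happy", "unhappy", "pleased",
             "grateful", "miserable", "comfortable", "uncomfortable",
             "tolerable", "manageable", "restricted", "swelling-free",
             "last", "past", "low", "high", "deep", "tight", "weak",
             "strong", "unstable", "steady", "wobbly", "numb", "tingling",
             "aching")

.lx_noun <- c("pain", "ache", "stiffness", "swelling", "knee", "joint",
              "leg", "legs", "morning", "mornings", "evening", "night",
              "nights", "week", "day", "days", "work", "job", "hobby",
              "hobbies", "exercise", "exercises", "physio", "physiotherapy",
              "surgery", "treatment", "condition", "injury", "symptom",
              "symptoms", "discomfort", "stairs", "steps", "step",
              "distance", "distances", "ground", "chair", "mechanic",
              "vehicle", "squash", "golf", "tennis", "yoga", "badminton",
              "football", "rugby", "netball", "cricket", "gym", "garden",
              "acl", "ligament", "meniscus", "kneecap", "patella",
              "cartilage", "hamstring", "quadriceps", "tendon", "cruciate",
              "osteoarthritis", "arthritis", "tear", "rupture", "tendinitis",
              "bursitis", "sprain", "strain", "dislocation", "fracture",
              "reconstruction", "replacement", "arthroscopy", "operation",
              "graft", "ibuprofen", "paracetamol", "naproxen", "codeine",
              "painkiller", "painkillers", "medication", "brace", "crutch",
              "crutches", "ice", "hydrotherapy", "acupuncture", "massage",
              "injection", "steroid", "bruising", "clicking", "popping",
              "locking", "grinding", "instability", "weakness", "numbness",
              "comment", "comments", "change", "changes", "confidence",
              "ability", "tasks", "task", "housework", "shopping", "driving",
              "walking", "bed", "office", "time", "lot", "bit", "couple",
              "side", "sides", "area", "areas", "part", "parts", "way",
              "stretches", "stretching", "rest", "support", "strapping",
              "therapy", "teacher", "nurse", "builder", "electrician",
              "plumber", "accountant", "care", "limp", "trouble", "issue",
              "issues", "problem", "problems", "progress", "flare", "month",
              "months", "year", "years", "stair", "floor", "surface",
              "surfaces", "level")

.lx_verb <- c("be", "have", "do", "walk", "sit", "stand", "run", "play",
              "feel", "hurt", "limit", "carry", "manage", "struggle",
              "improve", "worsen", "describe", "experience", "get", "go",
              "climb", "bend", "straighten", "twist", "kneel", "squat",
              "swim", "cycle", "use", "receive", "help", "scream", "cry",
              "regret", "happen", "ease", "rupture", "sleep", "wake",
              "rest", "wear", "take", "need", "stop", "start", "keep",
              "give", "pop", "click", "lock", "swell", "bruise", "avoid",
              "cope", "reduce", "increase", "remain", "stay", "look",
              "come", "make", "say", "think", "know", "find", "want",
              "try", "put", "move", "return", "recover", "bother",
              "complain", "notice", "cut", "drive", "lift", "settle",
              "stretch", "strengthen", "ache", "limp", "garden", "shop",
              "exercise")

.lx_irregular_lemma <- c(
  am = "be", is = "be", are = "be", was = "be", were = "be", been = "be",
  being = "be", has = "have", had = "have", does = "do", did = "do",
  felt = "feel", feels = "feel", went = "go", got = "get", gave = "give",
  took = "take", kept = "keep", woke = "wake", wore = "wear", worn = "wear",
  hurts = "hurt", hurting = "hurt", sat = "sit", stood = "stand",
  ran = "run", swam = "swim", knelt = "kneel", came = "come", made = "make",
  said = "say", thought = "think", knew = "know", found = "find",
  ached = "ache", aches = "ache", knees = "knee", "ca" = "can",
  "wo" = "will", worse = "worse", better = "better")

# Vocabulary used to validate candidate lemmas when stripping suffixes.
.known_vocab <- function() {
  unique(c(.lx_noun, .lx_verb, .lx_adj, .lx_adv, "ache", "swell"))
}

.tag_one <- function(w) {
  lw <- tolower(w)
  if (grepl("^[[:punct:]]+$", w) && !grepl("[A-Za-z0-9]", w)) return("PUNCT")
  if (grepl("^[0-9]+(\\.[0-9]+)?$", w)) return("NUM")
  if (lw %in% c("not", "n't")) return("ADV")
  if (lw == "to") return("PART")
  if (lw %in% .lx_det) return("DET")
  if (lw %in% .lx_pron) return("PRON")
  if (lw %in% .lx_aux) return("AUX")
  if (lw %in% .lx_sconj) return("SCONJ")
  if (lw %in% .lx_cconj) return("CCONJ")
  if (lw %in% .lx_adp) return("ADP")
  if (lw %in% .lx_adv) return("ADV")
  if (lw %in% .lx_adj) return("ADJ")
  if (lw %in% .lx_noun) return("NOUN")
  if (lw %in% .lx_verb) return("VERB")
  # suffix heuristics
  if (grepl("ly$", lw)) return("ADV")
  base <- .strip_inflection(lw)
  if (base %in% .lx_verb) return("VERB")
  if (base %in% .lx_adj) return("ADJ")
  if (base %in% .lx_noun) return("NOUN")
  if (grepl("(ing|ed)$", lw)) return("VERB")
  if (grepl("(ness|tion|ment|ity|ism)s?$", lw)) return("NOUN")
  "NOUN"
}

# candidate base forms after removing a single inflectional suffix
.strip_inflection <- function(lw) {
  vocab <- .known_vocab()
  cand <- character(0)
  if (grepl("ies$", lw) && nchar(lw) > 4) cand <- c(cand, sub("ies$", "y", lw))
  if (grepl("ing$", lw) && nchar(lw) > 4) {
    s <- sub("ing$", "", lw)
    cand <- c(cand, s, paste0(s, "e"),
              if (nchar(s) > 2 && substr(s, nchar(s), nchar(s)) ==
                  substr(s, nchar(s) - 1, nchar(s) - 1))
                substr(s, 1, nchar(s) - 1))
  }
  if (grepl("ed$", lw) && nchar(lw) > 3) {
    s <- sub("ed$", "", lw)
    cand <- c(cand, s, paste0(s, "e"),
              if (nchar(s) > 2 && substr(s, nchar(s), nchar(s)) ==
                  substr(s, nchar(s) - 1, nchar(s) - 1))
                substr(s, 1, nchar(s) - 1))
  }
  if (grepl("es$", lw) && nchar(lw) > 3)
    cand <- c(cand, sub("es$", "", lw))
  if (grepl("s$", lw) && !grepl("ss$", lw) && nchar(lw) > 2)
    cand <- c(cand, sub("s$", "", lw))
  hit <- cand[cand %in% vocab]
  if (length(hit)) hit[[1L]] else lw
}

.lemma_one <- function(w, pos) {
  lw <- tolower(w)
  if (pos %in% c("PUNCT", "NUM")) return(lw)
  if (lw %in% names(.lx_irregular_lemma)) return(unname(.lx_irregular_lemma[[lw]]))
  if (pos %in% c("VERB", "NOUN", "AUX", "ADJ")) {
    base <- .strip_inflection(lw)
    if (base != lw) return(base)
    if (pos == "NOUN" && grepl("s$", lw) && !grepl("(ss|us|is)$", lw) &&
        nchar(lw) > 3)
      return(sub("s$", "", lw))
  }
  lw
}

#' Lemmatise a vector of word forms
#'
#' Applies the same lemmatisation rules the parser uses, guessing a
#' part-of-speech for each word in isolation. Used by the lexicon loaders so
#' that dictionary names and parsed text meet in the same lemma space.
#'
#' @param words character vector of word forms.
#' @return character vector of lemmas (lower-cased).
#' @export
lemmatize <- function(words) {
  vapply(words, function(w) .lemma_one(w, .tag_one(w)), character(1),
         USE.NAMES = FALSE)
}

# -- tokenisation -----------------------------------------------------------

# Returns data.frame(surface, start, end) with 0-based half-open offsets.
.tokenize_raw <- function(text) {
  if (is.na(text) || !nzchar(text))
    return(data.frame(surface = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  pat <- "[A-Za-z]+(?:[-'][A-Za-z]+)*|[0-9]+(?:\\.[0-9]+)?|[^A-Za-z0-9[:space:]]"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(data.frame(surface = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  surf <- regmatches(text, list(m))[[1]]
  out <- data.frame(surface = surf, start = starts,
                    end = starts + lens, stringsAsFactors = FALSE)
  # split clitic negation: "haven't" -> "have" + "n't"; "can't" -> "ca" + "n't"
  rows <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    s <- out$surface[i]
    if (grepl("n't$", s, ignore.case = TRUE) && nchar(s) > 3) {
      k <- nchar(s) - 3L
      rows[[i]] <- data.frame(
        surface = c(substr(s, 1, k), substr(s, k + 1, nchar(s))),
        start = c(out$start[i], out$start[i] + k),
        end = c(out$start[i] + k, out$end[i]), stringsAsFactors = FALSE)
    } else rows[[i]] <- out[i, ]
  }
  do.call(rbind, rows)
}

# -- dependency attachment --------------------------------------------------

# tokens: data.frame with surface, pos (1-based row order). Returns
# list(head = integer (1-based; 0 = ROOT), rel = character)
.attach_deps <- function(tokens) {
  n <- nrow(tokens)
  pos <- tokens$pos
  low <- tolower(tokens$surface)
  head <- rep(NA_integer_, n)
  rel <- rep(NA_character_, n)

  prev_word <- function(i) {           # previous non-ADV, non-DET token index
    j <- i - 1L
    while (j >= 1L && pos[j] %in% c("ADV", "DET")) j <- j - 1L
    if (j >= 1L) j else NA_integer_
  }
  nearest_before <- function(i, kinds, stop_at = 0L) {
    j <- i - 1L
    while (j > stop_at) {
      if (pos[j] %in% kinds) return(j)
      j <- j - 1L
    }
    NA_integer_
  }
  nearest_after <- function(i, kinds, allow = NULL, limit = n) {
    j <- i + 1L
    while (j <= limit) {
      if (pos[j] %in% kinds) return(j)
      if (!is.null(allow) && !(pos[j] %in% allow)) return(NA_integer_)
      j <- j + 1L
    }
    NA_integer_
  }

  # root: first VERB not introduced by SCONJ/ADP/PART, else first AUX,
  # else first NOUN, else first non-PUNCT token, else token 1
  root <- NA_integer_
  for (i in seq_len(n)) {
    if (pos[i] == "VERB") {
      pw <- prev_word(i)
      if (is.na(pw) || !(pos[pw] %in% c("SCONJ", "ADP", "PART", "AUX")) ||
          (!is.na(pw) && pos[pw] == "AUX")) {
        if (is.na(pw) || !(pos[pw] %in% c("SCONJ", "ADP", "PART"))) {
          root <- i; break
        }
      }
    }
  }
  if (is.na(root)) root <- which(pos == "AUX")[1]
  if (is.na(root)) root <- which(pos == "NOUN")[1]
  if (is.na(root)) root <- which(pos != "PUNCT")[1]
  if (is.na(root)) root <- 1L
  head[root] <- 0L
  rel[root] <- "root"

  subj_taken <- FALSE
  for (i in seq_len(n)) {
    if (i == root) next
    p <- pos[i]
    if (p == "PUNCT") { head[i] <- root; rel[i] <- "punct"; next }
    if (p == "DET") {
      j <- nearest_after(i, "NOUN",
                         allow = c("ADJ", "ADV", "ADP", "DET", "NUM"))
      if (is.na(j)) j <- nearest_before(i, "NOUN")
      if (is.na(j)) j <- root
      head[i] <- j; rel[i] <- "det"; next
    }
    if (p == "NUM") {
      j <- nearest_after(i, "NOUN", allow = c("ADJ", "NUM"))
      if (is.na(j)) j <- root
      head[i] <- j; rel[i] <- "nummod"; next
    }
    if (p == "ADJ") {
      j <- nearest_after(i, "NOUN",
                         allow = c("ADJ", "ADV", "CCONJ", "NUM"))
      if (!is.na(j)) { head[i] <- j; rel[i] <- "amod"; next }
      jb <- nearest_before(i, c("AUX", "VERB"))
      if (!is.na(jb) && (jb == root || pos[jb] == "VERB")) {
        head[i] <- jb; rel[i] <- "attr"; next
      }
      jb <- nearest_before(i, "NOUN")
      if (!is.na(jb)) { head[i] <- jb; rel[i] <- "amod"; next }
      head[i] <- root; rel[i] <- "dep"; next
    }
    if (p == "ADV") {
      if (low[i] %in% c("not", "n't")) {
        j <- nearest_before(i, c("AUX", "VERB"))
        if (is.na(j)) j <- nearest_after(i, c("ADJ", "VERB", "AUX", "NOUN"),
                                         allow = c("ADV", "DET", "PART"))
        if (is.na(j)) j <- root
        head[i] <- j; rel[i] <- "neg"; next
      }
      j <- nearest_after(i, c("ADJ", "VERB"), allow = c("ADV", "DET"),
                         limit = min(n, i + 3L))
      if (is.na(j)) j <- nearest_before(i, c("VERB", "AUX"))
      if (is.na(j)) j <- root
      head[i] <- j; rel[i] <- "advmod"; next
    }
    if (p == "AUX") {
      j <- nearest_after(i, "VERB",
                         allow = c("ADV", "AUX", "PART", "PRON", "DET"))
      if (!is.na(j)) { head[i] <- j; rel[i] <- "aux"; next }
      j <- nearest_after(i, "ADJ", allow = c("ADV", "DET", "NUM"))
      if (!is.na(j) && i != root) { head[i] <- j; rel[i] <- "cop"; next }
      head[i] <- root; rel[i] <- "aux"; next
    }
    if (p == "PART") {
      j <- nearest_after(i, "VERB", allow = c("ADV", "AUX"))
      if (is.na(j)) j <- root
      head[i] <- j; rel[i] <- "mark"; next
    }
    if (p == "SCONJ") {
      j <- nearest_after(i, c("VERB", "NOUN", "AUX", "PRON"),
                         allow = c("ADV", "DET", "ADJ"))
      if (is.na(j)) j <- root
      head[i] <- j; rel[i] <- "mark"; next
    }
    if (p == "CCONJ") {
      j <- nearest_after(i, c("VERB", "NOUN", "ADJ", "AUX"))
      if (is.na(j)) j <- root
      head[i] <- j; rel[i] <- "cc"; next
    }
    if (p == "ADP") {
      j <- nearest_after(i, "NOUN", allow = c("DET", "ADJ", "ADV", "NUM"))
      if (is.na(j)) { head[i] <- root; rel[i] <- "case"; next }
      head[i] <- j; rel[i] <- "case"; next
    }
    if (p %in% c("NOUN", "PRON")) {
      # compound run: noun immediately followed by noun(s)
      if (p == "NOUN" && i < n && pos[i + 1L] == "NOUN") {
        j <- i + 1L
        while (j < n && pos[j + 1L] == "NOUN") j <- j + 1L
        head[i] <- j; rel[i] <- "compound"; next
      }
      if (!subj_taken && i < root && pos[root] %in% c("VERB", "AUX")) {
        # nearest pre-root noun/pronoun becomes the subject
        pre <- which(seq_len(n) < root & pos %in% c("NOUN", "PRON") &
                     is.na(head))
        if (length(pre) && i == max(pre)) {
          head[i] <- root; rel[i] <- "nsubj"; subj_taken <- TRUE; next
        }
      }
      jb <- nearest_before(i, c("VERB", "AUX"))
      if (!is.na(jb)) {
        has_case <- any(pos[seq(jb + 1L, i - 1L)] == "ADP") &&
          (i - jb) > 1L
        head[i] <- jb; rel[i] <- if (isTRUE(has_case)) "obl" else "obj"
        next
      }
      jb <- nearest_before(i, "NOUN")
      if (!is.na(jb) && jb != i) { head[i] <- jb; rel[i] <- "nmod"; next }
      head[i] <- root; rel[i] <- "dep"; next
    }
    if (p == "VERB") {
      pw <- prev_word(i)
      if (!is.na(pw) && pos[pw] == "PART") {
        jb <- nearest_before(i, c("VERB", "ADJ", "AUX"))
        if (!is.na(jb) && jb != i) { head[i] <- jb; rel[i] <- "xcomp"; next }
      }
      if (!is.na(pw) && pos[pw] %in% c("SCONJ", "ADP")) {
        head[i] <- root; rel[i] <- "advcl"; next
      }
      head[i] <- root; rel[i] <- "conj"; next
    }
    head[i] <- root; rel[i] <- "dep"
  }

  # safety: break any cycle / unreachable chain by re-attaching to root
  reach <- function(i) {
    seen <- integer(0)
    while (i != 0L) {
      if (i %in% seen) return(FALSE)
      seen <- c(seen, i)
      i <- head[i]
    }
    TRUE
  }
  for (i in seq_len(n)) {
    if (i != root && !reach(i)) { head[i] <- root; rel[i] <- "dep" }
  }
  list(head = head, rel = rel, root = root)
}

# -- public API -------------------------------------------------------------

#' Parser backend registry
#'
#' The pre-processing stage is an adapter: a backend is a function taking a
#' raw string and returning a ParsedDocument. The shipped default is the
#' package's rule-based parser; an alternative backend (e.g. a binding to a
#' statistical parser) can be registered and selected by name.
#'
#' @param name backend name; `"rulebased"` is always available.
#' @param fun for `register_parser_backend()`, a `function(text, id)`
#'   returning a ParsedDocument.
#' @return `parser_backend()` returns the backend function invisibly.
#' @export
parser_backend <- local({
  backends <- new.env(parent = emptyenv())
  function(name = "rulebased", fun = NULL) {
    if (!is.null(fun)) {
      assign(name, fun, envir = backends)
      return(invisible(fun))
    }
    if (name == "rulebased") return(.parse_rulebased)
    if (!exists(name, envir = backends))
      stop("parser backend not available: ", name, call. = FALSE)
    get(name, envir = backends)
  }
})

#' Register an alternative parser backend
#' @rdname parser_backend
#' @export
register_parser_backend <- function(name, fun) parser_backend(name, fun)

.parse_rulebased <- function(text, id = NA_character_) {
  toks <- .tokenize_raw(text)
  sentences <- list()
  if (nrow(toks)) {
    toks$pos <- vapply(toks$surface, .tag_one, character(1), USE.NAMES = FALSE)
    toks$lemma <- mapply(.lemma_one, toks$surface, toks$pos, USE.NAMES = FALSE)
    # sentence boundaries after ./!/? runs
    is_end <- toks$surface %in% c(".", "!", "?")
    bound <- which(is_end & c(!is_end[-1], TRUE))
    sent_id <- cumsum(c(0L, head(seq_len(nrow(toks)), -1) %in% bound)) + 1L
    for (s in unique(sent_id)) {
      st <- toks[sent_id == s, , drop = FALSE]
      if (!nrow(st)) next
      dep <- .attach_deps(st)
      tokens <- data.frame(
        index = seq_len(nrow(st)) - 1L,
        surface = st$surface, lemma = st$lemma, pos = st$pos,
        start = st$start, end = st$end, stringsAsFactors = FALSE)
      edges <- data.frame(
        dependent = tokens$index,
        head = ifelse(dep$head == 0L, -1L, dep$head - 1L),
        relation = dep$rel, stringsAsFactors = FALSE)
      sentences[[length(sentences) + 1L]] <-
        list(tokens = tokens, edges = edges)
    }
  }
  structure(list(id = id, text = text, sentences = sentences),
            class = "parsed_document")
}

#' Parse a free-text questionnaire response
#'
#' Splits a raw response into sentences and tokens, assigns coarse
#' part-of-speech tags and lemmas, and attaches every token to a head under a
#' universal-dependency-style relation, producing one dependency tree per
#' sentence. Token character offsets are 0-based and half-open, so
#' `substr(text, start + 1, end)` recovers each surface form. Text is not
#' lower-cased at parse time; downstream matching is case-insensitive over
#' lemmas.
#'
#' @param text a single UTF-8 string (may be empty).
#' @param id optional response identifier carried on the document.
#' @param backend parser backend name (see [parser_backend()]).
#' @return an object of class `parsed_document`: a list with elements `id`,
#'   `text` and `sentences`; each sentence is a list with a `tokens` data
#'   frame (`index`, `surface`, `lemma`, `pos`, `start`, `end`) and an
#'   `edges` data frame (`dependent`, `head`, `relation`), where `head = -1`
#'   marks the sentence root. Indices are 0-based.
#' @examples
#' doc <- parse_response("Intermittent pain around the joint.")
#' doc$sentences[[1]]$tokens
#' @export
parse_response <- function(text, id = NA_character_, backend = "rulebased") {
  stopifnot(is.character(text), length(text) == 1)
  parser_backend(backend)(text, id)
}

#' @export
print.parsed_document <- function(x, ...) {
  cat("<parsed_document>", if (!is.na(x$id)) paste0(" id=", x$id), " ",
      length(x$sentences), " sentence(s)\n", sep = "")
  invisible(x)
}

#' CoNLL-U-style dump of a parsed document
#'
#' One token per line (`index+1`, surface, lemma, POS, head, relation), a
#' blank line between sentences. Intended for debugging parser behaviour.
#'
#' @param doc a `parsed_document`.
#' @return a single string.
#' @export
as_conllu <- function(doc) {
  stopifnot(inherits(doc, "parsed_document"))
  blocks <- vapply(doc$sentences, function(s) {
    paste(sprintf("%d\t%s\t%s\t%s\t%d\t%s",
                  s$tokens$index + 1L, s$tokens$surface, s$tokens$lemma,
                  s$tokens$pos, s$edges$head + 1L, s$edges$relation),
          collapse = "\n")
  }, character(1))
  paste(blocks, collapse = "\n\n")
}
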