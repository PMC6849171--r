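# ---------------------------------------------------------------------------
# Bundled default resources. The mini-lexicon stands where a full clinical
# terminology would in production: a loader hook (load_lexicon on any TSV
# with the same columns) allows substituting a larger terminology without
# code changes. Loaded objects are cached per session.
# ---------------------------------------------------------------------------

.res_cache <- new.env(parent = emptyenv())

.extdata <- function(...) {
  p <- system.file("extdata", ..., package = "likertext")
  if (!nzchar(p)) stop("bundled resource not found: ",
                       paste(c(...), collapse = "/"), call. = FALSE)
  p
}

#' Bundled default resources
#'
#' `default_mini_lexicon()` loads the bundled concept mini-lexicon (knee
#' conditions, procedures, anatomy, treatments, activities and symptoms,
#' including layman synonyms such as *physio* for *physiotherapy*).
#' `default_polarity_lexicon()` loads the graded sentiment polarity lexicon
#' and `default_graded_lexicons()` the per-aspect severity modifier
#' lexicons (pain, stiffness, symptoms, confidence, limitation).
#'
#' @return see the individual loaders.
#' @export
default_mini_lexicon <- function() {
  if (is.null(.res_cache$minilex))
    .res_cache$minilex <- load_lexicon(.extdata("minilexicon.tsv"))
  .res_cache$minilex
}

#' @rdname default_mini_lexicon
#' @export
default_polarity_lexicon <- function() {
  if (is.null(.res_cache$polarity))
    .res_cache$polarity <- load_polarity_lexicon(.extdata("polarity.tsv"))
  .res_cache$polarity
}

#' @rdname default_mini_lexicon
#' @export
default_graded_lexicons <- function() {
  if (is.null(.res_cache$graded))
    .res_cache$graded <- load_graded_lexicons(.extdata("graded"))
  .res_cache$graded
}
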