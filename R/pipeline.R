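# ---------------------------------------------------------------------------
# End-to-end orchestration: the feature-extraction subsystem (pre-process ->
# sentiment -> NER -> lexicon lookup, combined into per-question feature
# vectors) and the classification subsystem (one ordinal classifier per
# question Q3-Q10, Q10 served by the sentiment-only path), with run
# manifests for reproducibility.
# ---------------------------------------------------------------------------

.question_topics <- c(Q1 = "condition", Q2 = "treatment", Q3 = "changes",
                      Q4 = "confidence", Q5 = "stiffness", Q6 = "pain",
                      Q7 = "other symptoms", Q8 = "daily activities",
                      Q9 = "other activities", Q10 = "other comments")

#' Load (or build) a pipeline configuration
#'
#' Reads a YAML configuration naming resource files, per-question classifier
#' methods, the cross-validation plan, the negation rule subset and the
#' sentiment neutral band; `path = NULL` loads the bundled default. Relative
#' resource paths are resolved against the YAML file's directory, falling
#' back to the bundled resources. All referenced paths are validated at load
#' time and the named resources are loaded eagerly.
#'
#' @param path YAML file, or NULL for the bundled default configuration.
#' @return list of class `pipeline_config` with elements `questions`, `cv`,
#'   `resources` (loaded), `negation_rules`, `neutral_band`, `source`.
#' @export
pipeline_config <- function(path = NULL) {
  src <- if (is.null(path)) .extdata("config.yaml") else path
  cfg <- yaml::read_yaml(src)
  base <- dirname(src)
  resolve <- function(p) {
    if (file.exists(p)) return(p)
    cand <- file.path(base, p)
    if (file.exists(cand)) return(cand)
    cand <- system.file("extdata", p, package = "likertext")
    if (nzchar(cand) && file.exists(cand)) return(cand)
    stop("configured resource not found: ", p, call. = FALSE)
  }
  minilex <- load_lexicon(resolve(cfg$resources$minilexicon))
  polarity <- load_polarity_lexicon(resolve(cfg$resources$polarity))
  graded <- load_graded_lexicons(resolve(cfg$resources$graded_dir))
  qcfg <- cfg$questions
  need <- paste0("Q", 3:10)
  missing <- setdiff(need, names(qcfg))
  if (length(missing))
    stop("configuration lacks classifier specs for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  specs <- lapply(names(qcfg), function(q) {
    qc <- qcfg[[q]]
    if (identical(qc$method, "sentiment")) return("sentiment")
    classifier_spec(qc$method, hyper = qc$hyper %||% list(),
                    ordinal = qc$ordinal %||% TRUE,
                    seed = qc$seed %||% cfg$cv$seed %||% 42L)
  })
  names(specs) <- names(qcfg)
  structure(list(
    questions = specs,
    cv = list(k = cfg$cv$k %||% 10L,
              stratified = cfg$cv$stratified %||% TRUE,
              seed = cfg$cv$seed %||% 42L),
    resources = list(minilex = minilex, polarity = polarity, graded = graded),
    resource_paths = vapply(c(minilexicon = cfg$resources$minilexicon,
                              polarity = cfg$resources$polarity),
                            resolve, character(1)),
    negation_rules = cfg$negation_rules %||% negation_rules(),
    neutral_band = cfg$neutral_band %||% 0.1,
    source = src), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> from ", x$source, "\n", sep = "")
  for (q in names(x$questions)) {
    s <- x$questions[[q]]
    cat("  ", q, ": ",
        if (identical(s, "sentiment")) "sentiment-only" else s$method,
        "\n", sep = "")
  }
  invisible(x)
}

.run_manifest <- function(config, extra = list()) {
  cfgmd5 <- as.character(tools::md5sum(config$source))
  res <- as.character(tools::md5sum(config$resource_paths))
  c(list(config = config$source, config_md5 = cfgmd5,
         resource_md5 = stats::setNames(res, names(config$resource_paths)),
         cv_seed = config$cv$seed,
         package_version = as.character(utils::packageVersion("likertext")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    extra)
}

#' Run the feature-extraction subsystem over a response file
#'
#' Reads JSON-lines responses (`participant_id`, `timestamp`, `question_id`,
#' `text`, optional `response_id`/`label`), answers Q1-Q2 with normalised
#' concept mentions and builds one feature matrix per question Q3-Q10 (the
#' Q10 matrix carries the sentiment score and the sentiment-path prediction).
#' Unparseable lines are logged, skipped and counted in the manifest.
#' Responses with empty text are processed (empty feature context) but
#' flagged in the manifest.
#'
#' @param responses path to a JSON-lines file, or an equivalent data frame.
#' @param config a `pipeline_config`.
#' @param out_dir optional output directory: writes `features_Q*.csv`,
#'   `answers_open.json` and `manifest.json`.
#' @return list with `features` (named list of data frames), `answers`
#'   (Q1/Q2 mention tables), `manifest`.
#' @export
run_extract <- function(responses, config = pipeline_config(),
                        out_dir = NULL) {
  if (is.character(responses)) responses <- read_responses_jsonl(responses)
  skipped <- attr(responses, "skipped") %||% 0L
  if (is.null(responses$response_id))
    responses$response_id <- sprintf("R%05d", seq_len(nrow(responses)))
  resources <- list(minilex = config$resources$minilex,
                    graded = config$resources$graded,
                    polarity = config$resources$polarity)
  schemas <- default_schemas()
  empty_flagged <- sum(!nzchar(trimws(responses$text)))

  answers <- list()
  for (q in c("Q1", "Q2")) {
    sub <- responses[responses$question_id == q, , drop = FALSE]
    if (!nrow(sub)) next
    ans <- lapply(seq_len(nrow(sub)), function(i) {
      doc <- parse_response(sub$text[i], id = sub$response_id[i])
      answer_open_question(doc, resources$minilex, q)
    })
    answers[[q]] <- do.call(rbind, ans)
  }

  features <- list()
  for (q in paste0("Q", 3:10)) {
    sub <- responses[responses$question_id == q, , drop = FALSE]
    if (!nrow(sub)) { features[[q]] <- NULL; next }
    if (q == "Q10") {
      rows <- lapply(sub$text, function(tx) {
        doc <- parse_response(tx)
        sp <- score_sentiment(doc, lexicon = resources$polarity,
                              neutral_band = config$neutral_band,
                              rules = config$negation_rules)
        data.frame(sentiment_score = if (nrow(sp)) mean(sp$score) else 0,
                   sentiment_pred = predict_sentiment_label(
                     doc, polarity = resources$polarity,
                     neutral_band = config$neutral_band))
      })
      fm <- do.call(rbind, rows)
    } else {
      fm <- feature_matrix(sub$text, q, schema = schemas[[q]],
                           resources = resources)
    }
    fm <- cbind(response_id = sub$response_id, fm,
                stringsAsFactors = FALSE)
    if (!is.null(sub$label) && !all(is.na(sub$label)))
      fm$label <- as.integer(sub$label)
    features[[q]] <- fm
  }

  manifest <- .run_manifest(config, list(
    n_responses = nrow(responses), n_skipped_lines = skipped,
    n_empty_flagged = empty_flagged,
    questions = names(features)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (q in names(features))
      utils::write.csv(features[[q]],
                       file.path(out_dir, paste0("features_", q, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(answers, file.path(out_dir, "answers_open.json"),
                         dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(features = features, answers = answers, manifest = manifest)
}

#' Evaluate per-question classifiers by cross-validation
#'
#' For each question Q3-Q9, runs the configured classifier under k-fold
#' cross-validation on its feature matrix (gold labels required) and pools
#' test-fold predictions into a confusion matrix; Q10 is scored by the
#' sentiment-only path. Reports support-weighted precision/recall/F (as
#' percentages) per question plus mean / sample sd / min / max across
#' questions.
#'
#' @param features named list of feature data frames with `label` columns
#'   (from [run_extract()]).
#' @param config a `pipeline_config`.
#' @param out_dir optional: writes `report.csv` (per-question table),
#'   `report.json` (full precision) and `confusions.json`.
#' @return list of class `pipeline_report`: `table` (per-question data
#'   frame with Question, Topic, Classes, Method, Features, P, R, F),
#'   `summary` (a `summary_report`), `confusions`.
#' @export
run_evaluate <- function(features, config = pipeline_config(),
                         out_dir = NULL) {
  need <- paste0("Q", 3:10)
  missing <- setdiff(need, names(features))
  if (length(missing))
    stop("missing feature matrices for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  schemas <- default_schemas()
  rows <- list(); confusions <- list()
  for (q in need) {
    fm <- features[[q]]
    if (is.null(fm$label) || all(is.na(fm$label)))
      stop("gold labels required for ", q, call. = FALSE)
    spec <- config$questions[[q]]
    if (identical(spec, "sentiment")) {
      cm <- confusion_matrix(fm$label, fm$sentiment_pred,
                             classes = as.character(1:3))
      method <- "sentiment polarity"
      nfeat <- NA_integer_
    } else {
      data <- fm[, setdiff(names(fm), c("response_id", "sentiment_pred")),
                 drop = FALSE]
      cm <- cross_validate(data, spec, k = config$cv$k,
                           stratified = config$cv$stratified,
                           seed = config$cv$seed)
      method <- spec$method
      nfeat <- schema_length(schemas[[q]])
    }
    wm <- weighted_metrics(cm)
    confusions[[q]] <- cm
    rows[[q]] <- data.frame(
      question = q, topic = unname(.question_topics[q]), classes = 3L,
      method = method, features = nfeat,
      precision = 100 * wm[["precision"]], recall = 100 * wm[["recall"]],
      f = 100 * wm[["f"]], stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  summary <- summarize_questions(table)
  report <- structure(list(table = table, summary = summary,
                           confusions = confusions),
                      class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- table
    out[c("precision", "recall", "f")] <-
      lapply(out[c("precision", "recall", "f")], round_half_up, 1)
    names(out) <- c("Question", "Topic", "Classes", "Method", "Features",
                    "P (%)", "R (%)", "F (%)")
    utils::write.csv(out, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(table = table, stats = cbind(metric = rownames(summary$stats),
                                        summary$stats)),
      file.path(out_dir, "report.json"), dataframe = "rows",
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      lapply(confusions, function(m) as.data.frame(unclass(m))),
      file.path(out_dir, "confusions.json"), dataframe = "rows",
      auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  out <- x$table
  out[c("precision", "recall", "f")] <-
    lapply(out[c("precision", "recall", "f")], round_half_up, 1)
  print(out, row.names = FALSE)
  cat("\n")
  print(x$summary)
  invisible(x)
}
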