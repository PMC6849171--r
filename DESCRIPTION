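Package: likertext
Title: Mining Open-Ended Patient Questionnaire Responses onto Likert Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated analysis of free-text answers to open-ended
    patient-reported outcome questionnaires about knee health. Responses are
    parsed into tokens, part-of-speech tags and dependency relations by a
    compact rule-based parser; named entities are recognised against a
    concept-normalising mini-lexicon with UMLS-like structure; explicit
    syntactic negation is detected from dependency graphs; graded modifier
    lexicons and sentence-level sentiment polarity provide severity evidence.
    Per-question feature vectors feed ordinal classifiers (with an
    ordering-aware binary decomposition wrapper) evaluated by 10-fold
    cross-validation, weighted precision/recall/F-measure, and Cohen's and
    weighted kappa. A seeded synthetic-response generator makes every stage
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    e1071,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
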