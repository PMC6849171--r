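---
title: "Mining open-ended questionnaire responses onto ordinal scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining open-ended questionnaire responses onto ordinal scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(likertext)
```

## The problem

Open-ended patient-reported outcome questionnaires elicit short free-text
answers ("No pain when sitting, some pain when walking upstairs and
walking long distances.") that clinicians would otherwise read and score
by hand. `likertext` maps such answers onto the instruments' own scales:
named-entity answers for the two open questions (current condition,
current treatment) and a 3-point ordinal label for the remaining eight
(e.g. *none < some < severe* for stiffness, pain and other symptoms;
*worse < same < better* for change; *not at all < somewhat < a lot* for
activity limitation; *negative < neutral < positive* for free comments).

The system has two subsystems. Feature extraction runs four modules over
each response — linguistic pre-processing, sentiment analysis, named
entity recognition and graded-lexicon lookup — and combines their outputs
into per-question feature vectors. Classification trains one ordinal
classifier per question and evaluates it under 10-fold cross-validation.

## Linguistic pre-processing

Every downstream stage consumes one contract: sentences of tokens with
coarse POS tags, lemmas, character offsets (0-based, half-open) and a
dependency tree (one head per token, labelled relations). The default
backend is a compact deterministic rule-based parser written for this
domain: closed-class word lists, a domain content vocabulary, suffix
heuristics, and a small set of attachment rules (determiners and
adjectives to the following noun, negation adverbs to the nearest verb,
subjects to the root, a cycle-breaking safety pass that guarantees a
tree). It is exposed through an adapter (`parser_backend()`) so a
statistical parser can be substituted without touching any other module;
parser-version-specific attachment differences are absorbed by that
contract. Text is never lower-cased at parse time — offsets and
case-sensitive surface forms are preserved, and matching is
case-insensitive over lemmas instead.

The rule-based backend is intentionally small. It is accurate on the
short first-person symptom narratives this package targets (and on every
worked example in the test suite), but it is not a general-purpose parser;
long multi-clause sentences outside the domain vocabulary will parse as
flatter, noisier trees.

## Concept recognition and normalisation

NER is dictionary-based against a mini-lexicon with the structure of a
full clinical terminology: rows of (concept id, name, semantic type),
synonyms sharing one id. Matching is greedy leftmost-longest over lemmas;
nested and overlapping mentions are never emitted (mirroring the
maximal-extent, non-nested annotation convention), and ties between
equal-length candidates fall back to lexicon file order so results are
deterministic. The bundled lexicon (~140 names) covers knee conditions,
anatomy, procedures, treatments, activities and symptoms, including
layman synonyms (*physio*) precisely because their absence is a known
failure mode of stock terminologies; knee-rehabilitation-specific
exercises (e.g. *hamstring curls*) are deliberately absent to preserve
that documented gap. `load_lexicon()` accepts any TSV with the same
columns, so a full terminology can be substituted without code changes.

Q1 is answered by mentions of conditions, surgical procedures and
anatomy; Q2 by therapeutic procedures, drugs, devices and
exercise-activity concepts. The four treatment type codes are this
package's choice — the source architecture never enumerates Q2's types,
only that its answers span four classes.

## Negation

Only explicit syntactic negation is handled. Four rules run over the
dependency tree to a fixpoint:

* **R1** — a negation adverb (*not*, *n't*) marks its head.
* **R2** — a negative determiner (*no*, *neither*, *none*) marks its
  nominal head.
* **R3** — propagation along the verbal backbone: a marked auxiliary or
  copula passes the mark to the verb or predicate it supports, a marked
  copular verb to its subject and predicate, and a marked verb to its
  direct object. This is what lets "The pain is not constant." negate
  both *constant* and *pain*, and "I have not had any pain" reach the
  *pain* mention.
* **R4** — a marked nominal cancels its adjectival modifiers, so "no
  constant pain" also cancels *constant*.

R3 is deliberately broader than a minimal copula rule: without the
aux-chain and object steps, negation expressed through auxiliaries
("haven't had any pain") never reaches the symptom mention it plainly
scopes over. Implicit, pragmatic negation (the verb *to ease*
effectively negating *pain*) is out of scope; the sentiment scorer
partially covers such cases. Coordinated cues ("neither … nor") are
handled by R2 only through the *neither* determiner — scope across the
coordination is a known simplification.

## Graded lexicons and sentiment

Each symptom aspect (pain, stiffness, other symptoms, confidence,
limitation) has a graded modifier lexicon mapping modifiers to the
3-point scheme (1 none-level, 2 some, 3 severe): *mild* < *severe*,
*slight* < *bad*, *sharp* → 3, absence modifiers such as *pain-free* → 1.
`lookup_grade()` takes the maximum grade over a headword's adjectival,
adverbial and determiner-adjacent modifiers and its copular predicates,
skipping any modifier cancelled by negation. "Some" is graded 2: the
middle class of the severity scheme is literally *some*, and determiner
grading is what carries sentences like "Some pain when walking
upstairs."

Candidate modifiers for new aspects can be induced from any plain-text
corpus with the PMI collocation extractor
(`PMI(c,t) = log2(N·f(c,t)/(f(c)·f(t)))`, `N` the corpus token count,
joint counts within a ±5-token window inside sentences, adjectives only
by default — standard corpus-linguistics settings; the base, window and
POS filter are all arguments). Grading the resulting shortlist is a
manual step that needs no medical expertise. A word is not counted as its
own collocate.

Sentiment is a pluggable scorer; the default sums a graded polarity
lexicon over a sentence's lemmas, flips the sign of negated tokens, and
averages, yielding a score in [−1, 1] with a neutral band of |score| <
0.1 (configurable). The cited production systems use a neural sentence
model here; the scorer interface (`sentiment_scorer()`) is the seam where
one would plug it in.

## Feature schemas

Only the per-question feature *counts* of the original system are public
(Q3: 8, Q4: 8, Q5: 8, Q6: 10, Q7: 5, Q8: 14, Q9: 14); the identity of
each feature is not. The shipped schemas are therefore this package's own
construction honouring those dimensionalities, built from seven descriptor
types (`ner-count`, `ner-negated-count`, `grade-max`, `negation-count`,
`sentiment-score`, one-hot `sentiment-label`, `keyword-flag`) and marked
non-canonical in the configuration. Multi-sentence responses sum counts,
take the maximum grade, average the sentiment score and majority-vote the
label (ties neutral). A missing grade is encoded as 0.

Q10 bypasses feature extraction entirely: the prediction is the majority
polarity label over the *polar* sentences of the response (positive /
negative ties and all-neutral responses fall back to neutral), mapped
onto 1/2/3. Restricting the vote to polar sentences was a design choice:
responses routinely contain an incidental neutral sentence ("I will
mention it at my next appointment."), and letting it tie out an expressed
opinion misclassifies every two-sentence opinionated response.

## Ordinal classification

The method roster mirrors the original workbench: naive Bayes, complement
naive Bayes, three pruned-decision-tree variants and a random forest.
Trees and forests are backed by `rpart` and `randomForest`; the
best-first and reduced-error-pruning variants share one pruned-CART
implementation distinguished by pruning-strategy flags, since their
splitting subtleties are not this system's contribution — method names
are preserved for reporting fidelity. Complement naive Bayes is
implemented in-package (complement frequency estimates, add-one
smoothing, per-class weight normalisation, class-prior term). Naive
Bayes is implemented in-package too, for a concrete numerical reason:
keyword-flag features are routinely constant within a class, and a
textbook Gaussian fit then produces degenerate likelihood ratios. The
default treatment is a per-class, per-feature Gaussian *kernel* density
(Silverman-style bandwidth with a floor); a parametric Gaussian with
variance smoothing is available via `hyper = list(density = "gaussian")`.

The ordering-aware wrapper decomposes the k-class ordinal problem into
k−1 binary threshold problems `Pr(y > t)`, recombined as
`P(1) = 1 − Pr(y>1)`, `P(j) = Pr(y>j−1) − Pr(y>j)`, `P(k) = Pr(y>k−1)`,
with negative intermediate masses clipped to 0, renormalisation, and
ties resolved toward the lower class. For the tree family the threshold
models are trained on the pooled binary labels, as in the original
formulation. For naive Bayes they are not: fitting a naive *product* of
feature densities to the pooled "y ≤ t" class multiplies the pool
proportion into every feature's likelihood — with several redundant
features this systematically biases the upper threshold and shows up as
class-2 → class-3 errors. The correct generative treatment of a pooled
ordinal class is a *mixture* of the per-class components, so the naive
Bayes threshold models compute `Pr(y > t | x) = Σ_{c>t} P(c | x)` from
one set of per-class fits. With k = 2 both formulations coincide with
the plain binary classifier.

Complement naive Bayes deserves a caveat: it is a one-sided
evidence model designed for high-dimensional count vectors. On
low-dimensional features where classes differ in the *magnitude* of one
graded value it cannot express "absence of evidence" (a zero vector
always falls back to the prior) and underperforms — consistent with the
pain-severity question being the weakest result in the original report.
It is kept in the roster for fidelity and is exercised on count-style
data in the tests.

Cross-validation is stratified when every class has at least k members
(plain random with a warning otherwise); test-fold predictions are
pooled into a single confusion matrix. All randomness flows through
recorded seeds (spec seed for training, plan seed for folds; defaults
42), and trained models serialise with a JSON sidecar recording method,
seed and the feature-schema fingerprint, which prediction verifies.

## Evaluation conventions

Per-class precision and recall use the standard TP ratios with 0/0
reported as 0 and flagged degenerate; F is 0 when P + R = 0. Weighted
averages weight per-class values by actual-class support, and the
weighted F is the weighted mean of per-class F values — deliberately not
the harmonic mean of the weighted P and R, which does not reproduce the
original per-question figures. Summary statistics across questions use
the sample (n−1) standard deviation; reported percentages round half-up
to one decimal. Cohen's kappa uses the marginal-product expected
agreement; weighted kappa is computed in the disagreement form
`1 − Σw'o/Σw'e` with `w' = 1 − w`, linear agreement weights by default
(quadratic or identity by argument), and identity weights reduce it to
the unweighted kappa exactly.

## The synthetic corpus: what it does and does not show

Real responses to this kind of questionnaire are private, so the
generator is a first-class module, not a fixture. Templates per question
encode exactly the signal the features are designed to capture: class-3
responses draw grade-3 modifiers, class-1 responses draw negated symptom
mentions (with probability `negation_rate`, default 0.5) or absence
phrasing, class-2 sits between; NE slots are filled from the
mini-lexicon so NER recall on the generated gold is exact at zero noise.
Noise operators apply, each with the per-response probability `noise`: a
character typo outside slot spans, a synonym swap within a concept, and
a distractor clause. Defaults are the study conditions used throughout:
300 responses per question, balanced classes, 5% noise, 1–2 sentences
per response; the recovery analyses in the tests and the acceptance
script run at exactly those sizes (the noise-degradation comparison runs
at 100 responses per question over five seeds, which is ample for a mean
comparison).

Passing on this corpus shows the pipeline recovers labels whose
generating signal its features measure — template-level severity,
negation and entity structure, under lexical perturbation. It does not
show robustness to paraphrase diversity, spelling variation beyond
single typos, implicit negation, or the class-imbalance and
inter-annotator ambiguity of real clinical text; near-ceiling synthetic
scores are a correctness check on the machinery, not a clinical
performance claim.

## Numerical and degenerate-input choices

Empty text parses to zero sentences and classifies as neutral on the
sentiment path; empty mandatory answers are processed and flagged in the
run manifest. Unknown concept names normalise to `NA` rather than
erroring. Unparseable response lines are skipped, logged and counted.
Kappa is `NA` with a warning when expected agreement is 1. Equal-length
NER match ties use lexicon file order; ordinal prediction ties take the
lower class; the sentiment majority vote ties to neutral. The kernel NB
bandwidth floor (5% of the global feature scale, minimum 1e-3) and the
Gaussian variance floor exist so constant features cannot dominate.

## Known limitations

The rule-based parser is domain-tuned, not general. Negation scope over
coordination is approximate. Grades attach to single-word modifiers only
(no multiword grading). The 24-lexicon inventory of the original system
is represented by five aspect lexicons; the remainder of that inventory
was never enumerated publicly. Feature identities behind the published
per-question counts are reconstructed, not canonical. Complement naive
Bayes underperforms on magnitude-style features by construction. The
automatic induction of grades by distributional semantics is out of
scope — the collocation extractor produces candidates, a human grades
them.
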