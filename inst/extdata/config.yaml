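# Default pipeline configuration.
#
# The per-question feature schemas shipped in code match the published
# per-question feature counts, but the identity of each feature is this
# package's construction (non-canonical); swap schemas/resources here.
resources:
  minilexicon: minilexicon.tsv
  polarity: polarity.tsv
  graded_dir: graded
questions:
  Q3: { method: naive-bayes, ordinal: true }
  Q4: { method: best-first-tree, ordinal: true }
  Q5: { method: reduced-error-pruning-tree, ordinal: true }
  Q6: { method: complement-naive-bayes, ordinal: true }
  Q7: { method: naive-bayes, ordinal: true }
  Q8: { method: decision-tree-pruned, ordinal: true }
  Q9: { method: random-forest, ordinal: true }
  Q10: { method: sentiment }
cv:
  k: 10
  stratified: true
  seed: 42
negation_rules: [R1, R2, R3, R4]
neutral_band: 0.1
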