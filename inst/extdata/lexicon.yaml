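schema_version: "1.0"
# Footnote vocabulary -> triggered downgrading criterion. Lookup is
# case-insensitive and whitespace-normalised; longest match wins.
terms:
  risk of bias: risk_of_bias
  study limitations: risk_of_bias
  limitations in design: risk_of_bias
  lack of blinding: risk_of_bias
  unclear allocation concealment: risk_of_bias
  high attrition: risk_of_bias
  methodological limitations: risk_of_bias
  imprecision: imprecision
  wide confidence interval: imprecision
  wide confidence intervals: imprecision
  small sample size: imprecision
  few events: imprecision
  optimal information size not met: imprecision
  inconsistency: inconsistency
  heterogeneity: inconsistency
  inconsistent results: inconsistency
  unexplained variability: inconsistency
  indirectness: indirectness
  indirect evidence: indirectness
  surrogate outcome: indirectness
  applicability concerns: indirectness
  publication bias: publication_bias
  funnel plot asymmetry: publication_bias
  selective publication: publication_bias
  missing studies suspected: publication_bias
# Phrases marking a multi-step downgrade, adjacent to a matched term.
multipliers:
  two levels: 2
  2 levels: 2
  by two: 2
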