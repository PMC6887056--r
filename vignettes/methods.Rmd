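---
title: "Methods: mining ratio confidence intervals and diagnosing the just-significant excess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining ratio confidence intervals and diagnosing the just-significant excess}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(justsig)
```

## The problem

Health and medical journals preferentially contain statistically
significant results, through a combination of p-hacking by authors and
significance-dependent publication. For ratio effect measures — odds,
hazard, risk, rate and prevalence ratios — the fingerprint of that
distortion is visible in the reported confidence intervals themselves: an
excess of lower limits just above the null value 1 and of upper limits
just below it. `justsig` packages the full chain needed to measure that
fingerprint — extraction of intervals from text, quality control,
distribution diagnostics — together with a ground-truth simulator that can
generate both an unbiased literature and a deliberately distorted one, so
that every stage is testable against known truth.

## Extraction grammar

The extractor recognises an explicit catalogue of typeset forms
(`template_catalogue()`), organised in three regex families:
parenthesised (`"OR 1.50 (95% CI 1.20 to 1.90)"` with to/dash/comma/colon
variants), bracketed (`"RR = 2.0 [1.1–3.6]"`, CI label optional), and
inline (`"HR 0.85; 95% CI 0.75 to 0.97"`, also with a comma). Design
choices that matter:

* **Numbers are read exactly as printed.** The numeric sub-grammar accepts
  plain decimals with a period only; thousands separators and
  comma-as-decimal are rejected (`parse_number("1,204")` is `NA`) because
  ratio values rarely exceed three digits and the ambiguity would cost
  precision.
* **Negative values reject the match.** Ratios are positive; intervals on
  difference scales (negative limits) are out of scope.
* **Estimate type and fallback level come from a bounded context window**
  of 60 characters before the interval, truncated at the previous match so
  spans never overlap. Bounded context keeps behaviour deterministic. The
  type token nearest the interval wins; abbreviations (`OR`, `aHR`, ...)
  are matched case-sensitively, spelled-out names case-insensitively.
* **Overlap resolution: longest match wins**, remaining text is re-scanned.
* **Reversed printed limits are swapped**, not discarded, and flagged
  `reordered` — orientation is a typesetting artefact, and QC then applies
  to the corrected values.
* **Missing confidence levels are retained as unknown.** In practice a
  substantial minority of printed intervals never state their level; they
  are kept, and `impute_ci_level()` makes the conventional treat-as-95%
  assumption explicit (flag `level_imputed`). A strict analysis can simply
  filter them out instead.

Two deliberate non-clones: the catalogue is a reconstruction of the
typical reporting forms, not of any specific production system's regular
expressions; and abstract and full-text streams are kept separate with no
cross-deduplication, since whether identical intervals in both sections
should be merged is a corpus-dependent judgement the package does not
make.

A second parser, `oracle_parse()`, implements the same contract as a
numeric-token scan with explicit inspection of the text between tokens. It
shares only the specification with the main grammar, and the test suite
requires exact record-for-record agreement between the two on rendered
corpora — the same dual-implementation validation one would use before
trusting a large-scale text-mining run.

## Quality control

Two substantive rules, applied in a fixed order with each record counted
under the first rule it violates:

1. `zero_lower` — a printed lower limit of exactly zero is impossible for
   a ratio interval and is taken as an author error. The test is on the
   exactly parsed printed value, not a floating-point tolerance.
2. `mean_outside` — a point estimate outside its own interval means the
   interval or the estimate is wrong. Containment is read *inclusive* of
   both limits: estimates printed equal to a limit are a legitimate
   rounding outcome and are kept.

Two bookkeeping reasons (`nonpositive_value`, `malformed`) catch records
that cannot arise from the parser but could arrive in externally produced
tables. Rule precedence is a package decision — the two substantive
exclusions are reported independently in the literature this emulates, so
no precedence is prescribed there. No width-based plausibility filter is
applied: extremely wide intervals are a validation concern, not a stated
exclusion.

## Diagnostics

* **ECDF** (`ci_ecdf()`): right-continuous, proportion ≤ x, ties collapsed.
  The ECDF needs no tuning parameter, which is why it is the primary view;
  histograms (binwidth 0.1) are a supplementary view only.
* **Significance** (`classify_significance()`): `sig_above` iff lower
  limit > 1, `sig_below` iff upper limit < 1, strict inequalities — an
  interval whose printed limit equals 1.00 exactly is *not* counted
  significant. This is a sensitivity knob worth remembering: printed
  rounding moves limits in `[0.995, 1.005)` onto exactly 1.00, so corpora
  of coarsely rounded intervals classify slightly fewer significant
  results than their unrounded truth.
* **Jump statistic** (`jump_statistic()`): with window half-width ε
  (default 0.05 ratio units, configurable), the excess for lower limits is
  `P(limit ∈ (1, 1+ε]) − P(limit ∈ [1−ε, 1))`, mirrored for upper limits.
  It is a *descriptive* effect measure of the visual discontinuity at 1;
  no p value is attached and no formal test of p-hacking is intended or
  provided.
* **Periods** (`bin_by_period()`): 5-year bins anchored at 1976 (the first
  year of the literature this pipeline is designed for); the final partial
  period is reported as-is. The 0.25–4 ratio restriction applies to axes
  and histograms only — ECDFs and jump statistics always use all retained
  values, because the restriction belongs to presentation, not data.

### What the jump statistic does and does not measure

The two ±ε windows have equal mass only where the limit density is locally
flat. For a *smooth* density whose slope changes through 1 the excess is
non-zero even with no distortion at all. This matters quantitatively:
under this package's simulator defaults, precise null studies
(se near 0.02) concentrate their lower limits in a narrow band just below
1, so an unbiased mixed corpus has an *expected* lower-limit excess around
−0.06 — many Monte-Carlo standard errors from zero — and a mirrored
negative excess on the upper side. The statistic therefore supports
*contrasts* (distorted vs unbiased arm, where it flips from negative to
clearly positive and grows monotonically with both bias knobs), not an
absolute "zero means unbiased" reading. The test suite asserts the
contrast and the monotonicity; an absolute near-zero criterion for the
unbiased arm is retained in the acceptance tests for completeness and
fails for exactly this structural reason. Anyone wanting an absolute
diagnostic should compare the window masses against a smooth fit of the
ECDF rather than against each other.

## The simulator

`sim_config()` defaults define the reference conditions:

* `n_studies = 11968` — the size of an all-pairs reference design
  (17 treatments × 22 outcomes × 4 databases) that motivates the unbiased
  control set.
* `positive_ratio = 1.5` — the injected hazard ratio of the positive
  controls; negatives have true ratio 1.
* `prop_positive = 0.5` — the mixture weight of true effects is not a
  quantity the reference literature states; an even mixture is a neutral
  choice and the parameter is exposed, never asserted by tests.
* `se_min = 0.02, se_max = 0.5`, log-uniform — one log-ratio standard
  error per study, spanning very precise registry-scale studies to small
  trials, giving a realistic spread of interval widths. No empirical SE
  distribution is prescribed anywhere; this is a package choice, stated
  here once.
* `p_hack_looks` — p-hacking as independent repeated analyses with the
  first significant result reported. Real p-hacking re-analyses correlated
  variants of the same data, so at equal k the independent-looks model
  *overstates* the distortion; the knob is kept simple because it is meant
  to generate a detectable, tunable glut, not to estimate real-world
  hacking intensity.
* `pub_bias_retention` — significant studies always published,
  non-significant ones with this probability, independently.
* `rounding_digits = 2` — the *printed* precision. Simulated records keep
  full precision; rounding happens at the rendering step, so round-trip
  equality of parse(render(record)) is exact by construction and the
  statistical calibration of the simulator (5% type-I rate on pure nulls,
  median 1.5 for positives) is not perturbed by rounding artefacts.

A single configuration seed drives generation (via an isolated RNG scope,
so the caller's RNG state is untouched), making corpora bit-reproducible;
the renderer takes its own seed for the sentence dressing and years.

What the simulator deliberately does **not** emulate: survival-analysis
estimation on real claims data (estimates are drawn directly from the
normal log-ratio model the Wald interval assumes); correlated outcomes
within a paper; heterogeneous true effect sizes; rounded *levels* other
than the configured one; typography errors (the QC rules are exercised by
hand-built fixtures instead). Passing end-to-end tests therefore show the
pipeline is internally correct, not that real abstracts are as clean as
rendered ones.

## Numerical choices and degenerate inputs

* Histogram bin assignment adds a 1e-8 tolerance before flooring so that
  values like 0.35 land in `[0.35, 0.45)` despite floating-point
  representation of the anchor arithmetic; bins are half-open, anchored at
  the lower range end, and counts sum to the in-range values.
* `ci_ecdf()` refuses empty input; `jump_statistic()` reports the
  Monte-Carlo standard error `sqrt((p₊ + p₋ − excess²)/n)` alongside the
  excess so callers can judge noise.
* Records without a year are dropped from period binning with a message;
  empty QC input yields a well-formed all-zero report.
* Test-suite problem sizes (corpora of a few hundred to 1e5 studies,
  ~1000 rendered documents for the round-trip, 1000 brute-force trials)
  keep the full suite under a minute while leaving Monte-Carlo tolerances
  at 3 standard errors.

## Limitations

The extractor targets the catalogued reporting forms; recall on arbitrary
prose is untested by construction (that is what the validated-dual-parser
design is for when scaling to a real corpus). The jump statistic is
descriptive and slope-confounded as discussed above. The simulator's
distortion operators are stylised; they bound intuition and validate
machinery, they do not estimate the size of real-world bias.
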