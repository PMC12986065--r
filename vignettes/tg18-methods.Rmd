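---
title: "Methods: a deterministic TG18 engine, consensus arbitration, and its evaluation harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a deterministic TG18 engine, consensus arbitration, and its evaluation harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tg18cds)
```

## The clinical model

The package encodes the Tokyo Guidelines 2018 (TG18) pathway for acute
cholecystitis as an explicit, auditable rule system.

**Diagnosis.** Criteria are grouped into three domains: local inflammation
(Domain A: Murphy's sign; right-upper-quadrant mass, pain or tenderness),
systemic inflammation (Domain B: temperature > 38 °C, CRP ≥ 3 mg/dL,
white-cell count > 10,000/μL) and characteristic imaging (Domain C: wall
thickening ≥ 4 mm, enlarged gallbladder, pericholecystic fluid, incarcerated
stone, sonographic Murphy's sign, debris echo, intramural gas). *Suspected*
disease requires at least one criterion from A and one from B; a *definite*
diagnosis additionally requires at least one Domain C finding. Operator
strictness follows the guideline wording exactly — fever is a strict
inequality, the CRP cutoff is inclusive — and is pinned by boundary tests at
threshold − ε, the threshold itself, and threshold + ε for every comparison
rule.

Intramural gas is listed under Domain C in the shipped rule file. The
guideline's imaging list is sometimes quoted without it, but a gas-containing
wall is a characteristic (indeed pathognomonic) imaging finding of
emphysematous cholecystitis, and the engine's reference behaviour on the
shipped validation case depends on counting it; the rule's citation field
marks the provenance.

**Severity.** Grade III (severe) is defined by dysfunction of any of six
organ systems: cardiovascular (dopamine ≥ 5 μg/kg/min or any dose of
norepinephrine — the latter encoded as a presence flag since "any dose"
admits no threshold), neurological (decreased consciousness), respiratory
(PaO₂/FiO₂ < 300), renal (oliguria or creatinine > 2.0 mg/dL, a disjunction
of a flag and a comparison), hepatic (PT-INR > 1.5) and hematological
(platelets < 100,000/μL). Grade II (moderate) is defined by white-cell count
> 18,000/μL, a palpable tender right-upper-quadrant mass (decomposed as
palpable mass ∧ tenderness, both recorded in the trace), symptom duration
> 72 h, or marked local inflammation (gangrenous change, pericholecystic or
hepatic abscess, biliary peritonitis, emphysematous change, perforation).
Grade I is the absence of Grade II and III criteria. Grading is therefore
monotone: adding a satisfied criterion can never lower the grade, a property
the test suite checks directly.

**Management.** The recommendation is total over the severity × surgical-risk
grid. Low surgical risk is a conjunction — Charlson Comorbidity Index ≤ 5
*and* ASA-PS ≤ 2 — so an ASA-PS of 3 with a low CCI is high-risk. Grade I
low-risk patients get early laparoscopic cholecystectomy within 72 h of
onset; Grade II low-risk, early cholecystectomy by an experienced surgeon
(the "experienced surgeon" qualifier has no operational definition and is
retained as narrative only); Grade II high-risk, medical treatment and
gallbladder drainage followed by delayed cholecystectomy; Grade III, organ
support and urgent percutaneous cholecystostomy with delayed
cholecystectomy, for either risk level. The Grade I high-risk cell is not
spelled out in the guideline text the rules were transcribed from; the
shipped file encodes the conventional flowchart answer (medical treatment
with elective cholecystectomy after risk optimization) and marks it
externally sourced. Special conditions (emphysematous, gangrenous,
perforated cholecystitis, Mirizzi syndrome with Csendes typing, carcinoma
suspicion, Strasberg-typed bile-duct injury) never change the management
cell directly; they enter grading only through the marked-local-inflammation
criterion and annotate the management narrative. Csendes and Strasberg
subtype definitions are conventional and flagged `source: external` in the
rule file; a documented cholecystobiliary fistula with unstated extent is
typed Csendes II, the most common fistulous presentation.

Rules live in a versioned YAML file (`inst/extdata/tg18_rules.yaml`), not in
code, so the knowledge base can be revised when the guideline is. The loader
is strict (unknown keys, fields, operators and duplicate ids are errors) and
`build_knowledge_graph()` enforces structural invariants: exactly three
grade nodes, acyclic escalation edges, every grade reachable from a
criterion.

## Feature extraction

Extraction is deterministic: a lexicon of folded surface forms (case,
punctuation and whitespace insensitive) for findings, and a pattern layer
for value-bearing mentions with unit normalization — counts written as
"12 × 10³/μL" are rescaled to /μL, CRP in mg/L to mg/dL, day-denominated
durations to hours, Roman-numeral ASA-PS classes to integers. Every field
carries a tri-state: present-with-value, explicitly-absent (a negated
mention: *no*, *without*, *negative for* … within the same clause), or
unmentioned. During rule evaluation both of the latter count as not met —
multiple-choice vignettes are complete by construction, so an unmentioned
finding is treated as a clinically silent one — but the two states remain
distinguishable in the audit trail. Duplicate mentions resolve
last-mention-wins and are logged as conflicts; numeric spans with a clinical
unit that no pattern claims are recorded as unmapped rather than silently
dropped. Structured fields attached to a vignette always override
text-derived values. The original system resolved synonyms with dense
embeddings; here an exact-match folded lexicon stands in its place, with
`map_to_canonical()` as the seam where an embedding matcher could be plugged
in. Hedged findings ("suggestive of") are out of scope by design.

## Agents and consensus arbitration

Agents are pluggable: the package ships a deterministic symbolic agent
(running the rule engine and matching its conclusions to option text through
a canonical phrase table, with abstention on ties or zero matches) and a
seeded simulated agent (gold with probability 1 − error rate, otherwise a
uniform wrong option, Beta-distributed confidences moment-matched to a
well-calibrated reference: mean ≈ 0.93, SD ≈ 0.04 when correct, mean ≈ 0.72
when wrong). External generative agents are an interface only.

Arbitration runs four deterministic stages: confidence-weighted voting
(tally = sum of confidences per option, no normalization), hard-constraint
filtering (rejecting severity undergrades and immediate-surgery claims under
Grade III with hemodynamic instability), uncertainty quantification, and
selection. If all admissible agents agree, the final confidence is the
arithmetic mean of their confidences; if they disagree, the admissible
option with the highest weighted vote wins; if everything is rejected, the
symbolic agent's answer is substituted with an explanatory note. A learned
arbitration function could sit in the last stage, but no training objective
or data exists for one, and the deterministic cascade reproduces the
reference behaviour exactly, so determinism won. Ties break
lexicographically by option label — never by arrival order, making
arbitration permutation invariant — and raise an explicit low-confidence
flag. Uncertainty is estimated by seeded Gaussian perturbation of the
confidences (SD 0.05 by default, clipped to [0, 1]) with vote recomputation,
reported as the fraction of resamples that flip the winner; this replaces
dropout-based resampling, which has no meaning without neural weights, while
preserving the quantity it estimated: the stability of the consensus under
confidence noise.

```{r worked}
kg <- build_knowledge_graph()
vg <- validation_vignette()
assess_vignette(vg, kg)
```

## The evaluation harness

Accuracy is the proportion correct, printed to one decimal with half-up
rounding (96.65 → 96.7; base R's round-half-even would print 96.6).
Binomial confidence intervals are Clopper–Pearson, computed from the beta
quantiles behind `binom.test()`: the exact interval is the only standard
method that reproduces the reference bounds for 29/30 (82.8–99.9%), and its
conservatism is verified by a simulated-coverage test. AUC is the
Mann–Whitney statistic computed via midranks and checked against exhaustive
pair counting; DeLong comparisons of correlated AUCs use placement values,
whose variance is validated against a grouped (within-class) delete-one
jackknife — the two are algebraically identical, which the suite confirms to
10⁻⁹ — and cross-checked against an independent implementation. Fleiss' and
Cohen's kappa are computed from the standard formulas (no agreement-statistics
package is declared as a dependency) and validated against a pair-counting
oracle; their confidence intervals use a seeded item-resampling bootstrap
(2,000 resamples by default) since no analytic CI convention is imposed.
McNemar's statistic is (b − c)²/(b + c) without continuity correction by
default — the correction is a flag — and group comparisons use classical
one-way ANOVA with Tukey HSD plus pairwise Welch t-tests under Bonferroni.
Contingency tests switch from chi-square to Fisher's exact test whenever any
expected cell count falls below 5, and report which branch ran.

For ROC curves over rater cohorts the score construction is genuinely
underdetermined when responses are only correct/incorrect: the report
supports both per-response confidences (when supplied) and, otherwise, each
respondent's overall accuracy as the ranking score for their responses, and
records which mode produced the numbers.

## What the synthetic generator emulates — and what it does not

`generate_question_bank()` reproduces the *structure* of a 30-item
case-based instrument: domains stratified 10/10/10
(diagnosis/treatment/complications) and eight disease categories with
counts 6/2/5/4/3/2/4/4 (calculous, acalculous, complicated, chronic/biliary
colic, polyps, Mirizzi, carcinoma, post-cholecystectomy). Each item plants a
ground-truth configuration (diagnosis class, grade, risk, special
conditions) and renders a narrative whose values are sampled strictly
inside or outside each rule threshold, keeping a guard margin of at least 5%
of the threshold away from every boundary so that extraction noise cannot
flip a criterion; a separate boundary-stress path samples exactly at
thresholds for the operator-strictness tests. Gold options are rendered from
the same canonical phrase table the symbolic agent matches against, so
option matching is testable independently of free-text variety. Cohorts are
simulated as independent Bernoulli raters with per-group accuracy profiles
(defaults 0.823/0.787/0.710 for the three specialty groups at 10 raters ×
30 items) and uniform wrong-option choice.

The generator does **not** emulate: linguistic variety beyond templates,
per-item difficulty structure (difficulty enters only through group accuracy
profiles), hedged or contradictory findings, or the content of any real
instrument. Passing the plant-and-recover battery therefore demonstrates
that the engine implements the encoded rules faithfully on complete,
unambiguous cases — not that extraction would survive free-text clinical
notes, which is exactly the boundary the original neural pipeline was built
to cross.

## Problem sizes and numerical choices

The test suite's end-to-end battery uses 510 clean vignettes (17 seeded
banks) for the 100% plant-and-recover check, 200 replicate cohorts of
3 × 10 × 30 responses for profile recovery within three binomial standard
errors, AUC fixtures up to n = 50 against the pair-counting oracle, and an
ANOVA fixture checked to 10⁻¹⁰ against a hand sum-of-squares decomposition —
sizes chosen so the full suite runs in well under a minute while every
stochastic check retains comfortable power. All randomness flows through
explicit seeds with save/restore of the caller's RNG state; identical seeds
give bit-identical banks, cohorts, arbitration results and bootstrap
intervals.

## Known limitations

The lexicon covers the vocabulary of the domain's vignette idiom, not
clinical free text; negation handling is clause-local and deliberately
simple. The constraint checker decodes claims from structured assessments or
option text and treats undecodable claims as admissible (logged), so it
bounds rather than eliminates guideline-discordant answers. Choledocholithiasis
and cholangitis grading, imaging pixel analysis, and patient-preference
modelling are out of scope. The knowledge base is a snapshot of one
guideline edition; the rule file is versioned precisely so that updates are
data changes, not code changes.
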