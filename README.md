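# tg18cds

Deterministic, auditable clinical decision support for acute cholecystitis,
built on the Tokyo Guidelines 2018 (TG18) — plus the statistical harness
needed to evaluate such a system against rater cohorts on multiple-choice
case vignettes.

Guideline adherence in acute cholecystitis care is known to be inconsistent:
applying the TG18 pathway correctly means combining three diagnostic
criterion domains, a three-tier severity grade over six organ systems, a
comorbidity-based surgical-risk rule, and a management grid — under time
pressure. `tg18cds` encodes that pathway once, declaratively, and applies it
identically every time, producing a full rule-activation trace for every
conclusion. It is aimed at medical-informatics researchers who need a
reproducible symbolic reference engine, a constraint checker for
AI-generated answers, or an offline benchmark harness for rater studies.

## What is inside

* **Knowledge base** — the TG18 diagnostic criteria (Domains A/B/C), Grade
  II/III severity rules, the CCI ≤ 5 ∧ ASA-PS ≤ 2 surgical-risk rule, the
  severity × risk management grid, and special-condition rules
  (emphysematous, gangrenous, perforated, Mirizzi/Csendes, carcinoma
  suspicion, Strasberg bile-duct injury), all in a versioned YAML file
  compiled into a typed graph with structural invariants.

  Diagnosis: *suspected* ⟺ ≥1 Domain A ∧ ≥1 Domain B; *definite* ⟺
  suspected ∧ ≥1 Domain C. Severity: Grade III ⟺ any organ dysfunction
  (e.g. creatinine > 2.0 mg/dL, platelets < 100,000/μL, any norepinephrine);
  Grade II ⟺ WBC > 18,000/μL ∨ duration > 72 h ∨ palpable tender mass ∨
  marked local inflammation; Grade I otherwise.
* **Feature extraction** — deterministic lexicon + pattern layer turning
  vignette narratives into typed clinical facts with tri-state semantics
  (present / explicitly absent / unmentioned) and unit normalization.
* **Inference engine** — `assess_vignette()` composes diagnosis, grade,
  special conditions, risk and management with an ordered reasoning trace.
* **Agents & arbitration** — a pluggable agent contract, a symbolic
  reference agent, seeded simulated agents, and a four-stage consensus:
  confidence-weighted voting → hard-constraint filtering → uncertainty
  quantification → selection.
* **Evaluation harness** — exact Clopper–Pearson intervals, Mann–Whitney
  AUC with DeLong comparison, Fleiss'/Cohen's kappa, McNemar, one-way ANOVA
  with Tukey and Bonferroni, and the chi-square/Fisher switch, wrapped into
  a stratified cohort report.
* **Synthetic vignettes** — a generator with planted ground truth
  (30 items, domains 10/10/10, eight disease categories 6/2/5/4/3/2/4/4)
  and simulated expert cohorts, so everything above is testable offline.

## Worked example

The shipped validation case: a 72-year-old with 4 days of right-upper-quadrant
pain, fever 39.2 °C, confusion, WBC 22,400/μL, CRP 24.5 mg/dL, creatinine
2.4 mg/dL, platelets 89,000/μL, norepinephrine-dependent hypotension, an
8 mm thickened gallbladder wall with intramural gas, CCI 4 and ASA-PS IV.

```r
library(tg18cds)
kg <- build_knowledge_graph()
vg <- validation_vignette()
assess_vignette(vg, kg)
#> <tg18_assessment>
#>   Diagnosis:   definite
#>     Domain A: met (A2)
#>     Domain B: met (B1, B2, B3)
#>     Domain C: met (C1, C2, C3, C7)
#>   Grade:       III
#>     ...
#>     G3-CV   [Cardiovascular dysfunction] system: cardiovascular
#>     G3-HEMA [Hematological dysfunction]  system: hematological
#>     G3-NEURO [Neurological dysfunction]  system: neurological
#>     G3-RENAL [Renal dysfunction]         system: renal
#>   Special:     emphysematous
#>   Risk:        high
#>   Management:  organ_support_urgent_drainage
#>   Trace:       19 activation(s)
```

The case is definite acute cholecystitis; four organ systems
(cardiovascular, renal, hematological, neurological) are dysfunctional, so
it grades III; intramural gas flags emphysematous cholecystitis; ASA-PS IV
makes the patient high-risk; the engine recommends organ support with
urgent percutaneous cholecystostomy — option C of the attached question,
which the symbolic agent selects with confidence 1.0. Two agreeing external
agents at confidences 0.96 and 0.95 arbitrate to:

```r
feats <- extract_features(vg)
arbitrate(list(agent_response("agent1", "C", 0.96, option_text = vg$options[["C"]]),
               agent_response("agent2", "C", 0.95, option_text = vg$options[["C"]])),
          feats, kg, vignette = vg)
#> <tg18_consensus>
#>   Final answer:     C
#>   Final confidence: 0.955
#>   Vote tally:       C=1.910
#>   Violations:       0 agent(s)
#>   Uncertainty:      0
```

The final confidence is the mean of the agreeing confidences; unanimity
means no perturbation resample can flip the vote, so uncertainty is 0.

A full cohort study in four lines — synthetic bank, simulated raters at
per-group accuracy profiles, stratified report:

```r
bank <- generate_question_bank(generation_spec(seed = 1))
rm   <- simulate_expert_cohort(bank, c(surgery = 0.823, gastro = 0.787, em = 0.710), 10, seed = 1)
evaluate_matrix(rm)
#> Group accuracy
#>    group  n mean_accuracy  sd ci_lo ci_hi errors error_rate
#>       em 10          71.3 5.7  67.3  75.4     86       28.7
#>   gastro 10          78.7 7.1  73.6  83.7     64       21.3
#>  surgery 10          84.7 4.8  81.3  88.1     46       15.3
#> Pooled: 900 responses, 196 errors (error rate 21.8%)
#> ...
#> ANOVA: F = 12.697 (df 2, 27), p = 0.0001298
```

Each row is 10 simulated raters × 30 items; the error rates recover the
planted profiles up to binomial noise, and `binomial_ci(29, 30)` gives the
exact interval (82.8, 99.9)% for a 29/30 score.

## Command line

```sh
Rscript inst/cli/tg18cds assess   --vignette case.json --out report.json
Rscript inst/cli/tg18cds simulate --seed 7 --out bank.json
Rscript inst/cli/tg18cds validate-kb
```

`validate-kb` lints a rule file and re-runs the operator-strictness
boundary checks against every encoded threshold.

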