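kg <- default_kg()

test_that("diagnosis classes follow the two-out-of-three-domain logic", {
  expect_identical(
    classify_diagnosis(extract_features(validation_vignette()),
                       kg)$diagnosis_class,
    "definite")
  expect_identical(classify_diagnosis(new_features(), kg)$diagnosis_class,
                   "not-cholecystitis")
  # local + systemic signs without imaging -> suspected
  susp <- features_with(murphy_sign = TRUE, temperature = 38.5)
  dx <- classify_diagnosis(susp, kg)
  expect_identical(dx$diagnosis_class, "suspected")
  expect_true(dx$domain_status$A$met)
  expect_true(dx$domain_status$B$met)
  expect_false(dx$domain_status$C$met)
  # imaging alone is not cholecystitis
  img <- features_with(wall_thickness = 6)
  expect_identical(classify_diagnosis(img, kg)$diagnosis_class,
                   "not-cholecystitis")
})

test_that("severity grading: organ dysfunction dominates, absence is mild", {
  # prolonged symptoms + marked leukocytosis without organ dysfunction
  g2 <- features_with(murphy_sign = TRUE, temperature = 38.6, wbc = 19200,
                      symptom_duration = 80, wall_thickness = 5)
  gs <- grade_severity(g2, kg)
  expect_identical(gs$grade, "II")
  expect_setequal(vapply(gs$grade_basis, `[[`, character(1), "rule"),
                  c("G2-WBC", "G2-DUR"))
  # no moderate or severe criteria -> Grade I by definition
  g1 <- features_with(murphy_sign = TRUE, temperature = 38.4, wbc = 12000,
                      crp = 5, wall_thickness = 5, symptom_duration = 24)
  gs1 <- grade_severity(g1, kg)
  expect_identical(gs1$grade, "I")
  expect_length(gs1$grade_basis, 0L)
  # any single organ dysfunction forces Grade III
  g3 <- features_with(murphy_sign = TRUE, wbc = 12000, creatinine = 2.4)
  gs3 <- grade_severity(g3, kg)
  expect_identical(gs3$grade, "III")
  expect_true("G3-RENAL" %in% vapply(gs3$grade_basis, `[[`, character(1),
                                     "rule"))
})

test_that("special conditions and subtype typing", {
  expect_identical(
    names(detect_special_conditions(features_with(intramural_gas = TRUE),
                                    kg)),
    "emphysematous")
  expect_identical(
    names(detect_special_conditions(features_with(wall_discontinuity = TRUE),
                                    kg)),
    "gangrenous")
  expect_length(detect_special_conditions(new_features(), kg), 0L)
  # Mirizzi typing: compression only -> I; fistula -> II; extent 0.5 -> III
  m1 <- detect_special_conditions(features_with(cbd_compression = TRUE), kg)
  expect_identical(m1$mirizzi$type, "I")
  m2 <- detect_special_conditions(
    features_with(cholecystobiliary_fistula = TRUE), kg)
  expect_identical(m2$mirizzi$type, "II")
  m3 <- detect_special_conditions(
    features_with(cholecystobiliary_fistula = TRUE, fistula_extent = 0.5),
    kg)
  expect_identical(m3$mirizzi$type, "III")
  # Strasberg lettering
  s <- detect_special_conditions(features_with(bile_leak_cystic_duct = TRUE),
                                 kg)
  expect_identical(s$`bile-duct-injury`$type, "A")
  sE <- detect_special_conditions(features_with(cbd_transection = TRUE), kg)
  expect_identical(sE$`bile-duct-injury`$type, "E")
})

test_that("surgical risk is a conjunction of both score bounds", {
  expect_identical(classify_surgical_risk(4, 4, kg), "high")
  expect_identical(classify_surgical_risk(5, 2, kg), "low")
  expect_identical(classify_surgical_risk(6, 2, kg), "high")
  expect_identical(classify_surgical_risk(3, 3, kg), "high")
  expect_error(classify_surgical_risk(NA, 2, kg),
               class = "tg18_unknown_risk")
})

test_that("management is total over the grade x risk grid", {
  for (grade in c("I", "II", "III")) {
    for (risk in c("low", "high")) {
      m <- recommend_management("definite", grade, risk, kg = kg)
      expect_true(is.character(m$action) && nzchar(m$action))
      expect_true(nzchar(m$narrative))
    }
  }
  expect_identical(recommend_management("definite", "I", "low", kg = kg)$action,
                   "early_lap_chole_72h")
  expect_identical(recommend_management("definite", "II", "high",
                                        kg = kg)$action,
                   "drainage_then_delayed")
  # severe disease: drainage-first regardless of risk
  expect_identical(recommend_management("definite", "III", "high",
                                        kg = kg)$action,
                   "organ_support_urgent_drainage")
  expect_identical(recommend_management("definite", "III", "low",
                                        kg = kg)$action,
                   "organ_support_urgent_drainage")
  expect_null(recommend_management("not-cholecystitis", NA, NA, kg = kg))
})

test_that("moderate disease with borderline comorbidity routes to drainage first", {
  # 58-year-old with >72 h of symptoms, WBC 19,200 and CCI 4 / ASA-PS III
  vg <- clinical_vignette(
    "q17-style",
    text = paste(
      "A 58-year-old male presents with right upper quadrant pain for 90",
      "hours. Physical examination reveals Murphy's sign and right upper",
      "quadrant tenderness. Temperature 38.4 °C. Laboratory findings show",
      "WBC 19,200/μL and CRP 9.1 mg/dL.",
      "Ultrasound demonstrates gallbladder wall thickening of 6 mm with",
      "pericholecystic fluid; and multiple gallstones are seen.",
      "CCI score is 4 and ASA-PS is III."))
  a <- assess_vignette(vg, kg)
  expect_identical(a$diagnosis_class, "definite")
  expect_identical(a$grade, "II")
  expect_identical(a$risk_level, "high")
  expect_identical(a$management$action, "drainage_then_delayed")
})

test_that("assessment composes the pieces with a sound trace", {
  a <- assess_vignette(validation_vignette(), kg)
  expect_identical(a$diagnosis_class, "definite")
  expect_identical(a$grade, "III")
  expect_identical(a$risk_level, "high")
  expect_identical(a$management$action, "organ_support_urgent_drainage")
  rules <- vapply(a$trace, `[[`, character(1), "rule")
  concl <- vapply(a$trace, `[[`, character(1), "conclusion")
  # every conclusion is supported by at least one activation in the trace
  expect_true(any(concl == "domain:A"))
  expect_true(any(concl == "domain:B"))
  expect_true(any(concl == "domain:C"))
  expect_true(any(concl == "grade:III"))
  expect_true(any(concl == paste0("action:", a$management$action)))
  expect_true(any(concl == paste0("risk:", a$risk_level)))
  expect_true(any(concl == paste0("cond:", names(a$special_conditions)[1])))
  # empty vignette -> nothing concluded, nothing recommended
  e <- assess_vignette(clinical_vignette("empty", text = "Well adult."), kg)
  expect_identical(e$diagnosis_class, "not-cholecystitis")
  expect_null(e$management)
  # unknown risk propagates when the management cell needs it
  vg <- clinical_vignette("norisk", text = paste(
    "Right upper quadrant pain for 30 hours with Murphy's sign.",
    "Temperature 38.5 °C. WBC 12,000/μL."))
  expect_error(assess_vignette(vg, kg), class = "tg18_unknown_risk")
})

test_that("grading is monotone under added criteria", {
  rank <- c(I = 1, II = 2, III = 3)
  base_sets <- list(
    features_with(murphy_sign = TRUE, temperature = 38.5, wbc = 12000),
    features_with(ruq_pain = TRUE, crp = 8, wbc = 15000,
                  symptom_duration = 40),
    features_with(murphy_sign = TRUE, wbc = 19000, wall_thickness = 5))
  adders <- list(
    function(f) feat_set(f, "wbc", 20000),
    function(f) feat_set(f, "symptom_duration", 100),
    function(f) feat_set(f, "intramural_gas", TRUE),
    function(f) feat_set(f, "creatinine", 3.0),
    function(f) feat_set(f, "norepinephrine_any", TRUE),
    function(f) feat_set(f, "pt_inr", 2.0))
  for (f in base_sets) {
    g0 <- grade_severity(f, kg)$grade
    for (add in adders) {
      g1 <- grade_severity(add(f), kg)$grade
      expect_gte(rank[[g1]], rank[[g0]])
    }
    # adding an imaging finding never demotes definite to suspected
    d0 <- classify_diagnosis(f, kg)$diagnosis_class
    d1 <- classify_diagnosis(feat_set(f, "pericholecystic_fluid", TRUE),
                             kg)$diagnosis_class
    if (d0 == "definite") expect_identical(d1, "definite")
  }
})
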