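# ---------------------------------------------------------------------------
# Canonical phrasing table shared by the option renderer (synthetic module)
# and the symbolic agent's option matcher. Keys are conclusion concepts;
# values are the surface phrases an option may use for that conclusion.
# Phrases are chosen to be mutually non-overlapping within one option pool.
# ---------------------------------------------------------------------------

concept_phrases <- function() {
  list(
    "dx:definite"  = c("definite acute cholecystitis"),
    "dx:suspected" = c("suspected acute cholecystitis"),
    "grade:I"   = c("grade i"),
    "grade:II"  = c("grade ii"),
    "grade:III" = c("grade iii"),
    "action:early_lap_chole_72h" =
      c("within 72 h", "within 72 hours"),
    "action:early_lap_chole_expert" =
      c("experienced surgeon"),
    "action:drainage_then_delayed" =
      c("followed by delayed cholecystectomy",
        "drainage followed by delayed"),
    "action:organ_support_urgent_drainage" =
      c("organ support"),
    "action:conservative_then_elective" =
      c("elective cholecystectomy"),
    "cond:emphysematous" = c("emphysematous"),
    "cond:gangrenous" = c("gangrenous"),
    "cond:perforated" = c("perforated", "perforation"),
    "cond:mirizzi" = c("mirizzi"),
    "cond:carcinoma-suspect" = c("carcinoma"),
    "cond:bile-duct-injury" = c("bile duct injury", "strasberg"),
    "risk:high" = c("high surgical risk"),
    "risk:low" = c("low surgical risk")
  )
}

# Does folded option text contain the phrase as whole words?
phrase_hits <- function(option_text, phrases) {
  txt <- fold_term(option_text)
  any(vapply(phrases, function(p) {
    pat <- paste0("\\b", gsub(" ", "\\\\s+", fold_term(p)), "\\b")
    grepl(pat, txt, perl = TRUE)
  }, logical(1)))
}

# Conclusion concepts carried by an assessment (used for option scoring).
assessment_concepts <- function(assessment) {
  cc <- character(0)
  if (assessment$diagnosis_class %in% c("definite", "suspected")) {
    cc <- c(cc, paste0("dx:", assessment$diagnosis_class))
  }
  if (!is.na(assessment$grade)) cc <- c(cc, paste0("grade:", assessment$grade))
  if (!is.null(assessment$management)) {
    cc <- c(cc, paste0("action:", assessment$management$action))
  }
  for (sc in assessment$special_conditions) {
    cc <- c(cc, paste0("cond:", sc$condition))
  }
  if (!is.na(assessment$risk_level)) {
    cc <- c(cc, paste0("risk:", assessment$risk_level))
  }
  cc
}
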