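# ---------------------------------------------------------------------------
# TG18 inference engine: diagnosis, severity grade, special conditions,
# surgical risk, management, with a full rule-activation trace.
# ---------------------------------------------------------------------------

acts_by_tag <- function(acts, tag) {
  Filter(function(a) a$domain_tag == tag, acts)
}

#' Classify the diagnosis from extracted features
#'
#' Suspected acute cholecystitis requires at least one local-inflammation
#' (Domain A) and one systemic-inflammation (Domain B) criterion; a definite
#' diagnosis additionally requires at least one characteristic imaging
#' (Domain C) finding.
#'
#' @param features a `tg18_features` object.
#' @param kg a `tg18_kg`.
#' @return list with `diagnosis_class` (`"not-cholecystitis"`, `"suspected"`,
#'   `"definite"`) and `domain_status`, a per-domain list of `met` flag and
#'   activating criterion ids.
#' @export
classify_diagnosis <- function(features, kg) {
  acts <- query_rules(kg, features)
  domain_status <- lapply(c(A = "A", B = "B", C = "C"), function(d) {
    hits <- acts_by_tag(acts, d)
    list(met = length(hits) > 0L,
         criteria = vapply(hits, `[[`, character(1), "rule"))
  })
  cls <- if (domain_status$A$met && domain_status$B$met) {
    if (domain_status$C$met) "definite" else "suspected"
  } else "not-cholecystitis"
  list(diagnosis_class = cls, domain_status = domain_status,
       activations = acts)
}

#' Grade severity
#'
#' Grade III (severe) when any organ-system dysfunction criterion is met;
#' otherwise Grade II (moderate) when any Grade II criterion is met;
#' otherwise Grade I (mild), defined by the absence of Grade II and III
#' criteria. `grade_basis` lists every satisfied Grade II/III criterion with
#' its organ-system label.
#'
#' @inheritParams classify_diagnosis
#' @return list with `grade` (`"I"`, `"II"`, `"III"`) and `grade_basis`.
#' @export
grade_severity <- function(features, kg) {
  acts <- query_rules(kg, features)
  g3 <- acts_by_tag(acts, "gradeIII-organ")
  g2 <- acts_by_tag(acts, "gradeII")
  grade <- if (length(g3)) "III" else if (length(g2)) "II" else "I"
  list(grade = grade, grade_basis = c(g2, g3))
}

#' Detect special conditions
#'
#' Recognizes emphysematous, gangrenous and perforated cholecystitis, Mirizzi
#' syndrome (with Csendes type where determinable), suspected gallbladder
#' carcinoma and post-cholecystectomy bile-duct injury (with Strasberg type).
#' Subtype definitions beyond the guideline text are conventional and marked
#' `source: external` in the rule file.
#'
#' @inheritParams classify_diagnosis
#' @return named list: condition -> list(condition, type, rule).
#' @export
detect_special_conditions <- function(features, kg) {
  acts <- acts_by_tag(query_rules(kg, features), "special")
  out <- list()
  for (a in acts) {
    cond <- a$condition
    type <- NA_character_
    if (cond == "mirizzi") {
      type <- csendes_type(features, kg)
    } else if (cond == "bile-duct-injury") {
      type <- strasberg_type(features, kg)
    }
    out[[cond]] <- list(condition = cond, type = type, rule = a$rule)
  }
  out
}

csendes_type <- function(features, kg) {
  if (!feat_present(features, "cholecystobiliary_fistula")) {
    # extrinsic compression without fistula
    if (feat_present(features, "cbd_compression")) return("I")
    return(NA_character_)
  }
  ext <- if (feat_status(features, "fistula_extent") == "present") {
    feat_value(features, "fistula_extent")
  } else NA_real_
  tab <- kg$ruleset$csendes$types
  if (is.na(ext)) return("II")  # fistula documented, extent unstated
  for (t in tab) {
    if (!is.null(t$max_extent) && ext <= t$max_extent + 1e-9) return(t$type)
  }
  "IV"
}

strasberg_type <- function(features, kg) {
  for (t in kg$ruleset$strasberg$types) {
    if (feat_present(features, t$field)) return(t$type)
  }
  NA_character_
}

#' Classify surgical risk from comorbidity scores
#'
#' Low risk requires BOTH a Charlson Comorbidity Index of at most 5 and an
#' ASA Physical Status of at most 2 (a conjunction); anything else is high
#' risk. Missing either score is an explicit error: the caller decides how to
#' proceed when risk is unknown.
#'
#' @param cci Charlson Comorbidity Index (non-negative integer).
#' @param asa_ps ASA Physical Status class (1-6).
#' @param kg a `tg18_kg` (supplies the bounds from the rule file).
#' @return `"low"` or `"high"`.
#' @export
classify_surgical_risk <- function(cci, asa_ps, kg = NULL) {
  if (is.null(cci) || is.null(asa_ps) || is.na(cci) || is.na(asa_ps)) {
    abort_tg18("surgical risk is unknown: both CCI and ASA-PS are required",
               "tg18_unknown_risk")
  }
  stopifnot(cci >= 0, asa_ps %in% 1:6)
  bounds <- if (!is.null(kg)) kg$ruleset$risk else list(cci_max = 5,
                                                        asa_ps_max = 2)
  if (cci <= bounds$cci_max && asa_ps <= bounds$asa_ps_max) "low" else "high"
}

#' Recommend management
#'
#' Total over the severity-grade x surgical-risk grid: Grade I low-risk gets
#' early laparoscopic cholecystectomy within 72 h; Grade II low-risk early
#' cholecystectomy by an experienced surgeon; Grade II high-risk medical
#' treatment plus gallbladder drainage then delayed cholecystectomy; Grade
#' III (either risk) organ support with urgent drainage and delayed
#' cholecystectomy. Special conditions modify the narrative, never the cell.
#'
#' @param diagnosis_class diagnosis class string.
#' @param grade severity grade (`"I"`, `"II"`, `"III"`).
#' @param risk_level `"low"` or `"high"`.
#' @param special_conditions result of [detect_special_conditions()].
#' @param kg a `tg18_kg`.
#' @return list with `action` id and `narrative`, or `NULL` when
#'   `diagnosis_class` is `"not-cholecystitis"`.
#' @export
recommend_management <- function(diagnosis_class, grade, risk_level,
                                 special_conditions = list(),
                                 kg = build_knowledge_graph()) {
  if (identical(diagnosis_class, "not-cholecystitis")) return(NULL)
  rows <- kg$ruleset$management
  hit <- NULL
  for (m in rows) {
    if (identical(m$grade, grade) && identical(m$risk, risk_level)) {
      hit <- m; break
    }
  }
  if (is.null(hit)) {
    abort_tg18(sprintf("no management rule for grade %s / risk %s", grade,
                       risk_level), "tg18_validation_error")
  }
  narrative <- hit$narrative
  if (length(special_conditions)) {
    mods <- vapply(special_conditions, function(sc) {
      lbl <- sc$condition
      if (!is.na(sc$type)) lbl <- paste0(lbl, " (type ", sc$type, ")")
      lbl
    }, character(1))
    narrative <- paste0(narrative, " Special condition(s): ",
                        paste(mods, collapse = ", "), ".")
  }
  list(rule = hit$id, action = hit$action, narrative = narrative)
}

#' Assess a vignette end to end
#'
#' Composes feature extraction, diagnosis classification, severity grading,
#' special-condition detection, surgical-risk classification and management
#' recommendation into a single deterministic assessment with an ordered
#' rule-activation trace.
#'
#' @param vignette a `tg18_vignette` (or raw narrative text).
#' @param kg a `tg18_kg`.
#' @param features optionally, pre-extracted features (skips extraction).
#' @return an object of class `tg18_assessment`.
#' @export
assess_vignette <- function(vignette, kg = build_knowledge_graph(),
                            features = NULL) {
  if (is.null(features)) features <- extract_features(vignette)
  dx <- classify_diagnosis(features, kg)
  trace <- dx$activations
  special <- detect_special_conditions(features, kg)
  grade <- NA_character_
  grade_basis <- list()
  risk <- NA_character_
  mgmt <- NULL

  cci <- if (feat_status(features, "cci") == "present")
    feat_value(features, "cci") else NA
  asa <- if (feat_status(features, "asa_ps") == "present")
    feat_value(features, "asa_ps") else NA
  risk_known <- !is.na(cci) && !is.na(asa)
  if (risk_known) risk <- classify_surgical_risk(cci, asa, kg)

  if (dx$diagnosis_class != "not-cholecystitis") {
    gs <- grade_severity(features, kg)
    grade <- gs$grade
    grade_basis <- gs$grade_basis
    if (!risk_known && grade %in% c("I", "II")) {
      # management for Grade I/II depends on the risk cell
      abort_tg18(
        "surgical risk is unknown: both CCI and ASA-PS are required",
        "tg18_unknown_risk")
    }
    mgmt_risk <- if (risk_known) risk else "high"  # Grade III cells coincide
    mgmt <- recommend_management(dx$diagnosis_class, grade, mgmt_risk,
                                 special, kg)
    trace <- c(trace, list(structure(
      list(rule = mgmt$rule, domain_tag = "management",
           label = "management pathway", system = NA_character_,
           condition = NA_character_,
           matched = list(list(field = "grade", observed = grade,
                               operator = "==", threshold = grade,
                               units = ""),
                          list(field = "risk", observed = mgmt_risk,
                               operator = "==", threshold = mgmt_risk,
                               units = "")),
           conclusion = paste0("action:", mgmt$action)),
      class = "tg18_activation")))
  }
  if (risk_known) {
    bounds <- kg$ruleset$risk %||% list(cci_max = 5, asa_ps_max = 2)
    trace <- c(trace, list(structure(
      list(rule = "RISK", domain_tag = "risk",
           label = "surgical risk classification", system = NA_character_,
           condition = NA_character_,
           matched = list(list(field = "cci", observed = cci,
                               operator = "<=", threshold = bounds$cci_max,
                               units = "score"),
                          list(field = "asa_ps", observed = asa,
                               operator = "<=", threshold = bounds$asa_ps_max,
                               units = "class")),
           conclusion = paste0("risk:", risk)),
      class = "tg18_activation")))
  }
  structure(list(
    diagnosis_class = dx$diagnosis_class,
    domain_status = dx$domain_status,
    grade = grade,
    grade_basis = grade_basis,
    special_conditions = special,
    risk_level = risk,
    management = mgmt,
    trace = structure(trace, class = "tg18_activations")
  ), class = "tg18_assessment")
}

#' @export
print.tg18_assessment <- function(x, ...) {
  cat("<tg18_assessment>\n")
  cat("  Diagnosis:  ", x$diagnosis_class, "\n")
  for (d in names(x$domain_status)) {
    ds <- x$domain_status[[d]]
    cat(sprintf("    Domain %s: %s%s\n", d, if (ds$met) "met" else "not met",
                if (ds$met) paste0(" (", paste(ds$criteria, collapse = ", "),
                                   ")") else ""))
  }
  cat("  Grade:      ", x$grade, "\n")
  if (length(x$grade_basis)) {
    for (a in x$grade_basis) {
      cat(sprintf("    %s [%s]%s\n", a$rule, a$label,
                  if (!is.na(a$system)) paste0(" system: ", a$system) else ""))
    }
  }
  if (length(x$special_conditions)) {
    cat("  Special:    ",
        paste(vapply(x$special_conditions, function(sc) {
          if (is.na(sc$type)) sc$condition
          else paste0(sc$condition, " (type ", sc$type, ")")
        }, character(1)), collapse = ", "), "\n")
  }
  cat("  Risk:       ", x$risk_level, "\n")
  if (!is.null(x$management)) {
    cat("  Management: ", x$management$action, "\n")
    cat(strwrap(x$management$narrative, 72, prefix = "    "), sep = "\n")
  }
  cat(sprintf("  Trace:       %d activation(s)\n", length(x$trace)))
  invisible(x)
}
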