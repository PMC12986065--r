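#' @importFrom utils read.csv
NULL

# ---------------------------------------------------------------------------
# Canonical feature registry
# ---------------------------------------------------------------------------

# Every clinical fact the engine can reason over, with its type, canonical
# unit, and a physiologically plausible range used by the synthetic generator
# and by validation. Flags take TRUE/FALSE; numerics are stored in the
# canonical unit after conversion.
.field_registry <- data.frame(
  field = c(
    "wbc", "crp", "bilirubin", "creatinine", "platelets", "pt_inr",
    "pao2_fio2",
    "temperature", "sbp", "dbp", "norepinephrine_any", "dopamine_dose",
    "decreased_consciousness", "oliguria",
    "murphy_sign", "ruq_pain", "ruq_tenderness", "palpable_mass",
    "wall_thickness", "enlarged_gb", "pericholecystic_fluid", "gallstones",
    "incarcerated_stone", "sonographic_murphy", "debris_echo",
    "intramural_gas", "wall_discontinuity", "irregular_wall",
    "pericholecystic_abscess", "hepatic_abscess", "biliary_peritonitis",
    "gb_perforation", "gb_mass", "polyp_size", "cbd_compression",
    "fistula_extent", "cholecystobiliary_fistula",
    "bile_leak_cystic_duct", "cbd_lateral_injury", "cbd_transection",
    "symptom_duration", "cci", "asa_ps"
  ),
  type = c(
    "numeric", "numeric", "numeric", "numeric", "numeric", "numeric",
    "numeric",
    "numeric", "numeric", "numeric", "flag", "numeric",
    "flag", "flag",
    "flag", "flag", "flag", "flag",
    "numeric", "flag", "flag", "flag",
    "flag", "flag", "flag",
    "flag", "flag", "flag",
    "flag", "flag", "flag",
    "flag", "flag", "numeric", "flag",
    "numeric", "flag",
    "flag", "flag", "flag",
    "numeric", "integer", "integer"
  ),
  unit = c(
    "/uL", "mg/dL", "mg/dL", "mg/dL", "/uL", "ratio",
    "ratio",
    "degC", "mmHg", "mmHg", "", "ug/kg/min",
    "", "",
    "", "", "", "",
    "mm", "", "", "",
    "", "", "",
    "", "", "",
    "", "", "",
    "", "", "mm", "",
    "fraction", "",
    "", "", "",
    "h", "score", "class"
  ),
  lo = c(500, 0, 0.1, 0.2, 5000, 0.8,
         40,
         34, 50, 30, NA, 0,
         NA, NA,
         NA, NA, NA, NA,
         1, NA, NA, NA,
         NA, NA, NA,
         NA, NA, NA,
         NA, NA, NA,
         NA, NA, 1, NA,
         0, NA,
         NA, NA, NA,
         1, 0, 1),
  hi = c(60000, 50, 30, 12, 900000, 8,
         600,
         42, 250, 150, NA, 50,
         NA, NA,
         NA, NA, NA, NA,
         20, NA, NA, NA,
         NA, NA, NA,
         NA, NA, NA,
         NA, NA, NA,
         NA, NA, 40, NA,
         1, NA,
         NA, NA, NA,
         720, 20, 6),
  stringsAsFactors = FALSE
)

#' Canonical clinical feature registry
#'
#' The table of feature fields the TG18 engine reasons over: field name, type
#' (`numeric`, `integer` or `flag`), canonical unit, and the physiologically
#' plausible range used by the synthetic generator.
#'
#' @return a data.frame with columns `field`, `type`, `unit`, `lo`, `hi`.
#' @export
tg18_field_registry <- function() .field_registry

field_names <- function() .field_registry$field
field_type <- function(f) .field_registry$type[match(f, .field_registry$field)]

# ---------------------------------------------------------------------------
# ExtractedFeatures container: every field carries a tri-state
# (present / absent / unknown) plus a value and a provenance source.
# ---------------------------------------------------------------------------

#' Create an empty feature set
#'
#' All fields start in the `unknown` tri-state (unmentioned). During rule
#' evaluation unknown and explicitly-absent findings both count as not met,
#' but they remain distinguishable in the audit trail.
#'
#' @return an object of class `tg18_features`.
#' @export
new_features <- function() {
  fields <- stats::setNames(
    lapply(field_names(), function(f) {
      list(value = NULL, status = "unknown", source = NULL)
    }),
    field_names()
  )
  structure(list(fields = fields, conflicts = list(), unmapped = list()),
            class = "tg18_features")
}

#' Set a feature value
#'
#' @param features a `tg18_features` object.
#' @param field canonical field name (see [tg18_field_registry()]).
#' @param value numeric value, or TRUE for flags.
#' @param status one of `"present"`, `"absent"`, `"unknown"`.
#' @param source provenance tag, e.g. `"structured"` or a text span.
#' @return the updated `tg18_features` object.
#' @export
feat_set <- function(features, field, value = TRUE, status = "present",
                     source = "manual") {
  stopifnot(inherits(features, "tg18_features"))
  if (!field %in% field_names()) {
    abort_tg18(sprintf("unknown feature field '%s'", field),
               "tg18_schema_error")
  }
  status <- match.arg(status, c("present", "absent", "unknown"))
  if (status == "present" && field_type(field) %in% c("numeric", "integer")) {
    if (!is.numeric(value) || length(value) != 1L || is.na(value)) {
      abort_tg18(sprintf("field '%s' requires a single numeric value", field),
                 "tg18_schema_error")
    }
    if (value < 0) {
      abort_tg18(sprintf("field '%s' must be non-negative", field),
                 "tg18_schema_error")
    }
    if (field == "asa_ps" && !(value %in% 1:6)) {
      abort_tg18("asa_ps must be an integer between 1 and 6",
                 "tg18_schema_error")
    }
  }
  prev <- features$fields[[field]]
  if (prev$status != "unknown" &&
      !identical(prev$value, value) && status == "present") {
    features$conflicts[[length(features$conflicts) + 1L]] <-
      list(field = field, previous = prev$value, replacement = value,
           source = source)
  }
  features$fields[[field]] <- list(value = value, status = status,
                                   source = source)
  features
}

#' @export
feat_value <- function(features, field) features$fields[[field]]$value

#' @export
feat_status <- function(features, field) features$fields[[field]]$status

feat_present <- function(features, field) {
  f <- features$fields[[field]]
  f$status == "present" && !identical(f$value, FALSE)
}

#' @export
print.tg18_features <- function(x, ...) {
  known <- Filter(function(f) f$status != "unknown", x$fields)
  cat(sprintf("<tg18_features> %d of %d fields known\n",
              length(known), length(x$fields)))
  for (nm in names(known)) {
    f <- known[[nm]]
    val <- if (isTRUE(f$value)) "present" else format(f$value)
    cat(sprintf("  %-24s %-8s %s\n", nm, f$status, val))
  }
  if (length(x$conflicts)) {
    cat(sprintf("  (%d conflicting mention(s) resolved: last mention wins)\n",
                length(x$conflicts)))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Lexicon
# ---------------------------------------------------------------------------

#' Load a surface-form lexicon
#'
#' @param path CSV file with columns `surface`, `concept`. Defaults to the
#'   lexicon shipped with the package.
#' @return a data.frame of class `tg18_lexicon` with folded surface forms.
#' @export
load_lexicon <- function(path = system.file("extdata", "lexicon.csv",
                                            package = "tg18cds")) {
  lx <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("surface", "concept") %in% names(lx))) {
    abort_tg18("lexicon must have columns 'surface' and 'concept'",
               "tg18_schema_error")
  }
  lx$folded <- fold_term(lx$surface)
  if (anyDuplicated(lx$folded)) {
    dup <- lx$surface[duplicated(lx$folded)]
    abort_tg18(sprintf("duplicate lexicon surface form(s) after folding: %s",
                       paste(dup, collapse = ", ")), "tg18_schema_error")
  }
  class(lx) <- c("tg18_lexicon", "data.frame")
  lx
}

#' Map a clinical term to its canonical concept
#'
#' Matching is insensitive to case, punctuation and whitespace.
#'
#' @param term character scalar.
#' @param lexicon a lexicon from [load_lexicon()].
#' @return a list with `concept` (canonical id or `NA`) and `unmapped` flag.
#' @export
map_to_canonical <- function(term, lexicon = load_lexicon()) {
  hit <- match(fold_term(term), lexicon$folded)
  if (is.na(hit)) {
    list(concept = NA_character_, unmapped = TRUE)
  } else {
    list(concept = lexicon$concept[hit], unmapped = FALSE)
  }
}

# ---------------------------------------------------------------------------
# Numeric extraction rules
# ---------------------------------------------------------------------------

.NUM <- "([0-9]{1,3}(?:,[0-9]{3})+|[0-9]+(?:\\.[0-9]+)?)"

# Each rule: field, regex over folded text (group 1 = number), optional
# groups handled by `post`, which maps (value, full match) -> canonical value.
numeric_rules <- function() {
  list(
    list(field = "wbc",
         pattern = paste0("(?:wbc(?: count)?|white (?:blood )?cell count|",
                          "leukocyte count|leukocytosis of)[^0-9]{0,15}", .NUM,
                          "(\\s*x\\s*10\\^?3)?"),
         post = function(v, m) if (grepl("x\\s*10", m)) v * 1000 else v),
    list(field = "crp",
         pattern = paste0("(?:crp|c-reactive protein)[^0-9]{0,15}", .NUM,
                          "(\\s*mg\\s*/\\s*l\\b)?"),
         post = function(v, m) {
           if (grepl("mg\\s*/\\s*l\\b", m) && !grepl("/\\s*dl", m)) v / 10 else v
         }),
    list(field = "bilirubin",
         pattern = paste0("(?:total )?bilirubin[^0-9]{0,15}", .NUM)),
    list(field = "creatinine",
         pattern = paste0("creatinine[^0-9]{0,15}", .NUM)),
    list(field = "platelets",
         pattern = paste0("platelets?(?: count)?[^0-9]{0,15}", .NUM,
                          "(\\s*x\\s*10\\^?3)?"),
         post = function(v, m) if (grepl("x\\s*10", m)) v * 1000 else v),
    list(field = "pt_inr",
         pattern = paste0("(?:pt[- ]?inr|\\binr)[^0-9]{0,12}", .NUM)),
    list(field = "pao2_fio2",
         pattern = paste0("pao2\\s*/\\s*fio2(?: ratio)?[^0-9]{0,12}", .NUM)),
    list(field = "temperature",
         pattern = paste0("(?:temperature|fever)[^0-9]{0,12}", .NUM,
                          "\\s*c\\b")),
    list(field = "dopamine_dose",
         pattern = paste0("dopamine[^0-9]{0,20}", .NUM,
                          "\\s*(?:ug|mcg)\\s*/\\s*kg\\s*/\\s*min")),
    list(field = "wall_thickness",
         pattern = paste0("wall(?: thickness| thickening)?",
                          "[^0-9]{0,18}", .NUM, "\\s*mm\\b")),
    list(field = "polyp_size",
         pattern = paste0("polyp[^0-9]{0,25}", .NUM, "\\s*mm\\b")),
    list(field = "polyp_size",
         pattern = paste0(.NUM, "\\s*mm(?: gallbladder)? polyp")),
    list(field = "symptom_duration",
         pattern = paste0("(?:for(?: the past| the last)?|duration of|",
                          "lasting|over the past)\\s+", .NUM,
                          "\\s*(hours?|h\\b|days?)"),
         post = function(v, m) if (grepl("day", m)) v * 24 else v),
    list(field = "cci",
         pattern = paste0("(?:cci(?: score)?|charlson comorbidity index",
                          "(?: \\(cci\\))?(?: score)?)[^0-9]{0,6}", .NUM))
  )
}

parse_num <- function(x) as.numeric(gsub(",", "", x))

# ---------------------------------------------------------------------------
# extract_features
# ---------------------------------------------------------------------------

#' Extract clinical features from a vignette
#'
#' Deterministic lexicon + pattern extraction: numeric laboratory, vital,
#' imaging, temporal and risk values are pulled with unit normalization
#' (10^3-scaled counts, mg/L CRP, day-denominated durations, Roman-numeral
#' ASA-PS); findings are matched against the surface-form lexicon with simple
#' in-sentence negation handling. Structured fields on the vignette override
#' text-derived values. Duplicate mentions are resolved last-mention-wins and
#' logged as conflicts.
#'
#' @param vignette a `tg18_vignette` (see [clinical_vignette()]) or a
#'   character string of narrative text.
#' @param lexicon lexicon to use; defaults to the shipped one.
#' @return a `tg18_features` object.
#' @export
extract_features <- function(vignette, lexicon = load_lexicon()) {
  if (is.character(vignette)) {
    vignette <- clinical_vignette(id = "adhoc", text = vignette)
  }
  stopifnot(inherits(vignette, "tg18_vignette"))
  text <- vignette$text %||% ""
  structured <- vignette$structured %||% list()
  if (!nzchar(text) && length(structured) == 0L) {
    abort_tg18("vignette has neither narrative text nor structured fields",
               "tg18_schema_error")
  }
  feats <- new_features()
  if (nzchar(text)) {
    folded <- fold_text(text)
    feats <- extract_numeric(feats, folded)
    feats <- extract_bp(feats, folded)
    feats <- extract_flags(feats, folded, lexicon)
    feats <- extract_asa(feats, folded)
    feats <- record_unmapped(feats, folded)
  }
  # Structured fields take precedence over text on conflict.
  for (nm in names(structured)) {
    if (!nm %in% field_names()) {
      abort_tg18(sprintf("unknown structured field '%s'", nm),
                 "tg18_schema_error")
    }
    v <- structured[[nm]]
    if (is.list(v)) {
      feats <- feat_set(feats, nm, value = v$value %||% TRUE,
                        status = v$status %||% "present",
                        source = "structured")
    } else if (isFALSE(v)) {
      feats <- feat_set(feats, nm, value = FALSE, status = "absent",
                        source = "structured")
    } else {
      feats <- feat_set(feats, nm, value = v, status = "present",
                        source = "structured")
    }
  }
  feats
}

extract_numeric <- function(feats, folded) {
  for (rule in numeric_rules()) {
    ms <- gregexpr(rule$pattern, folded, perl = TRUE)[[1]]
    if (ms[1] == -1L) next
    lens <- attr(ms, "match.length")
    for (i in seq_along(ms)) {
      m <- substr(folded, ms[i], ms[i] + lens[i] - 1L)
      # the value is capture group 1, never just the first digit span (the
      # keyword itself may contain digits, e.g. pao2/fio2)
      grp <- regmatches(m, regexec(rule$pattern, m, perl = TRUE))[[1]]
      if (length(grp) < 2L || !nzchar(grp[2])) next
      v <- parse_num(grp[2])
      if (!is.null(rule$post)) v <- rule$post(v, m)
      # last mention wins; feat_set logs the conflict
      feats <- feat_set(feats, rule$field, value = v, status = "present",
                        source = paste0("text:", m))
    }
  }
  feats
}

extract_bp <- function(feats, folded) {
  pat <- paste0("(?:blood pressure|\\bbp\\b)(?: is|:)?\\s*", .NUM,
                "\\s*/\\s*", .NUM)
  ms <- regmatches(folded, gregexpr(pat, folded, perl = TRUE))[[1]]
  for (m in ms) {
    nums <- regmatches(m, gregexpr(.NUM, m, perl = TRUE))[[1]]
    if (length(nums) >= 2) {
      feats <- feat_set(feats, "sbp", value = parse_num(nums[1]),
                        source = paste0("text:", m))
      feats <- feat_set(feats, "dbp", value = parse_num(nums[2]),
                        source = paste0("text:", m))
    }
  }
  feats
}

.negation_re <-"(?:\\bno\\b|\\bwithout\\b|\\bdenies\\b|negative for|\\babsent\\b|\\bnot\\b)"

extract_flags <- function(feats, folded, lexicon) {
  flag_fields <- field_names()[field_type(field_names()) == "flag"]
  lx <- lexicon[lexicon$concept %in% flag_fields, , drop = FALSE]
  # longest surface first so e.g. "sonographic murphy sign" claims its span
  # before "murphy sign" can
  lx <- lx[order(-nchar(lx$folded)), , drop = FALSE]
  claimed <- matrix(numeric(0), ncol = 2)
  punct_folded <- gsub("'", "", folded)
  # sentence/clause boundaries survive folding so negation cannot leak
  # across them
  punct_folded <- gsub("[.;]", " . ", punct_folded)
  punct_folded <- gsub("(?![.])[[:punct:]]+", " ", punct_folded,
                       perl = TRUE)
  punct_folded <- gsub("\\s+", " ", punct_folded)
  for (i in seq_len(nrow(lx))) {
    pat <- paste0("\\b", gsub(" ", "\\\\s+", lx$folded[i]), "\\b")
    ms <- gregexpr(pat, punct_folded, perl = TRUE)[[1]]
    if (ms[1] == -1L) next
    lens <- attr(ms, "match.length")
    for (j in seq_along(ms)) {
      span <- c(ms[j], ms[j] + lens[j] - 1L)
      if (nrow(claimed) &&
          any(span[1] <= claimed[, 2] & span[2] >= claimed[, 1])) next
      claimed <- rbind(claimed, span)
      ctx_start <- max(1L, span[1] - 30L)
      ctx <- substr(punct_folded, ctx_start, span[1] - 1L)
      # negation scope does not cross a sentence boundary (folded '.' was
      # replaced by space, so approximate with the 30-char window)
      negated <- grepl(paste0(.negation_re, "[^.]{0,25}$"), ctx, perl = TRUE)
      fld <- lx$concept[i]
      if (negated) {
        feats <- feat_set(feats, fld, value = FALSE, status = "absent",
                          source = paste0("text:", lx$surface[i]))
      } else if (!feat_present(feats, fld)) {
        feats <- feat_set(feats, fld, value = TRUE, status = "present",
                          source = paste0("text:", lx$surface[i]))
      }
    }
  }
  feats
}

extract_asa <- function(feats, folded) {
  pat <- paste0("asa[- ]?ps(?: classification| class| status| score)?",
                "(?: of| is|:)?\\s*(vi|iv|v|iii|ii|i|[1-6])\\b")
  ms <- regmatches(folded, gregexpr(pat, folded, perl = TRUE))[[1]]
  for (m in ms) {
    tok <- sub(pat, "\\1", m, perl = TRUE)
    v <- roman_to_int(tok)
    if (!is.na(v)) {
      feats <- feat_set(feats, "asa_ps", value = v, status = "present",
                        source = paste0("text:", m))
    }
  }
  feats
}

# Numeric spans with a clinical unit that no rule claimed are recorded, never
# silently dropped.
record_unmapped <- function(feats, folded) {
  unit_pat <- paste0(.NUM, "\\s*(?:mg\\s*/\\s*dl|/\\s*ul|mm\\b|\\bc\\b)")
  spans <- regmatches(folded, gregexpr(unit_pat, folded, perl = TRUE))[[1]]
  known <- vapply(Filter(function(f) f$status != "unknown",
                         feats$fields), function(f) {
    if (is.numeric(f$value)) f$value else NA_real_
  }, numeric(1))
  known <- known[!is.na(known)]
  for (s in spans) {
    v <- parse_num(regmatches(s, regexpr(.NUM, s, perl = TRUE)))
    # also accept values that were unit-rescaled on capture
    if (!any(abs(known - v) < 1e-9) && !any(abs(known - v * 1000) < 1e-9) &&
        !any(abs(known - v * 24) < 1e-9)) {
      feats$unmapped[[length(feats$unmapped) + 1L]] <- s
    }
  }
  feats
}
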