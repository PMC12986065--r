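# ---------------------------------------------------------------------------
# ClinicalVignette container
# ---------------------------------------------------------------------------

.vignette_keys <- c("id", "category", "domain", "text", "structured",
                    "question", "options", "gold")

#' Construct a clinical vignette
#'
#' A vignette couples a case narrative (and/or structured clinical fields)
#' with an optional multiple-choice question: a stem, five options A-E and a
#' gold answer, plus stratification tags (disease category, clinical domain).
#'
#' @param id item identifier.
#' @param text narrative text.
#' @param structured named list of canonical feature fields overriding the
#'   text (values, or `FALSE` for explicitly-absent findings).
#' @param question question stem.
#' @param options named character vector (names `A`..`E`).
#' @param gold gold option letter, if known.
#' @param category disease-category tag.
#' @param domain clinical-domain tag (`diagnosis`, `treatment`,
#'   `complications`).
#' @return an object of class `tg18_vignette`.
#' @export
clinical_vignette <- function(id, text = "", structured = list(),
                              question = NULL, options = NULL, gold = NULL,
                              category = NULL, domain = NULL) {
  if ((is.null(text) || !nzchar(text)) && length(structured) == 0L) {
    abort_tg18("vignette needs narrative text or structured fields",
               "tg18_validation_error")
  }
  if (!is.null(options)) {
    if (is.null(names(options)) || any(!nzchar(names(options)))) {
      abort_tg18("options must be a named vector (A..E)",
                 "tg18_validation_error")
    }
    if (!all(names(options) %in% LETTERS[1:5])) {
      abort_tg18("option names must be letters A..E", "tg18_validation_error")
    }
  }
  if (!is.null(gold)) {
    if (is.null(options) || !gold %in% names(options)) {
      abort_tg18("gold answer must name one of the options",
                 "tg18_validation_error")
    }
  }
  bad <- setdiff(names(structured), field_names())
  if (length(bad)) {
    abort_tg18(sprintf("unknown structured field '%s'", bad[1]),
               "tg18_schema_error")
  }
  structure(list(id = id, category = category, domain = domain, text = text,
                 structured = structured, question = question,
                 options = options, gold = gold),
            class = "tg18_vignette")
}

#' @export
print.tg18_vignette <- function(x, ...) {
  cat(sprintf("<tg18_vignette> %s%s%s\n", x$id,
              if (!is.null(x$category)) paste0(" [", x$category, "]") else "",
              if (!is.null(x$domain)) paste0(" [", x$domain, "]") else ""))
  if (nzchar(x$text)) cat(strwrap(x$text, 76, prefix = "  "), sep = "\n")
  if (!is.null(x$question)) cat("  Q:", x$question, "\n")
  for (o in names(x$options %||% character(0))) {
    cat(sprintf("   (%s) %s%s\n", o, x$options[[o]],
                if (identical(x$gold, o)) " *" else ""))
  }
  invisible(x)
}
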