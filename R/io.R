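#' @importFrom jsonlite fromJSON toJSON write_json read_json
NULL

# ---------------------------------------------------------------------------
# File formats: vignettes and banks as JSON, response matrices as CSV,
# reports as JSON or text tables. All round-trips are lossless.
# ---------------------------------------------------------------------------

vignette_from_list <- function(x, where = "vignette") {
  extra <- setdiff(names(x), .vignette_keys)
  if (length(extra)) {
    abort_tg18(sprintf("%s: unknown field(s) %s", where,
                       paste(extra, collapse = ", ")),
               "tg18_validation_error")
  }
  for (req in c("id")) {
    if (is.null(x[[req]])) {
      abort_tg18(sprintf("%s: missing required field '%s'", where, req),
                 "tg18_validation_error")
    }
  }
  if (!is.null(x$question) && is.null(x$options)) {
    abort_tg18(sprintf("%s: question present but options list missing",
                       where), "tg18_validation_error")
  }
  opts <- if (!is.null(x$options)) unlist(x$options) else NULL
  clinical_vignette(id = x$id, text = x$text %||% "",
                    structured = x$structured %||% list(),
                    question = x$question, options = opts,
                    gold = x$gold, category = x$category,
                    domain = x$domain)
}

vignette_to_list <- function(vg) {
  out <- list(id = vg$id)
  if (!is.null(vg$category)) out$category <- vg$category
  if (!is.null(vg$domain)) out$domain <- vg$domain
  if (nzchar(vg$text %||% "")) out$text <- vg$text
  if (length(vg$structured)) out$structured <- vg$structured
  if (!is.null(vg$question)) out$question <- vg$question
  if (!is.null(vg$options)) out$options <- as.list(vg$options)
  if (!is.null(vg$gold)) out$gold <- vg$gold
  out
}

#' Read a vignette or question bank from JSON
#'
#' A single vignette is an object; a bank is an object with an `items` array
#' (and optional `truth` table). Schemas are validated strictly: unknown
#' fields are rejected with their location.
#'
#' @param path JSON file path.
#' @return a `tg18_vignette` or `tg18_bank`.
#' @export
read_vignette_file <- function(path) {
  if (!file.exists(path)) {
    abort_tg18(sprintf("file not found: %s", path), "tg18_io_error")
  }
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(x$items)) {
    items <- lapply(seq_along(x$items), function(i) {
      vignette_from_list(x$items[[i]], where = sprintf("items[%d]", i))
    })
    names(items) <- vapply(items, `[[`, character(1), "id")
    truth <- if (!is.null(x$truth)) {
      do.call(rbind, lapply(x$truth, function(row) {
        as.data.frame(lapply(row, function(v) if (is.null(v)) NA else v),
                      stringsAsFactors = FALSE)
      }))
    } else NULL
    structure(list(items = items, truth = truth, spec = NULL),
              class = "tg18_bank")
  } else {
    vignette_from_list(x)
  }
}

#' Write a vignette or question bank to JSON
#'
#' @param x a `tg18_vignette` or `tg18_bank`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vignette_file <- function(x, path) {
  payload <- if (inherits(x, "tg18_bank")) {
    out <- list(items = lapply(unname(x$items), vignette_to_list))
    if (!is.null(x$truth)) {
      out$truth <- lapply(seq_len(nrow(x$truth)), function(i) {
        as.list(x$truth[i, , drop = FALSE])
      })
    }
    out
  } else if (inherits(x, "tg18_vignette")) {
    vignette_to_list(x)
  } else {
    abort_tg18("x must be a tg18_vignette or tg18_bank",
               "tg18_validation_error")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a response matrix from CSV
#'
#' @param responses_path CSV with columns `respondent_id`, `group`,
#'   `item_id`, `selection`.
#' @param key_path CSV with columns `item_id`, `key` and optional `domain`,
#'   `category`.
#' @return a `tg18_response_matrix`.
#' @export
read_response_matrix <- function(responses_path, key_path) {
  response_matrix(utils::read.csv(responses_path, stringsAsFactors = FALSE),
                  utils::read.csv(key_path, stringsAsFactors = FALSE))
}

#' Write a response matrix to CSV
#'
#' @param matrix a `tg18_response_matrix`.
#' @param responses_path,key_path output paths.
#' @return `responses_path`, invisibly.
#' @export
write_response_matrix <- function(matrix, responses_path, key_path) {
  utils::write.csv(matrix$responses, responses_path, row.names = FALSE)
  utils::write.csv(matrix$key, key_path, row.names = FALSE)
  invisible(responses_path)
}

assessment_to_list <- function(a) {
  list(
    diagnosis_class = a$diagnosis_class,
    domain_status = lapply(a$domain_status, function(d) {
      list(met = d$met, criteria = as.list(d$criteria))
    }),
    severity_grade = a$grade,
    grade_basis = lapply(a$grade_basis, activation_to_list),
    special_conditions = lapply(unname(a$special_conditions), function(sc) {
      list(condition = sc$condition, type = sc$type, rule = sc$rule)
    }),
    risk_level = a$risk_level,
    management = if (!is.null(a$management)) {
      list(rule = a$management$rule, action = a$management$action,
           narrative = a$management$narrative)
    },
    trace = lapply(a$trace, activation_to_list))
}

activation_to_list <- function(act) {
  list(rule = act$rule, domain_tag = act$domain_tag, label = act$label,
       system = act$system, condition = act$condition,
       conclusion = act$conclusion,
       matched = lapply(act$matched, function(m) {
         list(field = m$field, observed = m$observed,
              operator = m$operator, threshold = m$threshold,
              units = m$units)
       }))
}

report_to_list <- function(r) {
  list(
    respondents = r$respondents, groups = r$groups,
    by_domain = r$by_domain, by_category = r$by_category,
    auc = as.list(r$auc), roc_mode = r$roc_mode,
    fleiss = lapply(r$fleiss, function(k) {
      out <- list(kappa = k$kappa, p_bar = k$p_bar, p_e = k$p_e)
      if (!is.null(k$ci)) out$ci <- k$ci
      out
    }),
    tests = list(anova = r$tests$anova, tukey = r$tests$tukey,
                 pairwise_t = r$tests$pairwise_t),
    overall = r$overall)
}

#' Write an assessment or evaluation report to disk
#'
#' JSON output is lossless (assessments serialize with their full
#' rule-activation trace); text output renders the human-readable tables.
#' Every write logs the rule-file version and seed when supplied.
#'
#' @param report a `tg18_assessment` or `tg18_evaluation_report`.
#' @param path output file.
#' @param format `"json"` or `"text"`.
#' @param kg optional `tg18_kg`; its rule-set version is stamped into the
#'   output.
#' @param seed optional seed to stamp into the output.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "text"),
                         kg = NULL, seed = NULL) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort_tg18(sprintf("directory does not exist: %s", dir),
               "tg18_io_error")
  }
  meta <- list(ruleset_version = if (!is.null(kg))
    kg$ruleset$version %||% "unversioned" else NULL, seed = seed)
  meta <- Filter(Negate(is.null), meta)
  if (format == "json") {
    body <- if (inherits(report, "tg18_assessment")) {
      assessment_to_list(report)
    } else if (inherits(report, "tg18_evaluation_report")) {
      report_to_list(report)
    } else {
      abort_tg18("unsupported report object", "tg18_validation_error")
    }
    payload <- c(list(kind = class(report)[1]), meta, list(report = body))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null",
                         dataframe = "rows")
  } else {
    txt <- utils::capture.output(print(report))
    if (length(meta)) {
      txt <- c(sprintf("# %s", paste(names(meta), unlist(meta), sep = "=",
                                     collapse = " ")), txt)
    }
    writeLines(txt, path)
  }
  invisible(path)
}

#' Read a JSON evaluation report back
#'
#' @param path JSON file written by [write_report()].
#' @return the parsed report payload (list).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' The shipped validation vignette
#'
#' The worked example distributed with the package: a Grade III
#' emphysematous cholecystitis presentation with multi-organ dysfunction and
#' high surgical risk, whose gold answer is urgent percutaneous
#' cholecystostomy with organ support.
#'
#' @return a `tg18_vignette`.
#' @export
validation_vignette <- function() {
  read_vignette_file(system.file("extdata", "validation_vignette.json",
                                 package = "tg18cds"))
}
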