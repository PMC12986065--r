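# ---------------------------------------------------------------------------
# Pluggable agents and four-stage consensus arbitration:
# vote -> constraint filter -> uncertainty -> selection.
# ---------------------------------------------------------------------------

#' Construct an agent response
#'
#' @param agent_id agent identifier.
#' @param selected_option option letter (`A`..`E`), or `NA` when abstaining.
#' @param confidence calibrated confidence in `[0, 1]`.
#' @param reasoning free-text reasoning.
#' @param key_findings character vector of extracted findings.
#' @param assessment optional `tg18_assessment` backing the response.
#' @param option_text the text of the selected option, when known (used by
#'   the constraint checker to decode the claim).
#' @param abstained logical abstention flag.
#' @return an object of class `tg18_agent_response`.
#' @export
agent_response <- function(agent_id, selected_option, confidence,
                           reasoning = "", key_findings = character(0),
                           assessment = NULL, option_text = NULL,
                           abstained = FALSE) {
  if (!abstained) {
    if (is.na(selected_option) || !selected_option %in% LETTERS[1:5]) {
      abort_tg18("selected_option must be one of A..E",
                 "tg18_validation_error")
    }
  }
  if (!is.numeric(confidence) || confidence < 0 || confidence > 1) {
    abort_tg18("confidence must lie in [0, 1]", "tg18_validation_error")
  }
  structure(list(agent_id = agent_id, selected_option = selected_option,
                 confidence = confidence, reasoning = reasoning,
                 key_findings = key_findings, assessment = assessment,
                 option_text = option_text, abstained = abstained),
            class = "tg18_agent_response")
}

#' Adapter configuration for agents and arbitration
#'
#' Mirrors the data-collection settings for generative agents: sampling
#' temperature 0.1 and three independent runs by default. The seed drives
#' every stochastic step of arbitration (uncertainty resampling).
#'
#' @param temperature sampling temperature for external generative agents.
#' @param runs number of independent runs.
#' @param seed integer seed.
#' @param perturb_sd standard deviation of the confidence perturbation used
#'   for uncertainty quantification.
#' @param n_samples number of uncertainty resamples.
#' @return a list of class `tg18_agent_config`.
#' @export
agent_config <- function(temperature = 0.1, runs = 3, seed = 1,
                         perturb_sd = 0.05, n_samples = 200) {
  stopifnot(temperature >= 0, runs >= 1, n_samples >= 1, perturb_sd >= 0)
  structure(list(temperature = temperature, runs = runs, seed = seed,
                 perturb_sd = perturb_sd, n_samples = n_samples),
            class = "tg18_agent_config")
}

#' Deterministic symbolic reference agent
#'
#' Runs the TG18 engine on the vignette and selects the option whose text
#' matches the engine's conclusions (diagnosis class, grade, special
#' conditions, management action) under canonical-concept phrase matching.
#' Confidence is the fraction of the four decision slots (diagnosis, grade,
#' risk, action) the engine resolved; 1.0 when all four are resolved and
#' exactly one option matches. Ties or a zero-match option pool yield an
#' abstention with confidence 0.
#'
#' @param vignette a `tg18_vignette` carrying at least two options.
#' @param kg a `tg18_kg`.
#' @return a `tg18_agent_response`.
#' @export
symbolic_agent_answer <- function(vignette, kg = build_knowledge_graph()) {
  stopifnot(inherits(vignette, "tg18_vignette"))
  if (length(vignette$options %||% character(0)) < 2L) {
    abort_tg18("symbolic agent requires a question with at least two options",
               "tg18_validation_error")
  }
  features <- extract_features(vignette)
  assessment <- tryCatch(
    assess_vignette(vignette, kg, features = features),
    tg18_unknown_risk = function(e) NULL)
  if (is.null(assessment)) {
    # risk scores absent: assemble the partial assessment by hand
    dx <- classify_diagnosis(features, kg)
    gs <- if (dx$diagnosis_class != "not-cholecystitis") {
      grade_severity(features, kg)
    } else list(grade = NA_character_, grade_basis = list())
    assessment <- structure(list(
      diagnosis_class = dx$diagnosis_class, domain_status = dx$domain_status,
      grade = gs$grade, grade_basis = gs$grade_basis,
      special_conditions = detect_special_conditions(features, kg),
      risk_level = NA_character_, management = NULL,
      trace = dx$activations), class = "tg18_assessment")
  }

  concepts <- assessment_concepts(assessment)
  tbl <- concept_phrases()
  scores <- vapply(vignette$options, function(opt) {
    sum(vapply(concepts, function(cc) {
      !is.null(tbl[[cc]]) && phrase_hits(opt, tbl[[cc]])
    }, logical(1)))
  }, numeric(1))

  slots <- c(diagnosis = TRUE,
             grade = !is.na(assessment$grade) ||
               assessment$diagnosis_class == "not-cholecystitis",
             risk = !is.na(assessment$risk_level),
             action = !is.null(assessment$management) ||
               assessment$diagnosis_class == "not-cholecystitis")
  resolved_frac <- mean(slots)

  top <- max(scores)
  winners <- names(scores)[scores == top]
  key_findings <- names(Filter(function(f) f$status == "present",
                               features$fields))
  if (top == 0 || length(winners) > 1L) {
    return(agent_response(
      agent_id = "tg18-symbolic", selected_option = NA_character_,
      confidence = 0,
      reasoning = if (top == 0) {
        "No option matches the engine's TG18 conclusions."
      } else {
        sprintf("Options %s tie under concept-overlap scoring.",
                paste(winners, collapse = ", "))
      },
      key_findings = key_findings, assessment = assessment,
      abstained = TRUE))
  }
  agent_response(
    agent_id = "tg18-symbolic", selected_option = winners,
    confidence = resolved_frac,
    reasoning = paste0("TG18 engine conclusion: ",
                       paste(concepts, collapse = ", "),
                       "; option ", winners, " uniquely matches."),
    key_findings = key_findings, assessment = assessment,
    option_text = vignette$options[[winners]])
}

#' Simulated noisy agent (test double for external generative models)
#'
#' Answers the gold option with probability `1 - error_rate`, otherwise a
#' uniformly chosen wrong option. Confidence is drawn from Beta
#' distributions moment-matched to typical calibrated agents (higher when
#' correct). Fully reproducible under `seed`.
#'
#' @param question a `tg18_vignette` with options (or a character vector of
#'   option letters).
#' @param gold gold option letter.
#' @param error_rate error probability in `[0, 1]`.
#' @param seed integer seed.
#' @param agent_id agent identifier.
#' @return a `tg18_agent_response`.
#' @export
simulated_agent_answer <- function(question, gold, error_rate = 0.1,
                                   seed = 1, agent_id = "sim-agent") {
  stopifnot(error_rate >= 0, error_rate <= 1)
  letters_pool <- if (inherits(question, "tg18_vignette")) {
    names(question$options)
  } else question
  if (!gold %in% letters_pool) {
    abort_tg18("gold option not among the question's options",
               "tg18_validation_error")
  }
  with_seed(seed, {
    correct <- stats::runif(1) >= error_rate
    sel <- if (correct) gold else sample(setdiff(letters_pool, gold), 1L)
    conf <- if (correct) stats::rbeta(1, 32.7, 2.5) else stats::rbeta(1, 57.3, 22.3)
    agent_response(agent_id = agent_id, selected_option = sel,
                   confidence = conf,
                   reasoning = "simulated response",
                   option_text = if (inherits(question, "tg18_vignette"))
                     question$options[[sel]] else NULL)
  })
}

# ---------------------------------------------------------------------------
# Constraint checking
# ---------------------------------------------------------------------------

decode_claim <- function(response) {
  if (!is.null(response$assessment)) {
    return(list(grade = response$assessment$grade,
                action = response$assessment$management$action %||% NA,
                immediate_surgery = FALSE, decodable = TRUE))
  }
  txt <- response$option_text
  if (is.null(txt) || !nzchar(txt)) {
    return(list(grade = NA, action = NA, immediate_surgery = NA,
                decodable = FALSE))
  }
  folded <- fold_term(txt)
  grade <- if (grepl("\\bgrade iii\\b", folded)) "III"
  else if (grepl("\\bgrade ii\\b", folded)) "II"
  else if (grepl("\\bgrade i\\b", folded)) "I"
  else NA_character_
  immediate <- grepl("cholecystectomy", folded) &&
    !grepl("delayed|elective|interval|followed by", folded)
  list(grade = grade, action = NA, immediate_surgery = immediate,
       decodable = TRUE)
}

.grade_rank <- c(I = 1L, II = 2L, III = 3L)

#' Check an agent response against hard guideline constraints
#'
#' Decodes the claim carried by the response (its assessment if present,
#' otherwise its option text) and compares it with what the rules conclude
#' from the case features. Two constraint families are enforced: severity
#' undergrading (claiming a grade below one whose criteria are satisfied,
#' e.g. Grade I despite a white-cell count above the Grade II threshold) and
#' recommending immediate cholecystectomy when Grade III criteria with
#' hemodynamic instability are present. An undecodable claim yields an
#' indeterminate (admissible) verdict, logged on the result.
#'
#' @param response a `tg18_agent_response`.
#' @param features the case's `tg18_features`.
#' @param kg a `tg18_kg`.
#' @return list of violation records (empty when admissible); attribute
#'   `indeterminate` is TRUE when the claim could not be decoded.
#' @export
check_constraints <- function(response, features, kg) {
  claim <- decode_claim(response)
  if (!claim$decodable) {
    return(structure(list(), indeterminate = TRUE))
  }
  gs <- grade_severity(features, kg)
  violations <- list()
  if (!is.na(claim$grade) && !is.na(gs$grade) &&
      .grade_rank[[claim$grade]] < .grade_rank[[gs$grade]]) {
    evidence <- vapply(gs$grade_basis, function(a) {
      paste0(a$rule, ": ", a$label)
    }, character(1))
    violations[[length(violations) + 1L]] <- list(
      type = "severity_undergrade",
      detail = sprintf(
        "claimed Grade %s but Grade %s criteria are satisfied (%s)",
        claim$grade, gs$grade, paste(evidence, collapse = "; ")))
  }
  cv_unstable <- any(vapply(gs$grade_basis, function(a) {
    identical(a$system, "cardiovascular")
  }, logical(1)))
  if (isTRUE(claim$immediate_surgery) && gs$grade == "III" && cv_unstable) {
    violations[[length(violations) + 1L]] <- list(
      type = "surgery_contraindicated",
      detail = paste("immediate cholecystectomy recommended despite Grade",
                     "III criteria with hemodynamic instability"))
  }
  structure(violations, indeterminate = FALSE)
}

# ---------------------------------------------------------------------------
# Voting, uncertainty, arbitration
# ---------------------------------------------------------------------------

#' Confidence-weighted vote tally
#'
#' Each response contributes its confidence score to the tally of its
#' selected option; no normalization is applied.
#'
#' @param responses list of `tg18_agent_response`.
#' @return named numeric vector, options sorted lexicographically.
#' @export
confidence_weighted_vote <- function(responses) {
  if (length(responses) < 1L) {
    abort_tg18("at least one response is required", "tg18_validation_error")
  }
  responses <- Filter(function(r) !isTRUE(r$abstained), responses)
  opts <- vapply(responses, `[[`, character(1), "selected_option")
  confs <- vapply(responses, `[[`, numeric(1), "confidence")
  tally <- tapply(confs, opts, sum)
  tally <- tally[order(names(tally))]
  stats::setNames(as.numeric(tally), names(tally))
}

vote_winner <- function(tally) {
  if (!length(tally)) return(NA_character_)
  top <- names(tally)[tally == max(tally)]
  sort(top)[1]  # lexicographic tie-break
}

#' Quantify decision uncertainty by confidence perturbation
#'
#' Seeded Gaussian perturbation of the confidence scores (clipped to
#' `[0, 1]`) with vote recomputation; the score is the fraction of resamples
#' whose winning option differs from the unperturbed winner. A unanimous
#' panel therefore scores 0.
#'
#' @param responses list of `tg18_agent_response`.
#' @param n_samples number of resamples (>= 1).
#' @param seed integer seed.
#' @param perturb_sd perturbation standard deviation.
#' @return uncertainty score in `[0, 1]`.
#' @export
quantify_uncertainty <- function(responses, n_samples = 200, seed = 1,
                                 perturb_sd = 0.05) {
  stopifnot(n_samples >= 1)
  responses <- Filter(function(r) !isTRUE(r$abstained), responses)
  if (!length(responses)) return(0)
  base <- vote_winner(confidence_weighted_vote(responses))
  opts <- vapply(responses, `[[`, character(1), "selected_option")
  confs <- vapply(responses, `[[`, numeric(1), "confidence")
  with_seed(seed, {
    flips <- vapply(seq_len(n_samples), function(i) {
      pc <- pmin(1, pmax(0, confs + stats::rnorm(length(confs), 0,
                                                 perturb_sd)))
      tally <- tapply(pc, opts, sum)
      vote_winner(stats::setNames(as.numeric(tally), names(tally))) != base
    }, logical(1))
    mean(flips)
  })
}

#' Arbitrate agent responses into a consensus answer
#'
#' Four deterministic stages: (1) confidence-weighted voting over all
#' responses; (2) symbolic constraint filtering, removing responses that
#' breach hard guideline constraints; (3) uncertainty quantification by
#' seeded confidence perturbation; (4) final selection. If all admissible
#' agents agree, the final confidence is the arithmetic mean of their
#' confidences; if they disagree, the admissible option with the highest
#' weighted vote wins (ties broken by option label with a low-confidence
#' flag); if every response violates constraints, the engine's symbolic
#' answer is substituted and noted.
#'
#' @param responses list of `tg18_agent_response` (>= 1).
#' @param features case features (enables constraint checking; optional).
#' @param kg a `tg18_kg` (optional, required for constraint checking).
#' @param config a [agent_config()].
#' @param vignette the vignette (required only for the all-violating
#'   fallback and abstention repair).
#' @return an object of class `tg18_consensus`.
#' @export
arbitrate <- function(responses, features = NULL, kg = NULL,
                      config = agent_config(), vignette = NULL) {
  if (length(responses) < 1L) {
    abort_tg18("cannot arbitrate an empty response list",
               "tg18_validation_error")
  }
  # permutation invariance: canonical ordering by (agent_id, option)
  ord <- order(vapply(responses, `[[`, character(1), "agent_id"),
               vapply(responses, function(r) {
                 if (is.na(r$selected_option %||% NA_character_)) "Z"
                 else r$selected_option
               }, character(1)))
  responses <- responses[ord]

  active <- Filter(function(r) !isTRUE(r$abstained), responses)
  if (!length(active)) {
    abort_tg18("all responses abstained", "tg18_validation_error")
  }
  tally <- confidence_weighted_vote(active)

  violations <- lapply(active, function(r) {
    if (is.null(features) || is.null(kg)) list()
    else check_constraints(r, features, kg)
  })
  names(violations) <- vapply(active, `[[`, character(1), "agent_id")
  admissible <- active[vapply(violations, length, integer(1)) == 0L]

  note <- NULL
  low_confidence <- FALSE
  if (length(admissible) == 0L) {
    if (is.null(vignette) || is.null(kg)) {
      abort_tg18(paste("every response violates constraints and no vignette",
                       "was supplied for the symbolic fallback"),
                 "tg18_validation_error")
    }
    fb <- symbolic_agent_answer(vignette, kg)
    final_option <- fb$selected_option
    final_confidence <- fb$confidence
    note <- "all agent responses rejected by constraint checking; symbolic engine answer substituted"
    unc <- quantify_uncertainty(active, config$n_samples, config$seed,
                                config$perturb_sd)
  } else {
    adm_opts <- vapply(admissible, `[[`, character(1), "selected_option")
    adm_confs <- vapply(admissible, `[[`, numeric(1), "confidence")
    unc <- quantify_uncertainty(admissible, config$n_samples, config$seed,
                                config$perturb_sd)
    if (length(unique(adm_opts)) == 1L) {
      final_option <- adm_opts[1]
      final_confidence <- mean(adm_confs)
      if (length(admissible) < length(active)) {
        note <- "disagreement resolved by constraint filtering"
      }
    } else {
      adm_tally <- confidence_weighted_vote(admissible)
      top <- names(adm_tally)[adm_tally == max(adm_tally)]
      final_option <- sort(top)[1]
      if (length(top) > 1L) {
        low_confidence <- TRUE
        note <- paste("tie between options", paste(sort(top), collapse = ", "),
                      "broken lexicographically")
      } else {
        note <- "disagreement resolved by confidence-weighted voting"
      }
      final_confidence <- mean(adm_confs[adm_opts == final_option])
    }
  }
  structure(list(
    final_option = final_option,
    final_confidence = final_confidence,
    vote_tally = tally,
    violations = violations,
    uncertainty = unc,
    low_confidence = low_confidence,
    resolution_note = note,
    n_responses = length(active),
    n_admissible = length(admissible)
  ), class = "tg18_consensus")
}

#' @export
print.tg18_consensus <- function(x, ...) {
  cat("<tg18_consensus>\n")
  cat("  Final answer:    ", x$final_option, "\n")
  cat("  Final confidence:", format(x$final_confidence), "\n")
  cat("  Vote tally:      ",
      paste(sprintf("%s=%.3f", names(x$vote_tally), x$vote_tally),
            collapse = ", "), "\n")
  nv <- sum(vapply(x$violations, length, integer(1)) > 0)
  cat("  Violations:      ", nv, "agent(s)\n")
  cat("  Uncertainty:     ", format(x$uncertainty), "\n")
  if (!is.null(x$resolution_note)) cat("  Note:", x$resolution_note, "\n")
  invisible(x)
}
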