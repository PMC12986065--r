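#' @importFrom yaml read_yaml
#' @importFrom igraph make_empty_graph add_vertices add_edges V E
#'   is_dag subgraph_from_edges distances vcount ecount
NULL

.allowed_criterion_keys <- c("id", "domain_tag", "label", "match",
                             "predicates", "citation", "system", "condition",
                             "source")
.allowed_predicate_keys <- c("field", "operator", "threshold", "units")
.domain_tags <- c("A", "B", "C", "gradeII", "gradeIII-organ", "special")
.operators <- c(">", ">=", "<", "<=", "==", "present")

#' Load a declarative TG18 rule set
#'
#' Rules live in a versioned YAML file, not in code, so the knowledge base can
#' be revised when the guideline is. The shipped default encodes the TG18
#' diagnostic domains, severity grades, surgical-risk rule and management
#' grid. The loader is strict: unknown keys, unknown feature fields, unknown
#' operators and duplicate rule ids are rejected.
#'
#' @param path YAML rule file; defaults to the shipped TG18 set.
#' @return a validated rule set (class `tg18_ruleset`).
#' @export
load_ruleset <- function(path = system.file("extdata", "tg18_rules.yaml",
                                            package = "tg18cds")) {
  rs <- yaml::read_yaml(path)
  rs$criteria <- rs$criteria %||% list()
  ids <- vapply(rs$criteria, function(cr) cr$id %||% "", character(1))
  if (anyDuplicated(ids)) {
    abort_tg18(sprintf("duplicate rule id(s): %s",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")),
               "tg18_validation_error")
  }
  for (cr in rs$criteria) {
    extra <- setdiff(names(cr), .allowed_criterion_keys)
    if (length(extra)) {
      abort_tg18(sprintf("rule '%s': unknown key(s) %s", cr$id %||% "?",
                         paste(extra, collapse = ", ")),
                 "tg18_validation_error")
    }
    if (is.null(cr$id) || is.null(cr$domain_tag) || is.null(cr$predicates)) {
      abort_tg18("each criterion needs id, domain_tag and predicates",
                 "tg18_validation_error")
    }
    if (!cr$domain_tag %in% .domain_tags) {
      abort_tg18(sprintf("rule '%s': invalid domain_tag '%s'", cr$id,
                         cr$domain_tag), "tg18_validation_error")
    }
    if (!(cr$match %||% "any") %in% c("any", "all")) {
      abort_tg18(sprintf("rule '%s': match must be 'any' or 'all'", cr$id),
                 "tg18_validation_error")
    }
    for (p in cr$predicates) {
      extra <- setdiff(names(p), .allowed_predicate_keys)
      if (length(extra)) {
        abort_tg18(sprintf("rule '%s': unknown predicate key(s) %s", cr$id,
                           paste(extra, collapse = ", ")),
                   "tg18_validation_error")
      }
      if (!p$field %in% field_names()) {
        abort_tg18(sprintf("rule '%s': unknown feature field '%s'", cr$id,
                           p$field), "tg18_schema_error")
      }
      if (!p$operator %in% .operators) {
        abort_tg18(sprintf("rule '%s': unknown operator '%s'", cr$id,
                           p$operator), "tg18_validation_error")
      }
      if (p$operator != "present" && is.null(p$threshold)) {
        abort_tg18(sprintf("rule '%s': comparison predicate needs a threshold",
                           cr$id), "tg18_validation_error")
      }
    }
  }
  structure(rs, class = "tg18_ruleset")
}

#' Compile a rule set into a knowledge graph
#'
#' Criteria, diagnostic domains, severity grades, management actions and
#' special conditions become typed nodes; directed edges of type `implies`,
#' `escalates`, `recommends` and `contraindicates` encode diagnostic
#' implications, severity escalation and treatment pathways. Invariants
#' (exactly three grade nodes, acyclic escalation, every grade reachable from
#' a criterion) are enforced at build time.
#'
#' @param ruleset a `tg18_ruleset` from [load_ruleset()], or a path to one.
#' @return an object of class `tg18_kg` with elements `graph` (igraph),
#'   `ruleset`, `criteria` (indexed by id).
#' @export
build_knowledge_graph <- function(ruleset = load_ruleset()) {
  if (is.character(ruleset)) ruleset <- load_ruleset(ruleset)
  stopifnot(inherits(ruleset, "tg18_ruleset"))
  g <- igraph::make_empty_graph(directed = TRUE)
  crit <- ruleset$criteria
  names(crit) <- vapply(crit, `[[`, character(1), "id")

  add_v <- function(g, name, kind) {
    igraph::add_vertices(g, 1, name = name, kind = kind)
  }
  if (length(crit) == 0L) {
    # empty rule file -> empty graph (identity case); invariants vacuous
    return(structure(list(graph = g, ruleset = ruleset, criteria = crit),
                     class = "tg18_kg"))
  }

  for (id in names(crit)) g <- add_v(g, id, "criterion")
  for (d in c("domain:A", "domain:B", "domain:C")) g <- add_v(g, d, "domain")
  for (dx in c("dx:suspected", "dx:definite")) g <- add_v(g, dx, "diagnosis")
  for (gr in c("grade:I", "grade:II", "grade:III")) g <- add_v(g, gr, "grade")
  conds <- unique(unlist(lapply(crit, function(cr) cr$condition)))
  for (cn in conds) g <- add_v(g, paste0("cond:", cn), "condition")
  actions <- unique(vapply(ruleset$management %||% list(), `[[`,
                           character(1), "action"))
  for (a in actions) g <- add_v(g, paste0("action:", a), "action")

  edges <- character(0); etypes <- character(0)
  add_e <- function(from, to, type) {
    edges <<- c(edges, from, to); etypes <<- c(etypes, type)
  }
  for (cr in crit) {
    tgt <- switch(cr$domain_tag,
      A = "domain:A", B = "domain:B", C = "domain:C",
      gradeII = "grade:II", `gradeIII-organ` = "grade:III",
      special = paste0("cond:", cr$condition))
    type <- switch(cr$domain_tag,
      gradeII = "escalates", `gradeIII-organ` = "escalates", "implies")
    add_e(cr$id, tgt, type)
  }
  add_e("domain:A", "dx:suspected", "implies")
  add_e("domain:B", "dx:suspected", "implies")
  add_e("dx:suspected", "dx:definite", "implies")
  add_e("domain:C", "dx:definite", "implies")
  # any confirmed diagnosis is at least mild; grades escalate I -> II -> III
  add_e("dx:suspected", "grade:I", "implies")
  add_e("grade:I", "grade:II", "escalates")
  add_e("grade:II", "grade:III", "escalates")
  for (m in ruleset$management %||% list()) {
    add_e(paste0("grade:", m$grade), paste0("action:", m$action),
          "recommends")
  }
  # Grade III contraindicates immediate surgery (drainage-first pathway)
  for (a in intersect(c("early_lap_chole_72h", "early_lap_chole_expert"),
                      actions)) {
    add_e("grade:III", paste0("action:", a), "contraindicates")
  }
  g <- igraph::add_edges(g, edges, type = etypes)

  # --- invariants ---
  grade_nodes <- igraph::V(g)[igraph::V(g)$kind == "grade"]
  if (length(grade_nodes) != 3L) {
    abort_tg18("knowledge graph must contain exactly three grade nodes",
               "tg18_validation_error")
  }
  esc <- igraph::subgraph_from_edges(g, igraph::E(g)[igraph::E(g)$type ==
                                                       "escalates"],
                                     delete.vertices = FALSE)
  if (!igraph::is_dag(esc)) {
    abort_tg18("escalation edges must be acyclic", "tg18_validation_error")
  }
  crit_nodes <- igraph::V(g)[igraph::V(g)$kind == "criterion"]
  d <- igraph::distances(g, v = crit_nodes, to = grade_nodes,
                         mode = "out")
  if (any(apply(d, 2, function(col) all(!is.finite(col))))) {
    abort_tg18("every grade node must be reachable from a criterion",
               "tg18_validation_error")
  }
  structure(list(graph = g, ruleset = ruleset, criteria = crit),
            class = "tg18_kg")
}

#' @export
print.tg18_kg <- function(x, ...) {
  cat(sprintf("<tg18_kg> %s: %d criteria, %d nodes, %d edges\n",
              x$ruleset$version %||% "unversioned", length(x$criteria),
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Predicate evaluation and rule querying
# ---------------------------------------------------------------------------

eval_predicate <- function(pred, features) {
  f <- features$fields[[pred$field]]
  if (f$status != "present") return(FALSE)
  if (pred$operator == "present") return(!identical(f$value, FALSE))
  v <- f$value
  if (!is.numeric(v)) return(FALSE)
  th <- pred$threshold
  switch(pred$operator,
         ">"  = v > th,
         ">=" = v >= th,
         "<"  = v < th,
         "<=" = v <= th,
         "==" = isTRUE(all.equal(v, th)))
}

criterion_fires <- function(cr, features) {
  hits <- vapply(cr$predicates, eval_predicate, logical(1),
                 features = features)
  if ((cr$match %||% "any") == "all") all(hits) else any(hits)
}

conclusion_node <- function(cr) {
  switch(cr$domain_tag,
         A = "domain:A", B = "domain:B", C = "domain:C",
         gradeII = "grade:II", `gradeIII-organ` = "grade:III",
         special = paste0("cond:", cr$condition))
}

#' Query the knowledge graph against extracted features
#'
#' Evaluates every criterion; returns the activations of exactly those rules
#' whose predicates are satisfied, in deterministic rule-id order, each with
#' the observed evidence (field, value, operator, threshold) and the
#' conclusion node it supports.
#'
#' @param kg a `tg18_kg`.
#' @param features a `tg18_features` object.
#' @return a list of rule activations (class `tg18_activations`).
#' @export
query_rules <- function(kg, features) {
  stopifnot(inherits(kg, "tg18_kg"), inherits(features, "tg18_features"))
  ids <- sort(names(kg$criteria))
  acts <- list()
  for (id in ids) {
    cr <- kg$criteria[[id]]
    if (!criterion_fires(cr, features)) next
    matched <- Filter(Negate(is.null), lapply(cr$predicates, function(p) {
      if (!eval_predicate(p, features)) return(NULL)
      list(field = p$field,
           observed = feat_value(features, p$field),
           operator = p$operator,
           threshold = p$threshold %||% NA,
           units = p$units %||% "")
    }))
    acts[[length(acts) + 1L]] <- structure(
      list(rule = id, domain_tag = cr$domain_tag, label = cr$label %||% id,
           system = cr$system %||% NA_character_,
           condition = cr$condition %||% NA_character_,
           matched = matched, conclusion = conclusion_node(cr)),
      class = "tg18_activation")
  }
  structure(acts, class = "tg18_activations")
}

#' @export
print.tg18_activations <- function(x, ...) {
  cat(sprintf("<tg18_activations> %d rule(s) fired\n", length(x)))
  for (a in x) {
    ev <- vapply(a$matched, function(m) {
      if (m$operator == "present") m$field
      else sprintf("%s %s %s %s (observed %s)", m$field, m$operator,
                   format(m$threshold), m$units, format(m$observed))
    }, character(1))
    cat(sprintf("  %-10s -> %-12s [%s]\n", a$rule, a$conclusion,
                paste(ev, collapse = "; ")))
  }
  invisible(x)
}

#' Tabulate every numeric threshold in a knowledge graph
#'
#' One row per comparison predicate: rule id, field, operator, threshold,
#' units. Used to audit threshold fidelity against the guideline text.
#'
#' @param kg a `tg18_kg`.
#' @return a data.frame sorted by rule id and field.
#' @export
kb_threshold_table <- function(kg) {
  rows <- list()
  for (cr in kg$criteria) {
    for (p in cr$predicates) {
      if (p$operator == "present") next
      rows[[length(rows) + 1L]] <- data.frame(
        rule = cr$id, field = p$field, operator = p$operator,
        threshold = p$threshold, units = p$units %||% "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$rule, out$field), , drop = FALSE]
  rownames(out) <- NULL
  out
}
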