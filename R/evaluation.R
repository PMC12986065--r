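# ---------------------------------------------------------------------------
# Statistical evaluation harness: scoring, exact binomial CIs, ROC/AUC with
# DeLong comparison, agreement statistics, and group tests.
# ---------------------------------------------------------------------------

#' Construct a rater response matrix
#'
#' @param responses data.frame with columns `respondent_id`, `group`,
#'   `item_id`, `selection`.
#' @param key data.frame with columns `item_id`, `key` and optionally
#'   `domain`, `category`.
#' @return an object of class `tg18_response_matrix`.
#' @export
response_matrix <- function(responses, key) {
  need <- c("respondent_id", "group", "item_id", "selection")
  if (!all(need %in% names(responses))) {
    abort_tg18(paste("responses must have columns",
                     paste(need, collapse = ", ")), "tg18_validation_error")
  }
  if (!all(c("item_id", "key") %in% names(key))) {
    abort_tg18("key must have columns item_id, key", "tg18_validation_error")
  }
  if (!all(responses$selection %in% LETTERS[1:5]) ||
      !all(key$key %in% LETTERS[1:5])) {
    abort_tg18("selections and keys must be options A..E",
               "tg18_validation_error")
  }
  if (anyNA(responses$selection)) {
    abort_tg18("response matrix has missing cells", "tg18_validation_error")
  }
  if (!all(responses$item_id %in% key$item_id)) {
    abort_tg18("responses reference items absent from the key",
               "tg18_validation_error")
  }
  # complete grid: every respondent answered every item exactly once
  tab <- table(responses$respondent_id, responses$item_id)
  if (any(tab != 1L)) {
    abort_tg18("every respondent must answer every item exactly once",
               "tg18_validation_error")
  }
  structure(list(responses = responses, key = key),
            class = "tg18_response_matrix")
}

#' Score a response matrix
#'
#' @param matrix a `tg18_response_matrix`.
#' @return data.frame with one row per respondent: `respondent_id`, `group`,
#'   `correct`, `total`, `accuracy` (percent, one decimal, half-up).
#' @export
score_responses <- function(matrix) {
  stopifnot(inherits(matrix, "tg18_response_matrix"))
  r <- matrix$responses
  r$gold <- matrix$key$key[match(r$item_id, matrix$key$item_id)]
  r$correct <- r$selection == r$gold
  agg <- stats::aggregate(correct ~ respondent_id + group, data = r,
                          FUN = function(x) c(sum(x), length(x)))
  out <- data.frame(respondent_id = agg$respondent_id, group = agg$group,
                    correct = agg$correct[, 1], total = agg$correct[, 2],
                    stringsAsFactors = FALSE)
  out$accuracy <- accuracy_pct(out$correct, out$total)
  out[order(out$group, out$respondent_id), , drop = FALSE]
}

#' Percentage accuracy with the print rounding convention
#'
#' @param k correct counts.
#' @param n totals.
#' @return `100 * k / n`, rounded half-up to one decimal.
#' @export
accuracy_pct <- function(k, n) round_half_up(100 * k / n, 1)

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Computed from the beta quantiles underlying [stats::binom.test()];
#' guaranteed to contain the point estimate and conservative in coverage.
#'
#' @param k number of successes.
#' @param n number of trials (> 0).
#' @param level confidence level in (0, 1).
#' @return numeric vector `c(lower, upper)` in percent.
#' @export
binomial_ci <- function(k, n, level = 0.95) {
  if (n <= 0) abort_tg18("n must be positive", "tg18_validation_error")
  stopifnot(k >= 0, k <= n, level > 0, level < 1)
  ci <- stats::binom.test(k, n, conf.level = level)$conf.int
  as.numeric(ci) * 100
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC equals the probability that a randomly chosen positive scores above a
#' randomly chosen negative, with ties counted half:
#' `(concordant + 0.5 * tied) / (n1 * n0)`, computed via midranks.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1/TRUE = positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    abort_tg18("both classes must be present", "tg18_validation_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Placement values: V10[i] = P(score_i beats a random negative), etc.
placements <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  cmp <- function(a, b) (a > b) + 0.5 * (a == b)
  list(v10 = vapply(x, function(a) mean(cmp(a, y)), numeric(1)),
       v01 = vapply(y, function(b) mean(cmp(x, b)), numeric(1)))
}

#' DeLong test for two correlated ROC curves
#'
#' Nonparametric comparison of two AUCs computed on the same cases, with the
#' covariance estimated from placement values.
#'
#' @param scores_a,scores_b score vectors over the same cases.
#' @param labels shared binary labels.
#' @return list with `auc_a`, `auc_b`, `z`, `p` (two-sided), `var_diff`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels)) {
    abort_tg18("scores and labels must have equal length",
               "tg18_validation_error")
  }
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    abort_tg18("both classes must be present", "tg18_validation_error")
  }
  auc_a <- roc_auc(scores_a, labels)
  auc_b <- roc_auc(scores_b, labels)
  pa <- placements(scores_a, labels)
  pb <- placements(scores_b, labels)
  if (identical(scores_a, scores_b)) {
    return(list(auc_a = auc_a, auc_b = auc_b, z = 0, p = 1, var_diff = 0))
  }
  var_diff <- stats::var(pa$v10 - pb$v10) / n1 +
    stats::var(pa$v01 - pb$v01) / n0
  if (var_diff <= .Machine$double.eps) {
    abort_tg18(sprintf(
      "degenerate DeLong variance (%.3e): curves differ nowhere informative",
      var_diff), "tg18_degenerate_variance")
  }
  z <- (auc_a - auc_b) / sqrt(var_diff)
  list(auc_a = auc_a, auc_b = auc_b, z = z, p = 2 * stats::pnorm(-abs(z)),
       var_diff = var_diff)
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for `n >= 2` raters assigning categorical
#' ratings to a set of items, from the items x categories count matrix.
#'
#' @param ratings matrix of counts, rows = items, columns = categories; every
#'   row must sum to the same rater count.
#' @param ci logical: compute a seeded bootstrap confidence interval
#'   (resampling items).
#' @param n_boot bootstrap resamples.
#' @param level confidence level.
#' @param seed bootstrap seed.
#' @return list with `kappa`, `p_bar`, `p_e`, and optionally `ci`.
#' @export
fleiss_kappa <- function(ratings, ci = FALSE, n_boot = 2000, level = 0.95,
                         seed = 1) {
  ratings <- as.matrix(ratings)
  n_raters <- unique(rowSums(ratings))
  if (length(n_raters) != 1L) {
    abort_tg18("every item must be rated by the same number of raters",
               "tg18_validation_error")
  }
  m <- n_raters
  if (m < 2) abort_tg18("need at least two raters", "tg18_validation_error")
  kap <- function(R) {
    pj <- colSums(R) / sum(R)
    pe <- sum(pj^2)
    pi <- (rowSums(R^2) - m) / (m * (m - 1))
    pbar <- mean(pi)
    if (1 - pe < .Machine$double.eps) {
      abort_tg18("expected agreement is 1: kappa undefined",
                 "tg18_degenerate_agreement")
    }
    (pbar - pe) / (1 - pe)
  }
  k <- kap(ratings)
  pj <- colSums(ratings) / sum(ratings)
  out <- list(kappa = k, p_bar = mean((rowSums(ratings^2) - m) /
                                        (m * (m - 1))),
              p_e = sum(pj^2))
  if (ci) {
    out$ci <- with_seed(seed, {
      n <- nrow(ratings)
      ks <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        tryCatch(kap(ratings[idx, , drop = FALSE]),
                 tg18_degenerate_agreement = function(e) NA_real_)
      }, numeric(1))
      stats::quantile(ks, c((1 - level) / 2, 1 - (1 - level) / 2),
                      na.rm = TRUE, names = FALSE)
    })
  }
  out
}

#' Cohen's kappa for two raters
#'
#' @param seq_a,seq_b equal-length categorical vectors.
#' @param ci,n_boot,level,seed bootstrap CI options as in [fleiss_kappa()].
#' @return list with `kappa`, `p_o`, `p_e`, optionally `ci`.
#' @export
cohen_kappa <- function(seq_a, seq_b, ci = FALSE, n_boot = 2000,
                        level = 0.95, seed = 1) {
  if (length(seq_a) == 0L || length(seq_a) != length(seq_b)) {
    abort_tg18("sequences must be non-empty and of equal length",
               "tg18_validation_error")
  }
  kap <- function(a, b) {
    lv <- sort(unique(c(a, b)))
    a <- factor(a, levels = lv); b <- factor(b, levels = lv)
    tab <- table(a, b) / length(a)
    po <- sum(diag(tab))
    pe <- sum(rowSums(tab) * colSums(tab))
    if (1 - pe < .Machine$double.eps) {
      abort_tg18("expected agreement is 1: kappa undefined",
                 "tg18_degenerate_agreement")
    }
    (po - pe) / (1 - pe)
  }
  k <- kap(seq_a, seq_b)
  lv <- sort(unique(c(seq_a, seq_b)))
  tab <- table(factor(seq_a, lv), factor(seq_b, lv)) / length(seq_a)
  out <- list(kappa = k, p_o = sum(diag(tab)),
              p_e = sum(rowSums(tab) * colSums(tab)))
  if (ci) {
    out$ci <- with_seed(seed, {
      n <- length(seq_a)
      ks <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        tryCatch(kap(seq_a[idx], seq_b[idx]),
                 tg18_degenerate_agreement = function(e) NA_real_)
      }, numeric(1))
      stats::quantile(ks, c((1 - level) / 2, 1 - (1 - level) / 2),
                      na.rm = TRUE, names = FALSE)
    })
  }
  out
}

#' McNemar's test from discordant counts
#'
#' Statistic `(b - c)^2 / (b + c)` on a chi-square with one degree of
#' freedom; no continuity correction by default (available by flag).
#'
#' @param b,c discordant pair counts.
#' @param correct apply the continuity correction.
#' @return list with `statistic`, `p`.
#' @export
mcnemar_test <- function(b, c, correct = FALSE) {
  stopifnot(b >= 0, c >= 0)
  if (b + c == 0) {
    abort_tg18("no discordant pairs: McNemar statistic undefined",
               "tg18_degenerate_table")
  }
  d <- abs(b - c)
  if (correct) d <- max(0, d - 1)
  stat <- d^2 / (b + c)
  list(statistic = stat, p = stats::pchisq(stat, df = 1,
                                           lower.tail = FALSE))
}

#' Omnibus and pairwise group comparisons
#'
#' Classical one-way ANOVA with Tukey HSD post hoc comparisons and pairwise
#' Welch t-tests with Bonferroni adjustment.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return list with `anova` (F, df, p), `tukey` (data.frame), `pairwise_t`
#'   (data.frame with raw and Bonferroni-adjusted p).
#' @export
group_tests <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    abort_tg18("need >= 2 groups with >= 2 values each",
               "tg18_validation_error")
  }
  if (all(vapply(groups, function(g) stats::var(g) == 0, logical(1)))) {
    abort_tg18("zero within-group variance in every group",
               "tg18_validation_error")
  }
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), lengths(groups)), levels = names(groups)))
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  pt <- do.call(rbind, lapply(pairs, function(pr) {
    tt <- stats::t.test(groups[[pr[1]]], groups[[pr[2]]])
    data.frame(a = pr[1], b = pr[2], t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  pt$p_bonferroni <- pmin(1, pt$p * nrow(pt))
  list(anova = list(F = an[["F value"]][1],
                    df = c(an[["Df"]][1], an[["Df"]][2]),
                    p = an[["Pr(>F)"]][1]),
       tukey = tukey, pairwise_t = pt)
}

#' Categorical association test with the small-expected-count switch
#'
#' Uses the chi-square test unless any expected cell frequency falls below
#' 5, in which case Fisher's exact test is used; reports which was chosen.
#'
#' @param table contingency table (matrix of non-negative integer counts).
#' @return list with `method` (`"chi-square"` or `"fisher"`), `statistic`
#'   (NA for Fisher), `p`, `expected`.
#' @export
categorical_test <- function(table) {
  table <- as.matrix(table)
  if (length(table) == 0L || sum(table) == 0) {
    abort_tg18("empty contingency table", "tg18_validation_error")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(table)
    list(method = "fisher", statistic = NA_real_, p = ft$p.value,
         expected = expected)
  } else {
    ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    list(method = "chi-square", statistic = unname(ct$statistic),
         p = ct$p.value, expected = expected)
  }
}

# ---------------------------------------------------------------------------
# Full evaluation report
# ---------------------------------------------------------------------------

#' Evaluate a rater cohort on a question bank
#'
#' Produces the full report: per-respondent and per-group accuracy (mean,
#' SD, t-based CI), accuracy stratified by clinical domain and disease
#' category, per-group ROC AUC (ranking responses by the respondent's
#' overall accuracy unless per-response confidences are supplied), omnibus
#' and pairwise group tests, and per-group Fleiss' kappa with a seeded
#' bootstrap CI.
#'
#' @param matrix a `tg18_response_matrix`.
#' @param confidences optional data.frame (`respondent_id`, `item_id`,
#'   `confidence`) switching the ROC score to per-response confidence.
#' @param kappa_ci logical, bootstrap CIs on the kappas.
#' @param seed seed for the bootstrap.
#' @return an object of class `tg18_evaluation_report`.
#' @export
evaluate_matrix <- function(matrix, confidences = NULL, kappa_ci = FALSE,
                            seed = 1) {
  scores <- score_responses(matrix)
  r <- matrix$responses
  key <- matrix$key
  r$gold <- key$key[match(r$item_id, key$item_id)]
  r$correct <- r$selection == r$gold

  group_summary <- do.call(rbind, lapply(split(scores, scores$group),
                                         function(s) {
    n <- nrow(s)
    m <- mean(s$accuracy); sdev <- stats::sd(s$accuracy)
    half <- if (n > 1) stats::qt(0.975, n - 1) * sdev / sqrt(n) else NA
    data.frame(group = s$group[1], n = n, mean_accuracy = round_half_up(m, 1),
               sd = round_half_up(sdev, 1),
               ci_lo = round_half_up(m - half, 1),
               ci_hi = round_half_up(m + half, 1),
               errors = sum(s$total - s$correct),
               error_rate = accuracy_pct(sum(s$total - s$correct),
                                         sum(s$total)),
               stringsAsFactors = FALSE)
  }))
  rownames(group_summary) <- NULL

  strat <- function(tag) {
    if (is.null(key[[tag]])) return(NULL)
    r$stratum <- key[[tag]][match(r$item_id, key$item_id)]
    agg <- stats::aggregate(correct ~ group + stratum, data = r,
                            FUN = function(x) c(sum(x), length(x)))
    data.frame(group = agg$group, stratum = agg$stratum,
               correct = agg$correct[, 1], total = agg$correct[, 2],
               accuracy = accuracy_pct(agg$correct[, 1], agg$correct[, 2]),
               stringsAsFactors = FALSE)
  }

  roc_mode <- if (is.null(confidences)) "respondent-accuracy" else
    "response-confidence"
  if (is.null(confidences)) {
    r$score <- scores$accuracy[match(r$respondent_id,
                                     scores$respondent_id)] / 100
  } else {
    idx <- match(paste(r$respondent_id, r$item_id),
                 paste(confidences$respondent_id, confidences$item_id))
    r$score <- confidences$confidence[idx]
  }
  aucs <- vapply(split(r, r$group), function(g) {
    if (length(unique(g$correct)) < 2L) return(NA_real_)
    roc_auc(g$score, g$correct)
  }, numeric(1))

  kappas <- lapply(split(r, r$group), function(g) {
    mat <- table(g$item_id, factor(g$selection, levels = LETTERS[1:5]))
    fleiss_kappa(unclass(as.matrix(mat)), ci = kappa_ci, seed = seed)
  })

  gt <- group_tests(split(scores$accuracy, scores$group))

  structure(list(
    respondents = scores,
    groups = group_summary,
    by_domain = strat("domain"),
    by_category = strat("category"),
    auc = aucs, roc_mode = roc_mode,
    fleiss = kappas,
    tests = gt,
    overall = list(
      responses = nrow(r), errors = sum(!r$correct),
      error_rate = accuracy_pct(sum(!r$correct), nrow(r)))
  ), class = "tg18_evaluation_report")
}

#' @export
print.tg18_evaluation_report <- function(x, ...) {
  cat("<tg18_evaluation_report>\n\nGroup accuracy\n")
  print(x$groups, row.names = FALSE)
  cat(sprintf("\nPooled: %d responses, %d errors (error rate %.1f%%)\n",
              x$overall$responses, x$overall$errors, x$overall$error_rate))
  cat("\nAUC by group (mode:", x$roc_mode, ")\n")
  print(round(x$auc, 3))
  cat("\nFleiss' kappa by group\n")
  print(vapply(x$fleiss, function(k) round(k$kappa, 3), numeric(1)))
  cat(sprintf("\nANOVA: F = %.3f (df %d, %d), p = %.4g\n",
              x$tests$anova$F, x$tests$anova$df[1], x$tests$anova$df[2],
              x$tests$anova$p))
  invisible(x)
}
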